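## Per-subject maximum-likelihood estimation over the discrete parameter
## grid, model comparison (likelihood ratio, BIC), parameter recovery, and
## the model-based 'perilous trustee' classifier.

#' One-step-ahead negative log likelihood of a subject's choices
#'
#' For each of the subject's decisions, the behavioural policy (planned
#' policy mixed with the irritated policy at the subject's current
#' irritation weight, given the dyad's actual prior history) is evaluated at
#' the observed action; the NLL is minus the sum of the log probabilities.
#' Forced trustee rounds (zero investment) contribute nothing. Predictive
#' probabilities are floored at 1e-12 before the log; the floor cannot bind
#' for finite softmax temperatures, so hitting it (e.g. with the beta = Inf
#' diagnostic sentinel) triggers a warning.
#'
#' @param params Candidate [tg_params()].
#' @param investments,repayments The dyad's observed rounds (amounts on the
#'   model grids; use [round_to_grid()] for raw data).
#' @return The NLL (numeric scalar) with attribute `p_obs`, the per-round
#'   predictive probabilities of the observed actions.
#' @examples
#' # a trustee who was never given anything has no free choices
#' p <- tg_params("trustee", alpha = 0, plan = 1, tom = 0, beta = 1,
#'                omega = 1, zeta = 0, awareness = 0)
#' tg_nll(p, rep(0, 10), rep(0, 10))  # 0
#' @export
tg_nll <- function(params, investments, repayments) {
  a <- tg_assess(params, investments, repayments)
  p <- a$p_obs
  free <- if (params$role == "trustee") !a$forced else rep(TRUE, length(p))
  if (any(p[free] < 1e-12)) {
    warning("predictive probability below 1e-12 clamped; ",
            "zero-probability observations cannot occur on the softmax grid")
    p <- pmax(p, 1e-12)
  }
  out <- -sum(log(p[free]))
  attr(out, "p_obs") <- a$p_obs
  attr(out, "forced") <- if (params$role == "trustee") a$forced
                         else rep(FALSE, length(p))
  out
}

#' Fit one subject by exhaustive maximum likelihood on the parameter grid
#'
#' Evaluates the one-step-ahead NLL of the subject's observed choices at
#' every point of a discrete parameter grid and returns the minimizer. Ties
#' are broken deterministically by the grid's lexicographic order (sorted by
#' alpha, plan, tom, beta, omega, zeta, awareness; the first minimum wins).
#'
#' @param record Either a data frame with columns `investment` and
#'   `repayment` (10 rounds of one dyad) or a numeric vector of investments
#'   (then `repayments` must be given).
#' @param role Which player of the record to fit.
#' @param grid A [tg_grid()] (defaults to the full 14400-point grid; use a
#'   reduced grid for desk-scale work).
#' @param repayments Repayment amounts when `record` is a vector.
#' @param keep_grid_nll Keep the full NLL vector over the grid?
#' @return An object of class `tg_fit`: best-fitting `params`, `nll`, `bic`
#'   (per-subject, [tg_bic()] with m = 10), `n_params`, per-round `p_obs`
#'   and `forced`, `m` (number of free choices), the `grid` and optionally
#'   `grid_nll`. Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `simulate`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' inv <- tg_params("investor", alpha = 0.4, plan = 1, tom = 0, beta = 1/3,
#'                  omega = 1, zeta = 0, awareness = 2)
#' tru <- tg_params("trustee", alpha = 1, plan = 1, tom = 0, beta = 1/3,
#'                  omega = 1, zeta = 0, awareness = 2)
#' sim <- tg_simulate(inv, tru, n_runs = 1, seed = 42)
#' d <- tg_dyad(sim)
#' fit <- tg_fit(d, role = "investor",
#'               grid = tg_grid("investor", plan = 1, tom = 0, beta = 1/3,
#'                              omega = 1, zeta = 0, awareness = 2))
#' coef(fit)
#' }
#' @export
tg_fit <- function(record, role = c("investor", "trustee"),
                   grid = tg_grid(role), repayments = NULL,
                   keep_grid_nll = FALSE) {
  role <- match.arg(role)
  if (is.data.frame(record)) {
    investments <- record$investment
    repayments <- record$repayment
  } else {
    investments <- record
  }
  stopifnot(!is.null(repayments))
  if (nrow(grid) < 1L) stop("empty parameter grid")
  if (!identical(attr(grid, "role"), role))
    stop("grid role does not match 'role'")
  nlls <- numeric(nrow(grid))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    p <- grid_row_params(grid, i)
    nlls[i] <- as.numeric(tg_nll(p, investments, repayments))
  }
  ibest <- which.min(nlls)  # first minimum: lexicographic tie-break
  params <- grid_row_params(grid, ibest)
  nb <- tg_nll(params, investments, repayments)
  n_params <- sum(vapply(
    c("alpha", "plan", "tom", "beta", "omega", "zeta", "awareness"),
    function(cn) length(unique(grid[[cn]])) > 1L, logical(1)))
  forced <- attr(nb, "forced")
  m <- sum(!forced)
  structure(list(params = params, nll = as.numeric(nb),
                 bic = tg_bic(as.numeric(nb), n_params = n_params, m = 10),
                 n_params = n_params,
                 p_obs = attr(nb, "p_obs"), forced = forced, m = m,
                 investments = investments, repayments = repayments,
                 role = role, grid = grid,
                 grid_nll = if (keep_grid_nll) nlls else NULL),
            class = "tg_fit")
}

#' @export
print.tg_fit <- function(x, ...) {
  cat(sprintf("<tg_fit> %s, NLL %.3f over %d free choice(s), BIC %.3f\n",
              x$role, x$nll, x$m, x$bic))
  print(x$params)
  invisible(x)
}

#' @export
summary.tg_fit <- function(object, ...) {
  cat(sprintf("Maximum-likelihood fit of a %s over %d grid points\n",
              object$role, nrow(object$grid)))
  print(object$params)
  cat(sprintf("  NLL %.4f  (chance: %d free choices x log 5 = %.4f)\n",
              object$nll, object$m, object$m * log(5)))
  cat(sprintf("  BIC %.4f with %d free parameters, m = 10\n",
              object$bic, object$n_params))
  cat(sprintf("  mean per-choice predictive probability %.3f\n",
              mean(object$p_obs[!object$forced])))
  invisible(object)
}

#' @export
coef.tg_fit <- function(object, ...) {
  p <- object$params
  c(alpha = p$alpha, plan = p$plan, tom = p$tom, beta = p$beta,
    omega = p$omega, zeta = p$zeta, awareness = p$awareness)
}

#' @export
logLik.tg_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, nobs = object$m,
            class = "logLik")
}

#' One-step-ahead predictions from a fitted subject
#'
#' @param object A [tg_fit()].
#' @param type `"prob"` for the per-round behavioural policy matrix,
#'   `"expected"` for the expected own action amount per round.
#' @param ... Unused.
#' @export
predict.tg_fit <- function(object, type = c("prob", "expected"), ...) {
  type <- match.arg(type)
  a <- tg_assess(object$params, object$investments, object$repayments)
  if (type == "prob") return(a$mixture)
  amounts <- t(vapply(1:10, function(r) {
    g <- if (object$role == "investor") tg_config()$investor_grid
         else tg_return_grid(object$investments[r])
    c(g, rep(0L, 5 - length(g)))
  }, numeric(5)))
  rowSums(a$mixture * amounts)
}

#' @export
residuals.tg_fit <- function(object, ...) {
  obs <- if (object$role == "investor") object$investments
         else object$repayments
  obs - predict(object, type = "expected")
}

#' @importFrom stats simulate
#' @export
simulate.tg_fit <- function(object, nsim = 200, seed = NULL, ...) {
  regenerate_trajectories(object$params, object$investments,
                          object$repayments, n_runs = nsim, seed = seed)
}

#' @export
plot.tg_fit <- function(x, nsim = 200, seed = 1, ...) {
  reg <- simulate(x, nsim = nsim, seed = seed)
  obs <- if (x$role == "investor") x$investments else x$repayments
  r <- 1:10
  graphics::plot(r, obs, type = "b", pch = 19, ylim = c(0, max(obs, 40)),
                 xlab = "round", ylab = "amount",
                 main = sprintf("one-step-ahead regeneration (%s)", x$role),
                 ...)
  graphics::polygon(c(r, rev(r)),
                    c(reg$mean - reg$sd, rev(reg$mean + reg$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(r, reg$mean, col = "steelblue", lwd = 2)
  invisible(x)
}

## --------------------------------------------------------- model comparison

#' Bayesian information criterion for grid fits
#'
#' Per subject, BIC = 2 * NLL + n * (log m - log 2 pi), summed over
#' subjects; n is the number of fitted parameters and m the number of data
#' points per subject (10 choices in the trust game). The log 2 pi term is
#' the small-sample correction appropriate for m this small.
#'
#' @param nll Vector of per-subject NLLs at the best-fitting parameters.
#' @param n_params Number of fitted parameters n.
#' @param m Data points per subject.
#' @return The summed BIC.
#' @examples
#' tg_bic(0, n_params = 7, m = 10)  # 7 * (log 10 - log 2*pi)
#' @export
tg_bic <- function(nll, n_params, m = 10) {
  stopifnot(n_params >= 0, m >= 1)
  sum(2 * nll + n_params * (log(m) - log(2 * pi)))
}

#' Likelihood ratio test between nested grid models
#'
#' The statistic sums 2 * (NLL_simple - NLL_rich) over subjects and is
#' compared against the chi-squared quantile at 1 - p with f degrees of
#' freedom (f = difference in parameter counts). With nested grids the
#' statistic is non-negative by construction.
#'
#' @param nll_simple,nll_rich Per-subject NLL vectors under the nested and
#'   the richer model.
#' @param df_diff Degrees-of-freedom difference f (>= 1).
#' @param p Significance threshold.
#' @return A list of class `tg_lrt`: `statistic`, `threshold`, `df`,
#'   `p_value`, and `accept_rich`.
#' @export
tg_lrt <- function(nll_simple, nll_rich, df_diff, p = 0.05) {
  stopifnot(length(nll_simple) == length(nll_rich), df_diff >= 1)
  stat <- sum(2 * (nll_simple - nll_rich))
  thr <- stats::qchisq(1 - p, df = df_diff)
  structure(list(statistic = stat, threshold = thr, df = df_diff,
                 p_value = stats::pchisq(stat, df = df_diff,
                                         lower.tail = FALSE),
                 accept_rich = stat > thr, n_subjects = length(nll_simple)),
            class = "tg_lrt")
}

#' @export
print.tg_lrt <- function(x, ...) {
  cat(sprintf(
    "<tg_lrt> statistic %.3f vs chi2 threshold %.3f (df %d, %d subject(s)): %s\n",
    x$statistic, x$threshold, x$df, x$n_subjects,
    if (x$accept_rich) "richer model accepted" else "simpler model retained"))
  invisible(x)
}

#' Classify a trustee as perilous
#'
#' A trustee is 'perilous' when totally guilt-free (alpha = 0) or
#' irritation-unaware (awareness q = 0), or both: either trait produces
#' exchanges that break down, deliberately (exploitation) or accidentally
#' (missed repair).
#'
#' @param params Trustee [tg_params()] (investors are rejected).
#' @return `"perilous"` or `"non-perilous"`.
#' @export
classify_perilous <- function(params) {
  stopifnot(inherits(params, "tg_params"))
  if (params$role != "trustee")
    stop("perilousness is defined for trustees only")
  if (params$alpha == 0 || params$awareness == 0) "perilous" else "non-perilous"
}

## ----------------------------------------------------------------- recovery

#' Parameter-recovery study on a synthetic cohort
#'
#' Fits every subject of a simulated cohort on a grid and tabulates, for
#' each parameter, the confusion matrix of true versus recovered grid
#' values. Row sums equal the number of simulated subjects at each true
#' value.
#'
#' @param cohort A [generate_cohort()] result.
#' @param role Which role to fit.
#' @param grid Fit grid ([tg_grid()]).
#' @param verbose Print progress?
#' @return A list of class `tg_recovery`: `fits` (data frame of true and
#'   recovered parameters plus NLL per subject) and `confusion` (named list
#'   of confusion matrices).
#' @export
recovery_study <- function(cohort, role = c("investor", "trustee"),
                           grid, verbose = FALSE) {
  role <- match.arg(role)
  stopifnot(inherits(cohort, "tg_cohort"))
  pfx <- if (role == "investor") "inv_" else "tru_"
  ids <- cohort$truth$dyad_id
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- cohort$records[cohort$records$dyad_id == ids[i], ]
    fit <- tg_fit(rec, role = role, grid = grid)
    est <- coef(fit)
    tru <- cohort$truth[i, paste0(pfx, names(est))]
    rows[[i]] <- data.frame(dyad_id = ids[i],
                            as.list(stats::setNames(as.numeric(tru),
                                                    paste0("true_",
                                                           names(est)))),
                            as.list(stats::setNames(as.numeric(est),
                                                    paste0("est_",
                                                           names(est)))),
                            nll = fit$nll)
    if (verbose) message("fitted ", ids[i], " (", i, "/", length(ids), ")")
  }
  fits <- do.call(rbind, rows)
  confusion <- lapply(
    stats::setNames(nm = c("alpha", "plan", "tom", "beta", "omega", "zeta",
                           "awareness")),
    function(par) {
      lev <- sort(unique(c(fits[[paste0("true_", par)]],
                           fits[[paste0("est_", par)]])))
      table(true = factor(fits[[paste0("true_", par)]], levels = lev),
            recovered = factor(fits[[paste0("est_", par)]], levels = lev))
    })
  structure(list(fits = fits, confusion = confusion, role = role),
            class = "tg_recovery")
}

#' @export
print.tg_recovery <- function(x, ...) {
  cat(sprintf("<tg_recovery> %d fitted %ss\n", nrow(x$fits), x$role))
  for (par in c("alpha", "zeta", "omega")) {
    cm <- x$confusion[[par]]
    if (sum(cm) == 0) next
    acc <- sum(diag(cm)) / sum(cm)
    cat(sprintf("  %s: diagonal fraction %.2f (chance %.2f)\n", par, acc,
                1 / nrow(cm)))
  }
  invisible(x)
}
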