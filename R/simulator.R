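## Dyad simulation: free-running, partially scripted (actions forced by
## fiat), and cohort-scale synthetic data generation.

#' Scenario: actions forced by fiat
#'
#' A scenario overrides the sampled action of either player in selected
#' rounds. Forced actions are observed by both players exactly as if they
#' had been chosen, so they drive belief updating and irritation like any
#' other action.
#'
#' @param forced_investments Length-10 vector of amounts; `NA` where the
#'   investor plays freely.
#' @param forced_repayments Length-10 vector of amounts; `NA` where the
#'   trustee plays freely. A forced repayment must be legal given the
#'   (possibly free) investment of its round.
#' @param description Free-text label.
#' @return An object of class `tg_scenario`.
#' @export
tg_scenario <- function(forced_investments = rep(NA_integer_, 10),
                        forced_repayments = rep(NA_integer_, 10),
                        description = "") {
  stopifnot(length(forced_investments) == 10, length(forced_repayments) == 10)
  fi <- as.integer(forced_investments)
  for (a in fi[!is.na(fi)]) check_investment(a)
  structure(list(forced_investments = fi,
                 forced_repayments = as.integer(forced_repayments),
                 description = description),
            class = "tg_scenario")
}

#' Scripted early-defection scenario
#'
#' The paired rupture/repair probe: round 1 is a scripted cooperative
#' exchange (full investment, fair half repaid: 20 in, 30 back), round 2
#' scripts a subpar repayment (20 in, only 10 = 1/6 back) to irritate an
#' irritable investor, and play is free from round 3 on. Run it with an
#' irritability-aware dyad (awareness q = 2) and with an ignorant dyad
#' (q = 0) to contrast repair against complete breaks.
#'
#' @return A [tg_scenario()].
#' @export
tg_scenario_rupture <- function() {
  tg_scenario(forced_investments = c(20L, 20L, rep(NA_integer_, 8)),
              forced_repayments = c(30L, 10L, rep(NA_integer_, 8)),
              description = "scripted cooperation then subpar repayment")
}

#' Simulate dyadic exchanges
#'
#' Plays out the 10-round game between two model subjects. Each round the
#' investor samples from their behavioural policy (the planned policy mixed
#' with the irritated policy at the current irritation weight), the trustee
#' observes the investment, updates, and samples likewise. A scenario can
#' force actions by fiat. Repeated runs share all deterministic planning
#' computations across identical histories.
#'
#' @param investor,trustee [tg_params()] objects for the two roles.
#' @param scenario Optional [tg_scenario()].
#' @param n_runs Number of independent exchanges.
#' @param seed Integer seed (required for reproducibility; sets R's RNG).
#' @param irritated_expectation See [irritated_policy()].
#' @return An object of class `tg_sim`: matrices `investments`, `repayments`
#'   (`n_runs` x 10, amounts), `v_investor`, `v_trustee` (irritation weights
#'   at each player's decision), plus the parameter objects and scenario.
#' @examples
#' inv <- tg_params("investor", alpha = 0.4, plan = 2, tom = 0, beta = 1/2,
#'                  omega = 1, zeta = 0.5, awareness = 2)
#' tru <- tg_params("trustee", alpha = 0.4, plan = 2, tom = 0, beta = 1/2,
#'                  omega = 1, zeta = 0, awareness = 2)
#' sim <- tg_simulate(inv, tru, n_runs = 3, seed = 1)
#' sim$investments
#' @export
tg_simulate <- function(investor, trustee, scenario = NULL, n_runs = 1,
                        seed = NULL,
                        irritated_expectation = c("distrust", "uniform")) {
  stopifnot(inherits(investor, "tg_params"), investor$role == "investor",
            inherits(trustee, "tg_params"), trustee$role == "trustee")
  irritated_expectation <- match.arg(irritated_expectation)
  if (is.null(scenario)) scenario <- tg_scenario()
  stopifnot(inherits(scenario, "tg_scenario"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fi <- scenario$forced_investments
  fr <- scenario$forced_repayments
  fi[is.na(fi)] <- -1L
  fr[is.na(fr)] <- -1L
  res <- cpp_simulate(params_ctx(investor, irritated_expectation),
                      params_ctx(trustee, irritated_expectation),
                      fi, fr, as.integer(n_runs))
  structure(list(investments = res$investments,
                 repayments = res$repayments,
                 v_investor = res$v_investor,
                 v_trustee = res$v_trustee,
                 investor = investor, trustee = trustee,
                 scenario = scenario, n_runs = n_runs),
            class = "tg_sim")
}

#' @export
print.tg_sim <- function(x, ...) {
  cat(sprintf("<tg_sim> %d simulated exchange(s), 10 rounds\n", x$n_runs))
  cat(sprintf("  mean total investment %.1f, mean total repayment %.1f\n",
              mean(rowSums(x$investments)), mean(rowSums(x$repayments))))
  if (nzchar(x$scenario$description))
    cat("  scenario:", x$scenario$description, "\n")
  invisible(x)
}

#' @export
plot.tg_sim <- function(x, run = 1, ...) {
  r <- seq_len(ncol(x$investments))
  inv <- x$investments[run, ]
  rep_ <- x$repayments[run, ]
  graphics::matplot(r, cbind(inv, rep_), type = "b", pch = c(19, 17),
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "round", ylab = "amount", ...)
  graphics::lines(r, 40 * x$v_investor[run, ], col = "goldenrod", lty = 2)
  graphics::legend("topright", c("investment", "repayment",
                                 "investor irritation (x40)"),
                   col = c("steelblue", "firebrick", "goldenrod"),
                   lty = c(1, 1, 2), pch = c(19, 17, NA), bty = "n")
  invisible(x)
}

#' Extract one run as a dyad record
#'
#' @param sim A [tg_simulate()] result.
#' @param run Run index.
#' @param dyad_id Identifier for the record.
#' @return A data frame of class `tg_dyad` with columns `dyad_id`, `round`
#'   (1-based), `investment`, `repayment`; the true parameters and the
#'   irritation traces are attached as attributes `investor`, `trustee`,
#'   `v_investor`, `v_trustee`.
#' @export
tg_dyad <- function(sim, run = 1, dyad_id = "dyad1") {
  stopifnot(inherits(sim, "tg_sim"), run >= 1, run <= sim$n_runs)
  out <- data.frame(dyad_id = dyad_id, round = 1:10,
                    investment = sim$investments[run, ],
                    repayment = sim$repayments[run, ])
  attr(out, "investor") <- sim$investor
  attr(out, "trustee") <- sim$trustee
  attr(out, "v_investor") <- sim$v_investor[run, ]
  attr(out, "v_trustee") <- sim$v_trustee[run, ]
  class(out) <- c("tg_dyad", "data.frame")
  out
}

#' One-step-ahead trajectory regeneration
#'
#' For each round, resimulates the fitted player's action conditional on the
#' dyad's actual prior history (the partner's actions and the player's own
#' past actions are taken from the record, not from the simulation). The
#' sampled trajectories estimate the model's per-round predictive
#' distribution; their mean and standard deviation are the shaded-band
#' summaries used to compare model and data.
#'
#' @param params Fitted [tg_params()] for the player being regenerated.
#' @param investments,repayments The dyad's actual 10-round record.
#' @param n_runs Number of resimulated trajectories.
#' @param seed Integer seed.
#' @return List: `prob` (10 x 5 analytic one-step-ahead policy),
#'   `actions` (10 x 5 matrix of the amounts the columns refer to),
#'   `samples` (`n_runs` x 10 sampled amounts), `mean`, `sd` (per round).
#' @export
regenerate_trajectories <- function(params, investments, repayments,
                                    n_runs = 200, seed = NULL) {
  stopifnot(n_runs >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- tg_assess(params, investments, repayments)
  acts <- matrix(0L, 10, 5)
  for (r in 1:10) {
    acts[r, ] <- if (params$role == "investor") tg_config()$investor_grid
    else c(tg_return_grid(investments[r]),
           integer(5 - length(tg_return_grid(investments[r]))))
  }
  samples <- matrix(0L, n_runs, 10)
  for (r in 1:10) {
    p <- a$mixture[r, ]
    samples[, r] <- acts[r, sample.int(5, n_runs, replace = TRUE, prob = p)]
  }
  list(prob = a$mixture, actions = acts, samples = samples,
       mean = colMeans(samples), sd = apply(samples, 2, stats::sd))
}

## ------------------------------------------------------------------ cohorts

#' Group specification for synthetic cohorts
#'
#' A group spec assigns sampling probabilities over the parameter grids of
#' both roles. The shipped presets emulate the composition the model-based
#' analysis attributes to clinical cohorts: trustees are "perilous" when
#' guilt-free (alpha = 0) or irritation-unaware (awareness q = 0), and the
#' preset prevalences are 0.29 for the healthy-control-like group and 0.60
#' for the borderline-like group. Perilousness is sampled exactly at the
#' target prevalence; all other parameters are drawn uniformly from the
#' supplied subgrids.
#'
#' @param name Group label.
#' @param perilous_prevalence Probability that a trustee is perilous.
#' @param alpha,plan,tom_investor,tom_trustee,beta,omega,zeta,awareness
#'   Candidate values for the uniform draws (defaults: modest desk-scale
#'   subgrids).
#' @return A list of class `tg_groupspec`.
#' @export
tg_group_spec <- function(name, perilous_prevalence = 0.29,
                          alpha = c(0, 0.4, 1), plan = 1:2,
                          tom_investor = c(0, 2), tom_trustee = c(0, 1),
                          beta = 1/3, omega = c(0.6, 1.0, 1.4, 1.8),
                          zeta = c(0, 0.5, 1), awareness = c(0, 2, 4)) {
  stopifnot(perilous_prevalence >= 0, perilous_prevalence <= 1)
  structure(list(name = name, perilous_prevalence = perilous_prevalence,
                 alpha = alpha, plan = plan, tom_investor = tom_investor,
                 tom_trustee = tom_trustee, beta = beta, omega = omega,
                 zeta = zeta, awareness = awareness),
            class = "tg_groupspec")
}

#' @rdname tg_group_spec
#' @export
tg_group_spec_hc <- function() tg_group_spec("HC-like", 0.29)

#' @rdname tg_group_spec
#' @export
tg_group_spec_bpd <- function() tg_group_spec("BPD-like", 0.60)

draw_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## Draw a (investor, trustee) parameter pair from a group spec.
draw_dyad_params <- function(spec) {
  inv <- tg_params("investor",
                   alpha = draw_one(spec$alpha), plan = draw_one(spec$plan),
                   tom = draw_one(spec$tom_investor),
                   beta = draw_one(spec$beta), omega = draw_one(spec$omega),
                   zeta = draw_one(spec$zeta),
                   awareness = draw_one(spec$awareness))
  perilous <- stats::runif(1) < spec$perilous_prevalence
  if (perilous) {
    branch <- sample(c("guiltless", "unaware", "both"), 1L,
                     prob = c(0.4, 0.4, 0.2))
    t_alpha <- if (branch %in% c("guiltless", "both")) 0
               else draw_one(setdiff(spec$alpha, 0))
    t_q <- if (branch %in% c("unaware", "both")) 0
           else draw_one(setdiff(spec$awareness, 0))
  } else {
    t_alpha <- draw_one(setdiff(spec$alpha, 0))
    t_q <- draw_one(setdiff(spec$awareness, 0))
  }
  tru <- tg_params("trustee",
                   alpha = t_alpha, plan = draw_one(spec$plan),
                   tom = draw_one(spec$tom_trustee),
                   beta = draw_one(spec$beta), omega = draw_one(spec$omega),
                   zeta = draw_one(spec$zeta), awareness = t_q)
  list(investor = inv, trustee = tru)
}

#' Generate a synthetic cohort of dyads
#'
#' Draws dyads independently from one or more group specifications and
#' simulates each exchange once. Per-dyad seeds are derived from the master
#' seed by counter, so any single dyad can be regenerated in isolation.
#'
#' @param groups List of [tg_group_spec()] objects.
#' @param n_per_group Integer vector, dyads per group.
#' @param seed Master integer seed.
#' @return A list of class `tg_cohort`: `records` (long data frame with
#'   columns dyad_id, group, round, investment, repayment) and `truth`
#'   (one row per dyad with the true parameters of both players).
#' @export
generate_cohort <- function(groups, n_per_group, seed) {
  if (inherits(groups, "tg_groupspec")) groups <- list(groups)
  stopifnot(length(groups) == length(n_per_group))
  seed <- as.integer(seed)
  set.seed(seed)
  param_list <- list()
  meta <- list()
  id <- 0L
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group[g])) {
      id <- id + 1L
      param_list[[id]] <- draw_dyad_params(groups[[g]])
      meta[[id]] <- groups[[g]]$name
    }
  }
  records <- vector("list", id)
  truth <- vector("list", id)
  for (i in seq_len(id)) {
    set.seed((seed + 7919L * i) %% 2147483647L)
    pp <- param_list[[i]]
    sim <- tg_simulate(pp$investor, pp$trustee, n_runs = 1, seed = NULL)
    did <- sprintf("dyad%03d", i)
    records[[i]] <- data.frame(dyad_id = did, group = meta[[i]], round = 1:10,
                               investment = sim$investments[1, ],
                               repayment = sim$repayments[1, ])
    pi_ <- pp$investor; pt <- pp$trustee
    truth[[i]] <- data.frame(
      dyad_id = did, group = meta[[i]],
      inv_alpha = pi_$alpha, inv_plan = pi_$plan, inv_tom = pi_$tom,
      inv_beta = pi_$beta, inv_omega = pi_$omega, inv_zeta = pi_$zeta,
      inv_awareness = pi_$awareness,
      tru_alpha = pt$alpha, tru_plan = pt$plan, tru_tom = pt$tom,
      tru_beta = pt$beta, tru_omega = pt$omega, tru_zeta = pt$zeta,
      tru_awareness = pt$awareness)
  }
  structure(list(records = do.call(rbind, records),
                 truth = do.call(rbind, truth), seed = seed),
            class = "tg_cohort")
}

#' @export
print.tg_cohort <- function(x, ...) {
  n <- nrow(x$truth)
  per <- mean(x$truth$tru_alpha == 0 | x$truth$tru_awareness == 0)
  cat(sprintf("<tg_cohort> %d dyads (%s); perilous trustee prevalence %.2f\n",
              n, paste(unique(x$truth$group), collapse = ", "), per))
  invisible(x)
}

#' Read and write scenario files
#'
#' Scenarios serialize as JSON (default) or YAML (by file extension, when the
#' yaml package is available): fields `forced_investments`,
#' `forced_repayments` (length 10, `null` where play is free) and
#' `description`.
#'
#' @param scenario A [tg_scenario()].
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `read_scenario()` returns a `tg_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "tg_scenario"))
  x <- list(forced_investments = scenario$forced_investments,
            forced_repayments = scenario$forced_repayments,
            description = scenario$description)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML scenario files")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                         na = "null", pretty = TRUE)
  }
  invisible(scenario)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML scenario files")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  norm <- function(v) {
    v <- unlist(lapply(v, function(e) if (is.null(e)) NA_integer_ else e))
    length(v) <- 10L
    as.integer(v)
  }
  tg_scenario(norm(x$forced_investments), norm(x$forced_repayments),
              description = if (is.null(x$description)) "" else x$description)
}

## --------------------------------------------------------------------- I/O

#' Read and write dyad records as CSV
#'
#' One row per round with 1-based round numbers; amounts are stored as
#' integers. Any extra columns (group labels, true parameters) round-trip
#' unchanged.
#'
#' @param records Data frame with columns `dyad_id`, `round`, `investment`,
#'   `repayment` (e.g. `tg_cohort$records` or a [tg_dyad()]).
#' @param path File path.
#' @return `read_dyads()` returns the data frame; `write_dyads()` its input,
#'   invisibly.
#' @export
write_dyads <- function(records, path) {
  stopifnot(all(c("dyad_id", "round", "investment", "repayment")
                %in% names(records)))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(records)
}

#' @rdname write_dyads
#' @export
read_dyads <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dyad_id", "round", "investment", "repayment")
                %in% names(df)))
  df
}
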