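## Subject parameter vectors and the discrete parameter grids they live on.

## The canonical parameter grids of the full model.
tg_grids <- function(role = c("investor", "trustee")) {
  role <- match.arg(role)
  list(
    alpha     = c(0, 0.4, 1),
    plan      = 1:4,
    tom       = if (role == "investor") c(0L, 2L, 4L) else c(0L, 1L, 3L),
    beta      = c(1, 1/2, 1/3, 1/4),
    omega     = seq(0.4, 1.8, by = 0.2),
    zeta      = c(0, 0.25, 0.5, 0.75, 1),
    awareness = 0:4
  )
}

#' Subject parameter configuration
#'
#' The full 7-parameter description of one player: guilt `alpha` (advantageous
#' inequality aversion, 0/0.4/1), planning horizon `plan` (1..4 future own
#' decision rounds), theory-of-mind level `tom` (investors reason at even
#' levels 0/2/4, trustees at 0/1/3), softmax inverse temperature `beta`
#' (1, 1/2, 1/3, 1/4), risk aversion `omega` (the investor's own multiplicative
#' weight on kept endowment, or for trustees the fixed belief b(omega) about
#' the investor's value; 0.4 to 1.8 in steps of 0.2), irritability `zeta`
#' (step size of the irritation weight, 0 to 1 in steps of 0.25) and
#' irritability awareness `awareness` (index 0..4 selecting the prior over the
#' partner's irritability, from ignorant to fatalistic, see
#' [irritability_prior()]).
#'
#' @param role `"investor"` or `"trustee"`.
#' @param alpha,plan,tom,beta,omega,zeta,awareness Parameter values on their
#'   grids (see above). `beta = Inf` is accepted as a diagnostic sentinel for
#'   the deterministic argmax policy.
#' @param validate If `FALSE`, skip grid membership checks (used for
#'   irritated variants and sensitivity analyses).
#' @return An object of class `tg_params`.
#' @examples
#' tg_params("investor", alpha = 0.4, plan = 4, tom = 2, beta = 1/3,
#'           omega = 1, zeta = 0.5, awareness = 2)
#' @export
tg_params <- function(role = c("investor", "trustee"), alpha, plan, tom,
                      beta, omega, zeta = 0, awareness = 2,
                      validate = TRUE) {
  role <- match.arg(role)
  g <- tg_grids(role)
  near <- function(x, set) any(abs(x - set) < 1e-9)
  if (validate) {
    if (!near(alpha, g$alpha)) stop("alpha must be one of {0, 0.4, 1}")
    if (!near(plan, g$plan)) stop("plan must be one of {1, 2, 3, 4}")
    if (!near(tom, g$tom))
      stop("tom must be one of {", paste(g$tom, collapse = ","), "} for the ",
           role)
    if (!is.infinite(beta) && !near(beta, g$beta))
      stop("beta must be one of {1, 1/2, 1/3, 1/4} (or Inf)")
    if (!near(omega, g$omega)) stop("omega must be on the grid 0.4..1.8 by 0.2")
    if (!near(zeta, g$zeta)) stop("zeta must be one of {0, 0.25, 0.5, 0.75, 1}")
    if (!near(awareness, g$awareness)) stop("awareness must be in 0..4")
  }
  structure(list(role = role, alpha = alpha, plan = as.integer(plan),
                 tom = as.integer(tom), beta = beta, omega = omega,
                 zeta = zeta, awareness = as.integer(awareness),
                 irritated = FALSE),
            class = "tg_params")
}

#' @export
print.tg_params <- function(x, ...) {
  cat(sprintf(
    "<tg_params> %s%s: alpha=%g P=%d k=%d beta=%g %s=%g zeta=%g q=%d\n",
    x$role, if (isTRUE(x$irritated)) " (irritated)" else "",
    x$alpha, x$plan, x$tom, x$beta,
    if (x$role == "investor") "omega" else "b(omega)", x$omega,
    x$zeta, x$awareness))
  invisible(x)
}

#' Discrete parameter grid for fitting
#'
#' Expands a (sub)grid of the model's parameter space into a data frame, one
#' row per candidate parameter vector, in a deterministic lexicographic order
#' (sorted by alpha, plan, tom, beta, omega, zeta, awareness). Maximum-
#' likelihood ties are broken by taking the first row in this order.
#'
#' @param role `"investor"` or `"trustee"`.
#' @param alpha,plan,tom,beta,omega,zeta,awareness Vectors of candidate
#'   values; each must be a subset of the canonical grid for the role.
#'   Defaults are the full grids (14400 points).
#' @return A data frame of class `tg_grid` with one column per parameter.
#' @export
tg_grid <- function(role = c("investor", "trustee"),
                    alpha = NULL, plan = NULL, tom = NULL, beta = NULL,
                    omega = NULL, zeta = NULL, awareness = NULL) {
  role <- match.arg(role)
  g <- tg_grids(role)
  pick <- function(x, full, nm) {
    if (is.null(x)) return(full)
    if (!all(vapply(x, function(v) any(abs(v - full) < 1e-9), logical(1))))
      stop("'", nm, "' values must be a subset of the canonical grid")
    sort(unique(x))
  }
  df <- expand.grid(
    awareness = pick(awareness, g$awareness, "awareness"),
    zeta      = pick(zeta, g$zeta, "zeta"),
    omega     = pick(omega, g$omega, "omega"),
    beta      = pick(beta, g$beta, "beta"),
    tom       = pick(tom, g$tom, "tom"),
    plan      = pick(plan, g$plan, "plan"),
    alpha     = pick(alpha, g$alpha, "alpha"),
    KEEP.OUT.ATTRS = FALSE)
  df <- df[, c("alpha", "plan", "tom", "beta", "omega", "zeta", "awareness")]
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "role") <- role
  class(df) <- c("tg_grid", "data.frame")
  df
}

## Row of a tg_grid -> tg_params
grid_row_params <- function(grid, i) {
  r <- grid[i, ]
  tg_params(attr(grid, "role"), alpha = r$alpha, plan = r$plan, tom = r$tom,
            beta = r$beta, omega = r$omega, zeta = r$zeta,
            awareness = r$awareness)
}
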