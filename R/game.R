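## Game rules of the 10-round multi-round trust task (MRT) on the coarse
## 5 x 5 action grid, and the utility transformations built on it.

#' Game configuration for the multi-round trust task
#'
#' The task is played over 10 sequential rounds. Each round the investor
#' receives an endowment of 20 monetary units and sends a fraction of it
#' (0, 1/4, 1/2, 3/4 or 1) to the trustee; the experimenter triples the
#' amount in transit; the trustee returns a fraction (0, 1/6, 1/3, 1/2 or
#' 2/3) of what was received. When the investment is 0 the trustee has no
#' choice but to return 0.
#'
#' @param endowment Monetary units handed to the investor each round.
#' @param multiplier Experimenter's factor applied to the investment.
#' @param n_rounds Number of rounds per exchange.
#' @return An object of class `tg_config`: a list with the constants above
#'   plus `investor_fractions`, `trustee_fractions`, the integer investor
#'   action grid `investor_grid`, and `return_grid(aI)` amounts accessible
#'   via [tg_return_grid()].
#' @examples
#' cfg <- tg_config()
#' cfg$investor_grid
#' @export
tg_config <- function(endowment = 20, multiplier = 3, n_rounds = 10) {
  stopifnot(endowment > 0, multiplier >= 1, n_rounds >= 1)
  inv_frac <- c(0, 1/4, 1/2, 3/4, 1)
  tru_frac <- c(0, 1/6, 1/3, 1/2, 2/3)
  structure(list(
    endowment = endowment,
    multiplier = multiplier,
    n_rounds = n_rounds,
    investor_fractions = inv_frac,
    trustee_fractions = tru_frac,
    investor_grid = as.integer(round(inv_frac * endowment))
  ), class = "tg_config")
}

## Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Trustee return grid for a given investment
#'
#' Returns the five integer repayment amounts available to the trustee after
#' an investment `aI`: the trustee fractions of `multiplier * aI`, rounded to
#' the nearest integer (halves away from zero). With the default
#' configuration the grids are: aI = 0 -> \{0\}; 5 -> \{0, 3, 5, 8, 10\};
#' 10 -> \{0, 5, 10, 15, 20\}; 15 -> \{0, 8, 15, 23, 30\};
#' 20 -> \{0, 10, 20, 30, 40\}. Only the 1/6 and 1/3 fractions of the odd
#' received amounts (15 and 45) need rounding.
#'
#' @param aI Investment amount on the investor grid.
#' @param config A [tg_config()] object.
#' @return Integer vector of legal repayments (length 1 when `aI == 0`).
#' @export
tg_return_grid <- function(aI, config = tg_config()) {
  aI <- check_investment(aI, config)
  if (aI == 0) return(0L)
  as.integer(round_half_up(config$trustee_fractions * config$multiplier * aI))
}

check_investment <- function(aI, config = tg_config()) {
  if (length(aI) != 1L || is.na(aI) || !(aI %in% config$investor_grid))
    stop("invalid-action: investment must lie on the investor grid {",
         paste(config$investor_grid, collapse = ","), "}", call. = FALSE)
  aI
}

check_repayment <- function(aI, aT, config = tg_config()) {
  if (length(aT) != 1L || is.na(aT) || aT < 0 || aT > config$multiplier * aI)
    stop("invalid-action: repayment must lie in [0, ", config$multiplier,
         "*aI]", call. = FALSE)
  aT
}

#' Monetary payoffs of one round
#'
#' The investor keeps the unsent endowment and receives the repayment:
#' chi_I = 20 - aI + aT. The trustee keeps what was received minus the
#' repayment: chi_T = 3 aI - aT. For every legal action pair the joint
#' payoff is chi_I + chi_T = 20 + 2 aI.
#'
#' @param aI Investment on the investor grid.
#' @param aT Repayment, between 0 and `multiplier * aI`.
#' @param config A [tg_config()] object.
#' @return Monetary payoff (numeric scalar).
#' @export
payoff_investor <- function(aI, aT, config = tg_config()) {
  aI <- check_investment(aI, config); aT <- check_repayment(aI, aT, config)
  config$endowment - aI + aT
}

#' @rdname payoff_investor
#' @export
payoff_trustee <- function(aI, aT, config = tg_config()) {
  aI <- check_investment(aI, config); aT <- check_repayment(aI, aT, config)
  config$multiplier * aI - aT
}

#' Fehr-Schmidt utility with guilt and (investor) risk aversion
#'
#' Subjective round utility. Both roles feel guilt `alpha` about advantageous
#' inequality: each point by which the own monetary payoff exceeds the
#' partner's is penalized by `alpha`. The investor additionally weights the
#' kept endowment by the risk-aversion factor `omega`, so her risk-weighted
#' payoff is omega * (20 - aI) + aT. The guilt comparison is made on the raw
#' monetary payoffs, not the omega-weighted ones: risk aversion redefines the
#' value of money kept, not the fairness ledger.
#'
#' @param role `"investor"` or `"trustee"`.
#' @param aI,aT Actions (amounts).
#' @param alpha Guilt, one of 0, 0.4, 1.
#' @param omega Risk aversion (investor only), one of the 8 grid values
#'   0.4, 0.6, ..., 1.8. Ignored for the trustee.
#' @param config A [tg_config()] object.
#' @return Utility value (numeric scalar).
#' @examples
#' tg_utility("trustee", 10, 15, alpha = 1)        # 15: no advantageous inequality
#' tg_utility("investor", 10, 15, alpha = 1, omega = 1)  # 25 - 10 = 15
#' @export
tg_utility <- function(role = c("investor", "trustee"), aI, aT,
                       alpha, omega = 1, config = tg_config()) {
  role <- match.arg(role)
  chiI <- payoff_investor(aI, aT, config)
  chiT <- payoff_trustee(aI, aT, config)
  if (role == "investor") {
    omega * (config$endowment - aI) + aT - alpha * max(chiI - chiT, 0)
  } else {
    chiT - alpha * max(chiT - chiI, 0)
  }
}

#' Irritated-state parameter transform
#'
#' An irritated player abandons planning and other-regard: planning horizon
#' P = 0, guilt alpha = 0, inverse temperature beta = 1/2, and beliefs about
#' the partner are disregarded. For investors the risk aversion under
#' irritation is bounded below at 1, `omega_irr = max(1, omega)`, which
#' guarantees punishing (zero-investment-leaning) behaviour. Theory-of-mind
#' level and irritability itself are untouched. Idempotent.
#'
#' @param params A [tg_params()] object.
#' @return A `tg_params` object describing the irritated variant, with an
#'   `irritated` flag set.
#' @export
irritated_params <- function(params) {
  stopifnot(inherits(params, "tg_params"))
  params$plan <- 0L
  params$alpha <- 0
  params$beta <- 0.5
  if (params$role == "investor") params$omega <- max(1, params$omega)
  params$irritated <- TRUE
  params
}

#' Round a raw action to the model grid
#'
#' Real subjects act on a fine monetary scale; the model works on the coarse
#' grid. Raw actions are mapped to the nearest grid amount; exact midpoints
#' round upward (deterministic; midpoints cannot occur for integer raw
#' investor actions).
#'
#' @param raw_action Raw amount within the legal range.
#' @param grid Increasing vector of grid amounts (e.g. `tg_config()$investor_grid`
#'   or [tg_return_grid()]).
#' @return The nearest grid amount.
#' @examples
#' round_to_grid(12, c(0, 5, 10, 15, 20))  # 10
#' round_to_grid(13, c(0, 5, 10, 15, 20))  # 15
#' @export
round_to_grid <- function(raw_action, grid) {
  if (length(raw_action) != 1L || is.na(raw_action) ||
      raw_action < min(grid) || raw_action > max(grid))
    stop("raw action ", raw_action, " outside the legal range [",
         min(grid), ",", max(grid), "]", call. = FALSE)
  d <- abs(grid - raw_action)
  ## ties round upward: among minimal distances take the largest amount
  grid[max(which(d == min(d)))]
}
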