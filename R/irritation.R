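## Own-state irritation dynamics: favourability classification of partner
## actions, the subject's own irritation weight, and the irritated policy.

#' Softmax action selection
#'
#' Converts action values Q into choice probabilities proportional to
#' exp(beta * Q). `beta = Inf` yields the deterministic limit: probability 1
#' on the maximizing action, or uniform over all maximizers when tied.
#'
#' @param q Numeric vector of action values.
#' @param beta Inverse temperature, > 0 or `Inf`.
#' @return Probability vector of the same length as `q`.
#' @export
softmax_policy <- function(q, beta) {
  stopifnot(beta > 0)
  if (is.infinite(beta)) {
    top <- abs(q - max(q)) < 1e-10
    return(top / sum(top))
  }
  e <- exp(beta * (q - max(q)))
  e / sum(e)
}

#' Classify a partner action as favorable, unfavorable or neutral
#'
#' The comparison is against the monetary value the observer expected the
#' partner's action to have under their full current partner model (the
#' posterior-predictive mean amount, including the partner's potential
#' irritation), computed before the action is observed. Forced moves (the
#' trustee's return after a zero investment) are neutral by definition.
#'
#' @param observed Monetary amount of the observed partner action.
#' @param expectation Expected monetary amount.
#' @param forced Was the partner's move forced?
#' @return `"unfavorable"`, `"favorable"` or `"neutral"`.
#' @export
classify_action <- function(observed, expectation, forced = FALSE) {
  if (isTRUE(forced)) return("neutral")
  if (observed < expectation) "unfavorable"
  else if (observed > expectation) "favorable"
  else "neutral"
}

#' Own irritation state and its update
#'
#' A subject's irritation weight v starts at 0 and moves in steps of their
#' irritability zeta: up (clipped at 1) after an unfavorable partner action,
#' down (clipped at 0) after a favorable one, unchanged otherwise. A zeta = 0
#' subject never becomes irritated; a zeta = 1 subject saturates after a
#' single unfavorable action.
#'
#' @param zeta Irritability on its grid \{0, 0.25, 0.5, 0.75, 1\}.
#' @param v Current irritation weight in \[0, 1\].
#' @return `own_irritation()` returns a list of class `tg_irritation`;
#'   `update_own_irritation()` the updated state.
#' @export
own_irritation <- function(zeta, v = 0) {
  stopifnot(any(abs(zeta - c(0, 0.25, 0.5, 0.75, 1)) < 1e-9),
            v >= 0, v <= 1)
  structure(list(zeta = zeta, v = v), class = "tg_irritation")
}

#' @rdname own_irritation
#' @param state A `tg_irritation` object.
#' @param favourability Result of [classify_action()].
#' @export
update_own_irritation <- function(state,
    favourability = c("neutral", "unfavorable", "favorable")) {
  stopifnot(inherits(state, "tg_irritation"))
  favourability <- match.arg(favourability)
  state$v <- switch(favourability,
    unfavorable = min(state$v + state$zeta, 1),
    favorable   = max(state$v - state$zeta, 0),
    neutral     = state$v)
  state
}

#' Irritated policy
#'
#' The policy of a player in the irritated state: guilt-free, myopic
#' (current round only), inverse temperature 1/2, and in complete disregard
#' of accumulated beliefs about the partner. By default the irritated player
#' assumes maximal distrust -- no forthcoming return (investor) and no value
#' beyond the current round (trustee) -- so the modal action is to send
#' nothing. The irritated investor's risk aversion is bounded below at 1.
#' The `"uniform"` alternative replaces maximal distrust with a uniform
#' partner-response assumption for sensitivity analyses.
#'
#' @param role `"investor"`, or `"trustee"`.
#' @param aI For the trustee: the current investment (determines the return
#'   grid). Ignored for the investor.
#' @param omega Investor risk aversion (bounded below at 1 internally).
#' @param expectation `"distrust"` (default) or `"uniform"`.
#' @param config A [tg_config()] object.
#' @return Probability vector over the role's 5 actions (over the return
#'   grid of `aI` for the trustee).
#' @export
irritated_policy <- function(role = c("investor", "trustee"), aI = NULL,
                             omega = 1, expectation = c("distrust", "uniform"),
                             config = tg_config()) {
  role <- match.arg(role)
  expectation <- match.arg(expectation)
  if (role == "investor") {
    wi <- max(1, omega)
    q <- wi * (config$endowment - config$investor_grid)
    if (expectation == "uniform")
      q <- q + vapply(config$investor_grid,
                      function(a) mean(tg_return_grid(a, config)), numeric(1))
  } else {
    grid <- tg_return_grid(check_investment(aI, config), config)
    q <- config$multiplier * aI - grid
  }
  softmax_policy(q, beta = 0.5)
}

#' Mix non-irritated and irritated policies
#'
#' The behavioural policy is the convex combination
#' (1 - v) * pi_nonirr + v * pi_irr with the current irritation weight v.
#'
#' @param pi_nonirr,pi_irr Probability vectors of equal length.
#' @param v Irritation weight in \[0, 1\].
#' @return Probability vector.
#' @export
mix_policies <- function(pi_nonirr, pi_irr, v) {
  stopifnot(length(pi_nonirr) == length(pi_irr), v >= 0, v <= 1)
  (1 - v) * pi_nonirr + v * pi_irr
}
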