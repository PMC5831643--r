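## R surface of the deterministic shared-tree planner.

## Build the C++ engine context from a tg_params object.
params_ctx <- function(params, irritated_expectation = c("distrust", "uniform"),
                       max_nodes = 2e6) {
  stopifnot(inherits(params, "tg_params"))
  irritated_expectation <- match.arg(irritated_expectation)
  list(role = if (params$role == "investor") 0L else 1L,
       k = params$tom, P = params$plan, beta = params$beta,
       omega = params$omega, zeta = params$zeta, q = params$awareness,
       alpha = params$alpha,
       irr_mode = if (irritated_expectation == "uniform") 1L else 0L,
       max_nodes = max_nodes)
}

## Validate a (partial) history of amounts; returns list of integer vectors.
check_history <- function(investments, repayments, config = tg_config()) {
  investments <- as.integer(investments)
  repayments <- as.integer(repayments)
  if (length(investments) != length(repayments))
    stop("investments and repayments must have equal length")
  if (length(investments) > config$n_rounds)
    stop("history longer than ", config$n_rounds, " rounds")
  for (r in seq_along(investments)) {
    check_investment(investments[r], config)
    if (!(repayments[r] %in% tg_return_grid(investments[r], config)))
      stop("round ", r, ": repayment ", repayments[r],
           " not on the return grid for investment ", investments[r])
  }
  list(investments = investments, repayments = repayments)
}

#' Planned, irritated and behavioural policies at the current decision
#'
#' Runs the deterministic shared-tree planner for a subject at the decision
#' node reached after a (possibly empty) history of completed rounds. The
#' planner builds a single game tree of depth `min(plan, rounds left)`;
#' within it, beliefs about the partner's guilt and irritability are filtered
#' along every branch, the partner's hypothetical irritation is propagated by
#' the rupture/repair dynamics, and every theory-of-mind level below the
#' subject's is evaluated bottom-up inside the same tree (each level's
#' policies are kept in memory for the level above, so cost grows linearly
#' with the level).
#'
#' @param params Subject parameters ([tg_params()]).
#' @param investments,repayments Amounts of the completed rounds (equal
#'   length, possibly empty).
#' @param current_investment For trustee subjects: this round's observed
#'   investment (required; their decision node lies after it).
#' @param irritated_expectation Partner assumption of the irritated policy,
#'   see [irritated_policy()].
#' @return A list: `planned` (softmax policy of the non-irritated planner),
#'   `irritated`, `mixture` (behavioural policy, mixed at the subject's
#'   current irritation weight `v_decision`), `q_values`, `pred_partner`
#'   (predicted partner action distribution; for investors a 5x5 matrix,
#'   one row per hypothetical investment), `expectation` (expected monetary
#'   value of the partner's action) and `forced`.
#' @examples
#' p <- tg_params("investor", alpha = 0.4, plan = 2, tom = 0, beta = 1/3,
#'                omega = 1, zeta = 0, awareness = 2)
#' tg_policy(p)$planned
#' @export
tg_policy <- function(params, investments = integer(0),
                      repayments = integer(0), current_investment = NULL,
                      irritated_expectation = c("distrust", "uniform")) {
  h <- check_history(investments, repayments)
  aI <- -1L
  if (params$role == "trustee") {
    if (is.null(current_investment))
      stop("trustee policies require 'current_investment'")
    aI <- as.integer(check_investment(current_investment))
  }
  res <- cpp_policy(params_ctx(params, match.arg(irritated_expectation)),
                    h$investments, h$repayments, aI)
  if (params$role == "trustee")
    res$actions <- tg_return_grid(aI)
  else
    res$actions <- tg_config()$investor_grid
  res
}

#' Action values at the current decision
#'
#' The expected sum of own round utilities over the planning horizon, one
#' value per available action, computed by the shared-tree planner (see
#' [tg_policy()]). The softmax of these values at the subject's inverse
#' temperature is the planned policy.
#'
#' @inheritParams tg_policy
#' @return Named numeric vector of Q-values (names are action amounts).
#' @export
tg_q_values <- function(params, investments = integer(0),
                        repayments = integer(0), current_investment = NULL,
                        irritated_expectation = c("distrust", "uniform")) {
  res <- tg_policy(params, investments, repayments, current_investment,
                   irritated_expectation)
  q <- res$q_values[seq_along(res$actions)]
  names(q) <- res$actions
  q
}

#' One-step-ahead assessment of a subject along an observed exchange
#'
#' Replays a complete (or partial) dyadic record from the subject's
#' perspective: at every round the planner is run on the actual prior
#' history, giving the behavioural policy, the probability assigned to the
#' action the subject actually took, the evolving irritation weight, and the
#' expectations that drive rupture and repair. This is the model's
#' one-step-ahead prediction protocol, and the basis of the likelihood used
#' for fitting.
#'
#' @inheritParams tg_policy
#' @return A list of per-round matrices/vectors: `planned`, `irritated`,
#'   `mixture` (rows = rounds, columns = the 5 actions), `pred_partner`,
#'   `q_values`, `v` (irritation weight at the subject's decision),
#'   `expectation`, `p_obs` (behavioural probability of the observed own
#'   action), `forced` (trustee rounds with zero investment).
#' @export
tg_assess <- function(params, investments, repayments,
                      irritated_expectation = c("distrust", "uniform")) {
  h <- check_history(investments, repayments)
  cpp_assess(params_ctx(params, match.arg(irritated_expectation)),
             h$investments, h$repayments)
}

#' Shared-tree size and pass structure
#'
#' Reports the number of tree nodes the planner visits for a decision at a
#' given round (depends only on the planning horizon) and the number of
#' level passes over that shared tree (one per theory-of-mind level, which
#' is what makes the computation linear in the level).
#'
#' @inheritParams tg_policy
#' @param round Round of the decision (1-based).
#' @return List with `n_slots`, `n_level_passes` and the horizon `H`.
#' @export
tg_tree_stats <- function(params, round = 1) {
  cpp_tree_stats(params_ctx(params), as.integer(round))
}
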