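## Intentional inference: Dirichlet-multinomial beliefs over the partner's
## guilt and irritability, and the per-hypothesis track of the partner's
## current irritation weight.

GUILT_VALUES <- c(0, 0.4, 1)
ZETA_VALUES  <- c(0, 0.25, 0.5, 0.75, 1)

#' Prior Dirichlet weights over the partner's irritability
#'
#' The awareness parameter q selects one of five prior belief settings over
#' the partner's irritability zeta in \{0, 0.25, 0.5, 0.75, 1\}: ignorant
#' (q=0: essentially certain the partner is non-irritable), optimistic (q=1),
#' realistic (q=2), pessimistic (q=3) and fatalistic (q=4: essentially
#' certain the partner is maximally irritable).
#'
#' @param q Awareness index in 0..4.
#' @return Numeric vector of 5 Dirichlet weights.
#' @examples
#' irritability_prior(0)  # c(400, 0.1, 0.1, 0.1, 0.1)
#' @export
irritability_prior <- function(q) {
  stopifnot(length(q) == 1L, q %in% 0:4)
  rows <- rbind(
    c(400, 0.1, 0.1, 0.1, 0.1),
    c(4, 0.5, 0.5, 0.5, 0.5),
    c(0.4, 0.1, 0.1, 0.1, 0.1),
    c(2, 1, 1, 1, 1),
    c(0.1, 0.1, 0.1, 0.1, 400))
  rows[q + 1L, ]
}

#' Initial belief state about a partner
#'
#' A factorized belief: a symmetric Dirichlet-multinomial over the partner's
#' guilt (weights (1,1,1) over alpha in \{0, 0.4, 1\}), a Dirichlet-
#' multinomial over the partner's irritability with prior selected by the
#' awareness index `q`, and a deterministic track of the partner's current
#' irritation weight under each irritability hypothesis (all starting at 0).
#' Guilt and irritability are inferred independently; the track is a pure
#' function of the favourability history.
#'
#' @param q Awareness index in 0..4.
#' @return A list of class `tg_belief` with components `guilt` (3 Dirichlet
#'   weights), `irritability` (5 Dirichlet weights), `q`, and `track`
#'   (5 irritation weights, one per zeta hypothesis).
#' @export
tg_belief <- function(q = 2) {
  structure(list(guilt = c(1, 1, 1), irritability = irritability_prior(q),
                 q = as.integer(q), track = rep(0, 5)),
            class = "tg_belief")
}

#' Additive Dirichlet belief updates
#'
#' The posterior over a partner trait is approximated by incrementing each
#' Dirichlet weight with the likelihood that the partner model assigns to the
#' observed action under the corresponding trait value:
#' d_i <- d_i + P(observed action | trait_i). Forced moves (the trustee's
#' return after a zero investment) carry no information and must be skipped
#' by the caller.
#'
#' @param belief A [tg_belief()] object.
#' @param obs_likelihoods Probability of the observed action under each trait
#'   value: length 3 (guilt) or 5 (irritability), values in \[0, 1\].
#' @return The updated `tg_belief`.
#' @export
update_guilt <- function(belief, obs_likelihoods) {
  stopifnot(inherits(belief, "tg_belief"), length(obs_likelihoods) == 3L)
  if (any(obs_likelihoods < 0 | obs_likelihoods > 1))
    stop("likelihoods must lie in [0, 1]")
  belief$guilt <- belief$guilt + obs_likelihoods
  belief
}

#' @rdname update_guilt
#' @export
update_irritability <- function(belief, obs_likelihoods) {
  stopifnot(inherits(belief, "tg_belief"), length(obs_likelihoods) == 5L)
  if (any(obs_likelihoods < 0 | obs_likelihoods > 1))
    stop("likelihoods must lie in [0, 1]")
  belief$irritability <- belief$irritability + obs_likelihoods
  belief
}

#' Track the partner's hypothetical irritation weight
#'
#' For each irritability hypothesis zeta, the partner's irritation weight
#' rises by zeta (clipped at 1) after an action of ours that the partner
#' experienced as unfavorable (below the value they expected), falls by zeta
#' (clipped at 0) after a favorable one, and is unchanged on neutral or
#' forced moves. The zeta = 0 hypothesis never moves.
#'
#' @param belief A [tg_belief()] object.
#' @param favourability `"unfavorable"`, `"favorable"` or `"neutral"`.
#' @return The updated `tg_belief`.
#' @export
update_partner_irritation <- function(belief,
    favourability = c("neutral", "unfavorable", "favorable")) {
  stopifnot(inherits(belief, "tg_belief"))
  favourability <- match.arg(favourability)
  belief$track <- switch(favourability,
    unfavorable = pmin(belief$track + ZETA_VALUES, 1),
    favorable   = pmax(belief$track - ZETA_VALUES, 0),
    neutral     = belief$track)
  belief
}

## Posterior means
posterior_guilt <- function(belief) belief$guilt / sum(belief$guilt)
posterior_irritability <- function(belief)
  belief$irritability / sum(belief$irritability)

#' Predicted partner action distribution
#'
#' Marginalizes the partner model over the posterior on guilt and
#' irritability: for each irritability hypothesis the partner's policy is the
#' mixture (1 - v(zeta)) * pi_nonirr(. | alpha) + v(zeta) * pi_irr(.), with
#' v(zeta) the tracked irritation weight; guilt enters through the
#' non-irritated policies.
#'
#' @param belief A [tg_belief()] object.
#' @param pi_nonirr Matrix of non-irritated partner policies, one column per
#'   guilt value (n_actions x 3).
#' @param pi_irr Irritated partner policy (length n_actions).
#' @return Probability vector over the partner's actions.
#' @export
predicted_partner_policy <- function(belief, pi_nonirr, pi_irr) {
  stopifnot(inherits(belief, "tg_belief"), ncol(pi_nonirr) == 3L,
            nrow(pi_nonirr) == length(pi_irr))
  pa <- posterior_guilt(belief)
  pz <- posterior_irritability(belief)
  base <- as.numeric(pi_nonirr %*% pa)
  drop(vapply(seq_len(5L), function(j)
    pz[j] * ((1 - belief$track[j]) * base + belief$track[j] * pi_irr),
    numeric(length(pi_irr))) %*% rep(1, 5L))
}
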