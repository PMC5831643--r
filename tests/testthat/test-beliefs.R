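# Dirichlet-multinomial opponent inference and partner irritation tracking.

test_that("irritability priors match the awareness settings", {
  expect_equal(irritability_prior(0), c(400, 0.1, 0.1, 0.1, 0.1))  # ignorant
  expect_equal(irritability_prior(1), c(4, 0.5, 0.5, 0.5, 0.5))    # optimistic
  expect_equal(irritability_prior(2), c(0.4, 0.1, 0.1, 0.1, 0.1))  # realistic
  expect_equal(irritability_prior(3), c(2, 1, 1, 1, 1))            # pessimistic
  expect_equal(irritability_prior(4), c(0.1, 0.1, 0.1, 0.1, 400))  # fatalistic
  p0 <- irritability_prior(0)
  expect_gt(p0[1] / sum(p0), 0.999)  # ignorant: certain of non-irritability
  p4 <- irritability_prior(4)
  expect_gt(p4[5] / sum(p4), 0.999)  # fatalistic: certain of irritability
})

test_that("additive belief updates behave like the approximate posterior", {
  b <- tg_belief(q = 2)
  expect_equal(b$guilt, c(1, 1, 1))
  b2 <- update_guilt(b, c(0.8, 0.15, 0.05))
  expect_equal(b2$guilt, c(1.8, 1.15, 1.05))
  expect_equal((b2$guilt / sum(b2$guilt))[1], 1.8 / 4.0)
  expect_equal(update_guilt(b, c(0, 0, 0))$guilt, c(1, 1, 1))
  b3 <- update_irritability(b, rep(0.2, 5))
  expect_equal(b3$irritability, c(0.6, 0.3, 0.3, 0.3, 0.3))
  expect_error(update_guilt(b, c(1.2, 0, 0)), "\\[0, 1\\]")
  expect_error(update_irritability(b, rep(-0.1, 5)), "\\[0, 1\\]")
})

test_that("each Dirichlet weight grows by at most one unit per observation", {
  set.seed(1)
  b <- tg_belief(q = 3)
  for (t in 1:10) {
    prev <- b$guilt
    b <- update_guilt(b, runif(3))
    expect_true(all(b$guilt >= prev))            # non-decreasing weights
    expect_true(all(b$guilt - prev <= 1))        # likelihoods are bounded
    expect_true(all(b$guilt <= 1 + t))           # per-weight mass <= 1 + t
  }
})

test_that("partner irritation tracks follow the rupture/repair dynamics", {
  b <- tg_belief(q = 2)
  # five consecutive unfavorable actions, read at the zeta = 0.25 hypothesis
  seq25 <- numeric(5)
  for (i in 1:5) {
    b <- update_partner_irritation(b, "unfavorable")
    seq25[i] <- b$track[2]
  }
  expect_equal(seq25, c(0.25, 0.5, 0.75, 1.0, 1.0))
  expect_equal(b$track[1], 0)          # nonirritable hypothesis never moves
  expect_equal(b$track[5], 1)          # zeta = 1 saturates immediately
  b <- update_partner_irritation(b, "favorable")
  expect_equal(b$track[3], 0.5)        # repair: 1.0 - 0.5
  b2 <- update_partner_irritation(tg_belief(2), "neutral")
  expect_equal(b2$track, rep(0, 5))
})

test_that("predicted partner policy is a correctly mixed distribution", {
  pi_a <- cbind(c(0.7, 0.1, 0.1, 0.05, 0.05),
                c(0.2, 0.2, 0.4, 0.1, 0.1),
                c(0.05, 0.05, 0.6, 0.2, 0.1))
  pi_irr <- c(0.9, 0.05, 0.03, 0.01, 0.01)
  # belief concentrated on zeta = 0: pure non-irritated mixture over guilt
  b <- tg_belief(q = 0)
  pred <- predicted_partner_policy(b, pi_a, pi_irr)
  expect_equal(sum(pred), 1)
  base <- as.numeric(pi_a %*% (b$guilt / sum(b$guilt)))
  expect_lt(max(abs(pred - base)), 2e-3)  # q=0 prior: ~99.9% on zeta = 0
  # full irritation on every hypothesis: pure irritated policy
  b$track <- rep(1, 5)
  pred1 <- predicted_partner_policy(b, pi_a, pi_irr)
  expect_equal(pred1, pi_irr)
  b$track <- c(0, rep(1, 4))  # zeta = 0 cannot carry irritation
  predm <- predicted_partner_policy(b, pi_a, pi_irr)
  expect_equal(sum(predm), 1)
  for (i in 1:20) {
    set.seed(i)
    b$guilt <- runif(3, 0.2, 5)
    b$irritability <- runif(5, 0.2, 5)
    b$track <- c(0, runif(4))
    p <- predicted_partner_policy(b, pi_a, pi_irr)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("a stationary partner's guilt type is recovered from 10 rounds", {
  # myopic softmax trustee at a fixed investment of 10; the guilt-free and
  # fully guilt-averse types generate clearly separable returns, and the
  # posterior mean concentrates on the true type in the majority of games
  g <- tg_return_grid(10)
  pols <- lapply(c(0, 0.4, 1), function(a)
    softmax_policy(vapply(g, function(aT) tg_utility("trustee", 10, aT, a), 0),
                   beta = 1))
  set.seed(42)
  for (ai in c(1, 3)) {  # alpha* = 0 and alpha* = 1
    wins <- 0
    for (s in 1:30) {
      b <- tg_belief(q = 0)
      for (r in 1:10) {
        obs <- sample(5, 1, prob = pols[[ai]])
        b <- update_guilt(b, vapply(pols, function(p) p[obs], 0))
      }
      wins <- wins + (which.max(b$guilt) == ai)
    }
    expect_gt(wins, 15)
  }
  # the intermediate type is behaviourally close to guilt-free in myopic
  # play; it should at least dominate the fully guilt-averse type
  wins <- 0
  set.seed(43)
  for (s in 1:30) {
    b <- tg_belief(q = 0)
    for (r in 1:10) {
      obs <- sample(5, 1, prob = pols[[2]])
      b <- update_guilt(b, vapply(pols, function(p) p[obs], 0))
    }
    wins <- wins + (b$guilt[2] > b$guilt[3])
  }
  expect_gt(wins, 15)
})

test_that("forced trustee moves leave beliefs and tracks unchanged", {
  # engine-level check: a zero investment forces the return, which must not
  # update the investor's beliefs about the trustee
  p <- tg_params("investor", alpha = 0.4, plan = 2, tom = 2, beta = 1/3,
                 omega = 1, zeta = 0, awareness = 2)
  pol0 <- tg_policy(p)                      # fresh beliefs
  pol1 <- tg_policy(p, 0L, 0L)              # after one forced round
  # one round has passed (horizon context identical: P=2 << rounds left),
  # and the zero investment shifted the modelled trustee's irritation track,
  # but the guilt/irritability posterior itself is untouched; the planned
  # policy can differ only through that track. Verify via the oracle's
  # belief filter directly:
  tab <- o_tables(p)
  B <- o_init_beliefs(p)
  tree <- o_run(p, B, 2, tab)
  nb <- o_edge_inv(B[[3]], tree$lev[[3]]$calc, tree$lev[[2]]$polT, tab, 1, 1)
  expect_equal(nb$guilt, B[[3]]$guilt)
  expect_equal(nb$irritability, B[[3]]$irritability)
  expect_true(all(is.finite(pol0$planned)) && all(is.finite(pol1$planned)))
})
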