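# Shared-tree planner: Q-values, policies, caching contract.

test_that("myopic trustee Q-values equal brute-force enumeration", {
  # enumerate the 5 returns with the raw payoff rules and the guilt penalty
  brute <- function(aI, alpha) {
    vapply(tg_return_grid(aI), function(aT) {
      chiT <- payoff_trustee(aI, aT)
      chiI <- payoff_investor(aI, aT)
      chiT - alpha * max(chiT - chiI, 0)
    }, 0)
  }
  for (alpha in c(0, 0.4, 1))
    for (aI in c(5, 10, 20)) {
      p <- tg_params("trustee", alpha = alpha, plan = 1, tom = 0, beta = 1/3,
                     omega = 1, zeta = 0, awareness = 2)
      # final round: planning horizon 1 regardless of P
      hist_i <- rep(10L, 9); hist_r <- rep(10L, 9)
      q <- tg_q_values(p, hist_i, hist_r, current_investment = aI)
      expect_equal(unname(q), brute(aI, alpha), tolerance = 1e-12)
    }
  # guilt-averse trustee receiving 30: equality split (return 10) maximizes
  p1 <- tg_params("trustee", alpha = 1, plan = 1, tom = 0, beta = 1/3,
                  omega = 1, zeta = 0, awareness = 2)
  q30 <- tg_q_values(p1, current_investment = 10)
  expect_equal(names(which.max(q30)), "10")
  expect_equal(unname(which.max(brute(10, 1))), 3L)
})

test_that("the engine matches the naive R oracle on every node and level", {
  configs <- list(
    tg_params("investor", alpha = 0.4, plan = 1, tom = 0, beta = 1/2,
              omega = 1, zeta = 0, awareness = 2),
    tg_params("investor", alpha = 1, plan = 2, tom = 0, beta = 1/4,
              omega = 0.6, zeta = 0.5, awareness = 1),
    tg_params("investor", alpha = 0, plan = 2, tom = 2, beta = 1/3,
              omega = 1.4, zeta = 1, awareness = 0),
    tg_params("trustee", alpha = 0.4, plan = 2, tom = 0, beta = 1,
              omega = 1.2, zeta = 0.25, awareness = 4),
    tg_params("trustee", alpha = 1, plan = 2, tom = 1, beta = 1/3,
              omega = 1.8, zeta = 0, awareness = 3))
  hists <- list(
    list(i = integer(0), r = integer(0)),
    list(i = c(20L, 0L), r = c(10L, 0L)),       # includes a forced round
    list(i = c(10L, 15L, 5L), r = c(15L, 8L, 0L)))
  for (p in configs)
    for (h in hists) {
      expect_lt(o_compare_tree(p, h$i, h$r), 1e-8)
    }
})

test_that("assessments along full records match the oracle", {
  inv <- tg_params("investor", alpha = 0.4, plan = 2, tom = 2, beta = 1/3,
                   omega = 0.8, zeta = 0.5, awareness = 2)
  tru <- tg_params("trustee", alpha = 0.4, plan = 2, tom = 1, beta = 1/3,
                   omega = 1.2, zeta = 0.25, awareness = 1)
  sim <- tg_simulate(inv, tru, n_runs = 1, seed = 7)
  I <- sim$investments[1, ]; Rp <- sim$repayments[1, ]
  for (p in list(inv, tru)) {
    a <- tg_assess(p, I, Rp)
    o <- o_assess(p, I, Rp)
    for (r in 1:10) {
      n <- length(o[[r]]$mixture)
      expect_equal(a$mixture[r, 1:n], o[[r]]$mixture, tolerance = 1e-10)
      expect_equal(a$v[r], o[[r]]$v, tolerance = 1e-12)
      expect_equal(a$p_obs[r], o[[r]]$p_obs, tolerance = 1e-10)
      expect_equal(a$expectation[r], o[[r]]$expectation, tolerance = 1e-10)
    }
  }
})

test_that("policies are deterministic and identical across repeated queries", {
  p <- tg_params("investor", alpha = 0.4, plan = 3, tom = 2, beta = 1/3,
                 omega = 1, zeta = 0.5, awareness = 2)
  h <- list(i = c(10L, 20L), r = c(5L, 30L))
  a <- tg_policy(p, h$i, h$r)
  b <- tg_policy(p, h$i, h$r)
  expect_identical(a$planned, b$planned)   # bit-identical recomputation
  expect_identical(a$q_values, b$q_values)
  expect_equal(sum(a$planned), 1)
  expect_equal(sum(a$mixture), 1)
})

test_that("tree size is level-independent and level passes grow linearly", {
  # the shared tree makes cost linear in the theory-of-mind level: the node
  # set is fixed by the horizon, and each level adds exactly one pass
  mk <- function(k) tg_params("investor", alpha = 0.4, plan = 4, tom = k,
                              beta = 1/3, omega = 1, zeta = 0, awareness = 2)
  s0 <- tg_tree_stats(mk(0)); s2 <- tg_tree_stats(mk(2)); s4 <- tg_tree_stats(mk(4))
  expect_equal(s0$n_slots, s2$n_slots)
  expect_equal(s2$n_slots, s4$n_slots)
  expect_equal(c(s0$n_level_passes, s2$n_level_passes, s4$n_level_passes),
               c(1, 3, 5))
  expect_equal(s0$n_slots, 1 + 21 + 21^2 + 21^3)  # horizon 4 at round 1
  expect_equal(tg_tree_stats(mk(0), round = 10)$H, 1)  # truncated at game end
})

test_that("a level-4 investor facing a level-3 trustee plans within budget", {
  p <- tg_params("investor", alpha = 0.4, plan = 2, tom = 4, beta = 1/3,
                 omega = 1, zeta = 0, awareness = 2)
  pol <- tg_policy(p)
  expect_equal(sum(pol$planned), 1)
  t3 <- tg_params("trustee", alpha = 0.4, plan = 2, tom = 3, beta = 1/3,
                  omega = 1, zeta = 0, awareness = 2)
  polT <- tg_policy(t3, current_investment = 10)
  expect_equal(sum(polT$planned), 1)
})

test_that("the node budget guard refuses oversized trees", {
  p <- tg_params("investor", alpha = 0.4, plan = 4, tom = 0, beta = 1/3,
                 omega = 1, zeta = 0, awareness = 2)
  ctx <- trustgame:::params_ctx(p, max_nodes = 100)
  expect_error(trustgame:::cpp_policy(ctx, integer(0), integer(0), -1L),
               "node budget")
})

test_that("endgame unravels for guilt-free argmax players", {
  # trustee: final-round defection is the dominant action
  pe <- tg_params("trustee", alpha = 0, plan = 1, tom = 0, beta = Inf,
                  omega = 1, zeta = 0, awareness = 0)
  pol <- tg_policy(pe, rep(10L, 9), rep(10L, 9), current_investment = 10)
  expect_equal(pol$mixture, c(1, 0, 0, 0, 0))
  # investor at round 10, convinced the trustee is guilt-free, keeps all
  pi_ <- tg_params("investor", alpha = 0, plan = 1, tom = 2, beta = Inf,
                   omega = 1, zeta = 0, awareness = 0)
  polI <- tg_policy(pi_, rep(10L, 9), rep(0L, 9))
  expect_equal(polI$mixture, c(1, 0, 0, 0, 0))
})

test_that("planned investment is non-increasing in risk aversion", {
  ev <- vapply(seq(0.4, 1.8, by = 0.2), function(w) {
    p <- tg_params("investor", alpha = 0.4, plan = 2, tom = 2, beta = 1/2,
                   omega = w, zeta = 0, awareness = 2)
    sum(tg_policy(p)$planned * tg_config()$investor_grid)
  }, 0)
  expect_true(all(diff(ev) <= 1e-9))
})

test_that("trustees expecting extreme risk aversion give up on building trust", {
  ev <- function(bw) {
    p <- tg_params("trustee", alpha = 0.4, plan = 2, tom = 1, beta = 1/3,
                   omega = bw, zeta = 0, awareness = 2)
    sum(tg_policy(p, current_investment = 10)$planned * tg_return_grid(10))
  }
  expect_lt(ev(1.8), ev(1.0))
  expect_lt(ev(1.6), ev(1.0))
})
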