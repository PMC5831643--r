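# Maximum-likelihood grid fitting, model comparison, classification.

fit_inv <- function(zeta = 0, q = 2)
  tg_params("investor", alpha = 0.4, plan = 1, tom = 0, beta = 1/3,
            omega = 1, zeta = zeta, awareness = q)

test_that("the one-step-ahead NLL sums the log predictive probabilities", {
  p <- fit_inv()
  sim <- tg_simulate(p, tg_params("trustee", alpha = 1, plan = 1, tom = 0,
                                  beta = 1/3, omega = 1, zeta = 0,
                                  awareness = 2), n_runs = 1, seed = 8)
  I <- sim$investments[1, ]; Rp <- sim$repayments[1, ]
  nll <- tg_nll(p, I, Rp)
  a <- tg_assess(p, I, Rp)
  expect_equal(as.numeric(nll), -sum(log(a$p_obs)))
  expect_true(all(attr(nll, "p_obs") > 0 & attr(nll, "p_obs") <= 1))
  # a trustee who was never given anything has no free choices: NLL = 0
  pt <- tg_params("trustee", alpha = 0, plan = 1, tom = 0, beta = 1,
                  omega = 1, zeta = 0, awareness = 0)
  expect_equal(as.numeric(tg_nll(pt, rep(0L, 10), rep(0L, 10))), 0)
  # argmax sentinel can put zero mass on an observed action: clamped + warning
  pinf <- tg_params("investor", alpha = 0, plan = 1, tom = 0, beta = Inf,
                    omega = 1.8, zeta = 0, awareness = 0)
  expect_warning(tg_nll(pinf, c(20L, rep(0L, 9)), c(0L, rep(0L, 9))),
                 "clamped")
})

test_that("grid fits recover the minimum with deterministic tie-breaking", {
  p <- fit_inv()
  sim <- tg_simulate(p, tg_params("trustee", alpha = 0.4, plan = 1, tom = 0,
                                  beta = 1/3, omega = 1, zeta = 0,
                                  awareness = 2), n_runs = 1, seed = 30)
  d <- tg_dyad(sim)
  # size-1 grid returns that point with its NLL
  g1 <- tg_grid("investor", alpha = 0.4, plan = 1, tom = 0, beta = 1/3,
                omega = 1, zeta = 0, awareness = 2)
  f1 <- tg_fit(d, "investor", g1)
  expect_equal(nrow(f1$grid), 1)
  expect_equal(coef(f1)[["alpha"]], 0.4)
  expect_equal(f1$nll, as.numeric(tg_nll(p, d$investment, d$repayment)))
  # grid enumeration order does not change the fitted point
  g <- tg_grid("investor", alpha = c(1, 0, 0.4), plan = 1, tom = 0,
               beta = 1/3, omega = c(1.4, 1, 0.6), zeta = c(0.5, 0),
               awareness = 2)
  g_rev <- tg_grid("investor", alpha = c(0, 0.4, 1), plan = 1, tom = 0,
                   beta = 1/3, omega = c(0.6, 1, 1.4), zeta = c(0, 0.5),
                   awareness = 2)
  fa <- tg_fit(d, "investor", g)
  fb <- tg_fit(d, "investor", g_rev)
  expect_identical(coef(fa), coef(fb))
  expect_equal(fa$nll, fb$nll)
  # fit object machinery
  expect_s3_class(fa, "tg_fit")
  expect_equal(as.numeric(logLik(fa)), -fa$nll)
  expect_equal(dim(predict(fa)), c(10, 5))
  expect_equal(length(residuals(fa)), 10)
})

test_that("min-NLL is non-increasing on nested grids and the LRT is valid", {
  p <- fit_inv(zeta = 0.5)
  sim <- tg_simulate(p, tg_params("trustee", alpha = 0, plan = 1, tom = 0,
                                  beta = 1/3, omega = 1, zeta = 0,
                                  awareness = 2), n_runs = 1, seed = 13)
  d <- tg_dyad(sim)
  small <- tg_grid("investor", alpha = c(0, 0.4, 1), plan = 1, tom = 0,
                   beta = 1/3, omega = 1, zeta = 0, awareness = 2)
  big <- tg_grid("investor", alpha = c(0, 0.4, 1), plan = 1, tom = 0,
                 beta = 1/3, omega = 1, zeta = c(0, 0.5, 1), awareness = 2)
  fs <- tg_fit(d, "investor", small)
  fb <- tg_fit(d, "investor", big)
  expect_lte(fb$nll, fs$nll)
  cmp <- tg_lrt(fs$nll, fb$nll, df_diff = 1)
  expect_gte(cmp$statistic, 0)
  # closed-form check: NLL drop of 3.0 with 1 dof clears the 5% threshold
  one <- tg_lrt(10, 7, df_diff = 1, p = 0.05)
  expect_equal(one$statistic, 6)
  expect_equal(one$threshold, qchisq(0.95, 1))
  expect_lt(abs(one$threshold - 3.8415), 1e-3)
  expect_true(one$accept_rich)
  # identical fits are never significant; the statistic sums over subjects
  expect_false(tg_lrt(c(5, 5), c(5, 5), 1)$accept_rich)
  expect_equal(tg_lrt(c(5, 6), c(4, 5), 2)$statistic,
               tg_lrt(5, 4, 2)$statistic + tg_lrt(6, 5, 2)$statistic)
})

test_that("BIC follows the small-sample closed form", {
  expect_equal(tg_bic(0, n_params = 7, m = 10), 7 * (log(10) - log(2 * pi)))
  expect_equal(tg_bic(0, n_params = 0, m = 10), 0)
  # more parameters at fixed NLL strictly increase BIC (log 10 > log 2pi)
  bics <- vapply(1:7, function(n) tg_bic(3, n, 10), 0)
  expect_true(all(diff(bics) > 0))
  # summing over subjects
  expect_equal(tg_bic(c(2, 3), 2, 10),
               tg_bic(2, 2, 10) + tg_bic(3, 2, 10))
})

test_that("perilous trustees are exactly the guilt-free or unaware ones", {
  mk <- function(alpha, q) tg_params("trustee", alpha = alpha, plan = 1,
                                     tom = 0, beta = 1/3, omega = 1,
                                     zeta = 0, awareness = q)
  expect_equal(classify_perilous(mk(0, 3)), "perilous")
  expect_equal(classify_perilous(mk(0.4, 0)), "perilous")
  expect_equal(classify_perilous(mk(0, 0)), "perilous")
  expect_equal(classify_perilous(mk(1, 2)), "non-perilous")
  expect_equal(classify_perilous(mk(0.4, 4)), "non-perilous")
  inv <- tg_params("investor", alpha = 0, plan = 1, tom = 0, beta = 1/3,
                   omega = 1, zeta = 0, awareness = 0)
  expect_error(classify_perilous(inv), "trustees")
})

test_that("recovery bookkeeping is exact and reproducible", {
  spec <- tg_group_spec("fixed", perilous_prevalence = 0, alpha = c(0.4, 1),
                        plan = 1, tom_investor = 0, tom_trustee = 0,
                        beta = 1/3, omega = c(1, 1.4), zeta = 0,
                        awareness = 2)
  coh <- generate_cohort(spec, 6, seed = 55)
  grid <- tg_grid("investor", alpha = c(0, 0.4, 1), plan = 1, tom = 0,
                  beta = 1/3, omega = c(0.6, 1, 1.4), zeta = 0, awareness = 2)
  rec <- recovery_study(coh, "investor", grid)
  expect_equal(nrow(rec$fits), 6)
  cm <- rec$confusion$alpha
  expect_equal(sum(cm), 6)
  for (lev in rownames(cm))
    expect_equal(sum(cm[lev, ]),
                 sum(rec$fits$true_alpha == as.numeric(lev)))
  rec2 <- recovery_study(coh, "investor", grid)
  expect_identical(rec$fits, rec2$fits)
})
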