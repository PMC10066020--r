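claims_wide <- function() {
  cl <- load_fixture("capra_claims")
  a <- cl[cl$part == "A", ]
  b <- cl[cl$part == "B", ]
  data.frame(
    incentive_a = a$incentive, claim_a = a$claim,
    incentive_b = b$incentive, claim_b = b$claim
  )
}

test_that("OLS reproduces the published estimates and standard errors", {
  w <- claims_wide()
  fa <- ols_fit(w, claim_a ~ incentive_a)
  expect_equal(unname(fa$coefficients), c(182.917, -1.471), tolerance = 5e-4)
  expect_equal(unname(fa$standard_errors), c(16.814, 0.411), tolerance = 5e-4)
  expect_equal(unname(fa$t_stats[2]), -3.581, tolerance = 5e-4)
  fb <- ols_fit(w, claim_b ~ incentive_b)
  expect_equal(unname(fb$coefficients), c(159.434, -0.977), tolerance = 5e-4)
  expect_equal(unname(fb$standard_errors), c(24.345, 0.595), tolerance = 5e-4)
  fm <- ols_fit(w, claim_b ~ claim_a + incentive_b)
  expect_equal(unname(fm$coefficients), c(93.300, 0.589, -1.425),
               tolerance = 5e-4)
  expect_equal(unname(fm$standard_errors), c(39.033, 0.305, 0.514),
               tolerance = 5e-4)
  expect_equal(unname(fm$t_stats[3]), -2.773, tolerance = 5e-4)
  # the fit decomposes the response and residuals are orthogonal to the design
  expect_equal(unname(fm$fitted + fm$residuals), w$claim_b, tolerance = 1e-10)
  X <- cbind(1, w$claim_a, w$incentive_b)
  expect_lt(max(abs(crossprod(X, fm$residuals))) /
              max(abs(crossprod(X, w$claim_b))), 1e-8)
  # intercept-only fit of a constant response
  cd <- data.frame(y = rep(4.2, 5))
  fc <- ols_fit(cd, y ~ 1)
  expect_equal(unname(fc$coefficients), 4.2)
  expect_equal(max(abs(fc$residuals)), 0)
})

test_that("simple permutation regression reproduces 12/720 and 150/720", {
  w <- claims_wide()
  ra <- perm_lm_test(w, claim_a ~ incentive_a)
  expect_equal(ra$statistic, -3.581, tolerance = 5e-4)
  expect_equal(ra$n_extreme, 12)
  expect_equal(ra$n_total, 720)
  rb <- perm_lm_test(w, claim_b ~ incentive_b)
  expect_equal(rb$n_extreme, 150)
  expect_equal(rb$p_value, 150 / 720, tolerance = 1e-12)
})

test_that("a constant response yields p = 1 by convention", {
  d <- data.frame(y = rep(3, 5), z = rnorm(5))
  r <- perm_lm_test(d, y ~ z)
  expect_equal(r$p_value, 1)
})

test_that("Freedman-Lane reproduces the 35/720 nuisance-adjusted test", {
  w <- claims_wide()
  r <- freedman_lane_test(w, claim_b ~ claim_a + incentive_b,
                          interest = "incentive_b")
  expect_equal(r$statistic, -2.773, tolerance = 5e-4)
  expect_equal(r$n_extreme, 35)
  expect_equal(r$n_total, 720)
  expect_equal(r$p_value, 35 / 720, tolerance = 1e-12)
})

test_that("Freedman-Lane with intercept-only nuisance equals simple permutation regression", {
  w <- claims_wide()
  fl <- freedman_lane_test(w, claim_a ~ incentive_a, interest = "incentive_a")
  sp <- perm_lm_test(w, claim_a ~ incentive_a)
  expect_equal(fl$n_extreme, sp$n_extreme)
  expect_equal(fl$p_value, sp$p_value)
  withr::with_seed(63, {
    for (i in 1:4) {
      d <- generate_linear_data(6, beta = 0, delta = rnorm(1), seed = 100 + i)
      fl_i <- freedman_lane_test(d, y ~ z, interest = "z")
      sp_i <- perm_lm_test(d, y ~ z)
      expect_equal(fl_i$n_extreme, sp_i$n_extreme)
    }
  })
})

test_that("the identity permutation reconstructs the observed response exactly", {
  w <- claims_wide()
  red <- lm(claim_b ~ claim_a, data = w)
  rebuilt <- fitted(red) + resid(red)[1:6]
  expect_equal(max(abs(rebuilt - w$claim_b)) / max(abs(w$claim_b)), 0,
               tolerance = 1e-12)
  # and in the engine: the observed statistic appears in the null set
  r <- freedman_lane_test(w, claim_b ~ claim_a + incentive_b,
                          interest = "incentive_b")
  expect_equal(r$null_distribution[1], r$statistic, tolerance = 1e-10)
})

test_that("correlation test and simple permutation regression count the same extremes", {
  w <- claims_wide()
  rc <- perm_cor_test(w, incentive_a, claim_a, alternative = "two_sided")
  rr <- perm_lm_test(w, claim_a ~ incentive_a, alternative = "two_sided")
  expect_equal(rc$n_extreme, rr$n_extreme) # |t| and |r| are monotone-linked
  expect_equal(rc$n_extreme, 12)
  # one-sided count for negative correlation is the published 3/720
  rneg <- perm_cor_test(w, incentive_a, claim_a, alternative = "less")
  expect_equal(rneg$statistic, -0.873, tolerance = 5e-4)
  expect_equal(rneg$n_extreme, 3)
  expect_equal(rneg$n_total, 720)
})

test_that("an uninformative regressor of interest gives a large p-value", {
  # z orthogonal to both y and the nuisance covariate by construction
  d <- data.frame(
    x = c(1, 2, 3, 4, 5, 6),
    z = c(1, -1, 1, -1, 1, -1),
    y = c(2, 4, 6, 8, 10, 12)
  )
  r <- freedman_lane_test(d, y ~ x + z, interest = "z")
  expect_gt(r$p_value, 0.9)
})

test_that("the partial F variant agrees with the squared t for one regressor", {
  w <- claims_wide()
  rt <- freedman_lane_test(w, claim_b ~ claim_a + incentive_b,
                           interest = "incentive_b", alternative = "two_sided")
  rf <- freedman_lane_test(w, claim_b ~ claim_a + incentive_b,
                           interest = "incentive_b", statistic = "F")
  expect_equal(rf$statistic, rt$statistic^2, tolerance = 1e-8)
  expect_equal(rf$n_extreme, rt$n_extreme)
})

test_that("Monte Carlo mode matches exact counts closely on the regression example", {
  w <- claims_wide()
  r <- perm_lm_test(w, claim_a ~ incentive_a, mode = "monte_carlo",
                    n_draws = 20000, seed = 5)
  expect_lt(abs(r$p_value - 12 / 720), 0.005)
})

test_that("rank-deficient designs are rejected", {
  d <- data.frame(y = rnorm(6), x = 1:6)
  d$x2 <- 2 * d$x
  expect_error(ols_fit(d, y ~ x + x2), "rank")
  expect_error(freedman_lane_test(d, y ~ x + x2, interest = "x2"), "rank")
})
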