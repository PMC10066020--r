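test_that("the generic engine reproduces the two-sample asset-price p-values", {
  d <- load_fixture("caginalp_prices")
  r2 <- permutation_pvalue(d, two_sample_scheme(3, 4), "mean_difference")
  expect_equal(r2$n_extreme, 2)
  expect_equal(r2$n_total, 35)
  expect_equal(r2$p_value, 2 / 35)
  r1 <- permutation_pvalue(d, two_sample_scheme(3, 4), "mean_difference",
                           alternative = "greater")
  expect_equal(r1$p_value, 1 / 35)
  # constant data: every permutation ties the observed statistic
  const <- labeled_data(rep(2.5, 7), rep(c("a", "b"), c(3, 4)))
  expect_equal(
    permutation_pvalue(const, two_sample_scheme(3, 4), "mean_difference")$p_value,
    1
  )
})

test_that("rent-seeking data: raw Pitman 28/70 but rank-based 14/70", {
  h <- load_fixture("holt_smith_rents")
  expect_equal(pitman_test(h)$n_extreme, 28)
  expect_equal(pitman_test(h)$p_value, 0.4)
  expect_equal(mann_whitney_test(h)$n_extreme, 14)
  expect_equal(mann_whitney_test(h)$p_value, 0.2)
})

test_that("peak-price data: Pitman 36/924 vs Mann-Whitney 86/924", {
  b <- load_fixture("bohr_peaks")
  rp <- pitman_test(b)
  rm <- mann_whitney_test(b)
  expect_equal(rp$n_extreme, 36)
  expect_equal(rp$n_total, 924)
  expect_equal(rm$n_extreme, 86)
  expect_equal(rp$p_value, 36 / 924, tolerance = 1e-12)
  expect_equal(rm$p_value, 86 / 924, tolerance = 1e-12)
})

test_that("matched-pair tests reproduce the oligopoly price analysis", {
  mp <- load_fixture("davis_holt_market_power")
  expect_equal(fisher_pairs_test(mp, "greater")$p_value, 1 / 64)
  expect_equal(fisher_pairs_test(mp, "two_sided")$p_value, 2 / 64)
  ne <- load_fixture("davis_holt_numbers_effect")
  expect_equal(fisher_pairs_test(ne, "greater")$p_value, 2 / 64)
  expect_equal(fisher_pairs_test(ne, "two_sided")$p_value, 4 / 64)
  # ignoring the pairing loses the effect entirely
  ne_unpaired <- ne[, c("value", "treatment")]
  expect_equal(round(pitman_test(ne_unpaired, "greater")$p_value, 3), 0.273)
  # Wilcoxon agrees with Fisher here (all signed ranks positive but one)
  expect_equal(wilcoxon_signed_rank_test(ne, "greater")$p_value, 2 / 64)
})

test_that("an outlier separates the Fisher and Wilcoxon matched-pair tests", {
  mp <- load_fixture("davis_holt_market_power")
  mp$value[mp$treatment == "five_no_power" & mp$block == "S1"] <- 700
  expect_equal(fisher_pairs_test(mp, "greater")$p_value, 26 / 64)
  expect_equal(wilcoxon_signed_rank_test(mp, "greater")$p_value, 14 / 64)
})

test_that("k-sample tests: F and H with their exact extreme counts", {
  w <- load_fixture("holt_sprott_auctions")
  rf <- permutation_f_test(w)
  expect_equal(rf$statistic, 5.54, tolerance = 1e-3)
  expect_equal(rf$n_extreme, 642)
  expect_equal(rf$n_total, 34650)
  rk <- kruskal_wallis_test(w)
  expect_equal(rk$statistic, 5.69, tolerance = 1e-3)
  expect_equal(rk$n_extreme, 1686)
})

test_that("ordered alternatives: J and D both give 2/90 on the trading-rule data", {
  sm <- load_fixture("smith_auctions")
  sm$stratum <- NULL
  rj <- jonckheere_test(sm)
  expect_equal(rj$statistic, 11)
  expect_equal(rj$n_extreme, 2)
  expect_equal(rj$n_total, 90)
  rd <- directional_difference_test(sm)
  expect_equal(rd$statistic, 108)
  expect_equal(rd$n_extreme, 2)
  expect_equal(rd$n_total, 90)
  # explicit reversed order flips the tail
  rj_rev <- jonckheere_test(sm, order = rev(levels(sm$treatment)),
                            alternative = "less")
  expect_equal(rj_rev$n_total, 90)
})

test_that("the exact engine agrees with a brute-force oracle on small schemes", {
  withr::with_seed(77, {
    for (i in 1:5) {
      # two-sample, raw and ranked (up to 924 <= 1000 permutations)
      x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
      d <- labeled_data(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
      for (alt in c("two_sided", "greater", "less")) {
        expect_equal(pitman_test(d, alt)$p_value,
                     oracle_two_sample(x, y, alt)$p)
      }
      rk <- rank(c(x, y))
      expect_equal(
        mann_whitney_test(d)$p_value,
        oracle_two_sample(rk[seq_along(x)], rk[-seq_along(x)], "two_sided")$p
      )
      # sign flip (2^7 = 128)
      dd <- rnorm(7)
      pd <- labeled_data(
        value = c(dd, rep(0, 7)), treatment = rep(c("t", "c"), each = 7),
        block = rep(sprintf("b%d", 1:7), 2)
      )
      expect_equal(fisher_pairs_test(pd, "greater")$p_value,
                   oracle_sign_flip(dd, "greater")$p)
      # k-sample F and H (90 permutations)
      ks <- lapply(1:3, function(j) rnorm(2))
      kd <- labeled_data(unlist(ks), rep(c("a", "b", "c"), each = 2))
      expect_equal(permutation_f_test(kd)$p_value,
                   oracle_k_sample(ks, "greater", anova_f)$p)
      expect_equal(kruskal_wallis_test(kd)$p_value,
                   oracle_k_sample(ks, "greater", kruskal_h)$p)
      expect_equal(jonckheere_test(kd)$p_value,
                   oracle_k_sample(ks, "greater", jonckheere_j)$p)
      # correlation (120 orderings)
      u <- rnorm(5); v <- rnorm(5)
      cd <- tibble::tibble(u = u, v = v)
      expect_equal(perm_cor_test(cd, u, v)$p_value,
                   oracle_correlation(u, v, "two_sided")$p)
      # stratified two-sample (3 x 6 = 18 relabelings)
      xs <- list(rnorm(1), rnorm(2)); ys <- list(rnorm(2), rnorm(2))
      sd <- labeled_data(
        value = c(xs[[1]], ys[[1]], xs[[2]], ys[[2]]),
        treatment = c("t", "c", "c", "t", "t", "c", "c"),
        stratum = rep(c("s1", "s2"), c(3, 4))
      )
      expect_equal(pitman_test(sd, "greater")$p_value,
                   oracle_stratified_two_sample(xs, ys, "greater")$p)
    }
  })
})

test_that("exact p-values are rationals over the scheme count, never below 1/N", {
  withr::with_seed(99, {
    for (i in 1:10) {
      d <- generate_shift_data(4, 4, shift = rnorm(1), seed = i)
      r <- pitman_test(d)
      expect_gte(r$n_extreme, 1) # the identity labeling counts itself
      expect_equal(r$n_total, 70)
      expect_equal(r$p_value, r$n_extreme / r$n_total)
      expect_gte(r$p_two_sided, min(r$p_greater, r$p_less) - 1e-12)
    }
  })
})

test_that("Monte Carlo p-values use the add-one estimator and converge to exact", {
  d <- load_fixture("caginalp_prices")
  r <- pitman_test(d, mode = "monte_carlo", n_draws = 1e5, seed = 360)
  expect_equal(r$mode, "monte_carlo")
  expect_equal(r$p_value, (r$n_extreme + 1) / (1e5 + 1))
  expect_gt(r$p_value, 0)
  expect_lt(abs(r$p_value - 2 / 35), 0.005)
  # reproducibility
  r2 <- pitman_test(d, mode = "monte_carlo", n_draws = 500, seed = 360)
  r3 <- pitman_test(d, mode = "monte_carlo", n_draws = 500, seed = 360)
  expect_identical(r2$p_value, r3$p_value)
  # Monte Carlo without a seed is refused
  expect_error(pitman_test(d, mode = "monte_carlo", n_draws = 100), "seed")
})

test_that("auto mode switches to Monte Carlo above the exhaustive limit", {
  d <- generate_shift_data(10, 10, shift = 2, seed = 4)
  r <- pitman_test(d, limit = 1000, n_draws = 2000, seed = 8)
  expect_equal(r$mode, "monte_carlo")
  expect_error(pitman_test(d, mode = "exact", limit = 1000), "Monte Carlo")
})

test_that("rank tests are invariant to monotone transforms; raw-value tests are not", {
  b <- load_fixture("bohr_peaks")
  b_exp <- b
  b_exp$value <- exp(b$value / 20)
  expect_equal(mann_whitney_test(b_exp)$p_value, mann_whitney_test(b)$p_value)
  expect_false(isTRUE(all.equal(pitman_test(b_exp)$p_value,
                                pitman_test(b)$p_value)))
})

test_that("nonnegative statistics refuse directional alternatives", {
  w <- load_fixture("holt_sprott_auctions")
  expect_error(
    permutation_pvalue(w, k_sample_scheme(c(4, 4, 4)), "anova_f",
                       alternative = "less"),
    "nonnegative"
  )
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.12, 0.028)), c(0.24, 0.056))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the string dispatcher wires the same tests", {
  d <- load_fixture("caginalp_prices")
  expect_equal(perm_test(d, "pitman")$p_value, pitman_test(d)$p_value)
  expect_equal(perm_test(d, "mann_whitney")$p_value,
               mann_whitney_test(d)$p_value)
  expect_error(perm_test(d, "no_such_test"), "unknown test")
})

test_that("tidy and glance return well-formed one-row summaries", {
  r <- pitman_test(load_fixture("caginalp_prices"))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$p_value, 2 / 35)
  gl <- glance(r)
  expect_true(all(c("p_greater", "p_less", "p_two_sided") %in% names(gl)))
  expect_s3_class(autoplot(r), "ggplot")
})
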