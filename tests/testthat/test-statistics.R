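test_that("mean difference matches the published treatment contrasts", {
  d <- load_fixture("caginalp_prices")
  s <- split(d$value, d$treatment)
  expect_equal(mean_difference(s[[1]], s[[2]]), 0.72, tolerance = 1e-12)
  expect_equal(mean_difference(s[[1]], s[[1]]), 0)
  g <- load_fixture("holt_gender_bubbles")
  pooled <- split(g$value, g$treatment)
  expect_equal(round(mean_difference(pooled$p25, pooled$p15), 1), 26.8)
})

test_that("mean difference is antisymmetric", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(sample(2:8, 1))
      y <- rnorm(sample(2:8, 1))
      expect_equal(mean_difference(x, y), -mean_difference(y, x))
    }
  })
})

test_that("pooled ranks use mid-ranks and always sum to n(n+1)/2", {
  d <- load_fixture("caginalp_prices")
  rk <- pooled_rank_transform(d$value)
  expect_equal(rk, c(5, 6, 7, 2, 4, 1, 3))
  expect_equal(pooled_rank_transform(c(1, 2, 2)), c(1, 2.5, 2.5))
  expect_equal(pooled_rank_transform(sort(rnorm(9))), as.numeric(1:9))
  withr::with_seed(9, {
    for (i in 1:20) {
      v <- sample(rnorm(6), sample(3:12, 1), replace = TRUE) # forces ties
      n <- length(v)
      expect_equal(sum(pooled_rank_transform(v)), n * (n + 1) / 2)
    }
  })
})

test_that("signed ranks keep zeros with positive sign and mid-rank ties", {
  expect_equal(signed_rank_transform(c(-6, 4, 0, -3)), c(-4, 3, 1, -2))
  expect_equal(signed_rank_transform(c(2, 5, 9)), c(1, 2, 3))
  expect_equal(signed_rank_transform(c(-1, 1)), c(-1.5, 1.5))
})

test_that("one-way F matches the published value and squares the pooled t", {
  w <- load_fixture("holt_sprott_auctions")
  expect_equal(anova_f(split(w$value, w$treatment)), 5.54, tolerance = 1e-3)
  # equal group means with residual noise -> F = 0
  expect_equal(anova_f(list(c(1, 3), c(0, 4))), 0)
  expect_error(anova_f(list(c(1, 1), c(1, 1))), "within-group")
  # two groups: F equals the squared pooled-variance two-sample t
  d <- load_fixture("caginalp_prices")
  s <- split(d$value, d$treatment)
  tt <- stats::t.test(s[[1]], s[[2]], var.equal = TRUE)
  expect_equal(anova_f(s), unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches the published value and kruskal.test", {
  w <- load_fixture("holt_sprott_auctions")
  h <- kruskal_h(split(w$value, w$treatment))
  expect_equal(h, 5.69, tolerance = 1e-3)
  kt <- stats::kruskal.test(w$value, w$treatment)
  expect_equal(h, unname(kt$statistic), tolerance = 1e-10)
  # equal mean ranks across groups -> 0
  expect_equal(kruskal_h(list(c(1, 4), c(2, 3))), 0)
})

test_that("J counts strict cross-column wins; D sums cross-column differences", {
  sm <- split(load_fixture("smith_auctions")$value,
              load_fixture("smith_auctions")$treatment)
  expect_equal(jonckheere_j(sm), 11) # the tied 213 contributes nothing
  expect_equal(directional_d(sm), 108)
  const <- list(c(5, 5), c(5, 5), c(5, 5))
  expect_equal(jonckheere_j(const), 0)
  expect_equal(directional_d(const), 0)
  perfect <- list(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(jonckheere_j(perfect), 12)
  expect_equal(directional_d(list(2, 7)), mean_difference(7, 2))
})

test_that("J is invariant to monotone transforms; D is affine-equivariant", {
  withr::with_seed(13, {
    for (i in 1:15) {
      s <- lapply(1:3, function(j) rnorm(sample(2:4, 1)))
      expect_equal(jonckheere_j(lapply(s, exp)), jonckheere_j(s))
      expect_equal(jonckheere_j(lapply(s, function(v) 3 * v + 2)),
                   jonckheere_j(s))
      a <- runif(1, 0.5, 3); b <- rnorm(1)
      expect_equal(directional_d(lapply(s, function(v) a * v + b)),
                   a * directional_d(s), tolerance = 1e-9)
    }
  })
})

test_that("F and H are invariant to relabeling equal-size groups; H to monotone transforms", {
  withr::with_seed(21, {
    for (i in 1:10) {
      s <- lapply(1:3, function(j) rnorm(4))
      perm <- sample(3)
      expect_equal(anova_f(s[perm]), anova_f(s))
      expect_equal(kruskal_h(s[perm]), kruskal_h(s))
      expect_equal(kruskal_h(lapply(s, function(v) exp(v))), kruskal_h(s))
    }
  })
})

test_that("Pearson r matches its definition, stays in [-1, 1], and is affine-invariant", {
  cl <- load_fixture("capra_claims")
  a <- cl[cl$part == "A", ]
  expect_equal(pearson_r(a$incentive, a$claim), -0.873, tolerance = 5e-4)
  expect_equal(pearson_r(a$incentive, a$claim),
               stats::cor(a$incentive, a$claim), tolerance = 1e-12)
  x <- c(1, 5, 2)
  expect_equal(pearson_r(x, x), 1)
  # antitonic data through the rank path gives exactly -1
  y <- c(9, 1, 7)
  expect_equal(pearson_r(pooled_rank_transform(x), pooled_rank_transform(-x)), -1)
  withr::with_seed(31, {
    for (i in 1:15) {
      u <- rnorm(6); v <- rnorm(6)
      r <- pearson_r(u, v)
      expect_true(abs(r) <= 1 + 1e-12)
      expect_equal(pearson_r(2 * u + 1, v), r, tolerance = 1e-10)
      expect_equal(pearson_r(u, 0.5 * v - 3), r, tolerance = 1e-10)
    }
  })
  expect_error(pearson_r(c(1, 1), c(0, 2)), "variance")
})
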