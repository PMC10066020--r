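#' Test statistics on raw and rank-transformed data
#'
#' Pure functions computing the statistics used throughout the package.
#' All of them are plain numeric functions so they can be reused, inspected,
#' or swapped into [permutation_pvalue()].
#'
#' `mean_difference()` is the two-sample statistic `T = x̄ − ȳ`.
#'
#' `anova_f()` is the one-factor ANOVA statistic
#' `F = [(k−1)^{-1} Σ n_j (x̄_j − x̄)²] / [(N−k)^{-1} Σ Σ (x_ij − x̄_j)²]`.
#'
#' `kruskal_h()` is the Kruskal–Wallis statistic on pooled mid-ranks,
#' `H = (N−1) Σ n_j (r̄_j − r̄)² / Σ Σ (r_ij − r̄)²`, identical to the
#' statistic reported by [stats::kruskal.test()] (including the tie
#' correction that the total-sum-of-squares denominator induces).
#'
#' `jonckheere_j()` counts, over every pair of groups in increasing predicted
#' order, the strictly increasing cross-group observation pairs; ties
#' contribute nothing.
#'
#' `directional_d()` is the magnitude-sensitive analogue: the sum of all
#' cross-group differences toward higher-ordered treatments,
#' `D = Σ_{s<t} Σ_{i,j} (x_jt − x_is)`.
#'
#' `pearson_r()` is the Pearson product-moment correlation.
#'
#' @param x,y Numeric samples (for `pearson_r()`, paired vectors of equal
#'   length).
#' @param samples A list of `k >= 2` numeric samples; for the ordered
#'   statistics, listed left to right in increasing order of predicted
#'   effect.
#' @return A single numeric value.
#' @examples
#' mean_difference(c(3.43, 3.73, 3.97), c(3.03, 3.32, 2.55, 3.06)) # 0.72
#' jonckheere_j(list(c(208, 195), c(213, 209), c(217, 213))) # 11
#' directional_d(list(c(208, 195), c(213, 209), c(217, 213))) # 108
#' @export
mean_difference <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  mean(x) - mean(y)
}

#' @rdname mean_difference
#' @export
anova_f <- function(samples) {
  check_samples(samples)
  k <- length(samples)
  sizes <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  n_total <- length(pooled)
  if (n_total <= k) abort("need more observations than groups.")
  grand <- mean(pooled)
  means <- vapply(samples, mean, numeric(1))
  between <- sum(sizes * (means - grand)^2) / (k - 1)
  within <- sum(vapply(samples, function(v) sum((v - mean(v))^2), numeric(1))) /
    (n_total - k)
  if (within <= 0) abort("zero within-group variance: F statistic undefined.")
  between / within
}

#' @rdname mean_difference
#' @export
kruskal_h <- function(samples) {
  check_samples(samples)
  sizes <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  ranks <- pooled_rank_transform(pooled)
  groups <- rep(seq_along(samples), sizes)
  n_total <- length(pooled)
  total_ss <- sum((ranks - mean(ranks))^2)
  if (total_ss <= 0) abort("all values tied: H statistic undefined.")
  rank_means <- tapply(ranks, groups, mean)
  between <- sum(sizes * (rank_means - mean(ranks))^2)
  (n_total - 1) * between / total_ss
}

#' @rdname mean_difference
#' @export
jonckheere_j <- function(samples) {
  check_samples(samples)
  k <- length(samples)
  total <- 0
  for (s in seq_len(k - 1)) {
    for (t in (s + 1):k) {
      total <- total + sum(outer(samples[[s]], samples[[t]], "<"))
    }
  }
  total
}

#' @rdname mean_difference
#' @export
directional_d <- function(samples) {
  check_samples(samples)
  k <- length(samples)
  sizes <- lengths(samples)
  sums <- vapply(samples, sum, numeric(1))
  total <- 0
  for (s in seq_len(k - 1)) {
    for (t in (s + 1):k) {
      total <- total + sizes[s] * sums[t] - sizes[t] * sums[s]
    }
  }
  unname(total)
}

#' @rdname mean_difference
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need at least two pairs.")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) abort("zero variance: correlation undefined.")
  sum(dx * dy) / (sx * sy)
}

check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2) {
    abort("`samples` must be a list of at least two numeric samples.")
  }
  if (any(lengths(samples) < 1)) abort("every sample must be non-empty.")
  invisible(TRUE)
}

#' Rank transforms
#'
#' `pooled_rank_transform()` replaces the pooled values with their ranks
#' `1..n`; tied values receive mid-ranks (the average of the positions they
#' would occupy). `signed_rank_transform()` ranks the differences by
#' absolute value (mid-ranks on ties, zeros included in the ranking) and
#' reattaches the sign of each difference, with a zero difference keeping a
#' positive sign. Keeping zeros, rather than dropping them as some texts do,
#' makes the transform a pure relabeling-compatible preprocessing step: the
#' sign-flip null distribution retains all `2^n` points.
#'
#' @param values Numeric vector (pooled sample).
#' @param d Numeric vector of matched-pair differences.
#' @return A numeric vector of (signed) ranks, same length as the input.
#' @examples
#' pooled_rank_transform(c(1, 2, 2)) # 1, 2.5, 2.5
#' signed_rank_transform(c(-6, 4, 0, -3)) # -4, 3, 1, -2
#' @export
pooled_rank_transform <- function(values) {
  if (!length(values)) abort("`values` must be non-empty.")
  rank(values, ties.method = "average")
}

#' @rdname pooled_rank_transform
#' @export
signed_rank_transform <- function(d) {
  if (!length(d)) abort("`d` must be non-empty.")
  rank(abs(d), ties.method = "average") * ifelse(d >= 0, 1, -1)
}
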