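#' Shift confidence interval by permutation-test inversion
#'
#' Under a shift model (the two treatment distributions differ at most by a
#' location shift) a `100(1 − α)%` confidence interval for the shift is the
#' set of hypothesized shifts `δ` that a two-sided level-`α` permutation
#' test fails to reject when sample *x* (first treatment level) is tested
#' against `y + δ`. The test rejects when `p ≤ α`. Because the permutation
#' p-value is a step function of `δ`, the endpoints are located by widening
#' a bracket around the observed mean difference, bisecting the
#' reject/accept boundary, and reporting the innermost multiples of
#' `resolution` that fail to reject. Rank-based intervals re-rank the
#' shifted pooled sample at every `δ`, so ties at crossing points resolve
#' through mid-ranks and the engine's non-strict counting rule.
#'
#' @param data A two-sample labeled data frame; the first treatment level
#'   plays the role of `x`, the second of `y`.
#' @param level Confidence level in (0, 1).
#' @param test `"pitman"` (raw values) or `"mann_whitney"` (pooled ranks,
#'   recomputed at every shift).
#' @param resolution Endpoint resolution (default `1e-3`).
#' @param limit See [exhaustive_limit()].
#' @return A `shift_ci` object with fields `lower`, `upper`, `level`,
#'   `estimate` (observed mean difference), `test` and `alpha`.
#' @examples
#' shift_ci(load_fixture("caginalp_prices"), level = 0.90) # (0.244, 1.182)
#' @export
shift_ci <- function(data, level = 0.95, test = c("pitman", "mann_whitney"),
                     resolution = 1e-3, limit = exhaustive_limit()) {
  test <- match.arg(test)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must lie strictly between 0 and 1.")
  }
  data <- validate_labeled_data(data)
  data$treatment <- droplevels(data$treatment)
  if (nlevels(data$treatment) != 2) {
    abort("shift intervals need exactly two treatment levels.")
  }
  lv <- levels(data$treatment)
  x <- data$value[data$treatment == lv[1]]
  y <- data$value[data$treatment == lv[2]]
  if (length(unique(c(x, y))) == 1) {
    abort("all observations are equal: shift interval undefined.")
  }
  alpha <- 1 - level
  scheme <- two_sample_scheme(length(x), length(y))
  check_exhaustive(scheme, limit)
  splits <- enumerate_relabelings(scheme, limit)
  stat <- stat_mean_difference(c(length(x), length(y)))$sum_fun
  n1 <- length(x)

  p_at <- function(delta) {
    pool <- c(x, y + delta)
    if (test == "mann_whitney") pool <- pooled_rank_transform(pool)
    S <- group_sums(splits, pool, 2)
    stats <- stat(S, pool)
    obs <- stats[1] # first row is the identity labeling
    tol <- 1e-9 * max(1, abs(obs))
    sum(abs(stats) >= abs(obs) - tol) / length(stats)
  }
  reject <- function(delta) p_at(delta) <= alpha

  center <- mean(x) - mean(y)
  if (reject(center)) {
    abort("the two-sided test rejects at the observed difference; no interval.")
  }
  span <- max(diff(range(c(x, y))), resolution)
  lo <- center - span
  hi <- center + span
  for (i in 1:60) {
    if (reject(lo)) break
    lo <- lo - span
    span <- span * 2
  }
  if (!reject(lo)) {
    abort("test never rejects below the bracket; interval unbounded.")
  }
  span <- max(diff(range(c(x, y))), resolution)
  for (i in 1:60) {
    if (reject(hi)) break
    hi <- hi + span
    span <- span * 2
  }
  if (!reject(hi)) {
    abort("test never rejects above the bracket; interval unbounded.")
  }

  bisect <- function(bad, good) {
    # bad rejected, good not; returns boundary to resolution / 16
    while (abs(good - bad) > resolution / 16) {
      mid <- (bad + good) / 2
      if (reject(mid)) bad <- mid else good <- mid
    }
    c(bad = bad, good = good)
  }
  b_lo <- bisect(lo, center)
  b_hi <- bisect(hi, center)

  digits <- max(0, ceiling(-log10(resolution)))
  snap_up <- function(b) {
    g <- round(floor(b / resolution) * resolution, digits)
    while (reject(g)) g <- round(g + resolution, digits)
    g
  }
  snap_down <- function(b) {
    g <- round(ceiling(b / resolution) * resolution, digits)
    while (reject(g)) g <- round(g - resolution, digits)
    g
  }

  structure(
    list(
      lower = snap_up(b_lo[["bad"]]),
      upper = snap_down(b_hi[["bad"]]),
      level = level,
      alpha = alpha,
      estimate = center,
      test = test,
      resolution = resolution,
      data = data
    ),
    class = "shift_ci"
  )
}

#' @export
print.shift_ci <- function(x, ...) {
  cat(sprintf(
    "%d%% shift confidence interval (%s test inversion)\n  (%.*f, %.*f)   observed difference: %.4g\n",
    round(100 * x$level), x$test,
    max(0, ceiling(-log10(x$resolution))), x$lower,
    max(0, ceiling(-log10(x$resolution))), x$upper,
    x$estimate
  ))
  invisible(x)
}
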