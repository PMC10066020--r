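#' Tidy a permutation test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with the observed statistic,
#'   extreme-permutation count, total permutations, p-value, alternative
#'   and mode; `glance()` adds the p-values under every alternative and the
#'   Monte Carlo seed.
#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    n_extreme = x$n_extreme,
    n_total = x$n_total,
    p_value = x$p_value,
    alternative = x$alternative,
    mode = x$mode,
    method = x$method
  )
}

#' @rdname tidy.perm_test
#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    n_extreme = x$n_extreme,
    n_total = x$n_total,
    p_value = x$p_value,
    p_greater = x$p_greater,
    p_less = x$p_less,
    p_two_sided = x$p_two_sided,
    alternative = x$alternative,
    mode = x$mode,
    seed = x$seed %||% NA_integer_,
    method = x$method
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("%s = %.6g\n", x$statistic_label, x$statistic))
  if (x$mode == "exact") {
    cat(sprintf("exact: %d of %s relabelings as or more extreme (%s)\n",
                x$n_extreme, format(x$n_total, big.mark = ","), x$alternative))
    cat(sprintf("p-value = %d/%s = %.4g\n", x$n_extreme,
                format(x$n_total, big.mark = ","), x$p_value))
  } else {
    cat(sprintf("Monte Carlo: %d of %s draws as or more extreme (%s), seed %s\n",
                x$n_extreme, format(x$n_total, big.mark = ","),
                x$alternative, format(x$seed)))
    cat(sprintf("p-value = (%d + 1)/(%s + 1) = %.4g\n", x$n_extreme,
                format(x$n_total, big.mark = ","), x$p_value))
  }
  invisible(x)
}

#' Plot the permutation null distribution
#'
#' Histogram of the statistic over all (or all sampled) relabelings, with
#' the observed value marked. Requires the result to have been computed
#' with `keep_null = TRUE` (the default).
#'
#' @param object A `perm_test` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, bins = 30, ...) {
  if (is.null(object$null_distribution)) {
    abort("no stored null distribution; rerun with `keep_null = TRUE`.")
  }
  df <- tibble(statistic = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      title = object$method,
      subtitle = sprintf("observed %s = %.4g;  p (%s) = %.4g",
                         object$statistic_label, object$statistic,
                         object$alternative, object$p_value),
      x = object$statistic_label, y = "relabelings"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.perm_test
#' @param x A result object.
#' @exportS3Method generics::tidy
tidy.shift_ci <- function(x, ...) {
  tibble(
    lower = x$lower,
    upper = x$upper,
    level = x$level,
    estimate = x$estimate,
    test = x$test
  )
}

#' Plot the p-value curve of a shift confidence interval
#'
#' Shows the two-sided permutation p-value as a (step) function of the
#' hypothesized shift, the rejection threshold `alpha`, and the reported
#' interval.
#'
#' @param object A `shift_ci` object.
#' @param n_grid Number of shift values to evaluate.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.shift_ci <- function(object, n_grid = 101, ...) {
  lv <- levels(object$data$treatment)
  x <- object$data$value[object$data$treatment == lv[1]]
  y <- object$data$value[object$data$treatment == lv[2]]
  width <- object$upper - object$lower
  grid <- seq(object$lower - 0.25 * width, object$upper + 0.25 * width,
              length.out = n_grid)
  splits <- enumerate_relabelings(two_sample_scheme(length(x), length(y)))
  p_at <- function(delta) {
    pool <- c(x, y + delta)
    if (object$test == "mann_whitney") pool <- pooled_rank_transform(pool)
    stats <- group_sums(splits, pool, 2)
    stats <- stats[, 1] / length(x) - stats[, 2] / length(y)
    obs <- stats[1]
    sum(abs(stats) >= abs(obs) - 1e-9 * max(1, abs(obs))) / length(stats)
  }
  df <- tibble(shift = grid, p = vapply(grid, p_at, numeric(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$p)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::annotate("rect", xmin = object$lower, xmax = object$upper,
                      ymin = 0, ymax = 1, alpha = 0.08, fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("%d%% shift interval by test inversion (%s)",
                      round(100 * object$level), object$test),
      x = "hypothesized shift", y = "two-sided p-value"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.perm_test
#' @exportS3Method generics::tidy
tidy.perm_ols <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    statistic = unname(x$t_stats),
    p.value = unname(x$p_values)
  )
}

#' @rdname tidy.perm_test
#' @exportS3Method generics::glance
glance.perm_ols <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    statistic = x$f_stat,
    df.residual = x$df_residual
  )
}
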