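#' Permutation p-value for an arbitrary statistic and scheme
#'
#' The reference engine: computes the observed statistic, evaluates it under
#' every admissible relabeling of the scheme (or under `n_draws` random
#' relabelings), and counts how many are at least as extreme as the observed
#' value. Comparisons are non-strict — relabelings whose statistic exactly
#' ties the observed value count as extreme — with a small numerical
#' tolerance (`1e-9` relative to the observed magnitude) so that
#' floating-point noise cannot split exact ties.
#'
#' In exact mode the p-value is `n_extreme / n_total` and is always at least
#' `1 / n_total` because the identity labeling counts itself. In Monte Carlo
#' mode the add-one estimator `(n_extreme + 1) / (n_draws + 1)` is used, so
#' the estimated p-value is always strictly positive and valid.
#'
#' @param data A labeled data frame (see [labeled_data()]) whose `value`
#'   column is permuted. For sign-flip schemes, `value` must hold the
#'   matched-pair differences.
#' @param scheme A [perm_scheme][two_sample_scheme]. For stratified schemes,
#'   observations must be ordered stratum by stratum to match the scheme.
#' @param statistic A function `f(values, relabeling)` returning a scalar,
#'   where `relabeling` is one row of [enumerate_relabelings()] for the
#'   scheme; or the name of a built-in: `"mean_difference"`, `"anova_f"`,
#'   `"kruskal_h"`, `"jonckheere_j"`, `"directional_d"`, `"sign_mean"`.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#'   Nonnegative statistics (`anova_f`, `kruskal_h`) admit only `"greater"`.
#' @param mode `"auto"` (exact when the scheme fits under
#'   `exhaustive_limit`, otherwise Monte Carlo), `"exact"`, or
#'   `"monte_carlo"`.
#' @param n_draws,seed Monte Carlo sample size and seed (both required in
#'   Monte Carlo mode).
#' @param limit Exhaustive enumeration cap, see [exhaustive_limit()].
#' @param keep_null Store the permutation null distribution in the result
#'   (used by [autoplot.perm_test()]).
#'
#' @return A `perm_test` object; see [tidy.perm_test()].
#' @examples
#' d <- load_fixture("caginalp_prices")
#' permutation_pvalue(d, two_sample_scheme(3, 4), "mean_difference")
#' @export
permutation_pvalue <- function(data, scheme, statistic,
                               alternative = c("two_sided", "greater", "less"),
                               mode = c("auto", "exact", "monte_carlo"),
                               n_draws = NULL, seed = NULL,
                               limit = exhaustive_limit(),
                               keep_null = TRUE) {
  data <- validate_labeled_data(data)
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  stat <- resolve_statistic(statistic, scheme)
  if (stat$nonnegative && alternative != "greater") {
    abort(paste0("statistic `", stat$label,
                 "` is nonnegative; only `alternative = \"greater\"` is meaningful."))
  }
  run_perm_test(
    values = data$value, scheme = scheme, stat = stat,
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste("permutation test,", stat$label, "statistic")
  )
}

# ---- statistic descriptors ------------------------------------------------

# kind: evaluation strategy. "group_sums"-kind statistics are functions of the
# per-treatment sums only (the pooled multiset being invariant under
# relabeling), which allows vectorized evaluation of very large schemes.
make_stat <- function(label, kind, fun = NULL, sum_fun = NULL,
                      nonnegative = FALSE, rank_values = FALSE) {
  list(label = label, kind = kind, fun = fun, sum_fun = sum_fun,
       nonnegative = nonnegative, rank_values = rank_values)
}

resolve_statistic <- function(statistic, scheme) {
  if (is.function(statistic)) {
    return(make_stat("custom", "generic", fun = statistic))
  }
  if (!is.character(statistic) || length(statistic) != 1) {
    abort("`statistic` must be a function or the name of a built-in statistic.")
  }
  sizes <- scheme_treatment_sizes(scheme)
  switch(statistic,
    mean_difference = stat_mean_difference(sizes),
    anova_f = stat_anova_f(sizes),
    kruskal_h = stat_kruskal_h(sizes),
    directional_d = stat_directional_d(sizes),
    jonckheere_j = stat_jonckheere_j(sizes),
    sign_mean = stat_sign_mean(),
    abort(paste0("unknown built-in statistic `", statistic, "`."))
  )
}

# pooled per-treatment sizes (summed across strata for stratified schemes)
scheme_treatment_sizes <- function(scheme) {
  if (scheme$kind == "stratified") {
    per <- lapply(scheme$strata, function(s) s$group_sizes)
    k <- unique(lengths(per))
    if (length(k) != 1) {
      abort("all strata must have the same number of treatment groups.")
    }
    Reduce(`+`, per)
  } else if (scheme$kind %in% c("two_sample", "k_sample", "ordering")) {
    scheme$group_sizes
  } else {
    NULL
  }
}

stat_mean_difference <- function(sizes) {
  if (length(sizes) != 2) abort("mean_difference needs exactly two groups.")
  make_stat(
    "mean difference", "group_sums",
    fun = function(v, a) mean(v[a == 1]) - mean(v[a == 2]),
    sum_fun = function(S, v) S[, 1] / sizes[1] - S[, 2] / sizes[2]
  )
}

stat_anova_f <- function(sizes) {
  k <- length(sizes)
  make_stat(
    "one-way F", "group_sums", nonnegative = TRUE,
    fun = function(v, a) anova_f(split(v, factor(a, levels = seq_len(k)))),
    sum_fun = function(S, v) {
      n_total <- length(v)
      total_ss <- sum((v - mean(v))^2)
      between <- S^2 %*% (1 / sizes) - sum(v)^2 / n_total
      within <- total_ss - between
      as.vector((between / (k - 1)) / (within / (n_total - k)))
    }
  )
}

stat_kruskal_h <- function(sizes) {
  k <- length(sizes)
  make_stat(
    "Kruskal-Wallis H", "group_sums", nonnegative = TRUE, rank_values = TRUE,
    fun = function(v, a) kruskal_h(split(v, factor(a, levels = seq_len(k)))),
    sum_fun = function(S, v) {
      # v holds pooled mid-ranks here
      n_total <- length(v)
      total_ss <- sum((v - mean(v))^2)
      between <- S^2 %*% (1 / sizes) - sum(v)^2 / n_total
      as.vector((n_total - 1) * between / total_ss)
    }
  )
}

stat_directional_d <- function(sizes) {
  k <- length(sizes)
  make_stat(
    "directional difference D", "group_sums",
    fun = function(v, a) directional_d(split(v, factor(a, levels = seq_len(k)))),
    sum_fun = function(S, v) {
      out <- numeric(nrow(S))
      for (s in seq_len(k - 1)) {
        for (t in (s + 1):k) {
          out <- out + sizes[s] * S[, t] - sizes[t] * S[, s]
        }
      }
      out
    }
  )
}

stat_jonckheere_j <- function(sizes) {
  k <- length(sizes)
  make_stat(
    "Jonckheere-Terpstra J", "generic",
    fun = function(v, a) jonckheere_j(split(v, factor(a, levels = seq_len(k))))
  )
}

stat_sign_mean <- function() {
  make_stat(
    "mean difference", "sign_mean",
    fun = function(v, a) mean(v * a)
  )
}

# ---- core runner ----------------------------------------------------------

run_perm_test <- function(values, scheme, stat, alternative, mode,
                          n_draws = NULL, seed = NULL,
                          limit = exhaustive_limit(), keep_null = TRUE,
                          method = "permutation test", estimate = NULL) {
  if (length(values) != scheme$n) {
    abort("number of observations does not match the scheme.")
  }
  if (stat$rank_values) values <- pooled_rank_transform(values)

  fits <- log_count_permutations(scheme) <= log(limit)
  if (mode == "auto") mode <- if (fits) "exact" else "monte_carlo"
  if (mode == "exact" && !fits) check_exhaustive(scheme, limit)
  if (mode == "monte_carlo") {
    if (is.null(n_draws) || is.null(seed)) {
      abort("Monte Carlo mode requires both `n_draws` and `seed`.")
    }
  }

  identity_row <- identity_relabeling(scheme)
  stat_obs <- stat$fun(values, identity_row)

  null_stats <- if (mode == "exact") {
    exhaustive_null_stats(scheme, values, stat, limit)
  } else {
    A <- sample_relabelings(scheme, n_draws, seed)
    matrix_null_stats(A, values, stat)
  }

  assemble_perm_test(
    stat_obs = stat_obs, null_stats = null_stats, alternative = alternative,
    mode = mode, seed = seed, method = method,
    statistic_label = stat$label, estimate = estimate, scheme = scheme,
    keep_null = keep_null
  )
}

# build a perm_test result from an observed statistic and its null values
assemble_perm_test <- function(stat_obs, null_stats, alternative, mode,
                               seed = NULL, method = "permutation test",
                               statistic_label = "statistic", estimate = NULL,
                               scheme = NULL, keep_null = TRUE) {
  counts <- extreme_counts(null_stats, stat_obs)
  n_total <- length(null_stats)
  p <- if (mode == "exact") {
    lapply(counts, function(b) b / n_total)
  } else {
    lapply(counts, function(b) (b + 1) / (n_total + 1))
  }

  structure(
    list(
      statistic = stat_obs,
      estimate = estimate %||% stat_obs,
      n_extreme = counts[[alternative]],
      n_total = n_total,
      p_value = p[[alternative]],
      p_greater = p$greater,
      p_less = p$less,
      p_two_sided = p$two_sided,
      alternative = alternative,
      mode = if (mode == "exact") "exact" else "monte_carlo",
      seed = if (mode == "monte_carlo") seed else NULL,
      n_draws = if (mode == "monte_carlo") n_total else NULL,
      method = method,
      statistic_label = statistic_label,
      null_distribution = if (keep_null) as.numeric(null_stats) else NULL,
      scheme = scheme
    ),
    class = "perm_test"
  )
}

identity_relabeling <- function(scheme) {
  switch(scheme$kind,
    two_sample = ,
    k_sample = rep(seq_along(scheme$group_sizes), scheme$group_sizes),
    sign_flip = rep(1L, scheme$n),
    ordering = seq_len(scheme$n),
    stratified = unlist(lapply(scheme$strata, identity_relabeling), use.names = FALSE)
  )
}

# non-strict extreme counts under all three alternatives
extreme_counts <- function(null_stats, stat_obs) {
  tol <- 1e-9 * max(1, abs(stat_obs))
  list(
    greater = sum(null_stats >= stat_obs - tol),
    less = sum(null_stats <= stat_obs + tol),
    two_sided = sum(abs(null_stats) >= abs(stat_obs) - tol)
  )
}

exhaustive_null_stats <- function(scheme, values, stat, limit) {
  if (stat$kind == "group_sums") {
    S <- exhaustive_group_sums(scheme, values, limit)
    return(stat$sum_fun(S, values))
  }
  A <- enumerate_relabelings(scheme, limit)
  matrix_null_stats(A, values, stat)
}

matrix_null_stats <- function(A, values, stat) {
  if (stat$kind == "group_sums") {
    k <- max(A)
    return(stat$sum_fun(group_sums(A, values, k), values))
  }
  if (stat$kind == "sign_mean") {
    return(as.vector(A %*% values) / length(values))
  }
  vapply(seq_len(nrow(A)), function(i) stat$fun(values, A[i, ]), numeric(1))
}

# per-treatment sums under every relabeling; stratified schemes are expanded
# from per-stratum sums without materializing the full assignment matrix
exhaustive_group_sums <- function(scheme, values, limit) {
  if (scheme$kind %in% c("two_sample", "k_sample")) {
    A <- enumerate_relabelings(scheme, limit)
    return(group_sums(A, values, length(scheme$group_sizes)))
  }
  if (scheme$kind != "stratified") {
    abort("group-sum statistics need a split or stratified scheme.")
  }
  check_exhaustive(scheme, limit)
  k <- length(scheme$strata[[1]]$group_sizes)
  ends <- cumsum(vapply(scheme$strata, function(s) s$n, integer(1)))
  starts <- c(1L, head(ends, -1) + 1L)
  per <- lapply(seq_along(scheme$strata), function(s) {
    sub <- scheme$strata[[s]]
    A <- enumerate_relabelings(sub, limit)
    group_sums(A, values[starts[s]:ends[s]], k)
  })
  idx <- stratified_row_index(vapply(per, nrow, numeric(1)))
  out <- per[[1]][idx[[1]], , drop = FALSE]
  for (s in seq_along(per)[-1]) {
    out <- out + per[[s]][idx[[s]], , drop = FALSE]
  }
  out
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests, capping at 1. A thin,
#' name-stable wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' bonferroni_adjust(c(0.12, 0.028)) # 0.24, 0.056
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p_values, method = "bonferroni")
}
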