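#' Named permutation tests
#'
#' Ready-wired permutation tests for the standard experimental designs. All
#' take a labeled data frame first (columns `value`, `treatment`, optional
#' `stratum`, optional `block`; see [labeled_data()]) and return a
#' `perm_test` object that works with [tidy()], [glance()] and
#' [autoplot.perm_test()].
#'
#' * `pitman_test()` — two independent samples, difference of means on the
#'   raw measurements. With a `stratum` column, treatment labels are only
#'   permuted within strata and the statistic is the difference of the
#'   *pooled* treatment means across strata.
#' * `mann_whitney_test()` — the same test run on the pooled mid-ranks of
#'   the measurements (for stratified data, ranks are computed on the full
#'   pooled sample across strata).
#' * `fisher_pairs_test()` — matched pairs (`block` column): sign-flip test
#'   on the within-pair differences, statistic `d̄` (first treatment level
#'   minus second).
#' * `wilcoxon_signed_rank_test()` — the sign-flip test run on the signed
#'   ranks of the pair differences (see [signed_rank_transform()]).
#' * `permutation_f_test()` — `k >= 2` unordered samples, one-way F
#'   statistic; upper tail only. Stratified when a `stratum` column is
#'   present.
#' * `kruskal_wallis_test()` — exact Kruskal–Wallis: the same enumeration
#'   with the H statistic on pooled ranks.
#' * `jonckheere_test()` — `k` ordered samples, J = count of
#'   correctly-ordered cross-group pairs; supply the predicted treatment
#'   order via `order` (defaults to the treatment level order). Stratified
#'   when a `stratum` column is present.
#' * `directional_difference_test()` — magnitude-sensitive ordered
#'   alternative, D = sum of cross-group differences.
#' * `friedman_exact_test()` — `k` treatments within blocks: values are
#'   ranked within each block, treatment labels are permuted within blocks
#'   only, and the statistic is the between-treatment sum of squares of the
#'   within-block ranks (monotone-equivalent to the two-way ANOVA F on
#'   ranks, and defined even under perfect agreement across blocks).
#'
#' @param data A labeled data frame.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`; directional
#'   alternatives refer to the first treatment level (or the stated `order`)
#'   minus the second. F and H are nonnegative, upper-tail only.
#' @param order For the ordered-alternative tests, a character vector of
#'   treatment levels in increasing order of predicted effect.
#' @param mode,n_draws,seed,limit,keep_null See [permutation_pvalue()].
#'
#' @return A `perm_test` object.
#' @examples
#' pitman_test(load_fixture("caginalp_prices"), alternative = "two_sided")
#' fisher_pairs_test(load_fixture("davis_holt_market_power"),
#'                   alternative = "greater")
#' @name named_tests
NULL

#' @rdname named_tests
#' @export
pitman_test <- function(data, alternative = c("two_sided", "greater", "less"),
                        mode = c("auto", "exact", "monte_carlo"),
                        n_draws = NULL, seed = NULL,
                        limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  prep <- build_split_design(data, n_groups = 2)
  run_perm_test(
    values = prep$data$value, scheme = prep$scheme,
    stat = stat_mean_difference(scheme_treatment_sizes(prep$scheme)),
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("Pitman two-sample permutation test", prep$suffix)
  )
}

#' @rdname named_tests
#' @export
mann_whitney_test <- function(data, alternative = c("two_sided", "greater", "less"),
                              mode = c("auto", "exact", "monte_carlo"),
                              n_draws = NULL, seed = NULL,
                              limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  prep <- build_split_design(data, n_groups = 2)
  values <- pooled_rank_transform(prep$data$value)
  run_perm_test(
    values = values, scheme = prep$scheme,
    stat = stat_mean_difference(scheme_treatment_sizes(prep$scheme)),
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("Mann-Whitney test (Pitman on pooled ranks)", prep$suffix)
  )
}

#' @rdname named_tests
#' @export
fisher_pairs_test <- function(data, alternative = c("two_sided", "greater", "less"),
                              mode = c("auto", "exact", "monte_carlo"),
                              n_draws = NULL, seed = NULL,
                              limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  d <- block_differences(validate_labeled_data(data))
  run_perm_test(
    values = d, scheme = sign_flip_scheme(length(d)), stat = stat_sign_mean(),
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = "Fisher matched-pairs permutation test"
  )
}

#' @rdname named_tests
#' @export
wilcoxon_signed_rank_test <- function(data,
                                      alternative = c("two_sided", "greater", "less"),
                                      mode = c("auto", "exact", "monte_carlo"),
                                      n_draws = NULL, seed = NULL,
                                      limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  d <- signed_rank_transform(block_differences(validate_labeled_data(data)))
  run_perm_test(
    values = d, scheme = sign_flip_scheme(length(d)), stat = stat_sign_mean(),
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = "Wilcoxon signed-rank test (sign flips on signed ranks)"
  )
}

#' @rdname named_tests
#' @export
permutation_f_test <- function(data, mode = c("auto", "exact", "monte_carlo"),
                               n_draws = NULL, seed = NULL,
                               limit = exhaustive_limit(), keep_null = TRUE) {
  mode <- match.arg(mode)
  prep <- build_split_design(data)
  run_perm_test(
    values = prep$data$value, scheme = prep$scheme,
    stat = stat_anova_f(scheme_treatment_sizes(prep$scheme)),
    alternative = "greater", mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("permutation F test", prep$suffix)
  )
}

#' @rdname named_tests
#' @export
kruskal_wallis_test <- function(data, mode = c("auto", "exact", "monte_carlo"),
                                n_draws = NULL, seed = NULL,
                                limit = exhaustive_limit(), keep_null = TRUE) {
  mode <- match.arg(mode)
  prep <- build_split_design(data)
  run_perm_test(
    values = prep$data$value, scheme = prep$scheme,
    stat = stat_kruskal_h(scheme_treatment_sizes(prep$scheme)),
    alternative = "greater", mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("exact Kruskal-Wallis test", prep$suffix)
  )
}

#' @rdname named_tests
#' @export
jonckheere_test <- function(data, order = NULL,
                            alternative = c("greater", "less", "two_sided"),
                            mode = c("auto", "exact", "monte_carlo"),
                            n_draws = NULL, seed = NULL,
                            limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  prep <- build_split_design(reorder_treatments(data, order))
  run_perm_test(
    values = prep$data$value, scheme = prep$scheme,
    stat = stat_jonckheere_j(scheme_treatment_sizes(prep$scheme)),
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("Jonckheere-Terpstra trend test", prep$suffix)
  )
}

#' @rdname named_tests
#' @export
directional_difference_test <- function(data, order = NULL,
                                        alternative = c("greater", "less", "two_sided"),
                                        mode = c("auto", "exact", "monte_carlo"),
                                        n_draws = NULL, seed = NULL,
                                        limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  prep <- build_split_design(reorder_treatments(data, order))
  run_perm_test(
    values = prep$data$value, scheme = prep$scheme,
    stat = stat_directional_d(scheme_treatment_sizes(prep$scheme)),
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("directional difference test", prep$suffix)
  )
}

#' @rdname named_tests
#' @export
friedman_exact_test <- function(data, mode = c("auto", "exact", "monte_carlo"),
                                n_draws = NULL, seed = NULL,
                                limit = exhaustive_limit(), keep_null = TRUE) {
  mode <- match.arg(mode)
  data <- validate_labeled_data(data)
  if (!"block" %in% names(data)) {
    abort("the Friedman test needs a `block` column.")
  }
  # rank within each block, then permute treatment labels within blocks only
  data$value <- stats::ave(data$value, data$block,
                           FUN = function(v) rank(v, ties.method = "average"))
  data$stratum <- factor(data$block, levels = unique(data$block))
  data$block <- NULL
  prep <- build_split_design(data)
  if (!all(unlist(lapply(prep$scheme$strata, function(s) s$group_sizes)) == 1L)) {
    abort("every block must contain each treatment exactly once.")
  }
  run_perm_test(
    values = prep$data$value, scheme = prep$scheme,
    stat = stat_between_ss(scheme_treatment_sizes(prep$scheme)),
    alternative = "greater", mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = "exact Friedman test (within-block ranks)"
  )
}

# between-treatment sum of squares; used where the within-group variance can
# legitimately vanish (within-block ranks under perfect agreement)
stat_between_ss <- function(sizes) {
  k <- length(sizes)
  make_stat(
    "between-treatment rank SS", "group_sums", nonnegative = TRUE,
    fun = function(v, a) {
      s <- split(v, factor(a, levels = seq_len(k)))
      gm <- mean(v)
      sum(lengths(s) * (vapply(s, mean, numeric(1)) - gm)^2)
    },
    sum_fun = function(S, v) {
      as.vector(S^2 %*% (1 / sizes)) - sum(v)^2 / length(v)
    }
  )
}

#' Permutation test of correlation
#'
#' Tests for association between two paired variables by recomputing the
#' correlation coefficient under every reordering of one variable against
#' the other (`n!` orderings, or `n_draws` random ones).
#'
#' @param data A data frame containing the two variables.
#' @param x,y Unquoted column names of the paired variables.
#' @param method `"pearson"` (Eq.-11-style product-moment correlation on the
#'   raw values) or `"spearman"` (the same statistic on ranks).
#' @inheritParams named_tests
#' @return A `perm_test` object whose `statistic` is the observed
#'   correlation.
#' @examples
#' claims <- load_fixture("capra_claims")
#' a <- claims[claims$part == "A", ]
#' perm_cor_test(a, incentive, claim, alternative = "less")
#' @export
perm_cor_test <- function(data, x, y,
                          alternative = c("two_sided", "greater", "less"),
                          method = c("pearson", "spearman"),
                          mode = c("auto", "exact", "monte_carlo"),
                          n_draws = NULL, seed = NULL,
                          limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  mode <- match.arg(mode)
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  if (method == "spearman") {
    xv <- pooled_rank_transform(xv)
    yv <- pooled_rank_transform(yv)
  }
  stat <- make_stat(
    if (method == "pearson") "Pearson r" else "Spearman rho", "generic",
    fun = function(v, a) pearson_r(xv, v[a])
  )
  run_perm_test(
    values = yv, scheme = ordering_scheme(length(yv)), stat = stat,
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = paste0("permutation correlation test (", method, ")")
  )
}

#' Dispatch a named permutation test
#'
#' Thin string dispatcher used by the command-line interface; maps a test
#' name to the corresponding function of this package.
#'
#' @param data A labeled data frame.
#' @param test One of `"pitman"`, `"mann_whitney"`, `"fisher_pairs"`,
#'   `"wilcoxon_signed_rank"`, `"permutation_f"`, `"kruskal_wallis"`,
#'   `"jonckheere_terpstra"`, `"directional_difference"`, `"friedman"`.
#' @param ... Passed to the test function.
#' @return A `perm_test` object.
#' @export
perm_test <- function(data, test, ...) {
  fun <- switch(test,
    pitman = pitman_test,
    mann_whitney = mann_whitney_test,
    fisher_pairs = fisher_pairs_test,
    wilcoxon_signed_rank = wilcoxon_signed_rank_test,
    permutation_f = permutation_f_test,
    kruskal_wallis = kruskal_wallis_test,
    jonckheere_terpstra = jonckheere_test,
    directional_difference = directional_difference_test,
    friedman = friedman_exact_test,
    abort(paste0("unknown test `", test, "`."))
  )
  fun(data, ...)
}

# ---- design builders ------------------------------------------------------

# order observations (stratum, treatment) and build the matching scheme
build_split_design <- function(data, n_groups = NULL) {
  data <- validate_labeled_data(data)
  data$treatment <- droplevels(data$treatment)
  k <- nlevels(data$treatment)
  if (!is.null(n_groups) && k != n_groups) {
    abort(paste0("this test needs exactly ", n_groups, " treatment levels (got ", k, ")."))
  }
  if (k < 2) abort("need at least two treatment levels.")
  stratified <- "stratum" %in% names(data) && nlevels(droplevels(data$stratum)) > 1
  if (stratified) {
    data$stratum <- droplevels(data$stratum)
    data <- data[order(data$stratum, data$treatment), , drop = FALSE]
    counts <- table(data$stratum, data$treatment)
    if (any(counts == 0)) {
      abort("every stratum must contain every treatment level.")
    }
    schemes <- lapply(seq_len(nrow(counts)), function(s) {
      k_sample_scheme(as.integer(counts[s, ]))
    })
    scheme <- stratified_scheme(schemes)
    suffix <- " (stratified)"
  } else {
    data <- data[order(data$treatment), , drop = FALSE]
    sizes <- as.integer(table(data$treatment))
    scheme <- if (k == 2) two_sample_scheme(sizes[1], sizes[2]) else k_sample_scheme(sizes)
    suffix <- ""
  }
  list(data = data, scheme = scheme, suffix = suffix)
}

reorder_treatments <- function(data, order) {
  data <- validate_labeled_data(data)
  if (is.null(order)) return(data)
  if (!setequal(order, levels(droplevels(data$treatment)))) {
    abort("`order` must list every treatment level exactly once.")
  }
  data$treatment <- factor(as.character(data$treatment), levels = order)
  data
}
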