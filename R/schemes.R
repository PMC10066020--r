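#' Permutation schemes: the admissible relabelings implied by a design
#'
#' A permutation scheme is a declarative description of which relabelings of
#' the observations are equally likely under the null hypothesis of no
#' treatment effect, given the randomization of the experimental design:
#'
#' * `two_sample_scheme(n, m)` — all `choose(n + m, n)` splits of the pooled
#'   observations into samples of size `n` and `m`;
#' * `k_sample_scheme(sizes)` — all `n!/(n_1! ... n_k!)` assignments into
#'   groups of the given sizes (a full ordering of labels over `k`
#'   observations is the special case `sizes = rep(1, k)`);
#' * `sign_flip_scheme(n)` — all `2^n` sign vectors applied to `n`
#'   matched-pair differences (equivalent to swapping the treatment labels
#'   within a pair);
#' * `ordering_scheme(n)` — all `n!` reorderings of one variable against
#'   another (correlation and regression);
#' * `stratified_scheme(...)` — the Cartesian product of per-stratum
#'   schemes; observations never cross strata.
#'
#' @param n,m,sizes Positive group sizes.
#' @param kind Internal label distinguishing the two-sample special case.
#' @param ... For `stratified_scheme()`, one sub-scheme per stratum.
#' @return An object of class `perm_scheme`.
#' @examples
#' count_permutations(two_sample_scheme(3, 4)) # 35
#' count_permutations(stratified_scheme(
#'   two_sample_scheme(7, 5), two_sample_scheme(7, 5)
#' )) # 792 * 792
#' @export
two_sample_scheme <- function(n, m) {
  k_sample_scheme(c(n, m), kind = "two_sample")
}

#' @rdname two_sample_scheme
#' @export
k_sample_scheme <- function(sizes, kind = "k_sample") {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1 || any(sizes < 1)) abort("group sizes must be positive.")
  structure(
    list(kind = kind, group_sizes = sizes, n = sum(sizes), strata = NULL),
    class = "perm_scheme"
  )
}

#' @rdname two_sample_scheme
#' @export
sign_flip_scheme <- function(n) {
  n <- as.integer(n)
  if (n < 0) abort("`n` must be non-negative.")
  structure(
    list(kind = "sign_flip", group_sizes = n, n = n, strata = NULL),
    class = "perm_scheme"
  )
}

#' @rdname two_sample_scheme
#' @export
ordering_scheme <- function(n) {
  n <- as.integer(n)
  if (n < 1) abort("`n` must be positive.")
  structure(
    list(kind = "ordering", group_sizes = rep(1L, n), n = n, strata = NULL),
    class = "perm_scheme"
  )
}

#' @rdname two_sample_scheme
#' @export
stratified_scheme <- function(...) {
  strata <- list(...)
  if (length(strata) == 1 && is.list(strata[[1]]) && !inherits(strata[[1]], "perm_scheme")) {
    strata <- strata[[1]]
  }
  if (!length(strata) || !all(vapply(strata, inherits, logical(1), "perm_scheme"))) {
    abort("`stratified_scheme()` takes one `perm_scheme` per stratum.")
  }
  if (any(vapply(strata, function(s) s$kind, character(1)) == "stratified")) {
    abort("strata cannot be nested.")
  }
  structure(
    list(
      kind = "stratified",
      group_sizes = lapply(strata, function(s) s$group_sizes),
      n = sum(vapply(strata, function(s) s$n, integer(1))),
      strata = strata
    ),
    class = "perm_scheme"
  )
}

#' @export
print.perm_scheme <- function(x, ...) {
  if (x$kind == "stratified") {
    cat("<perm_scheme: stratified,", length(x$strata), "strata,",
        format(count_permutations(x), big.mark = ","), "relabelings>\n")
  } else {
    cat("<perm_scheme:", x$kind, "(",
        paste(x$group_sizes, collapse = ", "), "),",
        format(count_permutations(x), big.mark = ","), "relabelings>\n")
  }
  invisible(x)
}

#' Number of admissible relabelings of a scheme
#'
#' Closed-form cardinality of the relabeling set: `choose(n + m, n)` for a
#' two-sample split, the multinomial coefficient for a k-sample split, `2^n`
#' for sign flips, `n!` for orderings, and the product of per-stratum counts
#' for stratified schemes. No enumeration is performed. Counts are exact in
#' double precision below `2^53` (which covers any design one could
#' exhaustively enumerate); far larger schemes are reported to double
#' accuracy, and all internal feasibility checks compare log-counts so no
#' overflow can occur.
#'
#' @param scheme A [perm_scheme][two_sample_scheme].
#' @return The number of relabelings, as a double.
#' @examples
#' count_permutations(two_sample_scheme(3, 4)) # 35
#' count_permutations(k_sample_scheme(c(4, 4, 4))) # 34650
#' count_permutations(sign_flip_scheme(0)) # 1
#' @export
count_permutations <- function(scheme) {
  stopifnot(inherits(scheme, "perm_scheme"))
  switch(scheme$kind,
    two_sample = ,
    k_sample = multinomial_count(scheme$group_sizes),
    sign_flip = 2^scheme$n,
    ordering = factorial(scheme$n),
    stratified = prod(vapply(scheme$strata, count_permutations, numeric(1)))
  )
}

multinomial_count <- function(sizes) {
  rem <- sum(sizes)
  out <- 1
  for (s in sizes) {
    out <- out * choose(rem, s)
    rem <- rem - s
  }
  out
}

# log of the count; safe for astronomically large schemes
log_count_permutations <- function(scheme) {
  switch(scheme$kind,
    two_sample = ,
    k_sample = lfactorial(sum(scheme$group_sizes)) -
      sum(lfactorial(scheme$group_sizes)),
    sign_flip = scheme$n * log(2),
    ordering = lfactorial(scheme$n),
    stratified = sum(vapply(scheme$strata, log_count_permutations, numeric(1)))
  )
}

#' Default cap on exhaustive enumeration
#'
#' Above this many statistic evaluations the engine refuses exhaustive mode
#' and requires Monte Carlo sampling with an explicit `n_draws` and `seed`.
#' Override per call or via `options(exactperm.exhaustive_limit = ...)`.
#' @return The limit (default `2e6`).
#' @export
exhaustive_limit <- function() {
  getOption("exactperm.exhaustive_limit", 2e6)
}

check_exhaustive <- function(scheme, limit = exhaustive_limit()) {
  if (log_count_permutations(scheme) > log(limit)) {
    abort(paste0(
      "scheme has more than ", format(limit, scientific = FALSE),
      " relabelings; use Monte Carlo mode (`mode = \"monte_carlo\"` with ",
      "`n_draws` and `seed`) instead of exhaustive enumeration."
    ))
  }
  invisible(TRUE)
}

#' Enumerate every admissible relabeling
#'
#' Materializes the full relabeling set as an integer matrix with one row
#' per relabeling, in a deterministic lexicographic order whose first row is
#' always the identity (observed) labeling. Row entries are group indices
#' (1..k) for split schemes, signs (+1/-1) for sign-flip schemes, and a
#' permutation of `1:n` for ordering schemes. For stratified schemes the
#' columns are the observations of stratum 1, then stratum 2, and so on;
#' entries are group indices within the observation's own stratum, so no
#' relabeling ever moves an observation across strata.
#'
#' @inheritParams count_permutations
#' @param limit Refuse to materialize more than this many rows
#'   (see [exhaustive_limit()]).
#' @return An integer matrix with `count_permutations(scheme)` rows.
#' @examples
#' enumerate_relabelings(two_sample_scheme(2, 1))
#' enumerate_relabelings(sign_flip_scheme(1)) # (+1), (-1)
#' @export
enumerate_relabelings <- function(scheme, limit = exhaustive_limit()) {
  stopifnot(inherits(scheme, "perm_scheme"))
  check_exhaustive(scheme, limit)
  switch(scheme$kind,
    two_sample = ,
    k_sample = enum_k_sample(scheme$group_sizes),
    sign_flip = enum_sign_flip(scheme$n),
    ordering = enum_orderings(scheme$n),
    stratified = enum_stratified(scheme, limit)
  )
}

enum_k_sample <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  if (k == 1) return(matrix(1L, nrow = 1, ncol = n))
  cmb <- combn(n, sizes[1])
  sub <- enum_k_sample(sizes[-1]) + 1L
  n_c <- ncol(cmb)
  n_s <- nrow(sub)
  out <- matrix(0L, nrow = n_c * n_s, ncol = n)
  for (i in seq_len(n_c)) {
    idx <- cmb[, i]
    rows <- ((i - 1L) * n_s + 1L):(i * n_s)
    out[rows, idx] <- 1L
    out[rows, -idx] <- sub
  }
  out
}

enum_sign_flip <- function(n) {
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  # row i encodes the bits of i - 1; first row is the identity (all +1)
  i <- 0:(2^n - 1)
  out <- matrix(0L, nrow = length(i), ncol = n)
  for (j in seq_len(n)) {
    out[, j] <- 1L - 2L * (i %/% 2^(n - j) %% 2L)
  }
  out
}

enum_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- enum_orderings(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    rows <- row:(row + nrow(sub) - 1L)
    out[rows, 1] <- first
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1)
    row <- row + nrow(sub)
  }
  out
}

# expansion indices: row r of the product maps to row idx[[s]][r] of stratum s,
# with the first stratum varying slowest (lexicographic)
stratified_row_index <- function(counts) {
  total <- prod(counts)
  lapply(seq_along(counts), function(s) {
    each <- prod(counts[seq_along(counts) > s])
    times <- total / (counts[s] * each)
    rep(rep(seq_len(counts[s]), each = each), times = times)
  })
}

enum_stratified <- function(scheme, limit) {
  subs <- lapply(scheme$strata, enumerate_relabelings, limit = limit)
  counts <- vapply(subs, nrow, numeric(1))
  idx <- stratified_row_index(counts)
  do.call(cbind, lapply(seq_along(subs), function(s) subs[[s]][idx[[s]], , drop = FALSE]))
}

#' Sample admissible relabelings uniformly at random
#'
#' Draws `n_draws` relabelings independently and uniformly (with replacement
#' across draws) from the admissible set of a scheme. The identity labeling
#' is not forcibly included; it enters the Monte Carlo p-value through the
#' add-one estimator (see [permutation_pvalue()]). The same `seed` always
#' yields the same stream.
#'
#' @inheritParams count_permutations
#' @param n_draws Number of draws (at least 1).
#' @param seed Integer seed; required for reproducibility.
#' @return An integer matrix with `n_draws` rows, same encoding as
#'   [enumerate_relabelings()].
#' @export
sample_relabelings <- function(scheme, n_draws, seed = NULL) {
  stopifnot(inherits(scheme, "perm_scheme"))
  n_draws <- as.integer(n_draws)
  if (n_draws < 1) abort("`n_draws` must be at least 1.")
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_relabelings(scheme, n_draws)))
  }
  switch(scheme$kind,
    two_sample = ,
    k_sample = {
      base <- rep(seq_along(scheme$group_sizes), scheme$group_sizes)
      n <- scheme$n
      t(vapply(seq_len(n_draws), function(i) base[sample.int(n)], integer(n)))
    },
    sign_flip = matrix(
      sample(c(-1L, 1L), n_draws * scheme$n, replace = TRUE),
      nrow = n_draws
    ),
    ordering = t(vapply(seq_len(n_draws), function(i) sample.int(scheme$n),
                        integer(scheme$n))),
    stratified = do.call(cbind, lapply(scheme$strata, sample_relabelings, n_draws = n_draws))
  )
}

# per-group sums of `values` for every row of an assignment matrix
group_sums <- function(assignments, values, k) {
  out <- matrix(0, nrow = nrow(assignments), ncol = k)
  for (j in seq_len(k)) {
    out[, j] <- (assignments == j) %*% values
  }
  out
}
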