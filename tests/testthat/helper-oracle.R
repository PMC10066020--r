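# Independent brute-force oracles: direct nested loops over relabelings,
# sharing no code with the package engine. Non-strict (>=) counting with a
# small tolerance, like the convention the engine documents.

oracle_count <- function(stats, obs, alternative) {
  tol <- 1e-9 * max(1, abs(obs))
  switch(alternative,
    greater = sum(stats >= obs - tol),
    less = sum(stats <= obs + tol),
    two_sided = sum(abs(stats) >= abs(obs) - tol)
  )
}

# two-sample: every subset of size n1 plays sample 1
oracle_two_sample <- function(x, y, alternative, statistic = NULL) {
  if (is.null(statistic)) statistic <- function(a, b) mean(a) - mean(b)
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  stats <- numeric(ncol(idx))
  for (i in seq_len(ncol(idx))) {
    stats[i] <- statistic(pool[idx[, i]], pool[-idx[, i]])
  }
  obs <- statistic(x, y)
  list(n_extreme = oracle_count(stats, obs, alternative), n_total = ncol(idx),
       p = oracle_count(stats, obs, alternative) / ncol(idx))
}

# k-sample: recursive assignment of the pooled values to groups
oracle_k_sample <- function(samples, alternative, statistic) {
  pool <- unlist(samples, use.names = FALSE)
  sizes <- lengths(samples)
  assignments <- list()
  recurse <- function(remaining_idx, sizes_left, acc) {
    if (!length(sizes_left)) {
      assignments[[length(assignments) + 1]] <<- acc
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining_idx, sizes_left[1], simplify = FALSE)
    for (p in picks) {
      recurse(setdiff(remaining_idx, p), sizes_left[-1], c(acc, list(p)))
    }
  }
  recurse(seq_along(pool), sizes, list())
  stats <- vapply(assignments, function(a) {
    statistic(lapply(a, function(ix) pool[ix]))
  }, numeric(1))
  obs <- statistic(samples)
  list(n_extreme = oracle_count(stats, obs, alternative),
       n_total = length(stats),
       p = oracle_count(stats, obs, alternative) / length(stats))
}

# matched pairs: every sign vector applied to the differences
oracle_sign_flip <- function(d, alternative, statistic = mean) {
  n <- length(d)
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  stats <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) stats[i] <- statistic(d * grid[i, ])
  obs <- statistic(d)
  list(n_extreme = oracle_count(stats, obs, alternative), n_total = nrow(grid),
       p = oracle_count(stats, obs, alternative) / nrow(grid))
}

# correlation: every reordering of y against x
oracle_orderings <- function(v) {
  if (length(v) == 1) return(matrix(v))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], oracle_orderings(v[-i]))
  }))
}

oracle_correlation <- function(x, y, alternative) {
  perms <- oracle_orderings(seq_along(y))
  stats <- vapply(seq_len(nrow(perms)), function(i) {
    suppressWarnings(stats::cor(x, y[perms[i, ]]))
  }, numeric(1))
  obs <- stats::cor(x, y)
  list(n_extreme = oracle_count(stats, obs, alternative),
       n_total = length(stats),
       p = oracle_count(stats, obs, alternative) / length(stats))
}

# stratified two-sample: cartesian product of per-stratum splits, pooled
# treatment-mean-difference statistic
oracle_stratified_two_sample <- function(xs, ys, alternative, ranks = FALSE) {
  pools <- mapply(function(x, y) c(x, y), xs, ys, SIMPLIFY = FALSE)
  if (ranks) {
    all_values <- unlist(pools, use.names = FALSE)
    rk <- rank(all_values, ties.method = "average")
    ix <- 0
    pools <- lapply(pools, function(p) {
      out <- rk[ix + seq_along(p)]
      ix <<- ix + length(p)
      out
    })
  }
  n1s <- lengths(xs)
  split_sets <- lapply(seq_along(pools), function(s) {
    utils::combn(length(pools[[s]]), n1s[s], simplify = FALSE)
  })
  combos <- expand.grid(lapply(split_sets, seq_along))
  stat_of <- function(pick_idx) {
    g1 <- c(); g2 <- c()
    for (s in seq_along(pools)) {
      sel <- split_sets[[s]][[pick_idx[s]]]
      g1 <- c(g1, pools[[s]][sel])
      g2 <- c(g2, pools[[s]][-sel])
    }
    mean(g1) - mean(g2)
  }
  stats <- apply(combos, 1, stat_of)
  obs_idx <- vapply(seq_along(pools), function(s) {
    which(vapply(split_sets[[s]], function(sel) identical(sel, seq_len(n1s[s])),
                 logical(1)))
  }, numeric(1))
  obs <- stat_of(obs_idx)
  list(n_extreme = oracle_count(stats, obs, alternative),
       n_total = length(stats),
       p = oracle_count(stats, obs, alternative) / length(stats))
}
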