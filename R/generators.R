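#' Synthetic data generators
#'
#' Reproducible simulated datasets with the statistical structure the tests
#' assume, used for property tests and power illustrations. Setting the
#' effect parameter to zero always produces exchangeable data satisfying
#' the corresponding null hypothesis.
#'
#' * `generate_shift_data()` — two independent samples from a common
#'   distribution, the first shifted by `shift` (the two-sample shift
#'   model).
#' * `generate_paired_data()` — matched pairs sharing a block-level offset
#'   (block heterogeneity) plus an additive treatment effect; emulates
#'   within-subjects designs where groups differ far more than treatments.
#' * `generate_stratified_data()` — two-sample strata with stratum-level
#'   location offsets and a common treatment effect.
#' * `generate_linear_data()` — covariate, regressor and response following
#'   `y = alpha + beta x + delta z + eps`.
#'
#' @param n,m Sample sizes of the two treatment groups.
#' @param shift Location shift added to the first treatment group.
#' @param distribution Base distribution of the noise:
#'   `"normal"`, `"uniform"` or `"exponential"` (unit scale).
#' @param seed Integer seed (required; all generators are deterministic
#'   given the seed).
#' @param n_pairs Number of matched pairs.
#' @param effect Additive treatment effect.
#' @param block_sd Standard deviation of the shared block offsets.
#' @param noise_sd Residual noise standard deviation.
#' @param strata_sizes List of two-element vectors, one per stratum: group
#'   sizes of the two treatments in that stratum.
#' @param stratum_offsets Numeric vector of per-stratum location offsets
#'   (recycled).
#' @param alpha,beta,delta Linear-model coefficients.
#' @return A labeled tibble (`generate_linear_data()` returns a tibble with
#'   columns `x`, `z`, `y`).
#' @examples
#' generate_shift_data(5, 5, shift = 0, seed = 1)
#' @export
generate_shift_data <- function(n, m, shift = 0,
                                distribution = c("normal", "uniform", "exponential"),
                                seed) {
  distribution <- match.arg(distribution)
  if (n < 1 || m < 1) abort("sample sizes must be positive.")
  withr::with_seed(seed, {
    noise <- draw_noise(n + m, distribution)
    labeled_data(
      value = noise + rep(c(shift, 0), c(n, m)),
      treatment = rep(c("treated", "control"), c(n, m))
    )
  })
}

#' @rdname generate_shift_data
#' @export
generate_paired_data <- function(n_pairs, effect = 0, block_sd = 1,
                                 noise_sd = 1, seed) {
  if (n_pairs < 1) abort("`n_pairs` must be positive.")
  withr::with_seed(seed, {
    offsets <- rnorm(n_pairs, sd = block_sd)
    labeled_data(
      value = c(offsets + effect + rnorm(n_pairs, sd = noise_sd),
                offsets + rnorm(n_pairs, sd = noise_sd)),
      treatment = rep(c("treated", "control"), each = n_pairs),
      block = rep(sprintf("B%02d", seq_len(n_pairs)), 2)
    )
  })
}

#' @rdname generate_shift_data
#' @export
generate_stratified_data <- function(strata_sizes, effect = 0,
                                     stratum_offsets = 0, seed) {
  if (!is.list(strata_sizes) || !length(strata_sizes)) {
    abort("`strata_sizes` must be a non-empty list of two group sizes per stratum.")
  }
  offsets <- rep_len(stratum_offsets, length(strata_sizes))
  withr::with_seed(seed, {
    parts <- lapply(seq_along(strata_sizes), function(s) {
      sz <- strata_sizes[[s]]
      if (length(sz) != 2 || any(sz < 1)) {
        abort("each stratum needs two positive group sizes.")
      }
      tibble(
        value = offsets[s] + rnorm(sum(sz)) + rep(c(effect, 0), sz),
        treatment = rep(c("treated", "control"), sz),
        stratum = sprintf("G%02d", s)
      )
    })
    out <- dplyr::bind_rows(parts)
    labeled_data(out$value, out$treatment, stratum = out$stratum)
  })
}

#' @rdname generate_shift_data
#' @export
generate_linear_data <- function(n, alpha = 0, beta = 0, delta = 0,
                                 noise_sd = 1, seed) {
  if (n < 3) abort("need at least 3 observations.")
  withr::with_seed(seed, {
    x <- rnorm(n)
    z <- rnorm(n)
    tibble(
      x = x,
      z = z,
      y = alpha + beta * x + delta * z + rnorm(n, sd = noise_sd)
    )
  })
}

draw_noise <- function(n, distribution) {
  switch(distribution,
    normal = rnorm(n),
    uniform = runif(n, -0.5, 0.5),
    exponential = rexp(n) - 1
  )
}
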