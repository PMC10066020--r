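#' Ordinary least squares fit
#'
#' Classical OLS with homoskedastic standard errors, wrapped so the result
#' carries exactly the pieces the permutation procedures need (coefficients,
#' standard errors, t statistics, overall F, fitted values and residuals)
#' and works with [tidy()] and [glance()].
#'
#' @param data A data frame.
#' @param formula Model formula, e.g. `y ~ x + z`.
#' @return A `perm_ols` object.
#' @examples
#' claims <- load_fixture("capra_claims")
#' a <- claims[claims$part == "A", ]
#' ols_fit(a, claim ~ incentive)
#' @export
ols_fit <- function(data, formula) {
  fit <- lm(formula, data = data)
  qr_rank <- fit$rank
  p <- length(coef(fit))
  if (qr_rank < p) abort("design matrix is rank deficient.")
  n <- length(fitted(fit))
  if (n <= p) abort("need more observations than coefficients.")
  sm <- suppressWarnings(summary(fit)) # silence the zero-residual edge case
  structure(
    list(
      coefficients = coef(fit),
      standard_errors = sm$coefficients[, "Std. Error"],
      t_stats = sm$coefficients[, "t value"],
      p_values = sm$coefficients[, "Pr(>|t|)"],
      f_stat = if (!is.null(sm$fstatistic)) unname(sm$fstatistic[1]) else NA_real_,
      df_residual = fit$df.residual,
      r_squared = sm$r.squared,
      sigma = sm$sigma,
      fitted = fitted(fit),
      residuals = resid(fit),
      formula = formula,
      lm = fit
    ),
    class = "perm_ols"
  )
}

#' @export
print.perm_ols <- function(x, ...) {
  cat("OLS fit:", deparse(x$formula), "\n")
  print(round(cbind(
    estimate = x$coefficients, std.error = x$standard_errors,
    t = x$t_stats
  ), 4))
  invisible(x)
}

#' Simple permutation regression (full reordering of the response)
#'
#' For the bivariate model `y = α + δ z + ε`, under `H0: δ = 0` every
#' ordering of the response against the regressor is equally likely, so the
#' observed t statistic for `δ` is compared against the t statistics from
#' all `n!` reorderings of `y` (or `n_draws` random ones).
#'
#' If the response is constant every permutation t statistic is undefined;
#' the test then reports `p = 1` (there is no evidence against the null in
#' data with no variation).
#'
#' @param data A data frame.
#' @param formula A bivariate formula `response ~ regressor`.
#' @inheritParams named_tests
#' @return A `perm_test` object whose `statistic` is the observed t.
#' @examples
#' claims <- load_fixture("capra_claims")
#' a <- claims[claims$part == "A", ]
#' perm_lm_test(a, claim ~ incentive) # 12/720
#' @export
perm_lm_test <- function(data, formula,
                         alternative = c("two_sided", "greater", "less"),
                         mode = c("auto", "exact", "monte_carlo"),
                         n_draws = NULL, seed = NULL,
                         limit = exhaustive_limit(), keep_null = TRUE) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  if (ncol(X) != 2) {
    abort("`perm_lm_test()` is for the bivariate model `y ~ z` only; use `freedman_lane_test()` for more regressors.")
  }
  y <- stats::model.response(mf)
  run_ordering_regression(
    X = X, y = y, coef_index = 2L, y_builder = function(ord) y[ord],
    alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
    limit = limit, keep_null = keep_null,
    method = "simple permutation regression (t statistic, response reordering)"
  )
}

#' Freedman-Lane permutation test for regression with nuisance covariates
#'
#' Tests `H0: δ = 0` in `y = Xβ + Zδ + ε`, where `X` holds nuisance
#' covariates (always including the intercept) whose influence on `y` must
#' not be destroyed by permutation. The procedure:
#'
#' 1. fit the full model and record the observed statistic (t for a single
#'    coefficient of interest, or the partial F for several);
#' 2. fit the reduced model `y = Xβ + ε`, keeping its fitted values `ŷ` and
#'    residuals `r`;
#' 3. for each permutation `π`, build `y_π = ŷ + π(r)` (the identity
#'    permutation reconstructs `y` exactly);
#' 4. refit the full model on `y_π` and record the statistic;
#' 5. count permutations at least as extreme as the observed value under
#'    the engine's non-strict rule.
#'
#' All `n!` orderings of the residual vector are enumerated when feasible
#' (equal residuals are treated as positionally distinct, keeping the
#' denominator at `n!`); otherwise supply `n_draws` and `seed`.
#'
#' @param data A data frame.
#' @param formula Full-model formula, e.g. `y ~ x + z`.
#' @param interest Character vector naming the model terms of interest
#'   (`Z`); every other term is a nuisance covariate.
#' @param statistic `"t"` (single coefficient of interest) or `"F"` (joint
#'   test of all interest terms).
#' @inheritParams named_tests
#' @return A `perm_test` object.
#' @examples
#' claims <- load_fixture("capra_claims")
#' wide <- data.frame(
#'   claim_a = claims$claim[claims$part == "A"],
#'   claim_b = claims$claim[claims$part == "B"],
#'   incentive_b = claims$incentive[claims$part == "B"]
#' )
#' freedman_lane_test(wide, claim_b ~ claim_a + incentive_b,
#'                    interest = "incentive_b") # 35/720
#' @export
freedman_lane_test <- function(data, formula, interest,
                               statistic = c("t", "F"),
                               alternative = c("two_sided", "greater", "less"),
                               mode = c("auto", "exact", "monte_carlo"),
                               n_draws = NULL, seed = NULL,
                               limit = exhaustive_limit(), keep_null = TRUE) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  mf <- stats::model.frame(formula, data)
  X_full <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  asg <- attr(X_full, "assign")
  labels <- attr(stats::terms(formula, data = data), "term.labels")
  if (!all(interest %in% labels)) {
    abort("`interest` must name terms of the model formula.")
  }
  interest_cols <- which(asg %in% which(labels %in% interest))
  if (!length(interest_cols)) abort("no design columns match `interest`.")
  if (statistic == "t" && length(interest_cols) != 1) {
    abort("the t statistic needs exactly one coefficient of interest; use `statistic = \"F\"`.")
  }
  X_red <- X_full[, -interest_cols, drop = FALSE]
  if (qr(X_full)$rank < ncol(X_full)) abort("design matrix is rank deficient.")

  red <- lm.fit(X_red, y)
  yhat <- red$fitted.values
  r <- red$residuals

  if (statistic == "t") {
    run_ordering_regression(
      X = X_full, y = y, coef_index = interest_cols,
      y_builder = function(ord) yhat + r[ord],
      alternative = alternative, mode = mode, n_draws = n_draws, seed = seed,
      limit = limit, keep_null = keep_null,
      method = "Freedman-Lane permutation test (t statistic)"
    )
  } else {
    if (alternative != "greater" && alternative != "two_sided") {
      abort("the F statistic is nonnegative; use alternative \"greater\".")
    }
    run_ordering_regression(
      X = X_full, y = y, coef_index = interest_cols, f_reduced = X_red,
      y_builder = function(ord) yhat + r[ord],
      alternative = "greater", mode = mode, n_draws = n_draws, seed = seed,
      limit = limit, keep_null = keep_null,
      method = "Freedman-Lane permutation test (partial F statistic)"
    )
  }
}

# shared machinery: evaluate the t (or partial F) statistic of the fixed
# design `X` on a response rebuilt from every ordering, fully vectorized
run_ordering_regression <- function(X, y, coef_index, y_builder,
                                    f_reduced = NULL,
                                    alternative, mode, n_draws, seed,
                                    limit, keep_null, method) {
  n <- length(y)
  scheme <- ordering_scheme(n)
  fits <- log_count_permutations(scheme) <= log(limit)
  if (mode == "auto") mode <- if (fits) "exact" else "monte_carlo"
  if (mode == "exact" && !fits) check_exhaustive(scheme, limit)
  if (mode == "monte_carlo" && (is.null(n_draws) || is.null(seed))) {
    abort("Monte Carlo mode requires both `n_draws` and `seed`.")
  }

  A <- if (mode == "exact") {
    enumerate_relabelings(scheme, limit)
  } else {
    sample_relabelings(scheme, n_draws, seed)
  }
  # responses, one column per ordering; identity ordering is row 1 in exact mode
  Ymat <- vapply(seq_len(nrow(A)), function(i) y_builder(A[i, ]), numeric(n))

  stats <- if (is.null(f_reduced)) {
    perm_t_stats(X, Ymat, coef_index)
  } else {
    perm_partial_f_stats(X, f_reduced, Ymat, length(coef_index))
  }
  obs <- if (is.null(f_reduced)) {
    perm_t_stats(X, matrix(y, ncol = 1), coef_index)
  } else {
    perm_partial_f_stats(X, f_reduced, matrix(y, ncol = 1), length(coef_index))
  }

  if (!is.finite(obs) || (stats::sd(y) == 0)) {
    # degenerate response: statistic undefined under every relabeling
    stats <- rep(0, length(stats))
    obs <- 0
  }

  assemble_perm_test(
    stat_obs = obs, null_stats = stats, alternative = alternative,
    mode = mode, seed = seed, method = method,
    statistic_label = if (is.null(f_reduced)) "t" else "partial F",
    scheme = scheme, keep_null = keep_null
  )
}

# t statistics of coefficient `j` for every column of Ymat (n x B)
perm_t_stats <- function(X, Ymat, j) {
  xtx_inv <- chol2inv(chol(crossprod(X)))
  coefs <- xtx_inv %*% crossprod(X, Ymat) # p x B
  fit <- X %*% coefs
  rss <- pmax(colSums(Ymat^2) - colSums(fit * Ymat), 0)
  df <- nrow(X) - ncol(X)
  se <- sqrt(rss / df * xtx_inv[j, j])
  t <- as.vector(coefs[j, ] / se)
  t[is.nan(t)] <- 0 # 0/0: no signal, no noise
  t
}

# partial F comparing the full design against the reduced design
perm_partial_f_stats <- function(X_full, X_red, Ymat, q) {
  rss_of <- function(X) {
    xtx_inv <- chol2inv(chol(crossprod(X)))
    coefs <- xtx_inv %*% crossprod(X, Ymat)
    pmax(colSums(Ymat^2) - colSums((X %*% coefs) * Ymat), 0)
  }
  rss_full <- rss_of(X_full)
  rss_red <- rss_of(X_red)
  df <- nrow(X_full) - ncol(X_full)
  f <- ((rss_red - rss_full) / q) / (rss_full / df)
  f <- as.vector(f)
  f[is.nan(f)] <- 0
  f
}
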