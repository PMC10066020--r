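---
title: "Permutation inference for small experimental samples: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for small experimental samples: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactperm)
```

## The model

All tests in this package share one construction. An experiment randomly
assigns observational units to treatments; under the null hypothesis of no
treatment effect the observed measurements are exchangeable across the
labels that the randomization could have produced. The set of *admissible
relabelings* is therefore a property of the design, not of the data:

| design | admissible relabelings | count |
|---|---|---|
| two independent samples (n, m) | all splits of the pooled values | `C(n+m, n)` |
| k independent samples (n₁…n_k) | all group assignments | `n!/(n₁!⋯n_k!)` |
| n matched pairs | all sign vectors on the pair differences | `2ⁿ` |
| paired variables (correlation, regression) | all orderings of one variable | `n!` |
| stratified design | Cartesian product of per-stratum schemes | product |

Given a statistic `T`, the exact p-value is the fraction of admissible
relabelings whose statistic is at least as extreme as the observed value:
two-sided `P(|T_i| ≥ |T_obs|)`, one-sided `P(T_i ≥ T_obs)` or
`P(T_i ≤ T_obs)`. The two-sided p-value is computed literally from this
definition, *not* as twice the one-sided value — on asymmetric null sets the
two differ, and the literal count is the probability statement the test
makes.

Two structural facts follow. First, the null distribution is discrete: with
3 vs 4 observations no configuration can beat `p = 1/35 ≈ 0.029`, so users
should read permutation p-values against the achievable levels of their
design, not against habitual thresholds. Second, the identity labeling
always counts itself, so exact p-values are bounded below by `1/N` and the
test can never anti-conservatively report zero.

### Shift models and what rejection means

For two-sample and paired location tests we follow the usual shift-model
framing: the treatment distributions differ, if at all, by a location shift.
Permutation tests are valid level-α tests of the sharp null of *identical*
distributions regardless; the shift assumption is what licenses attributing
a rejection to a difference in central tendency rather than in shape or
spread. The package does not implement the modified procedures needed when
distributions may differ in variance under the alternative of interest;
that is out of scope.

## Counting conventions and numerical choices

* **Non-strict comparisons.** Relabelings whose statistic exactly equals the
  observed value count as extreme. This is both the standard definition and
  a practical necessity: rank statistics produce massive ties, and the
  reference extreme counts on the bundled datasets (e.g. 86/924 rank-based
  splits, 11,577/627,264 stratified rank splits) are reproducible only
  under this rule.
* **Tie tolerance.** Statistics are compared with tolerance
  `1e-9 × max(1, |T_obs|)`. Rank and count statistics are integers or
  half-integers and the bundled level data are exact decimals, so this
  tolerance absorbs floating-point noise without ever bridging genuinely
  distinct values.
* **Exhaustive limit.** Enumeration is refused above 2×10⁶ statistic
  evaluations (override via `options(exactperm.exhaustive_limit = )`). The
  largest bundled exact analysis (627,264 stratified splits) stays
  comfortably under it; anything larger is the natural Monte Carlo regime.
* **Monte Carlo estimator.** Random relabelings are drawn i.i.d. uniformly
  (with replacement across draws), and the p-value is `(b + 1)/(B + 1)`.
  The identity labeling is not forcibly inserted into the sample; the
  add-one estimator is what keeps the estimate a valid, strictly positive
  p-value. With 999,999 draws and no extreme draw this reports the familiar
  "p < 0.001".
* **Counts as doubles.** Scheme cardinalities are computed in closed form
  and returned as doubles — exact below 2⁵³, which covers any scheme one
  could conceivably enumerate. Feasibility checks compare log-counts, so
  astronomically large designs (e.g. full orderings of hundreds of
  observations) never overflow; their exact cardinality is simply not a
  quantity the engine ever needs.
* **Deterministic enumeration order.** Relabelings are generated in a fixed
  lexicographic order with the identity labeling first, so exact counts are
  bit-reproducible and the identity's statistic is directly inspectable as
  `null_distribution[1]`.

## Statistics: definitions and deliberate choices

**Ranks.** `pooled_rank_transform()` uses mid-ranks for ties throughout.
None of the bundled level-data examples contains pooled ties, so this choice
is unconstrained by the reference results; mid-ranks are the standard
convention and keep the rank sum at `n(n+1)/2` identically.

**Signed ranks.** `signed_rank_transform()` ranks `|d|` with zeros included
and gives a zero difference a positive sign: `(−6, 4, 0, −3)` becomes
`(−4, 3, 1, −2)`. This departs from the "drop zeros" convention of some
texts. Keeping zeros makes the transform a pure preprocessing step — the
sign-flip scheme still has all `2ⁿ` points — at the cost of a (harmless,
sign-symmetric under the null only asymptotically) positive tie-break for
exact zeros. Users preferring the drop-zeros convention can filter pairs
before testing.

**Kruskal–Wallis H.** We use the standard definition
`H = (N−1) · Σ n_j (r̄_j − r̄)² / Σ_{ij} (r_{ij} − r̄)²` — between-group rank
sum of squares over *total* rank sum of squares — which equals the statistic
of `stats::kruskal.test()` including its tie correction. Because the total
sum of squares is invariant under relabeling, any monotone variant of H
(e.g. normalizing by the within-group sum of squares instead) yields the
identical permutation test; the definition only matters for the printed
value of the statistic, and we print the standard one.

**Jonckheere–Terpstra J.** Strict inequality: tied cross-group pairs
contribute nothing. With 2 observations per group and a tie present, J
tops out below its ceiling, which is exactly how the reference analysis of
the trading-rules data counts it (J = 11 of a possible 12).

**Directional difference D.** `D = Σ_{s<t} (n_s S_t − n_t S_s)` in terms of
group sums `S_j` — algebraically identical to the sum of all cross-column
differences, but linear in the group sums, which is what makes the
exhaustive stratified evaluation cheap.

**Friedman analogue.** The within-block design names a test but not a
formula, so this is an explicit interpretation: values are ranked within
each block, treatment labels are permuted within blocks only, and the
statistic is the between-treatment sum of squares of the within-block
ranks. With complete blocks the total rank sum of squares is invariant
under within-block permutation, so this statistic is monotone-equivalent to
the two-way ANOVA F on ranks — same extreme set, same p-value — while
remaining well-defined in the boundary case of perfect agreement across
blocks, where the F ratio degenerates to 0/0.

## Stratified tests

With a nuisance grouping (subject pool, gender, payoff scale, session
cohort), treatment labels are permuted *within* strata and never across:
the null hypothesis asserts exchangeability within strata without assuming
strata are comparable. The statistic is computed on the pooled
per-treatment aggregates (e.g. the difference of pooled treatment means),
not as a weighted combination of within-stratum contrasts. For rank-based
stratified tests, ranks are computed once on the fully pooled sample across
strata — this makes the single-stratum case collapse exactly to the
unstratified rank test and reproduces the reference stratified rank count
(11,577/627,264) on the gender-stratified bubbles data. Matched pairs are
the degenerate case of strata of size two; blocks in the Friedman analogue
are strata holding one observation per treatment.

For the two-group stratified engine the per-stratum group sums are
enumerated once per stratum and combined by indexed addition, so the
627,264-relabeling reference analysis evaluates in under a second without
materializing the full assignment matrix.

## Confidence intervals by test inversion

`shift_ci()` reports the set of hypothesized shifts δ for which the
two-sided test of `x` against `y + δ` fails to reject at level α
(rejection rule: `p ≤ α`). The p-value is a step function of δ, so the
boundary is found by bracketing and bisection, and the reported endpoints
are the innermost multiples of `resolution` (default 10⁻³) that fail to
reject — i.e. literally the smallest and largest representable shifts the
test cannot reject. The reject-at-`p ≤ α` rule together with this snapping
reproduces both reference 90% intervals, (0.244, 1.182) raw and
(0.111, 1.420) rank-based, on the asset-price data; the rank-based interval
re-ranks the shifted pooled sample at every δ, so boundary ties resolve
through mid-ranks. Step-function boundaries mean an exact tie at a grid
point is resolved by the non-strict counting rule inherited from the
engine.

## Regression

`perm_lm_test()` handles the bivariate model by reordering the response:
under `H0: δ = 0` all variation in `y` is exchangeable error. The statistic
is the OLS t ratio with classical homoskedastic standard errors (validated
against the reference coefficient tables to three decimals). Since `t` and
`|r|` are monotone-linked in the bivariate model, this test and the
correlation test produce identical extreme counts — asserted in the test
suite rather than assumed.

With nuisance covariates, naively reordering `y` destroys the
nuisance-response relationship. `freedman_lane_test()` instead permutes the
*reduced-model residuals*: fit `y ~ X`, form `y_π = ŷ + π(r)`, refit the
full model, and count. The identity permutation reconstructs `y` exactly.
Orderings of the residual vector are enumerated positionally (equal
residuals are distinct), keeping the denominator at `n!`. Degenerate
responses (zero residual variance everywhere) report `p = 1` by documented
convention. The partial-F variant follows the same flow for joint
hypotheses; only Freedman–Lane is implemented — the Kennedy and ter Braak
variants belong to a literature with no settled winner and are out of
scope.

## Synthetic data: what it emulates, what it does not

The generators exist so that properties (validity, calibration, the value
of pairing) can be tested on data with known structure:

* `generate_shift_data(n, m, shift, distribution, seed)` — i.i.d. noise
  (normal, uniform or centered exponential, unit scale) plus a location
  shift; `shift = 0` is the exact two-sample null.
* `generate_paired_data(n_pairs, effect, block_sd, noise_sd, seed)` — pair
  members share a `N(0, block_sd²)` offset. The test suite uses
  `block_sd = 10, noise_sd = 1, effect = 1.5` with 6 pairs: block
  heterogeneity dwarfs the effect, so the unpaired test is nearly blind
  while the sign-flip test retains power — the design lesson as a testable
  property (500 replicates).
* `generate_stratified_data(strata_sizes, effect, stratum_offsets, seed)` —
  stratum-level location offsets, common treatment effect.
* `generate_linear_data(n, alpha, beta, delta, noise_sd, seed)` — the
  nuisance-plus-interest linear model with standard-normal regressors.

These generators produce independent Gaussian-family noise with exact
additive effects. Real session-level experimental data have bounded
supports, heavy tails, outliers from procedural accidents, and effects that
interact with strata. Passing calibration tests on these generators
demonstrates the *engine* is correct (type-I error within binomial bands of
the achievable discrete levels; 2,000 replicates at n = m = 4 in the test
suite), not that any particular test is powerful or robust for a given real
dataset.

## Problem sizes and runtime

All bundled analyses are exact enumerations: 35, 64, 70, 90, 924, 34,650
and 627,264 relabelings, each well under a second to a few seconds on one
core. The test suite's stochastic checks use 10⁵ draws for sampler
uniformity and Monte Carlo convergence, 2,000 replicates for type-I
calibration, and 500 replicates for the pairing-power property; these sizes
give 3-standard-error margins comfortably narrower than the assertions they
support. The binary stratified example (256 observations, four strata) is
exercised at 4,999 draws in the tests; the same call scales to the
conventional 999,999 draws in about a minute.

## Known limitations

* Schemes cover independent, paired, ordered and stratified designs;
  cluster-randomized or sequentially randomized designs whose admissible
  set is not a product of within-stratum schemes are not representable.
* Nonnegative statistics (F, H, partial F) admit only upper-tail
  alternatives; hill-shaped ("umbrella") ordered alternatives are not
  implemented.
* Family-wise error control beyond Bonferroni, and sequential/adaptive
  Monte Carlo stopping rules, are out of scope.
* The shift interval assumes the shift model; it inverts the two-sample
  tests only (no intervals for k-sample contrasts or regression
  coefficients).
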