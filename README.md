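# exactperm

Exact and Monte Carlo permutation (randomization) inference for the small,
dependence-prone datasets typical of laboratory and field experiments.

## Why

Experimental economists and behavioral scientists routinely end up with a
handful of independent observations — often one session-level average per
group of interacting subjects. With 6–12 data points, parametric tests rest
on distributional assumptions that cannot be checked, and asymptotic
approximations have nothing to be asymptotic about. Permutation tests solve
this by using only the randomization of the design itself: under the null
hypothesis of no treatment effect, every admissible relabeling of the
observations was equally likely, so the null distribution of any test
statistic can be *constructed* rather than assumed.

`exactperm` implements this approach as three orthogonal ingredients:

1. **A relabeling scheme** implied by the design: all `C(n+m, n)` two-sample
   splits, all `n!/(n₁!⋯n_k!)` k-sample assignments, all `2ⁿ` sign flips of
   matched-pair differences, all `n!` orderings of one variable against
   another, or the Cartesian product of per-stratum schemes (restricted
   permutation: labels never cross strata).
2. **A test statistic**, on raw or rank-transformed data: the difference in
   means `T = x̄ − ȳ`, the one-way ANOVA `F`, the Kruskal–Wallis `H` on
   pooled mid-ranks, the trend statistics `J = Σ_{s<t} Σ_{i,j} 1(x_{is} < x_{jt})`
   (Jonckheere–Terpstra) and `D = Σ_{s<t} Σ_{i,j} (x_{jt} − x_{is})`, the
   Pearson correlation `r`, or a regression `t`/partial-`F`.
3. **A counting rule**: the p-value is the fraction of relabelings whose
   statistic is at least as extreme as the observed one (non-strict, so
   exact ties count), `P(|T_i| ≥ |T_obs|)` for two-sided alternatives. When
   full enumeration is infeasible, `B` uniform random relabelings give the
   add-one estimate `p = (b + 1)/(B + 1)`.

The familiar nonparametric tests fall out as special cases: Mann–Whitney is
the two-sample test on pooled ranks, Wilcoxon signed-rank is the sign-flip
test on signed ranks, exact Kruskal–Wallis is the k-sample test with `H`,
and Friedman is a within-block rank analogue. Beyond testing, the package
inverts the two-sample tests into shift confidence intervals and implements
the Freedman–Lane residual-permutation procedure for regression with
nuisance covariates.

## A worked example

Seven asset-market sessions: three "cash-rich" and four "asset-rich"
endowment treatments, one average share price per session. Did excess cash
push prices up?

```r
library(exactperm)
d <- load_fixture("caginalp_prices")
pitman_test(d, alternative = "greater")
#>
#> 	Pitman two-sample permutation test
#>
#> mean difference = 0.72
#> exact: 1 of 35 relabelings as or more extreme (greater)
#> p-value = 1/35 = 0.02857
```

The observed difference in mean prices is 0.72. Under the null, the 7
session averages could have landed in the two treatments in any of
`C(7,3) = 35` equally likely ways; only the observed split itself puts the
three largest prices together in the cash-rich group, so the one-sided
p-value is `1/35 ≈ 0.029` — the strongest rejection these sample sizes can
produce. Results are tibble-friendly:

```r
tidy(pitman_test(d))
#> # A tibble: 1 × 7
#>   statistic n_extreme n_total p_value alternative mode  method
#>       <dbl>     <int>   <int>   <dbl> <chr>       <chr> <chr>
#> 1      0.72         2      35  0.0571 two_sided   exact Pitman two-sample permu…
```

Inverting the two-sided test over hypothesized shifts gives a
distribution-free confidence interval for the treatment effect:

```r
shift_ci(d, level = 0.90)
#> 90% shift confidence interval (pitman test inversion)
#>   (0.244, 1.182)   observed difference: 0.72
```

`autoplot()` draws the permutation null distribution of any test and the
p-value curve of any interval. For stratified designs, add a `stratum`
column and the same functions restrict relabelings to within strata; for
matched pairs, add a `block` column and use `fisher_pairs_test()` or
`wilcoxon_signed_rank_test()`.

## Command line

```sh
scripts/permtest pitman --fixture caginalp_prices --alternative two-sided
scripts/permtest ci --fixture caginalp_prices --level 0.90 --test pitman
scripts/permtest fixtures --list
scripts/permtest pitman --file mydata.csv --mode monte-carlo --draws 99999 --seed 7
```

Input is long-format CSV (`value,treatment[,stratum][,block]`); output is a
JSON or TSV report with the statistic, extreme/total counts, p-values, mode
and seed. Identical arguments and seed always give a byte-identical report.

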