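# bwsmethyl

Age-adjusted nonparametric detection of differentially methylated loci in
case–control designs.

Illumina-style methylation β-values are bounded, multimodal and strongly
age-dependent, so the standard locus-wise tools — the two-sample t-test and
linear regression with a linear age term — are mis-specified twice over.
`bwsmethyl` implements a fully nonparametric alternative for analysts of
case–control methylation arrays: samples are stratified into age bins, each
bin is tested with a one-sided Baumgartner–Weiß–Schindler (BWS) rank
statistic, and the per-bin p-values are combined into one two-sided locus
p-value. Because the BWS statistic compares the entire empirical
distribution functions (with inverse-variance weights on the rank
discrepancies), it detects differences in spread and shape that mean-based
tests — and to a large extent the Wilcoxon test — cannot.

## The statistic

Within age group *k* (n₁ₖ controls, n₂ₖ cases; pooled mid-ranks, each
group's ranks sorted ascending):

    B1k = (1/n1k) Σᵢ [ (Gᵢ − ((n1k+n2k)/n1k)·i) · |Gᵢ − ((n1k+n2k)/n1k)·i| ]
                    / [ (i/(n1k+1))(1 − i/(n1k+1)) · n2k(n1k+n2k)/n1k ]

with `B2k` the mirror image over the case ranks, `Bk = (B1k − B2k)/2`, and
`D = −B` oriented so `D > 0` means cases are stochastically larger. The null
upper tail `P(b) = Pr(B ≥ b)` ships as a piecewise-exponential formula
(pieces `exp(−0.699 − 1.255b)`, `exp(−0.895 − 1.153b + 0.0173b²)`,
`exp(−2.895 − 0.786b)` cut at 1.5 and 9, with `P(−b) = 1 − P(b)`), derived
from 10⁷ rank permutations and refittable at any sample size with
`fit_null_tail()`. Per bin, `p_right = P(D)` and `p_left = 1 − p_right`;
across K bins, Fisher statistics `T_l = −2Σ log p_lk` and `T_r = −2Σ log
p_rk` give `T = max(T_l, T_r)` and the two-sided p-value `min(1, 2α)` with
`α = Pr(χ²_{2K} > T)`.

Combined t-test, combined Wilcoxon and age-adjusted regression comparators,
the full type-I-error/power simulation machinery, and a locus-wise pipeline
(QC filtering, age binning, pseudo case–control splits, TSV output) are
included.

## Worked example

Simulate one locus under the mean-shift alternative (6 age bins, 50 + 50
samples per bin, case truncated-normal mean drifting by 0.05 per bin) and
test it:

```r
library(bwsmethyl)
set.seed(20260901)
strata <- simulate_strata(mean_shift_scenario(delta_mu = 0.05))
combined_test(strata, method = "bws")
#> Combined bws across K = 6 strata (approx-2alpha)
#>   T_l = 4.2590, T_r = 33.4121, T = 33.4121, alpha = 0.0008345
#>   two-sided p-value = 0.001669
```

`T_r` dominates because the cases are shifted upward: the right-sided
per-bin p-values carry the signal (here 0.0019–0.67 across the six bins,
smallest in the older bins where the shift `k·δμ` is largest), Fisher's
method pools them into `T_r = 33.4`, and the χ²₁₂ tail of the larger
statistic, doubled, gives p ≈ 0.0017.

Power comparison under a pure scale difference — equal means, case arm
Beta(4,4) against control Beta(20,20):

```r
estimate_rejection_rate(beta_power_scenario(lambda = 0), c("bws", "t"),
                        n_reps = 500, seed = 7)
#>     scenario_id method n_reps alpha rejection_rate  mc_stderr seed
#> 1 beta-lambda-0    bws    500  0.05          0.652 0.02130239    7
#> 2 beta-lambda-0      t    500  0.05          0.058 0.01045332    7
```

The BWS combination rejects 65% of the time where the combined t-test stays
at its nominal level — the variance-only signal is invisible to a mean
comparison.

For β-matrices on disk, `load_study()` → `qc_filter()` →
`assign_age_groups()` → `run_locuswise()` produce a TSV of per-locus
p-values for all four methods; `inst/cli/bwsmethyl.R` wraps the same
pipeline for shell use (subcommands `test`, `simulate`, `fit-null`,
`pseudo-split`).

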