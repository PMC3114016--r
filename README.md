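# orhomog

Tests of homogeneity of odds ratios across K independent 2×2 tables, for
multicenter clinical trials and meta-analyses with a binary outcome.

Before pooling a common odds ratio across centers one should check that
the per-center odds ratios
`OR_k = y1k (n2k − y2k) / [(n1k − y1k) y2k]` are compatible with a
common value. `orhomog` implements three tests of that hypothesis:

- **Breslow-Day** (`breslow_day_test`): compares observed treated-arm
  counts with their expectations under the Mantel-Haenszel common odds
  ratio; χ² with K−1 df. Tarone's adjustment available as an option.
- **DerSimonian-Laird Q** (`dl_q_test`): inverse-variance-weighted
  dispersion of the per-center log odds ratios around their pooled mean;
  χ² with K−1 df.
- **Mixed-logistic likelihood ratio** (`lr_homogeneity_test`): fits the
  logistic-normal model
  `logit π_ik = α + β x_ik + u_k + b_k x_ik`,
  `u_k ~ N(0, σ_u²)`, `b_k ~ N(0, σ_b²)`,
  by marginal maximum likelihood (Gauss-Hermite quadrature, 15 nodes by
  default) and refers `Δ = −2(l₀ − l₁)` to the boundary mixture
  `½χ²₀ + ½χ²₁`, so `p = ½ P(χ²₁ > Δ)`.

A logistic-normal simulator (`simulate_tables`, `design_config`) and a
Monte-Carlo engine (`run_scenario`, `run_grid`,
`power_reduction_summary`, `ordering_check`) support size/power studies
under balanced designs and under two forms of unbalanced allocation at
fixed total cost: a 3:1 within-center split, and one dominant center
among K.

## Worked example

A two-center trial, 100 patients per arm per center
(`inst/extdata/two_center_trial.csv`):

```r
library(orhomog)
d <- read_tables_csv(system.file("extdata", "two_center_trial.csv",
                                 package = "orhomog"))
sample_or(d)        # 0.4285714 0.2727273
mh_or(d)            # 0.3442623

breslow_day_test(d)
#> 	Breslow-Day test of homogeneity of odds ratios
#> statistic = 1.1279, df = 1, p-value = 0.2882

dl_q_test(d)
#> 	DerSimonian-Laird Q test of homogeneity of odds ratios
#> statistic = 1.1265, df = 1, p-value = 0.2885

lr_homogeneity_test(d)
#> 	Mixed logistic likelihood-ratio test of homogeneity of odds ratios
#> 	(null: 0.5*chi2_0 + 0.5*chi2_1)
#> statistic = 0, mixture df = NA, p-value = 0.5
```

The two sample odds ratios (0.43 and 0.27) are pooled at 0.34 by
Mantel-Haenszel. None of the tests rejects homogeneity: the Breslow-Day
and Q statistics are near 1 on 1 df, and the mixed-model fit puts the
interaction variance on the boundary (`σ̂_b = 0`), so Δ = 0 and the
mixture p-value is its maximal 0.5.

A small power scenario:

```r
spec <- scenario_spec(K = 6, design = "within", level = 2,
                      sigma_u2 = 0.1, sigma_b2 = 0.4, reps = 200, seed = 42)
run_scenario(spec, tests = c("bd", "dl"))[, c("test", "power", "mc_se")]
#>   test power      mc_se
#> 1   bd 0.755 0.03041176
#> 2   dl 0.740 0.03101612
```

At these settings (six centers, 3:1 allocation, interaction variance
0.4) the closed-form tests detect heterogeneity in about three quarters
of trials at the 5% level.

A thin command-line wrapper over the same functions lives at
`inst/cli/orhomog.R` (`test` and `simulate` subcommands).

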