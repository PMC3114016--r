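---
title: "Testing homogeneity of odds ratios across centers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing homogeneity of odds ratios across centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orhomog)
```

## The problem

A multicenter trial (or a meta-analysis) with a binary outcome is
summarized as $K$ independent 2×2 tables: in center $k$, $y_{1k}$ of
$n_{1k}$ treated patients and $y_{2k}$ of $n_{2k}$ control patients
respond. Before pooling a common odds ratio it must be plausible that the
per-center odds ratios
$OR_k = \frac{y_{1k}(n_{2k}-y_{2k})}{(n_{1k}-y_{1k})\,y_{2k}}$
are homogeneous. This package implements three tests of that null
hypothesis, a logistic-normal simulator, and a Monte-Carlo engine for
studying the tests' empirical size and power under balanced and
unbalanced allocation.

## The three tests

**Breslow-Day** (`breslow_day_test`). With $\psi$ the Mantel-Haenszel
common odds ratio, the expected treated-arm count $E_k$ in center $k$
solves $\psi = \frac{E(n_{2k}-t_k+E)}{(n_{1k}-E)(t_k-E)}$ on the
admissible interval $[\max(0, t_k-n_{2k}), \min(n_{1k}, t_k)]$ — a
quadratic with a unique admissible root (`expected_count_given_or`). The
statistic $\sum_k (y_{1k}-E_k)^2 / V_k$, with $V_k$ the inverse of the
sum of reciprocal fitted cells, is referred to $\chi^2_{K-1}$. We use the
original statistic; Tarone's adjustment is available via `tarone = TRUE`
but off by default since the adjustment term is negligible unless tables
are tiny.

**DerSimonian-Laird Q** (`dl_q_test`). On the log odds-ratio scale with
$v_k$ the familiar sum of reciprocal cells,
$Q = \sum_k w_k (y_k - \bar y)^2$, $w_k = 1/v_k$, referred to
$\chi^2_{K-1}$. This is the heterogeneity statistic itself; estimating
the between-center variance $\tau^2$ (the pooling step of random-effects
meta-analysis) is out of scope.

**Mixed-logistic likelihood ratio** (`lr_homogeneity_test`). The
logistic-normal model for arm $i$, center $k$:
$$\mathrm{logit}\,\pi_{ik} = \alpha + \beta x_{ik} + u_k + b_k x_{ik},
\qquad u_k \sim N(0, \sigma_u^2),\; b_k \sim N(0, \sigma_b^2),$$
with $x_{ik}$ the treatment indicator and $u_k \perp b_k$. Homogeneity
of odds ratios is $\sigma_b^2 = 0$; the null model keeps only the random
intercept. Both models are fitted by marginal maximum likelihood
(`fit_mixed_logistic`), the random effects integrated out by
Gauss-Hermite quadrature, and $\Delta = -2(l_0 - l_1)$ is referred to the
50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ appropriate for a
variance component on the boundary (`mixture_pvalue`): $p =
\tfrac12 P(\chi^2_1 > \Delta)$, so $\Delta = 0$ gives $p = 0.5$ and
rejection at the 5% level requires $\Delta > 2.706$.

### Parameterization of the fitted model

Two parameterizations of "odds-ratio heterogeneity" coexist in this
problem. The *per-arm* form adds independent interaction effects
$b_{1k}, b_{2k}$ to the two arms, so the per-center log odds ratio is
$\beta + b_{1k} - b_{2k}$ with variance $2\sigma_b^2$. The *slope* form
adds a single $b_k$ to the treated arm only, giving log odds-ratio
variance $\sigma_b^2$. The fitted model uses the slope form with
independent intercept and slope — the operational definition used by
standard mixed-model software (it is what a random intercept plus
independent random treatment-slope specification fits). The simulator
defaults to the per-arm form (see below), so the fitted $\hat\sigma_b^2$
estimates twice the generator's interaction variance; the LR test itself
is unaffected, since both forms agree on the null $\sigma_b^2 = 0$ and
the test statistic does not require the variance scale to match.

## Numerical choices

**Quadrature.** Default: non-adaptive Gauss-Hermite with 15 nodes per
dimension (`nquad = 15`), the prior-scaled rule, tensor-product in the
full model. Non-adaptive quadrature is fully deterministic in the
parameters, which keeps likelihood surfaces smooth for the optimizer and
Monte-Carlo results exactly reproducible. Its accuracy degrades when the
per-center posterior is displaced far from the prior (large centers,
small $\sigma_u$): on a sharp two-center example the 15-node value is
within about $10^{-3}$ relative of the exact integral, while increasing
the node count or switching on `adaptive = TRUE` (posterior-mode
recentring and rescaling per center) reaches $10^{-6}$ or better. The
test suite verifies both regimes against a dense-grid trapezoid oracle.
Adaptive recentring costs a per-center mode search inside every
likelihood evaluation and can itself inject small spurious likelihood
differences near the boundary $\sigma_b = 0$, so the deterministic rule
remains the default for the simulation engine.

**Optimization.** `nlminb` with box constraints: standard deviations are
bounded in $[0, 20]$ on the natural scale (not log-transformed), so the
boundary solution $\hat\sigma = 0$ is attainable and reported as
converged. Starting points are deterministic — the conventional
$(\alpha, \beta, \sigma_u, \sigma_b) = (-1, 1, 0.2, 0.8)$, a data-driven
start from the Mantel-Haenszel odds ratio, and a fixed jitter — so fits
never consume the simulation RNG stream. The full model is additionally
seeded with the null fit's solution, which guarantees $l_1 \ge l_0$ in
practice; $\Delta$ is clipped at zero, and a value below $-10^{-6}$
flags the replicate as non-converged.

**Zero cells.** The DerSimonian-Laird path adds 0.5 to all four cells of
any table containing a zero (the Gart correction), only for odds-ratio
and variance computations; Breslow-Day and the LR test operate on raw
counts and need no correction. The policy is explicit
(`continuity_policy`) and can be disabled. Tables with $t_k = 0$ or
$t_k = n_k$ carry no information about the odds ratio: Breslow-Day
retains them with a zero contribution (df stays $K-1$, a warning is
raised), mirroring the naive formula.

**Root selection.** The Breslow-Day quadratic is solved in closed form
with the numerically stable root pair; the admissible-interval filter
picks the valid root and a bisection fallback guards against rounding at
extreme $\psi$.

## The simulator

`simulate_tables` draws, per center, $u_k \sim N(0, \sigma_u^2)$, then
interaction effects according to the generator (`per-arm`: independent
$b_{1k}, b_{2k}$; `slope`: a single $b_k$ on the treated arm), then
binomial outcomes. The per-arm form is the default because it is the
natural two-way mixed model for center-by-treatment interaction; the
slope form matches the fitted model and is provided for sensitivity
analysis. Draw order is fixed, so datasets are byte-identical given the
seed. The variance lists of the study grid — $\sigma_u^2 \in \{0.1,
0.5\}$ and $\sigma_b^2 \in \{0, 0.2, 0.4, 0.6, 0.8\}$ — are interpreted
on the variance scale, and the fixed effects default to $\alpha = -1$,
$\beta = 1$ (control response ≈ 27%, common odds ratio $e$).

`design_config` encodes the three allocation layouts at per-arm base
sizes 20/50/100 (levels 1–3): **equal** ($K$ centers at $m{:}m$);
**within-center inequality** (the same per-center total split 3:1, the
treated arm small: $m/2 : 3m/2$); **among-centers inequality** ($K-1$
small centers at $m/2 : m/2$ and one large center at
$m(K+1)/2$ per arm). Each unbalanced layout preserves the matching
equal layout's total, so power comparisons isolate the allocation
effect at fixed cost.

What the generator emulates: binomial sampling within arms, normally
distributed center effects and center-by-treatment interaction on the
logit scale, and the specific unbalanced allocations above. What it does
not: covariates, non-normal or correlated random effects, overdispersion
beyond the random effects, missingness, or informative center sizes.
Passing Monte-Carlo checks therefore says nothing about robustness to
those features in real data.

## The study engine

`run_scenario` simulates `reps` datasets per scenario with
per-replicate seeds derived from the scenario seed (results independent
of execution order; identical datasets regardless of which tests are
requested) and records the proportion of p-values strictly below 0.05.
`power_reduction_summary` reports either percentage-point differences or
(with `relative = TRUE`) relative percent losses, the form in which such
reductions are usually quoted; the packaged reproduction script uses the
relative form.
A non-converged LR replicate is retried with two extra starting points
and otherwise dropped from numerator and denominator, with the dropped
count reported; `drop_policy = "nonreject"` provides the
count-as-non-rejection sensitivity analysis. `run_grid` expands a
`study_config` factorially, caches finished cells on request, and
returns a tidy long-format table. `power_reduction_summary` averages the
paired equal-minus-unequal power differences over the 12
($\sigma_b^2$ × level) cells; `ordering_check` assesses the
BD ≥ DL ≥ LR power ordering per cell within paired Monte-Carlo standard
errors.

Problem sizes: the packaged checks run the grids at 100 replicates per
cell for the LR test and 200–500 for the closed-form tests, giving
per-cell Monte-Carlo standard errors of about 0.05 and 0.035–0.022;
averaging over 12–36 paired cells brings the standard error of the
reported reductions near one percentage point. The full factorial (270
scenarios × 1000 replicates) remains available by setting `reps = 1000`
in `study_config`; it is a long-running job dominated by roughly half a
million mixed-model fits.

## Known limitations

- The LR test's mixture null is asymptotic in $K$; with $K = 4$ the
  boundary mass of $\hat\sigma_b^2 = 0$ is well above $\tfrac12$ and the
  test is markedly conservative. The suite's calibration checks document
  this; the implementation has been cross-checked replicate-by-replicate
  against an independent mixed-model fitter on the same nested models.
- Non-adaptive quadrature accuracy is problem-dependent (see above);
  users fitting very large centers with small $\sigma_u$ should raise
  `nquad` or use `adaptive = TRUE` and compare.
- The package tests the odds-ratio scale only; risk differences and risk
  ratios, covariate adjustment, and empirical-Bayes center-specific
  estimates are out of scope.
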