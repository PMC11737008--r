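---
title: "A two-stage IPM for factorial grassland experiments: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage IPM for factorial grassland experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassipm)
```

## The demographic model

`grassipm` analyses annual (April-to-April) censuses of herbaceous plants
growing under a 2x2 factorial of climate (ambient vs. future) and land
management (extensive grazing vs. mowing), with five replicate plots
(subunits) per treatment combination and 50 x 50 cm subplots nested in
plots. The life cycle has two stages: a continuous class of established
plants structured by log size $z = \log_e(\text{size})$, and one discrete
class $M$ of spring seedlings. Size is basal area in cm^2 (or a leaf count
for rosette species); all models operate on its natural logarithm.

Seven vital-rate components are estimated per species:

* **Survival** $s(z) = \mathrm{logit}^{-1}(\alpha_S + \beta_S z)$ —
  Bernoulli GLM of survival to $t_1$ on $z$ at $t_0$.
* **Growth** $z' \sim \mathcal N(\alpha_G + \beta_G z,\ \sigma_G)$ —
  Gaussian regression on survivors; $\sigma_G$ is the residual SD.
* **Flowering probability**
  $p(z) = \mathrm{logit}^{-1}(\alpha_P + \beta_P z)$ — Bernoulli GLM of
  reproductive status at $t_0$.
* **Seed production** $f(z) = \exp(\alpha_F + \beta_F z)$ — Poisson GLM
  with natural-log link, flowering plants only. Per-plant seed counts are
  estimated as field-counted seed heads times the mean seeds-per-head from
  lab samples in the same plot (species-wide mean if a plot has no sample),
  so they are generally non-integer; the fit maximises the Poisson
  likelihood of these estimates, which leaves point estimates identical to
  a quasi-likelihood fit.
* **Recruitment** $\theta_f$, $\theta_s$ — mean per-subplot ratios of fall
  (resp. spring) seedlings to the subplot's total seed production, over
  subplot-years with nonzero seed totals. Ratios can exceed 1 in the field
  when seed input is underestimated, so the synthetic generator switches
  from binomial to Poisson draws above 1.
* **Establishment** $B$ — mean per-subplot ratio of new plants at $t_1$ to
  seedlings counted at $t_0$ (fall + spring). As a proportion it is
  clipped to 1 with a warning if the ratio estimate exceeds 1, which field
  data can produce when seedlings are missed.
* **Recruit sizes** $\eta(z') = \mathcal N(\mu_\eta, \sigma_\eta)$ — the
  log-size distribution of individuals first recorded in a stratum.

That is 14 parameters per stratum (`param_names()`), grouped for
decomposition purposes into five demographic processes: survival (2),
growth (3), reproduction (4), recruitment (2), establishment (3).

The annual projection couples the two stages:

$$
n(z', t_1) = M(t_0)\,B\,\eta(z') +
  \int_L^U \left[ s(z)\,g(z'\mid z) + p(z) f(z)\,\theta_f B\,\eta(z')
  \right] n(z, t_0)\, dz,
\qquad
M(t_1) = \int_L^U p(z) f(z)\, \theta_s\, n(z, t_0)\, dz .
$$

The establishment probability $B$ appears in both seedling pathways
because fall- and spring-germinated recruits cannot be told apart at the
April census. The second equation as we implement it carries the weight
$n(z, t_0)$ inside the integral; without it the model would not be a
linear operator, so we treat the unweighted form as a typographical
shortcut. The kernel is discretized by the midpoint rule on `n_bins`
(default 200) equal bins over $[L, U]$, giving a
$(n_\text{bins}+1)\times(n_\text{bins}+1)$ matrix whose first row/column
is the seedling class; $\lambda$ is its dominant eigenvalue and results
are reported as $\log\lambda$ throughout.

## Treatment structure

The four regression components are fitted **jointly** with full size x
climate x management interactions (a saturated two-factor structure), and
per-combination intercept/slope pairs are assembled from coefficient sums;
the discrete rates are estimated per combination directly. Main-effect
parameter sets (ambient, future, grazing, mowing) are the parameter-wise
arithmetic means of the two combinations sharing the level — averaging
happens on parameters, never on $\lambda$.

With `random_effects = TRUE` (the default of `ipm_fit()`), each
regression includes a `(1 | plot)` grouping term, reflecting that plots
nested in climate are the experimental units; only the population-level
coefficients are extracted (the plot effect is set to zero), because the
kernel consumes a single parameter vector per stratum. If the variance
component is degenerate — which is guaranteed on data from the bundled
generator, which has no plot-level heterogeneity — the model falls back to
the fixed-effects fit with a warning. Resampling procedures (bootstrap,
permutation) always refit with the fixed-effects path: they refit all
seven components hundreds of times per call, the extracted quantities are
the population-level coefficients either way, and on generator data the
two paths coincide.

Complete separation in a Bernoulli component (e.g. every plant of a small
post-drought stratum survives) triggers a weakly ridge-penalized
maximum-likelihood fallback (penalty $10^{-3}\|\beta\|^2$) with a warning,
keeping coefficients finite while leaving fitted probabilities within
0.01 of the degenerate outcome.

## Quasi-extinction

A species x combination stratum with fewer than 25 individuals **and**
fewer than 10 flowering individuals in the evaluated census year is
flagged quasi-extinct; `ipm_fit()` excludes such strata (and any main
effect missing a member combination) from the $\lambda$ table. Both
inequalities are strict: exactly 25 individuals or exactly 10 flowering
plants keeps the stratum in the analysis. Because the rule's evaluation
year is not fixed by the protocol, `quasi_extinct()` takes a `year`
argument and defaults to the latest census year.

## Inference and decomposition

* **Bootstrap** (default 1000 replicates): a two-level nonparametric
  resample — individual transition records with replacement (feeding the
  regressions and recruit sizes) and subplot-years with replacement
  (feeding $\theta_f, \theta_s, B$) — honouring both sampling designs.
  Each replicate refits everything and rebuilds the kernel on the
  stratum's fixed size domain; reported are the mean and SD of
  $\log\lambda$.
* **Permutation tests** (default 1000): treatments are applied at plot
  scale, so plots are the exchangeable units. Group labels are reassigned
  across plots (records stay with their plot), everything is refit, and
  the two-sided p-value for $T = \lambda_A - \lambda_B$ uses the add-one
  estimator; when the assignment space is at most `n_perm` it is
  enumerated exhaustively instead.
* **Sensitivities**: $\partial\lambda/\partial\alpha_i$ by forward finite
  difference with absolute step 0.001 (the conventional perturbation),
  each of the 14 parameters in turn; a central-difference option exists
  for verification. Lambdas inside the difference come from dense
  eigendecomposition so that small steps remain meaningful.
* **LTRE**: $\delta_{\alpha_i} = (\alpha_{i,1} - \alpha_{i,2})\,
  \partial\lambda/\partial\alpha_i$ with sensitivities evaluated at the
  elementwise midpoint of the two parameter sets (the classical
  fixed-design reference; endpoint references are available since the
  choice is not canonical). Contributions are summed into the five
  processes and scaled by the sum of absolute values — a norm that keeps
  mixed-sign contributions interpretable while making
  $\sum_i |\tilde\delta_i| = 1$.
* **Effect sizes**: $\lambda_\text{grazing} - \lambda_\text{mowing}$ and
  $\lambda_\text{ambient} - \lambda_\text{future}$ from the main-effect
  strata, so positive values indicate grazing/ambient preference; simple
  OLS regressions relate these to flowering start month and flowering
  duration (counted inclusively: May to June is 2 months).

## Numerical choices

* **Eviction.** The integration limits default to the observed log-size
  range across all strata (a common domain, so treatment $\lambda$s are
  comparable), padded by $0.5\,\sigma_G$. Growth and recruit-size
  densities lose mass beyond $[L, U]$; by default each growth column and
  the $\eta$ vector are renormalized to unit mass on the domain
  (`eviction = "renorm"`), so the survival-growth block's column sums
  equal $s(z_j)$ exactly and no survival leaks out at the boundaries.
  `eviction = "none"` reproduces the raw midpoint rule.
* **Eigensolver.** Dense nonsymmetric eigendecomposition with a
  power-iteration cross-check to relative $10^{-8}$; the resampling inner
  loops use power iteration alone for speed, falling back to the
  eigendecomposition if it fails to converge (reducible matrices, tied
  moduli).
* **Degenerate inputs.** Constant-size designs make the regressions rank
  deficient; aliased coefficients are set to zero (Gaussian/Poisson) or
  handled by the ridge fallback (Bernoulli), so fully degenerate data
  yield a well-defined, zero-variance bootstrap rather than an error.
  Residual SDs of saturated fits are floored at $10^{-8}$ inside the
  resampling path only to keep the kernel constructible.

## The synthetic generator

`simulate_census()` draws censuses from the exact statistical model the
estimators assume, with known ground truth, so every downstream stage is
testable without field data. Defaults mirror the targeted study design:
five plots per combination, eight subplots per plot, four annual
transitions from 2018, and first-year cohorts of 1141 / 1079 / 1075 /
1353 individuals (ambient-grazing, ambient-mowing, future-grazing,
future-mowing) — the pooled census of a common perennial grass. The
default truth (`default_truth()`) is a field-realistic parameterisation
of a persistent perennial: size-dependent survival around 0.6-0.9,
near-unit growth autoregression ($\beta_G = 0.9$), tens of seeds per
flowering plant, recruitment of a few percent per seed, establishment
0.3, and modest treatment contrasts (future climate depresses the
survival intercept by 0.15; mowing raises the seed intercept by 0.2 and
the flowering intercept by 0.1) so that contrasts, effect sizes and LTRE
decompositions are non-degenerate.

Seed output is generated mechanistically the way it is measured: a
flowering plant carries a Poisson number of seed heads scaled so its
expected total seed output is $f(z)$, each head holding a
negative-binomial number of seeds (mean 20, size 50 — mildly
overdispersed relative to Poisson, as seed counts per head typically
are); the lab table samples 10 heads per plot, representing cumulative
lab sampling across the study years. The estimation path (heads times the
plot's mean seeds-per-head) is therefore exercised end to end, including
its sensitivity to lab-sample noise. The seeds-per-head distribution is a
modelling convenience of the generator, not a field estimate.

One integer seed drives a hierarchy of per-combination, per-year,
per-table streams, so regeneration is bit-identical and partial
structures are reproducible.

What the generator does **not** emulate: plot-level random effects (every
plot of a combination shares the truth), spatial structure within
subplots, drought years or other temporal heterogeneity (vital rates are
time-constant), seed banks (the target species do not form persistent
ones), and within-year management events. Passing recovery tests
therefore demonstrates correctness of the estimators under the model's
own assumptions — not robustness to the field realities a real census
carries.

```{r example}
truth <- default_truth(census_design(n_individuals = 300, n_years = 2))
census <- simulate_census(truth)
fit <- ipm_fit(census, random_effects = FALSE, n_bins = 100)
fit
```

```{r decomposition}
lt <- ltre(fit$params[["ambient.mowing"]], fit$params[["ambient.grazing"]],
           fit$limits[1], fit$limits[2], n_bins = 100)
lt
```

## Problem sizes used by the test suite

The suite exercises recovery at 5,000 individuals per treatment
combination over two transitions (tolerances: each regression parameter
within 0.1 or two standard errors of truth; $|\Delta\log\lambda| < 0.05$),
kernel oracles at 3 and 200-400 bins, and a null-calibration study of the
permutation test with 200 simulated datasets of 150 individuals per group
and 200 permutations each (empirical size required in $[0.03, 0.07]$ at
$\alpha = 0.05$). Bootstrap and permutation defaults are 1000 replicates;
tests and the pipeline example scale these down since the quantities
checked (reproducibility, calibration, degeneracy) do not depend on the
replicate count.

## Known limitations

* Density independence and a time-constant environment: $\lambda$ is the
  asymptotic growth rate of the averaged environment, not a stochastic
  growth rate.
* The LTRE is first-order: with large parameter contrasts the sum of
  contributions drifts from $\Delta\lambda$ (the object reports both so
  the approximation error is visible).
* The seed-count response is an estimate (heads x mean seeds-per-head);
  its sampling error is not propagated into the reported standard errors.
* Per-year stratification refits every component on a single transition's
  data; small strata will frequently hit the separation fallback, and
  yearly recruit-size distributions can rest on very few recruits.
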