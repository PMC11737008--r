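# grassipm

Size-structured demographic analysis for grassland plant censuses from
factorial climate × land-management field experiments.

Long-term experiments that cross a realistic future-climate treatment with
extensive grazing vs. mowing ask a demographic question: which vital rates
— survival, growth, flowering, seed output, recruitment, establishment —
carry a treatment's effect on a species' long-term population growth rate?
`grassipm` answers it with a two-stage integral projection model (IPM)
fitted to annual individual-level census tables, plus the inference and
decomposition machinery around it: bootstrap uncertainty for λ, plot-level
permutation tests for treatment contrasts, finite-difference parameter
sensitivities, and life-table-response-experiment (LTRE) decompositions
grouped by demographic process. A synthetic census generator with known
ground truth makes the whole pipeline testable without field data.

## The model

Plants live in a continuous class structured by log size
*z* = log<sub>e</sub>(size) and a discrete spring-seedling class *M*.
Seven components are fitted per species and stratum (14 parameters):
logit-linear survival *s*(*z*) and flowering probability *p*(*z*),
Gaussian growth *g*(*z*′|*z*) with residual SD σ<sub>G</sub>, log-linear
seed production *f*(*z*), fall and spring per-seed recruitment rates
θ<sub>f</sub>, θ<sub>s</sub>, establishment probability *B*, and a normal
recruit log-size distribution η(*z*′). The annual projection is

```
n(z', t+1) = M(t) B η(z') + ∫ [ s(z) g(z'|z) + p(z) f(z) θ_f B η(z') ] n(z, t) dz
M(t+1)     = ∫ p(z) f(z) θ_s n(z, t) dz
```

discretized by the midpoint rule on 200 size bins (a 201 × 201 matrix
including the seedling class); λ is the dominant eigenvalue, reported as
log λ. Treatment-combination parameters come from one joint factorial fit
with full size × climate × management interactions; main-effect parameter
sets are parameter-wise means of the two combinations sharing a level.
Strata with fewer than 25 individuals and fewer than 10 flowering plants
are flagged quasi-extinct and dropped. See the methods vignette
(`vignettes/two-stage-ipm.Rmd`) for assumptions, defaults and numerical
choices.

## Worked example

```r
library(grassipm)

truth  <- default_truth(census_design(n_individuals = 300, n_years = 2))
census <- simulate_census(truth)          # three census tables, known truth
fit    <- ipm_fit(census, random_effects = FALSE, n_bins = 100)
fit
#> Two-stage IPM fit (100 bins on [-2.128, 4.416])
#>          stratum lambda log_lambda
#>  ambient.grazing 0.9920    -0.0080
#>   ambient.mowing 0.9679    -0.0326
#>   future.grazing 0.9908    -0.0092
#>    future.mowing 0.9632    -0.0375
#>          ambient 0.9810    -0.0192
#>           future 0.9748    -0.0256
#>          grazing 0.9917    -0.0083
#>           mowing 0.9640    -0.0367
```

Every stratum's λ is just below 1: all eight projected populations are
roughly stable, declining by 1–4% per year. Effect sizes difference the
main-effect λs (positive = preference for grazing / ambient):

```r
effect_size(fit)
#>   species       axis       value preference
#> 1    <NA> management 0.027740752    grazing
#> 2    <NA>    climate 0.006181967    ambient
```

An LTRE decomposes a λ difference into per-parameter contributions,
grouped into five demographic processes and scaled to unit absolute sum:

```r
ltre(fit$params[["ambient.mowing"]], fit$params[["ambient.grazing"]],
     fit$limits[1], fit$limits[2], n_bins = 100)
#> LTRE decomposition [ambient.mowing vs ambient.grazing]
#>   delta lambda = -0.0241; sum of contributions = -0.0241 (reference: mean)
#>   contributions by process (scaled to unit absolute sum):
#>              survival  growth reproduction recruitment establishment
#> contribution  -0.0208 -0.0150       0.0027      0.0014        0.0077
#> scaled        -0.3267 -0.2353       0.0415      0.0218        0.1210
```

Here the mowing stratum's lower λ is driven mainly by survival and growth
(negative contributions), partially offset by establishment. The sum of
contributions (−0.0241) matching Δλ (−0.0241) is the first-order accuracy
check the object always reports. Uncertainty and testing:

```r
bootstrap_lambda(census, "ambient.grazing", n_boot = 200, seed = 1,
                 n_bins = 100)
#> Bootstrap lambda [ambient.grazing]: 200 replicates (0 dropped)
#>   mean log lambda = -0.0109, sd = 0.0175

permutation_test(census, "ambient.grazing", "ambient.mowing",
                 n_perm = 1000, seed = 1)   # plot-level relabeling
```

`run_pipeline(config, out = "results")` drives the whole chain — census
(synthetic or read from CSV) → quasi-extinction report → fits → λ table
with bootstrap summaries → the six treatment-contrast permutation tests →
sensitivities → all pairwise LTREs → effect sizes — writing tidy CSVs and
a YAML manifest that reproduces the run exactly.

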