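# frsex

Sex-comparative functional response analysis for predator–prey foraging
experiments.

Functional-response experiments — offering a predator different prey
densities and counting what gets eaten — are a standard way to gauge the
potential impact of an invasive predator, and they are very often run on
males only. For sexually dimorphic predators (crabs are the motivating
case: crusher-claw size limits the shellfish an individual can open)
that shortcut can systematically overstate a population's impact.
`frsex` provides the complete analysis chain for testing this:

* **Rogers Type II random-predator fitting.** Trials deplete prey, so
  expected consumption solves the implicit equation
  `N_e = N_0 (1 − exp(a (N_e h − T)))`, with attack rate `a`, handling
  time `h`, and duration `T` (fixed to 1 for fitting). The package uses
  the Lambert-W closed form
  `N_e = N_0 − W0(a h N_0 exp(−a(T − h N_0))) / (a h)` inside a binomial
  maximum-likelihood fit on `(log a, log h)`, with AICc comparison
  against a Type I (`h = 0`) alternative and a logistic response-type
  test.
* **Stratified bootstrap inference.** Resampling within density strata,
  percentile intervals, and iteration-paired contrasts: consumption
  difference at the highest density, maximum consumption `1/(hT)`,
  functional response ratio `FRR = a/h` and the male:female FRR ratio,
  plus a within-strata permutation test.
* **Consumption vs morphology.** Binomial-logit GLM of proportion eaten
  on density, sex, centred claw height (or carapace width) and the
  sex-by-morphology interaction, with a design-stratified bootstrap.
* **Population-level sex-ratio sweep.** For each female proportion `q`,
  the proportional difference between a mixed-sex population's predicted
  consumption efficiency and an all-male reference, with a bootstrap
  band and the threshold `q` beyond which overestimation by a male-only
  study is near-certain.
* **Synthetic data generators** for foraging trials (binomial-expectation
  or continuous-time event simulation), morphology surveys, movement
  tracks and trapping records, so the entire pipeline is testable
  without field data.

## A worked example

```r
library(frsex)

trials <- generate_trials(seed = 42)          # 6 densities x 2 sexes x 6 reps
fit_m  <- fit_type2(trials[trials$sex == "M", ])
fit_f  <- fit_type2(trials[trials$sex == "F", ])
fit_m
#> Functional response fit (type2), n = 36 trials
#>   attack rate    a = 2.8829
#>   handling time  h = 0.0909
#>   logLik = -40.866   AICc = 86.096   converged: TRUE
fit_f
#> Functional response fit (type2), n = 36 trials
#>   attack rate    a = 1.6917
#>   handling time  h = 0.1194
#>   logLik = -47.501   AICc = 99.365   converged: TRUE

tt <- type_test(trials[trials$sex == "F", ])
#> female type test: coef -0.107, z = -3.92, p = 9e-05 -> type2

boot_m <- stratified_bootstrap(trials[trials$sex == "M", ], n_iter = 2000, seed = 101)
boot_f <- stratified_bootstrap(trials[trials$sex == "F", ], n_iter = 2000, seed = 102)
frr_ratio_contrast(boot_m, boot_f)
#> FRR ratio (A:B): 2.2959 [1.5203, 3.3860] (null 0, significant; 2000 paired draws)
group_difference_at_density(boot_m, boot_f, n0 = 16)
#> consumption difference at n0 = 16: 2.1838 [0.7902, 3.6120] (null 0, significant; 2000 paired draws)
```

Read: both sexes show a decelerating (Type II) response (significant
negative density term); the male fit has a higher attack rate and lower
handling time; per bootstrap iteration the male FRR is about 2.3 times
the female FRR, with a 95% interval excluding 1, and males eat about 2.2
more clams at the highest density. `fit_consumption_glm()`,
`bootstrap_glm()` and `sexratio_sweep()` continue the chain down to the
population-level overestimation threshold; `run_pipeline(fr_config(...))`
executes every stage and writes the tables of one reproducible run.

## Documentation

The methods vignette
(`vignettes/functional-response-by-sex.Rmd`) documents the model, the
bootstrap and contrast conventions, the sweep's assumptions, what the
synthetic-data generators do and do not emulate, and the package's
numerical choices.
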