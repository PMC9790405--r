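# popitc

Population-adjusted indirect treatment comparisons with limited
individual patient data.

## The problem

Health-technology assessment routinely has to compare a new treatment *A*
with an established competitor *B* that was never trialed against it. Both
have randomized trials against a common comparator *C*, but the sponsor
holds individual patient data (IPD) only for its own *AC* trial; for the
*BC* trial only published aggregates are available — covariate means and
SDs and a 2×2 events table. The anchored (Bucher) comparison

    Δ̂_AB = Δ̂_AC − Δ̂_BC,   V̂(Δ̂_AB) = V̂(Δ̂_AC) + V̂(Δ̂_BC)

is biased when effect modifiers are distributed differently across the two
trial populations. `popitc` implements the pairwise population-adjustment
methods for binary outcomes on the marginal log-odds ratio scale:

* **MAIC** (`maic_estimate()`): method-of-moments weighting of the AC IPD
  so the weighted effect-modifier means match the BC means, with
  ESS diagnostics, infeasibility detection when the BC means fall outside
  the observed covariate support, and non-parametric bootstrap inference.
* **Conventional STC** (`stc_estimate()`): the covariate-adjusted logistic
  regression centered at the BC means, whose treatment coefficient is a
  *conditional* log-odds ratio. Because the odds ratio is non-collapsible,
  that coefficient is a different estimand from the marginal one the
  anchored comparison needs; the package tags it `scale = "conditional"`
  and warns when it is combined. It is kept as the negative control.
* **Parametric G-computation**, the marginalization route: fit the
  uncentered Q-model `g(μ) = β0 + xβ1 + (βz + x_EM β2)·1[z = 1]` to the AC
  IPD, predict potential outcomes under each treatment for every member of
  a simulated BC pseudo-population, average on the probability scale and
  contrast on the logit scale, `Δ̂_AC = g(μ̂1) − g(μ̂0)`. Maximum-likelihood
  (`gcomp_ml_estimate()`, bootstrap or asymptotic-normal simulation
  inference) and Bayesian (`gcomp_bayes_estimate()`, JAGS MCMC with
  weakly informative priors and posterior-predictive outcome imputation)
  versions are provided.
* **Pseudo-populations** (`copula_population()`,
  `factorized_population()`): Gaussian-copula simulation from published
  margins with moment-matched marginal families (normal, lognormal, gamma,
  Bernoulli, truncated normal) and an assumed correlation structure, or a
  marginal/conditional factorization.
* **Simulation benchmark** (`scenario_config()`, `simulate_trial()`,
  `run_study()`, `performance_metrics()`): the full data-generating
  process and ADEMP-style harness for benchmarking the estimators' bias,
  empirical SE, MSE, variability ratio and coverage across a 3×3 grid of
  AC sample sizes and covariate-overlap levels, with Monte Carlo standard
  errors for every measure.

The methods vignette (`vignettes/population-adjusted-itc.Rmd`) documents
the models, the data-generating process, numerical choices and known
limitations.

## Worked example

Simulate a 200-subject AC trial with moderate covariate overlap against a
600-subject BC trial, then run MAIC and ML G-computation:

```r
library(popitc)
cfg <- scenario_config(n_ac = 200, mu_ac = 0.30)   # moderate overlap
ac  <- simulate_trial(cfg, cfg$mu_ac, seed = 101)
bc  <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = cfg$n_bc, seed = 102))
bc
#> Aggregate trial data: 400 active / 200 control subjects
#>   covariate means: 0.5880, 0.6214, 0.6031, 0.6159
#>   covariate SDs:   0.3867, 0.3890, 0.4061, 0.3944
#>   events (active/control): 174 / 151

maic_estimate(ac, bc, n_boot = 1000, seed = 103)
#> Marginal log-OR estimate [maic]: -0.9495 (SE 0.6129, 95% CI -2.1507 to 0.2518)

gc <- gcomp_ml_estimate(ac, bc, n_boot = 1000, seed = 104)
gc
#> Marginal log-OR estimate [gcomp-ml/bootstrap]: -1.0687 (SE 0.4716, 95% CI -1.9931 to -0.1443)

bucher_combine(gc, bc_marginal_logor(bc))
#> A vs B indirect comparison: 0.3182 (SE 0.5096, 95% CI -0.6805 to 1.3170)
```

Both adjusted estimates target the marginal A-vs-C log-odds ratio in the
BC population (true value −1.15 under this configuration; the A-vs-B truth
is 0 because both active treatments are simulated with identical effects).
G-computation is visibly more precise than MAIC here: the weighting
reduces the effective sample size from 200 to about 55 (a 72.6%
reduction), while the outcome-regression route uses all subjects and
extrapolates through the fitted model.

A thin command-line interface wraps the same functions:

```sh
popitc estimate --method gcomp-ml --ipd ac.csv --agg bc.json \
    --em-idx 3,4 --n-boot 1000 --seed 1 --out est.json
popitc compare --ac est.json --bc bc.json
popitc run-study --methods maic,stc --n-reps 2000 --seed 1 --out results/
```

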