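---
title: "Population-adjusted indirect comparisons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-adjusted indirect comparisons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popitc)
```

## The problem

A sponsor holds individual patient data (IPD) for a randomized trial of its
treatment *A* against a common comparator *C*, and must compare *A* with a
competitor *B* that was trialed against the same comparator in a different
study, for which only published aggregate data are available: covariate
means and SDs, and a 2x2 events table. When the two trial populations
differ in *effect modifiers* — covariates that alter the relative treatment
effect on the linear-predictor scale — the plain anchored (Bucher)
comparison

$$\hat\Delta_{AB} = \hat\Delta_{AC} - \hat\Delta_{BC}, \qquad
  \widehat V(\hat\Delta_{AB}) = \widehat V(\hat\Delta_{AC}) +
  \widehat V(\hat\Delta_{BC})$$

is biased, because the two within-trial effects are calibrated to different
populations. Population adjustment maps the A-vs-C effect into the BC
population before combining. Reimbursement decisions are made at the
population level, so the target estimand is the *marginal*
(population-average) log-odds ratio — the effect of switching the whole BC
population between treatments — not the *conditional* coefficient of a
covariate-adjusted regression. For non-collapsible effect measures such as
the odds ratio the two differ even without confounding, which is the
central design constraint for everything in this package.

## Estimators

**MAIC** (`maic_estimate()`) reweights the pooled AC IPD so the weighted
effect-modifier means equal the aggregate-trial means. The
method-of-moments weights are $w_n = \exp\{(x_n^{EM} - \theta^{EM})
\hat\alpha\}$ with $\hat\alpha$ minimizing the convex objective
$\sum_n \exp\{(x_n^{EM}-\theta^{EM})\alpha\}$; the first-order condition is
exact balance. The A-vs-C effect is then the treatment coefficient of a
weighted logistic regression of outcome on treatment alone, equal to the
log weighted odds ratio — a marginal quantity. Weighting cannot
extrapolate: if an aggregate mean lies outside the convex hull of the
observed effect-modifier values, the objective is unbounded and
`estimate_weights()` raises a classed "no feasible weighting solution"
error that the simulation harness counts. The effective sample size
$(\sum w)^2/\sum w^2$ is reported as the standard overlap diagnostic.

**Conventional STC** (`stc_estimate()`) fits the covariate-adjusted
logistic regression with every covariate centered at the aggregate-trial
means,

$$g(\mu_n) = \beta_0 + (x_n - \theta)\beta_1 +
  \{\beta_z + (x^{EM}_n - \theta^{EM})\beta_2\}\, 1[z_n = 1],$$

and reports $\hat\beta_z$ with its model-based SE. That coefficient is a
*conditional* log-odds ratio, so the result carries a
`scale = "conditional"` tag and `bucher_combine()` warns when it is used:
the method is retained deliberately as the benchmark's negative control for
non-collapsibility bias. One shared centering is used for both arms;
arm-specific centering would break randomization.

**Parametric G-computation** (`gcomp_ml_estimate()`,
`gcomp_bayes_estimate()`) marginalizes instead of conditioning. The
uncentered *Q-model* $g(\mu_n) = \beta_0 + x_n\beta_1 + (\beta_z +
x^{EM}_n\beta_2)1[z_n=1]$ is treated as a nuisance model; its fit predicts
a pair of potential outcomes for every member of a simulated BC
pseudo-population, the predictions are averaged on the probability scale
under each treatment,

$$\hat\mu_1 = \frac{1}{N^*}\sum_{i} g^{-1}(\hat\beta_0 + x^*_i\hat\beta_1 +
\hat\beta_z + x^{*EM}_i\hat\beta_2), \qquad
\hat\mu_0 = \frac{1}{N^*}\sum_{i} g^{-1}(\hat\beta_0 + x^*_i\hat\beta_1),$$

and contrasted on the linear-predictor scale, $\hat\Delta_{AC} =
g(\hat\mu_1) - g(\hat\mu_0)$. This is model-based standardization: for a
discrete covariate and a saturated model it reproduces crude
post-stratification exactly (tested to $10^{-12}$), and with an identity
link it collapses to the conditional contrast — the gap between the two
routes exists only for non-linear links.

In the maximum-likelihood version the sampling distribution of the contrast
has no convenient closed form, so inference is by ordinary non-parametric
bootstrap: whole AC rows (covariates, treatment, outcome jointly) are
resampled and the Q-model refitted per resample. An alternative
`inference = "mvn-sim"` mode draws coefficient vectors from the asymptotic
normal distribution of the ML fit; it is cheaper and approximates the same
distribution. The Bayesian version samples the Q-model posterior by MCMC
and, per draw, *imputes* binary potential outcomes in the
pseudo-population from their posterior-predictive Bernoulli distributions
before averaging and contrasting; the point estimate is the posterior mean
of the per-draw contrasts and the SE their posterior SD.

## Simulating the pseudo-population

The BC covariate joint distribution is unavailable, so it is reconstructed
from the published margins plus an assumed dependence structure — by
convention the Pearson correlations of the AC IPD when the aggregate
publication reports none. Two constructions are provided:

* **Gaussian copula** (`copula_population()`): a latent multivariate normal
  with the chosen correlation matrix is pushed through the standard normal
  CDF and each covariate's inverse marginal CDF. Marginal families
  (normal, lognormal, gamma, Bernoulli, truncated normal) are
  moment-matched analytically to the published mean and SD; the truncated
  normal solves its two parameters numerically to the same accuracy.
  With all-normal marginals — the configuration used throughout the
  benchmark — the construction is exactly multivariate normal, and the
  latent correlation equals the target Pearson correlation. For
  non-normal marginals feeding the Pearson matrix in directly is an
  approximation (no rank-to-Pearson conversion is applied), which is
  documented rather than corrected because the benchmark never exercises
  it.
* **Factorization** (`factorized_population()`): a root marginal plus a
  chain of Bernoulli conditionals with centered-parent link-linear means,
  for settings where a graphical factorization of the joint is more
  natural than a copula.

The pseudo-population is generated **once per analysis** and held fixed
across bootstrap resamples and posterior draws. Only the IPD carry
sampling uncertainty that resampling is meant to capture; regenerating the
target population each time would redefine the estimand per resample.
`n_star` defaults to 1000, large enough that pseudo-population noise is a
small fraction of the IPD sampling noise at the benchmark sample sizes.

## The data-generating process

`scenario_config()` fixes the benchmark conditions. Both trials draw
$K = 4$ covariates from a multivariate normal with SD 0.4 and exchangeable
correlation 0.2; the BC means are 0.6 and the AC means 0.45, 0.30 or 0.15,
giving standardized differences of 0.375 / 0.75 / 1.125 — by the
equal-variance normal overlap formula $100 \cdot 2\Phi(-d/2)$
(`cohen_overlap()`), 85%, 71% and 57% marginal overlap, i.e. strong,
moderate and poor overlap, with mean ESS reductions after MAIC weighting
of roughly 22%, 60% and 85%. All four covariates are prognostic
(conditional OR 2 each, $\beta_1 = -\ln 0.5$); the last two also modify
both active treatments' effects (conditional OR about 1.5 per unit,
$\beta_2 = -\ln 0.67$). The intercept $\beta_0 = -0.62$ fixes the baseline
event rate at 35%, and the shared conditional treatment coefficient is
$\beta_z = \ln 0.17$. Because A and B have identical coefficients, the
true A-vs-B marginal log-odds ratio in the BC population is exactly zero —
the benchmark truth — while each active-vs-C marginal effect is non-null.
The AC trial size is 200, 400 or 600 and the BC trial fixed at 600, both
with 2:1 active:control allocation.

Treatment assignment is deterministic (the first $\lceil 2N/3\rceil$
subjects are active): the covariate rows are exchangeable, so this is
distributionally equivalent to randomization with fixed arm sizes and
removes one irrelevant variance source. Covariates are not truncated;
truncation support in the marginal specs exists for real applications
where eligibility criteria bound a covariate.

`true_marginal_logor()` computes the oracle marginal active-vs-C effect by
standardizing the true outcome model over a large Monte Carlo draw from
the BC covariate distribution. At the benchmark parameters it evaluates to
$-1.154$ (within $\pm 0.002$ at $2 \times 10^6$ draws), while the
conditional coefficient at the BC covariate means is $\beta_z + 1.2
\beta_2 = -1.291$; the difference is the non-collapsibility gap that makes
conventional STC systematically biased. An independent check — simulating
a two-million-subject BC trial and fitting the unadjusted logistic
regression — agrees with the standardization route.

## Numerical choices

* **Weight estimation**: damped Newton on the convex method-of-moments
  objective with analytic gradient and Hessian, convergence declared at a
  balance residual below $10^{-11}$ (the balancing property is tested at
  $10^{-6}$ componentwise); infeasibility declared when
  $\lVert\alpha\rVert$ exceeds 100 or the iteration becomes non-finite.
  Weights are normalized to sum to $N$ for reporting only; every estimate
  is invariant to the normalization.
* **Outcome regressions**: IRLS maximum likelihood (up to 100 iterations);
  a fit is flagged non-converged — and the replicate recorded as failed —
  on IRLS non-convergence, a singular information matrix, or coefficients
  beyond 50 in absolute value (a separation heuristic).
* **Priors** (Bayesian Q-model): Normal(0, 10^2) on the intercept and
  Normal(0, 1.15^2) on every other coefficient. An SD of 1.15 puts just
  over 95% of the prior mass on conditional odds ratios between 0.1 and
  10 — weakly informative on the scale where effects live. Both scales are
  configurable through `prior_spec()`, and the degree of shrinkage they
  induce at small $N$ is a reportable sensitivity, not an assumption.
* **MCMC**: JAGS with its `glm` block-sampling module; defaults of 2
  chains x 4000 iterations each, the first 2000 as warmup. Convergence is
  flagged (not fatal) when the split-chain potential scale reduction
  factor exceeds 1.05 for any coefficient.
* **Degenerate cells and draws**: a zero cell in the 2x2 table, or an
  imputed pseudo-population arm that is all events or all non-events,
  receives a Haldane–Anscombe correction (0.5 added to the affected
  counts) and is counted; at the benchmark arm sizes and event rates these
  corrections essentially never trigger.
* **Intervals**: Wald, $\pm 1.96 \cdot \mathrm{SE}$, matching the normal
  combination used downstream; percentile intervals are retained in
  `meta$ci_percentile` for users who prefer not to assume normality.
* **Seeds**: the harness derives one seed per replicate
  (`base_seed + scenario * 1e5 + replicate`) and a fixed per-method offset
  within a replicate, so every method sees identical simulated data, any
  subset of the grid reproduces exactly, and execution order is
  irrelevant. JAGS chains receive explicit per-chain RNG seeds.

## Point-estimate conventions

Two conventions circulate for bootstrap-based estimators: report the
full-sample (plug-in) estimate with the bootstrap SD as its SE, or report
the mean of the bootstrap distribution itself. The plug-in convention is
the package default — it keeps the point estimate free of resampling noise
and is the textbook pairing with a bootstrap SE. The bootstrap-mean
convention (`point = "boot-mean"`) is also provided because published
benchmark results for MAIC follow it; it folds the bootstrap bias estimate
into the point estimate, which at small effective sample sizes roughly
doubles the finite-sample bias of the weighted logistic estimator and is
what drives the documented undercoverage of MAIC intervals in the hardest
scenario. The two conventions share the same SE.

## Performance measures

`performance_metrics()` computes, per scenario and method: bias, empirical
SE (SD of the estimates), MSE, variability ratio (mean model SE / ESE),
empirical coverage of the nominal 95% intervals, and standardized bias
(100 x bias / ESE), each with the standard Monte Carlo standard errors
(`ese/sqrt(n)`, `ese/sqrt(2(n-1))`, binomial for coverage, SD of squared
errors for the MSE). The identity `mse = bias^2 + ese^2 (n-1)/n` is
enforced by test. Because a single outlying model SE can distort the
variability ratio, a leave-one-out influence diagnostic (`vr_influence`,
the largest change in VR from removing one replicate) is always reported;
nothing is removed silently. Replicates with infeasible weights,
non-converged fits or degenerate estimates are excluded and counted —
never imputed.

## Problem sizes used by the tests

The full benchmark (9 scenarios x 2000 replicates x 1000 resamples, and
2 x 4000 MCMC iterations per Bayesian replicate) is the reference
configuration; the package's own test and verification runs use reduced
but statistically adequate scales, chosen so Monte Carlo error is small
relative to the quantities checked: 2000 point-estimate replicates where
no resampling is needed (bias MCSE about 0.02, ESE MCSE below 1%), 1000–
2000 replicates x 150 resamples for bootstrap-mean bias, 500 replicates x
250 resamples for coverage (MCSE about 0.012), and 500 Bayesian replicates
with 2 chains x 1000 iterations (500 warmup). These scales are stated
here so that any reported number can be tied to its Monte Carlo precision.

## What the benchmark does and does not show

The data-generating process is deliberately a best case: the Q-model and
the weight model are correctly specified by construction, covariates are
jointly normal so the all-normal copula is exact, there are no missing
data, no measurement error, and effect modifiers are known a priori.
Passing tests therefore demonstrate internal validity of the estimators
and their frequentist properties *under correct specification* — they say
nothing about robustness to misspecified outcome models, omitted effect
modifiers, non-normal covariates, or survival outcomes, none of which the
benchmark exercises. Known limitations: the methods are pairwise only (no
treatment networks); the marginal estimand is specific to the BC sample's
covariate distribution; extrapolation by the outcome-regression methods
under poor overlap rests entirely on the linearity of the link-scale
model; and MAIC simply fails, by design, when overlap is absent.
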