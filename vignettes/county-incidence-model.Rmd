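---
title: "Modelling bivariate county-level disease incidence with geopoisson"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bivariate county-level disease incidence with geopoisson}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`geopoisson` fits a bivariate-response, three-level mixed-effects Poisson
regression to county-level case counts of two related phenotypes — the
canonical application is autism spectrum disorders (ASD) and intellectual
disability (ID) — recorded separately by gender, with counties nested in
states. For state $i$, county $ij$, disease $k \in \{1, 2\}$ and gender
$l$, the observed count is

$$y_{ijkl} \sim \mathrm{Poisson}(N_{ijkl}\,\lambda_{ijkl}), \qquad
\log \lambda_{ijkl} = \mathbf{x}_{ijkl}^\top \mathbf{b}_k + v_{ik} + v_{ijk},$$

where $N_{ijkl}$ is the gender-specific county population (the offset),
$\mathbf{b}_k$ the disease-specific fixed-effect weights, and $v_{ik}$,
$v_{ijk}$ zero-mean random effects. The random effects are independent
across levels but correlated *across the two diseases within a level*:

$$(v_{i1}, v_{i2})^\top \sim N(\mathbf{0}, \Sigma_{state}), \qquad
(v_{ij1}, v_{ij2})^\top \sim N(\mathbf{0}, \Sigma_{county}),$$

each $\Sigma$ a free $2\times 2$ covariance. The default specification has
22 weights per disease (intercept; gender; income; urbanization, insurance
and poverty percentages; seven ethnic-composition percentages; the three
male environmental rates `ConGenM`, `CongMrepM`, `Viral_M`; the binary
state policy codes `CFR`, `DSM`, `ASD`; and three indicators for the
four-level `Eval` policy code), i.e. 44 fixed effects, plus the six free
covariance elements: 50 parameters, over $3111 \times 2 \times 2 = 12\,444$
level-1 cells at national scale.

Exponentiated weights are *event rate ratios*: the multiplicative change
in incidence per unit covariate increase. `event_rate_ratio()`,
`percent_change()` and `random_effect_correlation()` implement these
reporting transforms; credible intervals are transformed endpoint-wise.

### Design construction

`build_design()` assembles the response, offsets and the fixed-effect
matrix. Design choices a user should know:

* **Mean-centering.** Every non-intercept column, including the policy
  dummies and the gender indicator, is centered to mean zero within its
  disease block (unweighted over design rows, which equals unweighted
  centering over counties on a balanced panel). The intercept is therefore
  the log rate at average covariates.
* **Gender coding.** Male = 0, female = 1 before centering, so
  $\exp(b_{Gender})$ is the female-to-male rate ratio. The coding is
  configurable through `model_spec()`.
* **`Eval` expansion.** The four-level evaluation-rigor code enters as
  three indicators (`Eval1`, `Eval2`, `Eval-1`) against the reference
  level $-2$. Published codings of this variable are ambiguous between a
  three- and four-level convention, so the reference level is a
  `model_spec()` argument rather than a hard-coded truth.
* **Block diagonality.** Each disease has its own copy of every covariate
  column; perturbing a disease-1 weight cannot move disease-2 fitted
  rates except through shared random effects.
* **Zero offsets.** Cells with zero population are dropped with a warning
  rather than given $-\infty$ linear predictors; their counts are
  necessarily zero and carry no likelihood information.
* **Units.** Income is in thousands of currency units per capita; all
  rate covariates are percentages of county population. A weight of
  0.032 on income therefore reads "3.2% rate increase per additional
  $1{,}000 above the average county".

### Likelihood and marginalization

`conditional_loglik()` evaluates the exact joint log-density given the
random effects, retaining all constants (factorials via `lgamma`) so
values are comparable across implementations. `marginal_loglik()`
integrates the random effects out per state block (county effects nest
inside their state's integral) by either

* a **Laplace approximation** at the joint per-state mode, found by a
  damped Newton iteration with analytic gradient and Hessian; or
* **nested adaptive Gauss–Hermite quadrature**: each county's
  two-dimensional integral is evaluated on a mode-centered, curvature-
  scaled product grid conditional on the state effect, and the state
  effect is then integrated on an outer adapted grid (7 outer and 5 inner
  nodes per dimension by default).

The quadrature path is the accuracy reference: on single-county instances
it matches brute-force grid integration to $10^{-12}$. The Laplace error
scales like the inverse of the information in a block, i.e. roughly
$O(1/\text{count})$; the two methods agree to $10^{-3}$ on
information-rich instances (hundreds of events per cell), and the test
suite checks the agreement in that regime. In the degenerate limit
$\Sigma \to 0$ the marginal likelihood reduces exactly to the
fixed-effects Poisson GLM likelihood, which the tests verify against
`glm.fit` at variance $10^{-10}$.

## Inference

### MCMC (the primary path)

`fit_mcmc()` runs a Metropolis-within-Gibbs sampler:

* random-walk Metropolis on each fixed-effect weight, plus one jointly
  proposed move for the whole weight vector preconditioned by the GLM
  Fisher matrix;
* one vectorised sweep over all county random-effect pairs (they are
  conditionally independent given the state effects), and likewise over
  state pairs;
* conjugate inverse-Wishart updates for $\Sigma_{state}$ and
  $\Sigma_{county}$ given the sampled effects;
* **translation moves**: any covariate that is constant within states
  (intercepts, policy codes) or within counties (all county-level
  covariates) admits a likelihood-invariant proposal that shifts its
  weight while absorbing the shift into the corresponding random effects.
  Without these, the confounded directions — intercept versus mean state
  effect, a policy weight versus the state effects of the states carrying
  that policy — mix pathologically slowly; with them the sampler
  traverses those ridges directly. Only the Gaussian priors enter the
  acceptance ratio, so the moves are exact.

Proposal scales adapt toward standard acceptance targets (0.44 scalar,
0.30 block, 0.25 joint) during burn-in only, preserving detailed balance
afterwards. Priors default to $b_j \sim N(0, 10^2)$ and
$\Sigma \sim \mathrm{IW}(3, 0.1 I)$ — proper and weakly informative at
log-rate scale; both are configurable via `prior_spec()`. A prior-only
mode (`prior_only = TRUE`) drops the likelihood so the $\Sigma$ marginals
can be checked against the inverse-Wishart prior (a Kolmogorov–Smirnov
check in the test suite).

Summaries follow fixed conventions (`summarize_posterior()`): posterior
means, equal-tailed 95% intervals, rate ratios obtained by exponentiating
the *interval endpoints* (never by averaging exponentiated draws), and
two-sided MCMC p-values $\max(2\min(\hat F, 1-\hat F),\, 2/M)$ with the
floor $2/M$ flagged as censored when a tail is empty. Convergence is
labelled by split-$\hat R < 1.05$ on all parameters; otherwise summaries
are emitted with a warning.

### Laplace maximum likelihood (the cross-check)

`fit_laplace()` maximises the Laplace-approximate marginal likelihood:
the six covariance parameters move on an unconstrained log-Cholesky scale
under box-constrained quasi-Newton, while the fixed effects and random
effects are profiled at each step by a sparse joint Newton solve (all
states and counties simultaneously, via `Matrix`). Wald standard errors
come from the inverse joint Hessian at the optimum. Design columns that
carry no information in a given draw of the geography — e.g. a policy
level no sampled state exhibits — receive `NA` standard errors rather
than a ridge-flattered number.

`empirical_bayes()` returns the posterior mode of every random effect
given parameters (the quantities one maps when color-coding states and
counties), with curvature-based uncertainties; with vanishing variances
the estimates shrink to zero, and a county observed exactly at its
fixed-effect prediction has an estimate near zero.

## The synthetic-data generator

No public county-level claims tabulation exists, so `geopoisson` ships a
generator that emulates the statistical structure the model assumes; all
downstream stages are tested against it. What it does and does not
emulate:

* **Geography.** States holding counties, with gender-stratified
  log-normal county populations (median ~11,000 per gender, log-sd 1.3 —
  the heavy right tail of US county sizes). `geography_preset("national")`
  reproduces the 51-state / 3,111-county national structure;
  `"desk"` is a 10-state / 200-county configuration for fast work.
* **Covariates.** Ethnic percentages from a scaled Dirichlet with a
  remainder category (so sums stay below 100); socioeconomic percentages
  from beta distributions; environmental rates from right-skewed gammas
  whose medians and maxima bracket the descriptive values reported for
  claims data (e.g. mean male genital-malformation rate 0.27% with county
  maxima near 2.4%). Dispersion is deliberately modest for covariates
  with large per-percent weights, so that simulated log-rates stay in the
  rare-event regime; real county covariates are more dispersed, which is
  one reason passing recovery tests here does not certify behaviour on
  real census data.
* **Policy codes** are i.i.d. per state from configurable frequencies —
  a fixture, not a reconstruction of actual statutes.
* **Parameters.** `default_parameters()` uses published effect
  magnitudes for the weights and covariances (cross-disease correlations
  0.974 / 0.962 at state/county level). Intercepts are set from the
  *median* county rates (0.023% per male for the first phenotype): with
  log-scale random-effect variances above 3, the log-normal mean sits
  nearly an order of magnitude above the median, and seeding the
  intercept with the mean would push the upper tail of simulated rates
  past one case per person. The heavy tail this produces reproduces the
  qualitative mean ≫ median ≫ 0 spread of real county rates, though the
  simulated dispersion is somewhat wider than the descriptive spread
  reported for claims data — a consequence of taking the published
  covariance magnitudes at face value.
* **Counts** are drawn Poisson and capped at the offset so the panel
  invariant $y \le N$ always holds; under the defaults the cap does not
  bind.
* **Not emulated:** spatial autocorrelation between neighbouring
  counties (the model's random effects are exchangeable within a level,
  so the generator draws them i.i.d.), actual FIPS geography, and any
  claims-processing artefacts (deduplication, uneven insurer coverage).

Patient-level comorbidity tables (`generate_patients()`) draw a
malformation flag per patient from the county rate and disease flags from
the conditional probabilities implied by solving the $2\times2$ joint
distribution for given margins and odds ratio (the Plackett construction;
`joint_prob_from_or()` raises a feasibility error with the attainable
range when no such table exists). The odds-ratio contract holds within a
stratum; pooling strata with very different prevalences attenuates the
marginal odds ratio, which is a property of the estimand, not of the
generator.

## Numerical choices and degenerate inputs

* Covariances are validated positive semi-definite on entry; fitting uses
  a positive-diagonal Cholesky parameterisation so every iterate is
  positive definite. Fitted standard deviations are floored at $10^{-4}$.
* Newton iterations use step-halving line searches; non-positive-definite
  Hessians fall back to a jittered solve with a warning.
* Decile profiles rank by the predictor and cut at equal-count
  inverted-CDF quantiles with stable tie-breaking (input order), making
  the profile invariant to order-preserving predictor transforms; with
  $n \ge$ bins no bin can be empty.
* The comorbidity odds ratio is the cross-product sample ratio; its
  default interval is the log-scale normal approximation, with the exact
  conditional interval available by flag. Zero cells use the
  Haldane–Anscombe 0.5 correction and are flagged in the output.
* All generators and fitters derive per-stage RNG streams from one master
  seed, so regenerating one stage never perturbs another, and identical
  configurations are byte-identical.

## Problem sizes used in the test suite

The suite exercises the full national structure (51 states, 3,111
counties, 12,444 cells) for design construction and file round-trips,
and a 10-state × 300-county configuration with 1,500-iteration chains
for the 20-replicate parameter-recovery study — sizes chosen so the whole
suite completes in minutes on a laptop while leaving the recovery
criterion statistically meaningful (880 pooled fixed-effect checks).
Production analyses should use the `chain_config()` defaults
(2 chains × 25,000 iterations), which are sized for the national scale.

## Known limitations

* Only the Poisson/log-link family with two nested random-effect levels
  and at most two diseases is supported — this is not a general GLMM
  engine.
* The Laplace path's standard errors condition on the fitted covariances
  (no propagation of $\Sigma$ uncertainty); use the MCMC path when that
  uncertainty matters.
* With few states, state-level covariates (policy codes) are weakly
  identified and their maximum-likelihood variance components can
  collapse to zero; the Bayesian path keeps them proper through the
  prior, at the price of prior sensitivity.
* No spatial smoothing: estimates for a county borrow strength only
  through its state, never from neighbours.
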