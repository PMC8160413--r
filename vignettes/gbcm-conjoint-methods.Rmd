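---
title: "Methods: choice-based conjoint analysis of contrast-media preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice-based conjoint analysis of contrast-media preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a patient undergoes contrast-enhanced MRI, the gadolinium-based
contrast medium (GBCM) she receives trades off a benefit — cancer-detection
sensitivity — against several risks and costs: mild and severe
allergic-like reaction rates, long-term intracranial gadolinium retention,
and out-of-pocket expense. A discrete choice experiment (DCE) quantifies
how patients weigh these properties: each respondent answers a series of
paired tasks ("which of these two hypothetical agents would you prefer?"),
and a random-utility choice model turns the observed choices into
*part-worth utilities* for every attribute level.

`gbcmdce` implements the full analysis pipeline for such a study:

1. **design** — generation and diagnosis of level-balanced,
   near-orthogonal paired choice sets;
2. **estimation** — a hierarchical Bayes multinomial logit (HB-MNL) fit by
   Metropolis-within-Gibbs MCMC, yielding individual-level zero-centered
   part-worths;
3. **metrics** — the range-based attribute-importance statistic, its
   across-respondent summaries, subgroup regressions, and a CI-width
   sample-size formula;
4. **market simulation** — preference shares for arbitrary product
   profiles, including attribute values between or outside the design
   levels;
5. **synthetic respondents** — a seeded ground-truth generator so that
   every stage can be validated end to end without any external data.

## The choice model

Respondent $i$ facing task $t$ with alternatives $j = 1, \dots, J$ chooses
alternative $j$ with probability

$$P_{itj} = \frac{\exp(x_{itj}'\beta_i)}{\sum_k \exp(x_{itk}'\beta_i)},$$

where $x_{itj}$ is the effects-coded profile of alternative $j$ and
$\beta_i$ is the respondent's coefficient vector. Effects coding gives
each attribute with $L$ levels $L-1$ free columns, the reference level
coded $-1$ in all of them; the implied level utilities therefore sum to
zero within each attribute ("zero-centered part-worths"), so positive
values indicate increased likelihood of selection. Attributes hidden in a
task (partial profiles) code to a zero block and drop out of that task's
likelihood.

Heterogeneity follows the standard hierarchical prior

$$\beta_i \sim N(\alpha, \Sigma), \qquad
  \alpha \sim N(0, 100\,I), \qquad
  \Sigma \sim \mathrm{InvWishart}(p + 5,\ I),$$

with $p$ the number of coded columns. These weakly-informative defaults
are the ones hierarchical Bayes choice-based-conjoint practice has
converged on; they are configurable through `mcmc_config()`.

## Estimation

`fit_hb()` runs a Metropolis-within-Gibbs sampler (C++ core):

* $\alpha \mid \beta, \Sigma$ — conjugate multivariate-normal draw;
* $\Sigma \mid \beta, \alpha$ — conjugate inverse-Wishart draw (Bartlett
  decomposition);
* $\beta_i \mid \alpha, \Sigma$ — random-walk Metropolis with proposal
  $N(\beta_i, s_i^2\,\Sigma)$. Scaling the proposal by the current
  population covariance (rather than a spherical step) is what mature
  HB-CBC samplers do; at $p = 15$ it matters — spherical proposals mix
  poorly enough that posterior summaries visibly wander between chains.
  The scalar $s_i$ adapts every 100 burn-in iterations toward an
  acceptance rate in $[0.23, 0.44]$.

Defaults: 50,000 iterations, the first half burn-in, thinning 10. Draws
are exactly reproducible given `mcmc_config(seed = )`; all randomness
flows through R's RNG, including inside the C++ kernel. Validation runs in
this package use 20,000 iterations (and unit tests a few thousand): at
those chain lengths the population mean is recovered with correlation
above 0.99 on the package's synthetic populations, and doubling the chain
changes mean importances by well under a point. The point estimate for
each respondent is the posterior mean of $\beta_i$, expanded to full level
utilities and re-centered exactly; `tidy()` on the fitted object reports
posterior credible intervals for the population-mean utilities, while
across-respondent t-intervals are available downstream (both conventions
appear in applied reports, so both are exposed).

Respondents below a completeness threshold are dropped before fitting
(default: only complete responders enter, mirroring the exclusion of
incomplete surveys; `min_tasks` relaxes this). An empty response set is an
error unless `allow_prior_only = TRUE`, which returns prior draws — useful
for verifying that the prior-only limit centers at zero.

## Attribute importance and subgroup analysis

For respondent $i$ and attribute $a$, the importance is

$$\mathrm{imp}_{ia} = 100 \cdot
  \frac{\max_l u_{ial} - \min_l u_{ial}}
       {\sum_b \left(\max_l u_{ibl} - \min_l u_{ibl}\right)},$$

the utility range of the attribute over the sum of all ranges. Each
respondent's importances are non-negative, sum to 100 exactly, and are
invariant to rescaling the respondent's utilities by any positive
constant. A respondent whose ranges are all zero has no defined
importances and is excluded with a warning. `summarize_importance()`
reports across-respondent means with t-based confidence intervals
(95% by default).

`subgroup_regression()` fits a univariable OLS of importance on a
covariate, per attribute. For a binary covariate the coefficient equals
the difference in group means; for a numeric covariate it is the slope
per unit. Subgroup differences are secondary endpoints, so the default
interval is 99% with significance at $p < 0.01$ (a multiple-comparison
allowance); the primary-endpoint convention of 0.05 applies elsewhere.
Categorical covariates with more than two levels must be binarized
explicitly — the cut-point is an analysis decision the package refuses to
make silently.

`sample_size_for_ci(sd, half_width)` returns
$\lceil (z \cdot sd / h)^2 \rceil$, the respondents needed for a
normal-theory CI of a mean utility to reach half-width $h$. With the
across-respondent utility sd of about 66 implied by the published
planning pair, it reproduces the planning numbers (168 ≈ 170 respondents
for half-width 10, 670 for half-width 5).

## Market simulation

A product profile assigns one numeric value per attribute
(`gbcm_products()` ships the six profiles used in the packaged
scenarios). Because simulation products carry values between or outside
the design levels (retention 0.2 or 0.1 against a minimum design level of
1, sensitivity 78 against a minimum of 80), level utilities are
interpolated:

* piecewise-linearly between adjacent levels, on the attribute's metric —
  the raw value for linearly-scaled attributes (sensitivity, cost), the
  log10 value for attributes spanning orders of magnitude (retention and
  both reaction rates);
* linearly extrapolated from the boundary segment outside the range.

The log metric is a modelling decision, not something the estimation
step forces: interpolating retention on a linear axis would let the
segment from 1 to 10 molecules dominate three orders of magnitude of
range. Both the scale and the extrapolation rule are per-attribute
configuration (`attribute_spec(scale = )`), so sensitivity analyses can
flip them.

`share_of_preference()` supports three share rules:

* **logit** (default) — per respondent, the antilog (exponential) of each
  product's total utility, rescaled to sum to 100%; overall shares are
  the mean of respondent shares. This is the share-of-preference formula
  the simulator is described with, so it is the default.
* **first choice** — the indicator of each respondent's maximum-utility
  product, ties split equally.
* **randomized first choice (rfc)** — first choices tallied over
  Monte-Carlo draws with independent Gumbel perturbations of the product
  utilities; as the noise scale shrinks this converges to the
  first-choice rule, and its draws are seeded. The method that the
  literature *names* is RFC while the formula it *writes down* is the
  logit share; implementing both and defaulting to the written formula
  resolves that tension explicitly.

## The synthetic-respondent generator

`default_population_spec()` defines the validation population; it is a
fixed study condition, not a tuning knob.

* **Mean part-worths.** Evenly spaced, monotone in each attribute's
  preferred direction, with utility ranges proportional to the published
  mean importances (sensitivity 44.3%, mild reaction 19.5%, severe
  reaction 17.0%, retention 11.6%, cost 7.5%) and a total range of 6
  utility units — strong enough that 15 paired tasks are informative,
  weak enough that choices stay stochastic.
* **Heterogeneity.** Independent normal noise per (attribute, level) cell
  with sd equal to 0.25 of the attribute's range. Proportional noise
  perturbs all ranges by the same relative amount, so expected
  importances keep the target ratios; simulations at n = 2000 recover the
  analytic importances within half a point.
* **Covariates.** A binary low-income indicator (prevalence 0.15, the
  share of surveyed households under \$50k) adds +0.5 to the cost range
  and −0.8 to the sensitivity range, reproducing the direction and rough
  size of the published income contrast; an age covariate
  $N(50, 11.9^2)$ truncated to [26, 77] carries no effect and serves as a
  null for type-I-error checks.
* **Choices.** `simulate_choices()` draws from
  $\mathrm{softmax}(\mathrm{scale} \times u)$ per task; scale 0 is random
  answering, large scale is deterministic utility maximization. Passing a
  *list* of designs assigns an independent design to each respondent —
  the package's approximation of the personalized (adaptively generated)
  choice sets real survey software produces. Validation uses this
  per-respondent form: with a single shared design, whichever contrasts
  that one design happens to measure poorly bias the recovered
  importances by up to ±3 points, while averaging over independent
  designs removes the artefact.

What the generator deliberately does **not** emulate: non-compensatory
choice rules, inattention and straight-lining, learning or fatigue over
the 15 tasks, and adaptive dependence of later tasks on earlier answers.
Passing recovery tests therefore shows the estimation pipeline is
correct and well-calibrated for compensatory MNL behaviour — not that
real respondents behave this way.

## Design generation

`generate_design()` starts from an exactly level-balanced random
assignment (each level's count differs from the ideal by at most one, by
construction) and improves it by greedy pairwise swaps within an
attribute — which preserve balance — scored lexicographically: duplicate
alternatives within a task (forbidden; heavily penalized), then
within-task attribute-level overlap, then co-occurrence imbalance across
attribute pairs (near-orthogonality). A request that cannot host the
demanded number of distinct alternatives errors immediately. Partial
profiles rotate a fixed-size attribute subset across tasks
deterministically. The default full-profile reading (all 5 attributes
shown) follows the task description of the emulated survey; partial
profiles remain available via `n_shown`.

`diagnose_design()` recomputes all quantities by direct counting, so the
generator is never its own referee.

## Numerical choices and degenerate inputs

* Likelihoods use max-shifted log-sum-exp throughout; utilities of ±1000
  are safe.
* Zero-centering is exact (the reference level carries minus the sum of
  the free coefficients), and re-centering after posterior averaging is
  applied again defensively.
* First-choice ties split shares equally; RFC inherits R's RNG stream and
  is reproducible by seed.
* Interpolation at a level returns that level's utility exactly;
  log-scaled attributes reject non-positive values.
* All-zero utility ranges exclude the respondent from importance
  statistics with a warning rather than propagating NaN.

## Problem sizes used in validation

The package's acceptance checks run at the scale a single CPU handles
comfortably: full-chain recovery at 200 respondents × 15 tasks × 20,000
iterations; subgroup power over 100 replicates of 200 respondents using
the generator's true part-worths (isolating the generator → importance →
regression chain, since estimation quality is covered by the recovery
check); design quality over 100 seeds; RFC convergence at 10,000 draws.
The acceptance script emulates the complete study at 236 respondents.

## Limitations

* No covariate-driven upper-level model (demographics enter post hoc via
  regression on importances, matching the emulated analysis, not through
  the prior).
* No mixed logit with continuous attribute coefficients, nested logit, or
  marginal-likelihood model comparison.
* The Bayesian D-optimal and adaptive utility-balance design families are
  out of scope; the generator targets the balance/orthogonality/overlap
  criteria directly.
* Supplementary per-respondent utility workbooks are read from CSV
  exports with an explicit column mapping; no binary spreadsheet parsing.
* HB shrinkage attenuates individual-level differences at 15 tasks per
  respondent; range-based importances of weak attributes are inflated
  by estimation noise relative to their true values. These are properties
  of the method, visible in the recovery checks, and worth remembering
  when interpreting small between-attribute differences in real studies.
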