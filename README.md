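# gbcmdce

Choice-based conjoint (discrete choice experiment) analysis of patient
preferences for gadolinium-based contrast media (GBCM).

When patients undergo contrast-enhanced MRI — for example women at
intermediate or high risk of breast cancer in annual screening — the
contrast agent they receive trades a benefit (cancer-detection
sensitivity) against risks and costs: mild and severe allergic-like
reaction rates, long-term intracranial gadolinium retention, and
out-of-pocket expense. `gbcmdce` implements the complete analysis
pipeline for measuring how patients weigh these five attributes from
paired choice tasks, and for simulating how competing products would fare
if patients chose their own contrast agent. It is aimed at radiology
health-services researchers and anyone running a stated-preference study
with a similar structure.

## What it computes

**Choice model.** Respondent *i* chooses alternative *j* of a task with
multinomial-logit probability *P(j) = exp(x′ᵢⱼβᵢ) / Σₖ exp(x′ᵢₖβᵢ)* over
effects-coded attribute levels, with hierarchical heterogeneity
*βᵢ ~ N(α, Σ)* and conjugate weakly-informative priors
(*α ~ N(0, 100 I)*, *Σ ~ InvWishart(p + 5, I)*). Estimation is
Metropolis-within-Gibbs MCMC (C++ core, covariance-scaled random-walk
proposals with burn-in step adaptation), yielding zero-centered
part-worth utilities per respondent.

**Attribute importance.** For each respondent, an attribute's importance
is its utility range divided by the sum of all attribute ranges, × 100;
importances are summarized across respondents with t-intervals and
regressed on covariates (univariable OLS, 99% CIs for the secondary
endpoints).

**Market simulation.** Preference shares for arbitrary product profiles
by logit share of preference (exp of total utility, rescaled to 100%),
first choice, or randomized first choice, with piecewise-linear utility
interpolation (log axis for attributes spanning orders of magnitude) for
off-design attribute values.

**Synthetic ground truth.** A seeded generator produces populations with
known part-worths, covariate-linked heterogeneity (lower income → cost
matters more, sensitivity less), and MNL choice behaviour, so the whole
pipeline is validated end to end by parameter recovery.

## Worked example

```r
library(gbcmdce)

spec      <- default_population_spec(n_respondents = 60, seed = 7)
truth     <- sample_population(spec)
design    <- generate_design(seed = 8)              # 15 paired tasks, 5 attributes
responses <- simulate_choices(truth, design, seed = 9)
fit       <- fit_hb(responses, config = mcmc_config(n_iterations = 5000, seed = 10))
fit
#> <hb_fit: hierarchical Bayes multinomial logit>
#>   60 respondents, 900 tasks, 250 retained draws (5000 iterations)
#>   mean Metropolis acceptance: 0.32

partworths <- extract_partworths(fit)
importance <- importance_per_respondent(partworths)
summarize_importance(importance)
#> # A tibble: 5 × 5
#>   attribute        mean conf.low conf.high     n
#> 1 cost             9.38     8.45      10.3    60
#> 2 mild_reaction   14.8     13.4       16.2    60
#> 3 retention       10.3      8.82      11.8    60
#> 4 sensitivity     46.4     44.4       48.4    60
#> 5 severe_reaction 19.2     17.8       20.5    60
```

Sensitivity dominates (importance ≈ 46%), the reaction rates follow, and
retention and cost matter least — the ordering the generator encodes, and
the ordering observed in screening breast-MRI patients. Shares for three
existing products (profiles in `gbcm_products()`):

```r
share_of_preference(partworths, gbcm_products()[1:3, ])
#> # A tibble: 3 × 2
#>   product share
#> 1 A        8.40
#> 2 B       47.7
#> 3 C       43.9

sample_size_for_ci(sd = 66, half_width = 10)   # respondents for a ±10 utility CI
#> [1] 168
```

`autoplot()` methods visualize fitted utilities, importance summaries and
share results; `tidy()`/`glance()` give broom-style summaries of the fit.
`run_pipeline(pipeline_config(...))` executes the whole chain
(design → data → fit → importance → shares) into a directory of CSVs with
a seeded, hash-stamped run record.

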