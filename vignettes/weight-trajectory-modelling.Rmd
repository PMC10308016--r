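---
title: "Piecewise-linear mixture modelling of body-weight trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise-linear mixture modelling of body-weight trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Annual health checkups record weight, height, age, sex, a panel of
laboratory values, and an 11-item lifestyle questionnaire with a 3-level
intention-to-improve indicator. `weightcast` models the one-year weight
transition with a *gated mixture of sparse linear experts*: a small binary
tree over baseline BMI, age and sex routes each person-year to one leaf, and
each leaf predicts next-year weight as

\[
w_{t+1} \;=\; \beta_0 + \beta_w w_t + \beta_\Delta (w_t - w_{t-1})
  + \beta_h \,\mathrm{height} + \beta_a \,\mathrm{age}
  + \sum_j \beta_j x_j ,
\]

where the \(x_j\) are questionnaire indicators: baseline-interview
indicators fire when the answer equals the feature's level, and
predictive-year indicators fire only when, in addition, the respondent's
intention-to-improve level (1, 2 or 3) matches the feature's intention
column. Drinking enters as a numeric frequency/quantity score at both
interviews. The packaged reference model
(`load_published_model()`) has five leaves: BMI is split at 29.93 kg/m²,
the high-BMI group by sex, the 23.44–29.93 band by the 24/25-year age
boundary, and BMI < 23.44 forms one leaf. Its coefficients are stored at
their printed 2-decimal precision and are protected by a checksum; a
literal `0.00` coefficient (selected but null weight) is kept as a selected
term, distinct from an unselected one.

Multi-year forecasts are always *chained*: the year-1 prediction becomes
the baseline weight for year 2, the weight-difference covariate is updated
to (predicted − previous), and the predictive-year lifestyle is held fixed
at the chosen scenario for the whole horizon — the setting in which a person
commits to a lifestyle once. Two conventions are deliberately explicit
because the choice is genuinely open:

* **Leaf reassignment.** By default the gate is re-evaluated each year with
  the updated BMI (`reassign_leaf = TRUE`); freezing the baseline leaf is
  available because a person near a threshold can otherwise switch formulas
  mid-trajectory. Both modes are tested.
* **Age.** Age advances by one year per step by default; a frozen-age mode
  exists and is used by the worked single-step examples, where it keeps the
  arithmetic transparent.

The age gate is stored as the boundary value 24.5 under the package's
uniform "left `<` t, right `≥` t" convention, which on integer ages is
exactly "≤ 24 versus > 24", with 24 grouped into the young leaf.

## The synthetic cohort generator

Real checkup records of this kind are not publicly distributable, so every
downstream stage is exercised on synthetic cohorts
(`generate_cohort()`) whose defaults are fixed once:

* sex is male with probability 0.66; height and year−1 weight are
  sex-specific normals (male 170.8 ± 6.2 cm, 68.3 ± 11.1 kg; female
  157.8 ± 5.7 cm, 54.4 ± 9.6 kg); age is normal(48, 12) truncated to
  19–91 and rounded to whole years;
* the year-0 weight is the year−1 weight plus one Gaussian innovation, so
  the weight-difference covariate starts at its working scale;
* weights for years 1–3 follow the ground-truth model (by default the
  packaged five-formula model) plus Gaussian noise with
  `noise_sd_kg = 1.9` — a calibration to the scale of the reported
  validation error of such models, not an empirical claim about any real
  cohort; recovery studies use 1.0 kg;
* lifestyle answers persist year to year with flip probability 0.1
  (categorical items and the intention level are redrawn from their
  marginals with the same probability). The marginals themselves
  (e.g. 25% smokers, 20% breakfast skippers, eating speed 30/55/15,
  intention levels 35/40/25) are plausibility choices for a working-age
  checkup population, fixed once and documented here; the true rates are
  unknowable from the published material;
* missingness is person-level and MCAR with probability 12021/67021
  (one randomly chosen year's weight is blanked), matching the published
  single exclusion count; informative missingness and imputation are out
  of scope;
* the laboratory panel is drawn as independent sex-specific normals and
  serves only as decoy predictors for the learner's selection behaviour.

What the generator deliberately does **not** emulate: correlation between
height and weight (so the synthetic BMI spread is somewhat wider than a
real cohort's), correlations among labs, secular trends, and any
dependence of lifestyle dynamics on weight. Passing recovery tests
therefore show that the learner can re-identify a known generative
structure under realistic noise — not that it would produce these exact
formulas on real data.

## The learner

`fit_partition()` is a behavioural surrogate for proprietary heterogeneous
mixture learning: the published contract — an automatically chosen number
of partitions with an interpretable sparse linear model in each — is
reproduced with standard, fully documented machinery rather than the
original factorized-Bayesian derivation:

* **Criterion.** Each leaf is scored by its penalised Gaussian
  log-likelihood, charging `log(n_local)/2` per selected parameter
  (slopes + intercept + variance) with the *component-local* sample size;
  a split's gain is children-minus-parent on this criterion, and a split
  is accepted only if the gain is positive.
* **Search.** Greedy top-down recursion to `max_depth = 3` (the published
  tree needs depth 3), with gates restricted by default to baseline BMI,
  age and sex — the only gate variables in the published schema; a config
  switch opens all features for exploration.
* **Thresholds.** Candidates are midpoints between consecutive distinct
  empirical quantiles (64 per gate by default); the accepted split is then
  refined by an exact scan of the data between the bracketing grid points,
  because the published thresholds (29.93, 23.44) are not round numbers.
* **Leaf fits.** Forward selection on the same criterion, computed on
  cross-product (sufficient-statistic) matrices with the sweep operator, so
  scoring all thresholds of a gate costs one pass over the node's rows.
  Collinear candidates are skipped and logged. Ties break to the lowest
  feature index, then the lowest threshold.
* **Target.** One shared one-year transition model trained on all three
  observed transitions; multi-year prediction is always by chaining, never
  a direct 3-year regression.

A brute-force enumerator (`brute_force_best_split()`, naive `lm`-based
fits, no sweeps) serves as the greedy step's oracle in the tests.

## Validation design

The published model's real-data accuracy cannot be reproduced without the
private cohort, so validation is by *parameter recovery*
(`recovery_study()`): simulate cohorts of 20,000 persons from the packaged
model (noise 1.0 kg, no missingness, so the learner trains on exactly
20,000 persons — missingness fidelity is checked separately at its own
published rate), refit from scratch over 10 seeds, and compare. Because a
greedy search may discover the same five regions in a different split
order (at these conditions the root typically lands on the 23.44 boundary
first), `recovery_report()` matches fitted gates and leaves to the
reference model by *region overlap* on a dense BMI × age × sex probe grid,
which is invariant to split order and leaf labels. At these conditions the
recovered thresholds sit within a few hundredths of a BMI unit of 29.93
and 23.44, the age gate lands on the 24/25 boundary, matched leaves carry
a baseline-weight coefficient within a few thousandths of 1.00, and the
leaf matched to formula 1 recovers its weight-difference coefficient near
−0.14. One recovery run (generation + encoding + fit) takes a few seconds
on one CPU; `scripts/acceptance.R` re-runs the whole design.

Evaluation (`evaluate_model()`) follows the chained three-year protocol on
held-out persons, with the predictive-year lifestyle held fixed at each
person's actual year-1 answers (`lifestyle = "observed"` feeds the true
per-year profiles instead). RMSE is reported pooled and per horizon: the
one-year horizon sits at the generator's noise floor, while later horizons
compound the fed-forward innovation (with a weight-difference coefficient
around −0.2, the year-2 error is about \(\sigma\sqrt{1 + 0.8^2}\)); since
the published material does not state which pooling its headline error
uses, both are always available. The multiple-regression baseline
(`fit_multiple_regression()`) is a single OLS fit over the identical
encoding, wrapped as a one-leaf model so the same chained protocol applies.
`compare_models()` contrasts per-person squared errors with an unpaired
Student t-test — the conventional choice for such comparisons; a paired
test is statistically preferable on shared validation persons and is
available via `paired = TRUE`. Cohort tables are compared Table-1 style by
`compare_cohorts()`: chi-squared without continuity correction for
categorical variables (the correction is available by argument), Student's
t for continuous ones (Welch optional).

## Numerical choices and degenerate inputs

* Residual sums of squares are floored at `1e-10 · n` before entering the
  log-likelihood, so perfectly fit or constant targets yield finite
  criteria, no features, and no splits.
* Sweep pivots below `1e-10` of a column's original scale mark the column
  collinear; the candidate is skipped (leaf fits) or dropped with a
  warning (the dense baseline).
* Split candidates leaving a child below `min_leaf_n = 200` rows are
  infeasible, not errors.
* All randomness is owned by explicit seeds: a single master seed fans out
  to named substreams (`derive_seed()`), generator output is byte-stable,
  and prediction arithmetic is batch-size independent (row-wise
  accumulation), so the noise-free generative chain equals the model's
  chained predictions bit for bit.

## Known limitations

The learner is a surrogate: it reproduces the published method's contract,
not its exact selection mathematics. Synthetic cohorts omit the
correlations noted above, so absolute error magnitudes on synthetic data
transfer to real cohorts only as orders of magnitude. Scenario comparisons
are qualitative what-ifs — the intervention coefficients are associational,
learned from observational checkup data, and carry no causal guarantee.
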