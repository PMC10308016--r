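# weightcast

Predicting adult body weight over a three-year horizon from annual
health-checkup records — and understanding *which* lifestyle habits move it.

Clinicians running annual checkups (weight, height, labs, and an 11-item
lifestyle questionnaire with a 3-level intention-to-improve indicator) want a
quick, explainable forecast of a patient's weight a few years out, plus
what-if answers ("what if this patient stops skipping breakfast?"). A single
regression hides the fact that lifestyle matters very differently for
different people. `weightcast` implements the piecewise-linear
mixture-of-experts approach to this problem:

- a **gating tree** over baseline BMI, age and sex routes each person to one
  of a few groups;
- each group gets a **sparse linear formula** for next-year weight:

  w(t+1) = β₀ + β_w·w(t) + β_Δ·(w(t) − w(t−1)) + β_h·height + β_a·age + Σⱼ βⱼ·xⱼ

  where the xⱼ are questionnaire indicators, with predictive-year indicators
  additionally gated by the person's intention-to-improve level;
- **three-year forecasts chain** the one-year model, feeding each prediction
  back as the next baseline weight, with the chosen lifestyle held fixed.

The package ships:

- the published five-formula reference model as a checksummed JSON artifact
  (`load_published_model()`): BMI split at 29.93 kg/m², the high-BMI group by
  sex, the 23.44–29.93 band at the 24/25-year age boundary, BMI < 23.44 as
  one leaf;
- a synthetic longitudinal cohort generator calibrated to the published
  cohort characteristics (`generate_cohort()`), since real checkup data of
  this kind is private;
- a heterogeneous-mixture learner (`fit_partition()`): greedy
  penalised-likelihood gating-tree search with forward-selected sparse
  linear leaves, able to re-discover the published structure from data;
- forecasting and scenario tools (`predict_trajectory()`,
  `scenario_compare()`) and an evaluation layer (`rmse()`,
  `fit_multiple_regression()`, `compare_models()`, `compare_cohorts()`,
  `recovery_report()`, `run_pipeline()`).

See the vignette (`vignettes/weight-trajectory-modelling.Rmd`) for the model,
the generator's assumptions, and the validation design.

## Worked example

A 40-year-old man, 170 cm, 90 kg at baseline (BMI 31.1, so the high-BMI male
formula applies), weight up 0.8 kg on the year before. Compare committing to
eating breakfast against continuing to skip it:

```r
library(weightcast)
model <- load_published_model()
print(model)
#> Piecewise-linear weight model: 5 leaf formula(s)
#>   bmi_baseline >= 29.93?
#>     bmi_baseline >= 23.44?
#>       leaf 5: bias 0.18, 35 term(s)
#>       age_baseline >= 24.5?
#>         leaf 3: bias 1.57, 35 term(s)
#>         leaf 4: bias 0.16, 38 term(s)
#>     sex_male >= 0.5?
#>       leaf 2: bias -2.34, 33 term(s)
#>       leaf 1: bias 2.12, 41 term(s)

profile <- data.frame(
  wants_health_instruction = "no", heavy_smoker = "yes", drinking_score = 2,
  fast_walker = "no", daily_activity_1h = "no", exercise_2x30min = "no",
  skips_breakfast_3x = "yes", eating_speed = "quicker", late_supper_3x = "yes",
  snacks_between_meals = "yes", sleeps_well = "no", intention_level = 2)
history <- rbind(
  cbind(data.frame(person_id = 1, year_index = -1, sex = "male", age = 40,
                   height_cm = 170, weight_kg = 89.2), profile),
  cbind(data.frame(person_id = 1, year_index = 0, sex = "male", age = 40,
                   height_cm = 170, weight_kg = 90.0), profile))

eats <- profile
eats$skips_breakfast_3x <- "no"
trajectories <- scenario_compare(history, eats, profile, model,
                                 labels = c("eats breakfast", "skips breakfast"))
print(trajectories[[1]])
#> Weight trajectory for person 1 under scenario ' eats breakfast '
#>   measured (years -1, 0):  89.20, 90.00
#>   predicted (years 1..3): 91.14, 92.39, 93.60
print(trajectories[[2]])
#> Weight trajectory for person 1 under scenario ' skips breakfast '
#>   measured (years -1, 0):  89.20, 90.00
#>   predicted (years 1..3): 91.38, 92.66, 93.93
```

Both scenarios predict continued gain (his weight has been rising and the
formula's momentum terms dominate), but committing to breakfast trims about
0.3 kg off the three-year forecast — the kind of individualized, explainable
difference the model is built to surface.

The full pipeline — simulate a cohort, filter incomplete persons, split,
learn the tree from scratch, and evaluate against a multiple-regression
baseline by chained three-year prediction on held-out persons:

```r
cfg <- pipeline_config(
  generator = generator_config(n_persons = 24000, seed = 1, noise_sd_kg = 1.0),
  fit = fit_config(),
  n_learning = 18000, n_validation = 1500, seed = 2026)
report <- run_pipeline(cfg)
print(report)
#> Evaluation report (n = 1500 validation persons)
#>   piecewise model RMSE: 1.395 kg
#>   multiple-regression RMSE: 1.703 kg
#>   squared-error comparison: t = -8.711, p = 0.000
#>   recovered leaves: 5
```

The learner re-discovers the five-leaf structure and beats the single global
regression on data that genuinely mixes regimes; the per-horizon RMSEs
(0.962 / 1.332 / 1.772 kg here) show the one-year error at the generator's
1 kg noise floor and the chained horizons compounding it.

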