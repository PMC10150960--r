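# hypocause

Tools for studying the *causes* of hypoglycemia in type 1 diabetes from
routinely collected self-care diaries.

Hypoglycemia (self-monitored blood glucose below 4 mmol/L) is the most common
adverse consequence of insulin therapy, and its causes are usually
behavioural: physical activity without dose adjustment, mistakes in
carbohydrate counting, or mistakes in insulin dosage. Clinicians attribute
episodes to these cause families by reading diaries; `hypocause` implements
that attribution problem as a reproducible pipeline:

1. **Diary model and interchange** — typed per-subject diaries (SMBG
   readings, quick-acting and basal insulin, carbohydrate intakes,
   bolus-advisor records, quiz engagement, labelled episodes) with a
   seven-file CSV format, confidence/category episode filtering, and a
   configurable reason-to-category mapping.
2. **Synthetic cohort generator** — `generate_cohort()` simulates diaries
   with labelled episodes whose cause-conditional structure (episode timing,
   dose deviations, meal gaps, exercise tags) is injected with known
   directions, so every downstream stage is testable without clinical data.
3. **Event representation** — each filtered episode becomes a canonical
   83-variable feature vector: temporal context, shape-preserving (PCHIP)
   interpolated glucose-curve summaries over the ±3 h window, neighbouring
   readings and intakes (subject-centred), bolus-advisor context, 90-day
   self-care statistics, and quiz engagement.
4. **Association analysis** — per-feature random-intercept logistic models
   (adaptive Gauss–Hermite quadrature), for episode *j* of subject *i* and
   cause *k*:

   logit p<sub>ijk</sub> = β₀ + β₁ x<sub>ij</sub> + b<sub>i</sub>,  b<sub>i</sub> ~ N(0, σ<sub>b</sub>²)

   with Wald z statistics and significance stars, BIC screening, iterative
   VIF ≥ 10 filtering, Pearson |ρ| ≥ 0.7 correlation reporting, and a
   multi-predictor model per cause category.
5. **Classification experiments** — subject-grouped 10-fold CV; per fold,
   SFFS feature selection scored by an extremely-randomized-trees ensemble in
   nested subject-grouped 5-fold CV with inverse-frequency class weights
   w<sub>i</sub> = N<sub>obs</sub>/(N<sub>cl</sub>·N<sub>obs,i</sub>); then a
   3-hidden-layer neural classifier (width = selected subset size, 60%
   dropout) optimised for F1, recall or precision; one-vs-rest and exclusive
   3-class scenarios, raw or PCA feature spaces; per-class
   F1/recall/precision/MCC reported as mean ± SD across folds.

The methods vignette (`vignettes/methods.Rmd`) documents the model, every
tunable parameter, and the design decisions.

## Worked example

```r
library(hypocause)

# simulate a small labelled cohort and build the feature table
cfg <- cohort_config(n_subjects = 20, days = 150, episodes_per_subject = 12,
                     seed = 11)
cohort <- generate_cohort(cfg)
features <- featurize_cohort(cohort$diaries)
dim(features)
#> [1] 237  90

# association analysis: which self-care patterns mark each cause?
assoc <- multiple_regression_report(features, features$category,
                                    features$subject_id,
                                    association_config(top_k = 20))
subset(assoc$table, feature %in% c("sin_tod", "pre_ins_dosage"),
       select = c(feature, category, beta, z, stars, n))
#>         feature   category       beta         z stars   n
#>  pre_ins_dosage   ACTIVITY -1.0458381 -4.224532   ***  176
#>         sin_tod   ACTIVITY  0.8944471  3.922682   ***  176
#>  pre_ins_dosage       FOOD  1.4303527  3.854693   ***  176
#>         sin_tod       FOOD -0.5516807 -2.592438    **  176
#>         sin_tod MEDICATION -0.9765280 -1.867063       176

# activity episodes happen in daytime (positive sin_tod = hours from
# midnight) and follow below-average boluses; food-related episodes follow
# above-average boluses (carb overestimates)

# one-vs-rest classification of activity episodes
cv <- run_cv_experiment(features, scenario = "ovr", space = "raw",
                        objective = "f1", k = 5, seed = 3,
                        classes = "ACTIVITY",
                        sffs_control = list(max_features = 8))
subset(cv$summary, class == "ACTIVITY", select = c(metric, mean, sd))
#>     metric      mean         sd
#>         f1 0.7461002 0.07200585
#>     recall 0.9573199 0.02896326
#>  precision 0.6195815 0.09909026
#>        mcc 0.3753219 0.23596877
```

The F1 of 0.75 against an activity prevalence of 0.49 shows the classifier
recovering the injected activity signature well above the prevalence-matched
random baseline (expected F1 = prevalence); the ± values are the spread
across the five subject-grouped validation folds.

A full pipeline run (`run_pipeline(pipeline_config(), "out/")`) persists
diaries, features, association tables, CV reports, rendered summaries and a
seed manifest, and reruns byte-identically. A thin command-line wrapper is
installed at `inst/scripts/hypocause.R`.

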