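# nlrtrack

Detecting head-and-neck cancer recurrence from longitudinal blood counts
after concurrent chemoradiotherapy (CCRT).

## The problem

Patients treated with definitive CCRT are followed for years with
routine blood tests.  Two systemic-inflammation markers derived from
those tests — the neutrophil-to-lymphocyte ratio (NLR = absolute
neutrophil count / absolute lymphocyte count) and the
platelet-to-lymphocyte ratio (PLR = platelet count / lymphocyte
count) — tend to rise as an occult recurrence progresses.  The
surveillance record is an irregular time series: visit spacing and
follow-up duration differ per patient, which defeats sequence models
that assume a regular grid.

`nlrtrack` implements the tabular alternative, end to end:

1. **Meta-feature extraction** — each trajectory is compressed into 12
   windowed summaries (per ratio: mean, max−min, the day 14–90
   post-treatment window value `*_Tx`, the recurrence-window value
   `*_R` (detection −90 to +30 days; last visit for non-recurrent
   cases), and the differences `*_R − *_mean` and `*_R − *_Tx`), plus
   age, sex, smoking and one-hot stage — 16 model inputs.
2. **Temporal-split augmentation** — visits more than 180 days before a
   detected recurrence are plausibly measurements of a non-recurrent
   state, so the early segment of each eligible recurrent case becomes
   one additional derived non-recurrent training case, with provenance
   tracked for leakage-free cross-validation.
3. **Model suite** — logistic regression, random forest, gradient
   boosting, and a feed-forward neural network (64/32 ReLU units,
   dropout 0.3, Adam at learning rate 0.001, early stopping), behind a
   single fit/predict contract, all deterministic given a seed.
4. **Sensitivity-sweep RFE** — features are ranked by the dynamic range
   of the model's predicted probability when each input is swept over
   its observed range with the others held at their background value;
   the weakest is removed, the model refit, and the set maximizing the
   mean of cross-validated ROC-AUC and PR-AUC is selected.
5. **Evaluation** — stratified, group-aware 10-fold cross-validation;
   Mann–Whitney ROC-AUC; average-precision PR-AUC; and an external
   2×2 (training variant × validation variant) transfer matrix.
6. **Synthetic cohorts** — a generator emulating post-CCRT surveillance
   (irregular gamma-renewal visits, treatment-induced lymphopenia with
   exponential recovery, a log-linear marker ramp before detection,
   26.5% recurrence prevalence) for development and calibration.

## Worked example

```r
library(nlrtrack)

cohort <- generate_cohort(sim_config(n_patients = 300, seed = 7))
cohort
#> <nlr_cohort> 300 cases (64 recurrent, 21.3%), 3485 visits
#>   generator seed: 7

split <- split_cohort(cohort, margin_days = 180)
split
#> <nlr_cohort> 360 cases (64 recurrent, 17.8%), 4187 visits
#>   generator seed: 7
#>   split-augmented: 60 derived cases

features <- extract_features(split)$features
report <- cross_validate(model_spec("DNN", seed = 1), features,
                         cv_spec(n_folds = 10, seed = 1),
                         groups = provenance_groups(split))
report
#> <nlr_eval_report> DNN, 10-fold CV, 19 features
#>   roc_auc      0.951 +/- 0.056
#>   pr_auc       0.882 +/- 0.088
#>   accuracy     0.927 +/- 0.048
#>   precision    0.821 +/- 0.149
#>   sensitivity  0.740 +/- 0.170
#>   specificity  0.966 +/- 0.028
```

The 64 recurrent cases carry the generator's planted marker ramp
(platelets and neutrophils ×1.5, lymphocytes ×0.75 at detection), so
the classifier separates them well; the derived split cases (visits
ending 180 days before their parent's detection) enter as
non-recurrent and share cross-validation folds with their parents.

Feature selection on the same table:

```r
rfe <- run_rfe(model_spec("DNN", seed = 1), features,
               cv_spec(n_folds = 10, seed = 1),
               groups = provenance_groups(split))
rfe$selected
#> [1] "NLR_Rmean" "PLR_R"     "PLR_Rmean"
```

`run_pipeline(run_config(...))` performs all of the above plus
serialization of every artifact (cohort tables, feature matrices,
exclusion logs, CV reports, RFE trace, manifest with content hashes)
into a run directory.

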