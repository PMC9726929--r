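# cytodose

Radiation biodosimetry estimates the absorbed ionizing-radiation dose of an
exposed person from biological markers in a blood sample. The two standard
cytogenetic assays — the dicentric chromosome assay (DCA, dicentrics per
monocentric chromosome, `Yield`) and the cytokinesis-block micronucleus assay
(CBMN, micronuclei per binucleated cell, `Mi_BN`) — have complementary dose
responses: dicentric yields follow the classical linear-quadratic model
`median(y | D) = c + αD + βD²` over 0–8 Gy, while the raw micronucleus index
turns over at high dose as cell-cycle arrest removes scorable binucleated
cells. `cytodose` is an R package for reconstructing dose by **combining both
assays in one machine-learning model**, for biodosimetry researchers and
cytogenetic laboratories evaluating triage pipelines.

The core methods:

* a **linearized micronucleus index** `Mi_BN_c = Mi/BN + (1/k)·MN/BN`
  (MN = mononucleated cells), with the constant `k` calibrated by an
  incremental search that refits a median (τ = 0.5) linear-quadratic quantile
  regression and stops at the first `k` whose quadratic term β is
  statistically consistent with zero (bootstrap SE, two-sided p > 0.05);
* exact **median LQ quantile regression** (pinball-loss minimization with an
  LP-equivalent vertex solution) with case-resampling bootstrap inference;
* a **quantile regression forest** (bagging, per-split feature subsampling,
  random-threshold "extratrees" splits, leaf-target pooling) giving mean dose
  reconstructions and prediction quantiles, plus baseline learners (linear,
  elastic net, SVR, boosted trees, model tree) under repeated k-fold CV;
* shadow-feature (Boruta-style) selection, exact Shapley attribution,
  ICE/partial-dependence profiles, and assay-ablation testing with paired
  Wilcoxon signed-rank comparisons of squared errors;
* a **synthetic cohort generator** reproducing the statistical structure of a
  1349-aliquot, 155-donor ex vivo irradiation study (doses 0/3/4/8 Gy,
  ages 3–69, low-count tail tripping the ≥ 20-cell filters), so the entire
  pipeline is testable without any data download.

## Worked example

```r
library(cytodose)

cohort <- simulate_cohort(generator_config(seed = 1))   # 1349 raw aliquots
flt    <- filter_low_counts(cohort)                     # >= 20 BN, >= 20 MC
flt$filter_log$n_retained
#> [1] 1121

cal <- calibrate_k(flt$records, seed = 2)               # linearization search
cal$k_selected
#> [1] 70

rec <- compute_indices(flt$records, k = cal$k_selected)
fit_linear_after_drop(rec$dose_gy, rec$mi_bn_c, seed = 3)
#> quantile LQ fit (tau = 0.5, degree = 1, n = 1121)
#>   c = 0.19670 +/- 0.00472
#>   alpha = 0.09653 +/- 0.00206

mm <- encode_features(rec)                              # age, race, ethnicity,
sp <- split_data(rec, seed = 4)                         # yield, mi_bn, mi_bn_c
qf <- train_quantile_forest(mm$features[sp$part == "train", ],
                            mm$dose[sp$part == "train"],
                            n_trees = 500, mtry = 6, seed = 5)
test <- sp$part == "test"
regression_metrics(mm$dose[test], predict_mean(qf, mm$features[test, ]))
#> n = 560: MAE = 0.249 Gy, RMSE = 0.455 Gy, R2 (Pearson^2) = 0.976

q <- predict_quantiles(qf, mm$features[test, ])
quantile_coverage(mm$dose[test], q, 0.1, 0.9)
#> 557 of 560 actual doses (99.5%) within the 0.1-0.9 quantile interval
```

The calibration selects `k = 70`: at that constant the median of the
linearized index is linear in dose, with intercept ≈ 0.20 micronuclei per
binucleated cell and slope ≈ 0.095 Gy⁻¹ recovering the generator's
configuration. On the held-out half the forest reconstructs dose with
sub-0.5 Gy RMSE on this synthetic cohort, and nearly all actual doses fall
inside the predicted 10–90% quantile band. `run_pipeline(pipeline_config())`
chains every stage (simulation, filtering, calibration, selection, CV
comparison, test evaluation, Shapley attribution, ablations) under one seed
ledger and writes deterministic JSON/CSV reports.

## Package layout

* `R/generator.R` — synthetic cohort generator (configs, donors, aliquots)
* `R/dataprep.R` — reading, low-count filtering, indices, encoding, splits
* `R/doseresponse.R`, `src/quantlq.cpp` — quantile LQ fits, bootstrap,
  k calibration
* `R/qforest.R`, `src/qforest.cpp` — quantile regression forest
* `R/learners.R`, `R/cv.R`, `R/boruta.R` — baseline learners, repeated CV,
  grid search, shadow-feature selection
* `R/shap.R`, `R/metrics.R`, `R/pipeline.R` — attribution, metrics,
  ablations, end-to-end pipeline
* `vignettes/methods.Rmd` — models, assumptions, numerical choices and
  limitations
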