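# thyropanel

Protein-panel diagnostic classification of thyroid nodules from label-free
DIA proteomics, in R.

Thyroid nodules are frequent incidental findings; cytopathology leaves many
fine-needle aspirates indeterminate, and a large share of diagnostic
surgeries removes tissue that proves benign. `thyropanel` is for
computational proteomics groups building and stress-testing small-protein-
panel classifiers for this benign-vs-malignant triage: it implements a
complete, tested pipeline from abundance matrix to diagnostic report, plus
a cohort simulator so every stage can be exercised without access to
patient data.

## What's inside

| Stage | Functions |
|---|---|
| Synthetic cohorts (MNAR censoring, planted panels, replicates) | `cohort_config()`, `generate_cohort()`, `split_cohort()` |
| Detection-limit imputation + discovery-anchored z-normalization | `fit_normalizer()`, `apply_normalizer()`, `replicate_qc()` |
| Feature screen + genetic-algorithm panel search | `screen_features()`, `evaluate_fitness()`, `ga_select()` |
| Manifold-regularized neural classifier | `net_config()`, `train_dmt()`, `predict()`, `latent_embedding()` |
| Diagnostic reporting | `confusion()`, `diagnostic_metrics()`, `roc_auc()`, `prevalence_adjusted()`, `stratified_accuracy()` |
| Differential expression | `pairwise_dep()`, `dep_count_matrix()`, `anova_across_groups()` |

The classifier is a two-part multilayer perceptron (feature extractor to a
latent space, softmax head) trained end-to-end on

```
L = L_DMT + alpha1 * L_e + alpha2 * L_r
```

where `L_DMT` is a cross-layer two-way divergence — the sum over sample
pairs of the Bernoulli KL divergence between input-space similarities
`P = S(2*pi*kappa(D_X, 100)^2)` and latent-space similarities
`Q = S(2*pi*kappa(D_Z, 1)^2)`, with `kappa` the Student-t density kernel of
pairwise Euclidean distances and `S(A) = A + A' - 2A∘A'` — `L_e` a
class-weighted cross-entropy (`beta = 1.6` on the benign term, `2 - beta`
on the malignant), and `L_r` the squared L2 norm of the weights. Gradients
are hand-derived and finite-difference-verified; training is pure R, no
GPU. Panel search encodes candidates as fixed-size protein sets, scores
them by 3-fold cross-validated accuracy (`F^C = mean(A_k^C)`) on dataset A,
and ranks the finalists once on held-out dataset B.

## Worked example

```r
library(thyropanel)

cfg <- cohort_config(
  n_per_histotype = c(N = 20, MNG = 100, FA = 70, FTC = 40, PTC = 70),
  n_proteins = 400, n_informative = 12, effect_size = 2, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> synthetic_cohort: 300 samples (300 nodules), 400 proteins, 51.0% missing
#> histotypes: FA=70, FTC=40, MNG=100, N=20, PTC=70

sp <- split_cohort(cohort, c(0.8, 0.2), stratify_by = "class", seed = 8)
disc <- sp[[1]]; test <- sp[[2]]

nm <- fit_normalizer(disc$matrix)
nm
#> normalization_model: 351 features, impute_value = 14

panel <- screen_features(disc$matrix, disc$annotation$class, screen_config())
panel
#>  [1] "PROT0001" "PROT0002" "PROT0003" "PROT0004" "PROT0005" "PROT0006"
#>  [7] "PROT0007" "PROT0008" "PROT0009" "PROT0010" "PROT0011" "PROT0012"

Xtr <- apply_normalizer(nm, disc$matrix[, nm$feature_ids])[, panel]
Xte <- apply_normalizer(nm, test$matrix[, nm$feature_ids])[, panel]
clf <- train_dmt(Xtr, disc$annotation$class,
                 net_config(input_dim = length(panel), epochs = 50, seed = 9))
clf
#> dmt_classifier: 12-protein panel, latent dim 8
#> fold validation AUCs: 0.989, 0.995, 1.000, 1.000, 1.000 (best fold 3)

pred <- predict(clf, Xte)
cc <- confusion(test$annotation$class,
                ifelse(pred$P_label == 1, "benign", "malignant"))
diagnostic_metrics(cc, auc = roc_auc(pred$y0_hat, test$annotation$class)$auc)
#> metrics_report (n = 60, prevalence = 36.7%)
#>   sensitivity  95.5% (78.2-99.2)
#>   specificity  100.0% (90.8-100.0)
#>   ppv          100.0% (84.5-100.0)
#>   npv          97.4% (86.8-99.5)
#>   accuracy     98.3% (91.1-99.7)
#>   auc          1.000
```

Reading the report: the screen found exactly the 12 planted informative
proteins; the classifier then separates held-out benign from malignant
nodules nearly perfectly (the planted 2-log2-unit effect is strong).
Sensitivity is the malignant detection rate — malignant is the positive
class throughout — and each interval is the 95% Wilson score interval.
`prevalence_adjusted(0.92, 0.71, 0.30)` re-projects predictive values to a
screening population: NPV 95.4%.

A command-line interface covers the file-based workflow
(`simulate`, `fit-normalizer`, `normalize`, `screen`, `evaluate`, `dep`):

```sh
Rscript -e 'thyropanel::thyropanel_cli()' simulate --out cohort/ --seed 7
```

## Documentation

The methods vignette (`vignettes/thyropanel-methods.Rmd`) describes the
model, the simulator's assumptions and what a green test does and does not
establish, the numerical choices (clamping, tie-breaks, optimizer), and
known limitations.
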