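---
title: "Methods: protein-panel classification of thyroid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-panel classification of thyroid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyropanel)
```

## The problem

Thyroid nodules are common and mostly benign, but cytopathology of
fine-needle aspirates leaves a substantial fraction of nodules
indeterminate, driving diagnostic surgery on tissue that turns out benign.
`thyropanel` implements a proteomics route to this triage problem: given
sample-by-protein log2 abundance matrices from data-independent-acquisition
mass spectrometry, it (i) simulates realistic cohorts for testing, (ii)
normalizes against a discovery cohort, (iii) selects a small fixed-size
protein panel by a genetic algorithm, (iv) trains a manifold-regularized
neural classifier on that panel, (v) reports diagnostic performance with
Wilson intervals and prevalence re-projection, and (vi) counts
differentially expressed proteins between histological groups.

Histotypes are mapped to the binary outcome deterministically: N, MNG, FA,
L and HCA are benign; FTC, PTC, HCC and fvPTC are malignant. Malignant is
the positive class in every reported metric, and ties in the classifier's
output are broken toward malignant — the clinically conservative direction.

## The synthetic cohort: a stated world

`generate_cohort()` emulates the features of DIA tissue proteomics the
downstream stages rely on:

* **Pooled abundance.** Per-protein mean log2 intensities are drawn from a
  two-half-normal distribution fitted through three quartile anchors, with
  default target observed quartiles 18.0 / 19.0 / 20.3 — the shape of the
  discovery profile the defaults restate. A half-normal on each side of the
  median is the simplest distribution that honors all three quartiles of a
  right-skewed profile.
* **Missing-not-at-random censoring.** Each cell goes missing with
  probability `plogis(steepness * (threshold - x))`: missingness rises as
  abundance falls below a detection threshold. The threshold is calibrated
  by root finding so the expected overall missing fraction equals the
  target (default 0.51). Because censoring removes the low tail, the
  latent anchors are then re-calibrated iteratively (with expected survival
  weights, so the loop is deterministic given the draws) until the
  *observed* quartiles match the targets. Default steepness is 2 per log2
  unit, giving a detection transition roughly two log2 units wide, a
  realistic width for label-free data.
* **Planted signal.** `n_informative` proteins are shifted by exactly
  `effect_size` log2 units in malignant nodules. Informative proteins are
  drawn from the upper abundance range (mean-distribution quantiles
  0.70–0.995): panel-grade features sit above the median abundance and
  carry little missingness, and a strongly down-shifted low-abundance
  feature would be invisible under MNAR censoring. By default all planted
  shifts are upward in malignant tissue (`effect_direction = "mixed"`
  alternates signs).
* **Variance components.** One knob, `noise_sd` (default 1 log2 unit),
  sets both the inter-nodule biological scatter and the per-replicate
  measurement noise; replicates are resamples of the nodule mean.

What the generator does **not** emulate: batch effects (the study design
randomizes them away), peptide-level structure, correlated protein modules,
or histotype-specific effect sizes beyond the benign/malignant contrast. A
green end-to-end test therefore establishes that the pipeline recovers a
planted, independent, Gaussian signal under MNAR censoring — not that it
reproduces the published cohort results, which depend on real data.

`split_cohort()` partitions at the nodule level (replicates never straddle
splits), stratified, with largest-remainder allocation so that 579 samples
split 2/3 : 1/3 into exactly 386 + 193 and 0.8 : 0.2 into 463 + 116.

## Preprocessing

Missing values are imputed with `ceiling(D_min)`, the ceiling of the global
observed minimum of the **discovery** matrix — the rationale being that
most missingness is censoring below the detection limit, so a low constant
is less wrong than mean-like imputation. Each feature is then z-transformed
with the discovery-set mean and standard deviation; the same constants are
applied unchanged to test cohorts (`apply_normalizer()` never re-estimates).
Choices the source leaves open, decided here:

* standard deviation uses the unbiased (n−1) denominator;
* features with ≥ 90% missing values are dropped before modeling
  (configurable cutoff), and zero-variance features are excluded with a
  warning;
* technical replicates are averaged on observed values **before**
  imputation — averaging imputed constants would bias replicate means —
  and the imputation constant itself is the global observed minimum of the
  discovery matrix as supplied (replicate averaging, when wanted, is the
  caller's prior step);
* replicate QC reports the coefficient of variation of log2 intensities
  (sd/mean per protein within a replicate group) and pairwise Spearman
  correlations on commonly observed proteins.

## Panel selection

Stage 1 screens features: proteins differentially expressed between benign
and malignant (Welch's t-test on observed values, BH adjustment; default
screen thresholds fold change > 2 and adjusted p < 0.05, more permissive
than the fold-change-4 DEP rule because screening is meant to be
inclusive), unioned with an optional user-supplied whitelist standing in
for literature/database curation, then filtered to missing rate < 0.35.

Stage 2 runs a genetic algorithm over combinations of exactly K proteins
(default 19; encoding as a fixed-size index set enforces the panel-size cap
by construction). Fitness is the mean 3-fold cross-validated accuracy of a
compact two-hidden-layer perceptron trained with plain cross-entropy on
dataset A (2/3 of discovery); a light classifier is used here because the
GA evaluates thousands of candidates. All fitness evaluations share one
seed-derived fold split and are cached, so fitness is a deterministic
function of the candidate and elitism makes the best-fitness trajectory
monotone. Dataset B (the remaining 1/3) is consulted exactly once per
finalist: the distinct top-fitness candidates of the final population
(default 10) are ranked by dataset-B accuracy and the best is reported —
dataset B never influences the evolutionary search. Default budget:
population 60, 40 generations, crossover 0.7, mutation 0.2, elitism 2 —
chosen for desk-scale runtime.

**Known limitation — selection is not identifiability.** When the planted
signal is strong enough that a subset of the informative features already
saturates cross-validated accuracy, panels differing in a few features tie
(or reorder by noise) in fitness, and no search strategy can prefer the
"complete" informative panel. We observed panels of 14 informative + 5
decoy features beating the all-informative panel's fitness in a saturated
regime. Panel *recovery* is therefore only a meaningful benchmark in a
sensitivity regime where each feature carries visible marginal accuracy;
the recovery tests are designed accordingly. This mirrors the biological
reading that a panel functions as a whole rather than as a list of
individually necessary markers.

## The DMT classifier

The network is a multilayer perceptron in two parts: a feature-extraction
sub-model (default 19 → 64 → 32 → latent 8, ReLU hidden layers, linear
latent) and a classification head (latent → 2, softmax). The total loss is

$$L = L_{DMT} + \alpha_1 L_e + \alpha_2 L_r$$

* $L_{DMT}$, the cross-layer two-way divergence, constrains pairwise
  sample similarities in input space ($P$) and latent space ($Q$) to
  agree: $\sum_{i \ne j} P_{ij}\log\frac{P_{ij}}{Q_{ij}} +
  (1-P_{ij})\log\frac{1-P_{ij}}{1-Q_{ij}}$. Similarities come from a
  Student-t kernel of Euclidean distances,
  $\kappa(D,\nu) = \frac{\Gamma(\frac{\nu+1}{2})}{\sqrt{\nu\pi}\,
  \Gamma(\frac{\nu}{2})}(1 + D^2/\nu)^{-\frac{\nu+1}{2}}$, squared and
  scaled by $2\pi$ (which keeps the similarity of coincident points below 1
  for every $\nu$), then symmetrized by $S(A) = A + A^T - 2A \circ A^T$.
  Degrees of freedom: $\nu^X = 100$ in input space (near-Gaussian),
  $\nu^Z = 1$ in the latent space (heavy-tailed, the standard t).
* $L_e$ is a class-weighted cross-entropy: the benign term is weighted
  $\beta = 1.6$ and the malignant term $2-\beta$, up-weighting benign
  errors to push specificity in an imbalanced cohort.
* $L_r = \lVert W \rVert_2^2$ sums squared weights (biases excluded, the
  common convention).

Defaults are the stated regime: $\alpha_1 = 10^3$, $\alpha_2 = 50$,
$\beta = 1.6$, learning rate $2\times10^{-2}$, batch size 256, 100 epochs.
$P$ and $Q$ are recomputed per minibatch, keeping the $O(N^2)$ terms
tractable and matching the stated batch regime. Similarities and predicted
probabilities are clamped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 10^{-6}$) because both divergences blow up at exact 0/1.

**Optimizer.** The loss is optimized with Adam rather than plain SGD. This
is a deliberate deviation: with $\alpha_2 = 50$ on a raw sum-of-squares
penalty, a plain SGD step at learning rate $2\times10^{-2}$ maps each
weight $w \mapsto w - 2w = -w$ from the decay term alone — divergent by
construction. Adam's per-parameter normalization makes the stated learning
rate meaningful at the stated loss weights; no source statement contradicts
the choice, since no optimizer is named. Gradients are analytic
(hand-derived backpropagation through the kernel, symmetrization and clamp)
and are verified against central finite differences to $10^{-4}$ relative
error in the test suite.

Training runs stratified 5-fold cross-validation, scores each fold model by
validation AUC (malignant probability as the ranking score), and returns
the best fold model with all fold AUCs — hyperparameters are fixed, only
the model is selected, resolving an ambiguity in the source description.
Prediction returns $\hat y^0$ (malignant), $\hat y^1$ (benign),
`score` $= \hat y^1$ (score > 0.5 reads benign), and the label rule
$P = 1$ iff $\hat y^0 < \hat y^1$: an exact tie is malignant.

## Evaluation

Sensitivity, specificity, PPV, NPV and accuracy are computed from the
confusion table (malignant positive) with 95% Wilson score intervals —
the uncorrected score interval, without continuity correction, as the
variant is not specified in the source's reference; endpoints at k = 0 and
k = n are snapped to exactly 0 and 1. Undefined metrics (zero denominator)
are reported as `NA`, never 0. AUC uses the rank (Mann–Whitney)
formulation with tie correction, avoiding interpolation choices.
`prevalence_adjusted()` re-projects PPV/NPV to an assumed prevalence by
Bayes' rule — at the printed prospective operating point (sensitivity 92%,
specificity 71%) and 30% prevalence the NPV is 95.4%, rounding to the
printed 95%. Stratified accuracy tables optionally merge Hürthle-cell
strata into their follicular counterparts (HCA→FA, HCC→FTC).

## Differential expression

`pairwise_dep()` uses Welch's t-test on observed (never imputed) log2
values — testing imputed constants would fabricate signal — requiring at
least 3 observations per group per protein, BH adjustment across proteins
within a comparison, and the threshold fold change > 4 (i.e.
$|\Delta\log_2| > 2$) with adjusted p < 0.01, applied after adjustment.
`anova_across_groups()` is the classical equal-variance one-way F-test per
protein. With two groups it reduces exactly to the squared pooled t-test,
which the suite asserts.

## Numerical choices, determinism, limitations

* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical config + seed reproduces results
  bit-for-bit in single-threaded R.
* The detection-threshold calibration solves a monotone 1-D root-finding
  problem; an unreachable missing-fraction target raises a calibration
  error rather than silently clipping.
* Tests scale the heavy pieces down (small networks, 15–25 epochs, GA
  budgets of minutes) so the default suite runs in a few minutes; the
  end-to-end acceptance experiment (600 samples, 200 proteins, 51%
  missingness) runs the default GA budget and finishes in about a minute
  because the default screen already concentrates the pool.
* Validation AUC saturates at exactly 1.0 for planted effects ≥ 2 log2
  units at the test sample sizes; monotonicity of AUC in effect size is
  therefore asserted strictly only below the ceiling.
* The published headline numbers (discovery accuracy 91%, AUC 0.93–0.95)
  were measured on real cohorts and are not reproduction targets of the
  synthetic world.
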