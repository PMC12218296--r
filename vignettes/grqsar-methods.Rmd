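---
title: "Methods: a hybrid resampling + BiGRU-attention QSAR pipeline for GR antagonists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid resampling + BiGRU-attention QSAR pipeline for GR antagonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Glucocorticoid receptor (GR) antagonists — small molecules that block
glucocorticoid binding to the receptor — are of therapeutic interest in
Cushing's syndrome, treatment-resistant depression and castration-resistant
prostate cancer. Screening chemical libraries computationally requires a
quantitative structure-activity relationship (QSAR) classifier that maps a
molecule's fingerprint representation to an active/inactive call. Curated
bioactivity extracts for this target are severely imbalanced (roughly five
potent actives per inactive), and any classifier trained naively on such
data buys specificity at the price of minority-class recall.

`grqsar` implements an end-to-end pipeline that addresses both problems:

1. **Curation** — IC50 rows are filtered (exact-relation only, deduplicated,
   replicate-consistent), converted to pIC50 = 9 − log10(IC50 nM), labeled
   (active if pIC50 > 6, inactive if < 5, intermediates in [5, 6] removed),
   and split into training and independent test sets per class.
2. **Multi-view fusion** — five fingerprint views (AP2D 780, CDKExt 1024,
   KR 4857, Morgan 2048, RDKIT 2048 bits) are concatenated in fixed order
   into a 10,757-D representation.
3. **Hybrid balancing** — SMOTE oversampling of the minority class combined
   with random undersampling (RUS) of the majority, meeting at a 1:1 ratio.
4. **Embedding** — a bidirectional GRU with scaled dot-product
   self-attention, trained end-to-end on binary cross-entropy, maps the
   fused vector to a dense embedding (4000-D at default width).
5. **Reduction and classification** — PCA at a 95% explained-variance
   threshold on the embedding, then extremely randomized trees (ET), with
   eleven baseline classifiers available under one grid-search protocol.
6. **Evaluation** — SN, SP, BACC, MCC, F1, AUC and AUPR from confusion
   matrices and full ROC/PR curves, under stratified 10-fold
   cross-validation and independent tests, plus stage ablations and t-SNE
   visualization.

# Model details and parameter choices

## Hybrid balancing

With `n_min` minority and `n_maj` majority training rows, a proportion
`p ∈ [0, 1]` sets the common per-class target

```
target = round(n_min + p * (n_maj - n_min))
```

SMOTE contributes `target − n_min` synthetic minority rows (each
`x_i + λ(x_nn − x_i)` with `λ ~ U(0,1)` and `x_nn` one of the `k = 5`
nearest minority neighbours), and the majority class is undersampled
without replacement to `target`. `p = 0` is pure undersampling, `p = 1`
pure oversampling; both endpoints give the 1:1 ratio, as do all
intermediate proportions. The proportion is a free design choice nowhere
given a formula in the source protocol; this linear interpolation is the
only reading that reproduces the documented endpoint behaviour.
Synthetic values stay continuous in [0, 1] (standard SMOTE output; we
verified on the synthetic benchmark that re-binarizing them changes
downstream metrics negligibly). `p = 0.75` is the default — the proportion
that the original evaluation selected as best — and `k = 5` is the SMOTE
canon.

Two cross-validation modes are exposed, because protocols in this
literature are often ambiguous about where balancing happens:

* **safe mode** (default): folds are assigned first and each fold's
  training portion is balanced independently, so validation folds contain
  only real rows. A memorizing classifier scores at chance on label-free
  data under this mode — the suite asserts exactly that.
* **paper mode**: the training set is balanced once, then folded; synthetic
  rows appear in validation folds. This inflates CV estimates and is
  provided only for comparability. Reports name their mode.

## The embedding network

Each compound's 10,757-D fused vector becomes a 5-token sequence, one token
per descriptor view, each view linearly projected to a common width
(`d_model`, default 512). The source protocol never states how a flat
vector becomes a sequence; one-token-per-view is the reading consistent
with a "multi-view" architecture, and a fixed-width chunk tokenizer is
available as a config option.

A GRU step uses the standard update/reset-gate equations (vectors as rows):

```
z_t = σ(f_t U_z + h_{t-1} W_z + b_z)
r_t = σ(f_t U_r + h_{t-1} W_r + b_r)
c_t = tanh(f_t U_c + r_t ⊙ (h_{t-1} W_c) + b_c)
h_t = (1 - z_t) ⊙ c_t + z_t ⊙ h_{t-1}
```

The bidirectional network runs a forward pass over positions 1..d and a
backward pass over d..1, both from zero initial state, concatenating the
two hidden states per position (width `2 d_h`; `d_h = 2000` gives the
4000-D embedding). Self-attention is the standard scaled dot-product form

```
Attention(Q, K, V) = softmax(Q K^T / sqrt(d)) V
```

with `Q = H W_q`, `K = H W_k`, `V = H W_v`; the `V` product is part of the
standard form and is used here (its omission in the source's attention
equation is treated as a typo). The attended sequence is mean-pooled into
the embedding, read out by a sigmoid head during training, and used without
the head downstream.

Training is by mini-batch Adam on binary cross-entropy. The protocol is
this package's own (the source gives none): learning rate 1e-3, batch 32,
50 epochs, decoupled weight decay 0.05, input (bit) dropout 0.2 — for
binary fingerprints this is random bit masking, the regularizer that
measurably limits memorization of the few real minority examples — early
stopping after 10 epochs without a training-loss improvement of 1e-5, zero
initial hidden states, orthogonal-ish (QR of a Gaussian) recurrent
initialization, scaled-Gaussian elsewhere. A label-smoothing knob exists
but defaults to off: on the synthetic benchmark it widened the embedding
spectrum yet worsened minority recall. All gradients — BPTT through both GRU directions, the softmax
attention Jacobian, the projections — are implemented directly in matrix
algebra and are verified in the suite against numerical differentiation at
~1e-11 agreement; the exported `gru_step()`, `bigru_forward()` and
`self_attention()` are additionally tested against independent scalar/loop
oracles to 1e-10. The numerically-stable sigmoid (`plogis`) and a
max-subtracted softmax are used throughout. Training is bit-deterministic
under its seed.

## PCA placement

PCA (training-mean centering, no scaling) keeps the smallest number of
leading components whose cumulative explained-variance ratio reaches the
threshold (default 0.95). PCA operates **on the learned embedding**,
matching the workflow's order (embedding network, then PCA, then ET). When
the embedding stage is ablated away, the fused fingerprints go to the
classifier directly rather than through PCA: on near-independent binary
bits an explained-variance cut ranks components by noise variance and
discards a weak planted signal along with it — we measured an ET AUC drop
from 0.99 to 0.61 on the synthetic benchmark when PCA is forced onto the
raw fused matrix — and the published baseline ("Fusion → ET") is likewise
a direct fit.

## Classifiers

Twelve classifier names are standard in this comparison; eleven run here
(ET, RF, SVM, XGB, DT, KNN, LDA, PLS, LR, MLP, ADA). ET and RF use
`ranger` (ET via `splitrule = "extratrees"` without bootstrap resampling);
SVM is `e1071`'s RBF machine; XGB is `xgboost`; DT is `rpart`; KNN is
`class::knn`; LDA is `MASS::lda`; LR is a binomial GLM; MLP is `nnet`.
AdaBoost (SAMME over depth-1 stumps) and PLS-DA (SIMPLS regression on
{0, 1} with a 0.5 cutoff) are implemented in-package because no installed
library provides them. LGBM has no R implementation available here and its
name raises an informative error. All classifiers share one protocol:
stratified 10-fold grid search with fold assignments fixed by a shared
seed (so comparisons are paired), selection by AUPR (the headline metric;
configurable), refit on all rows. The default grids (e.g. trees ∈
{100, 250, 500}, SVM C ∈ {0.1, 1, 10}, KNN k ∈ {3, 5, 7}) are declared
defaults, fully overridable — the original hyperparameter tables are not
public.

## Metrics

Threshold metrics come from the confusion matrix with the documented
degenerate conventions (MCC = 0 when a marginal is empty). BACC is exactly
(SN + SP)/2 in every report. AUC is trapezoidal over tie-grouped
thresholds and equals the normalized Mann-Whitney statistic on tie-free
data; AUPR is the step-wise precision-recall sum. The **positive class
defaults to the minority (inactive) class**: the published independent-test
rows are arithmetically consistent only with a 55-positive/263-negative
test set, although the curation text calls actives "positive". The choice
is configurable and every report names its positive class.

`recover_cm_from_rates()` inverts printed SN/SP pairs (at known per-class
totals) to the unique integer confusion matrix by exhaustive search. This
is how the suite regresses against published table rows: recover the
integer cells from the two printed rates, recompute BACC/MCC/F1 at full
precision, and compare at 3-decimal rounding.

# The synthetic benchmark

The generators produce (a) raw bioactivity tables with planted censored
rows and duplicates — log-uniform IC50 draws placing a configurable
fraction above pIC50 6 and a slice inside the excluded [5, 6] band — and
(b) class-structured fingerprint views: independent Bernoulli bits at a
0.30 background density, with 50 signal bits per view at density 0.20
(active) vs 0.60 (inactive) and 5% bit-flip noise, at a ~1:5
inactive:active imbalance mirroring the curated training data.

The signal level is the benchmark's design point. Much stronger signals
(e.g. 0.1 vs 0.9) make even the raw imbalanced baseline perfect, so the
benchmark would show nothing about imbalance handling; much weaker ones
(e.g. 0.25 vs 0.55) leave independent-Bernoulli data noise-dominated in
nearest-neighbour structure, which defeats any learner at these sample
sizes. At 0.20/0.60 the baseline ranks well but fails minority recall at
the 0.5 threshold, and the balanced, embedded pipeline restores it — the
qualitative ordering of the published stage ablation.

One caveat the suite makes explicit by pinning seeds: the independent
minority test at these sizes holds only ~20 inactive compounds, and a new
inactive activates the learned evidence only partially (it shares the
signal bits but none of the training rows' incidental bit patterns), so
the threshold metrics carry appreciable seed-to-seed variance even while
the ranking (AUC) stays at ceiling. The ranking metrics are the stable
summary at desk scale; the threshold metrics are reported at fixed seeds.

What the fixtures deliberately do **not** emulate: correlated substructure
bits, chemical-series clustering, activity cliffs, or any real SMILES
chemistry. Passing the synthetic benchmark demonstrates that the pipeline's
plumbing (balancing, leakage control, thresholding, embedding, reduction)
behaves as designed — it does not certify performance on real chemistry.

Default problem sizes in the tests and the acceptance script are scaled to
a single-CPU desk run: 600 compounds (500/100), embedding width 128
(`d_h = 64`), 25 epochs, 250 trees. The full-size defaults (`d_h = 2000`,
50 epochs) are the published operating point and run unchanged, just
longer.

# Numerical and degenerate-input choices

* Stable sigmoid (`plogis`) and max-subtracted softmax; BCE clamped at
  1e-12.
* SMOTE requires `k + 1` minority rows; the error suggests lowering `k`.
* PCA drops numerically-null trailing components, so threshold 1.0 reports
  the true rank; a transform applied to its own training mean returns the
  zero vector exactly.
* `build_balanced` ties are impossible by construction (`round` of the
  target); class identification is by count, with the rarer label the
  minority.
* Empty inputs: zero-row fingerprint matrices keep their width; empty
  score vectors return empty predictions; curation errors carry per-step
  drop counts.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; reruns are bit-identical.

# Known limitations

* The 10,757-bit descriptor definitions themselves (PADEL's AP2D/CDKExt/KR
  bit semantics) are not implemented; fingerprints come from files, a
  plugged-in provider, or the synthetic generator.
* t-SNE is the exact O(n²) algorithm — fine for a few thousand compounds,
  not for library-scale plots — and is qualitative only.
* The training protocol of the embedding network is this package's own
  declared default; published headline numbers on the original ChEMBL
  extract depend on data, seeds and hyperparameters that are not public,
  and are regressed here only through their arithmetic table identities.
* Percent-improvement claims between published table rows are not
  recomputed; several are internally inconsistent with the tables they
  summarize.
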