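---
title: "Multi-modal adversarial domain adaptation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal adversarial domain adaptation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structural MRI and FDG-PET view Alzheimer's disease from complementary
angles — atrophy on one side, hypometabolism on the other — and
classifiers that fuse both modalities outperform single-modality models.
But neuroimaging cohorts acquired on different scanners or protocols
differ systematically in intensity statistics ("domain shift"), so a
model trained on one cohort (the labelled *source* domain) degrades on
another (the unlabelled *target* domain). This package implements a
multi-modal deep domain-adaptation classifier that addresses both
problems at once: attention-based fusion of the two modalities, and
adversarial alignment of the source and target feature distributions so
the source-trained classifier transfers without target labels.

## Model

**Encoders.** Each modality in each domain has its own 3D CNN branch
(four parallel encoders in total). The full-size branch stacks nine
valid 3x3x3 convolutions (stride 1, no padding) with channel counts
8, 8, 16, 16, 32, 32, 64, 64, 128, each followed by batch normalisation
and leaky ReLU (slope 0.01), with kernel-2 stride-2 max pooling after
layers 2, 4, 6 and 8. On a 113 x 137 x 113 volume the spatial grid
shrinks to 1 x 2 x 1 with 128 channels; `shape_trace()` computes this
arithmetic exactly and `encode()` is tested against it.

**Fusion.** The two modality feature maps are concatenated along
channels and reshaped to a sequence of `L = D*H*W` positions with
`E = 2C` features, then passed through one application of multi-head
scaled dot-product attention: per head, softmax(QK'/sqrt(d_k))V with
learned square projections and an output mix. The attended sequence is
reduced over `L` by arithmetic mean, giving a fused vector of dimension
`d = E` — 256 at full size. A raw flattening of the (L = 2, E = 256)
sequence would give 512, inconsistent with the stated d = 256; the mean
reduction is the only reading consistent with the encoder arithmetic,
and `reduce = "flatten"` is retained as a sensitivity option. Head
counts of 4 (AD vs CN and MCI vs CN), 8 (AD vs MCI) and 16
(pMCI vs sMCI) are the per-task defaults; `head_sweep()` re-runs the
pipeline across counts.

**Losses.** Five components sum, unweighted, into the training
objective (per-component weight hooks exist for ablations):

* *Correlation* (per domain): with the Gaussian kernel
  `K(x,y) = exp(-||x-y||^2 / (2 sigma^2))`, sigma = 1, the loss is
  `-sum_ij K(x_i, y_j) log(K(x_i, y_j) + 1e-6)` over the cross-modal
  Gram matrix of flattened encoder outputs. Note a structural property,
  implemented as printed rather than altered: for a single pair,
  `-K log(K + eps)` vanishes at both K → 0 and K → 1 and peaks near
  K = 1/e, so the term rewards either tight agreement or strong
  separation of the modalities; it does not strictly force alignment.
  At realistic feature dimensions (hundreds+) the kernel with sigma = 1
  is numerically ~0 and the term is inert; its closed forms are
  nevertheless exact and tested at small dimension.
* *Consistency*: mean squared difference between the source and target
  fused vectors of the current step.
* *Classification*: mean cross-entropy of the source classifier
  (three fully connected layers, 128/64/2 units, dropout 0.5 after the
  first two).
* *Domain*: mean cross-entropy of a structurally identical domain
  discriminator fed the concatenated source and target fused vectors
  (source = 1), behind a gradient-reversal layer — identity forward,
  gradient scaled by −0.1 backward — so discriminator training pushes
  the encoders toward domain-indistinguishable features.

**Training protocol.** Adam (0.9 / 0.999), batch size 1. Phase 1
trains the source branch on `L_cor^S + L_cls`. The trained source
weights (including batch-norm running statistics) are then copied to
the target branch, and phase 2 trains both branches jointly on the full
objective; target labels are never read, which is verified bit-for-bit
in the test-suite by scrambling them. The full-size schedule is
150 + 50 epochs at learning rate 9e-7.

**Ablation variants.** `SDA` (MRI only, classifier on the flattened
encoder output), `MSDA` (both modalities, plain concatenation, no
attention), `M3HF` (attention fusion, no correlation loss), `MMDDA`
(full model). Dropping the correlation-loss weight reduces `MMDDA` to
`M3HF` exactly, which the tests assert at the parameter level.

## Desk-scale configuration

All training-dependent tests run a reduced preset, `desk_config()`:
32^3 volumes, 8 subjects per class and domain, a three-layer encoder
(channels 4, 8, 8; pooling after every layer), 4 heads, 40 + 5 epochs
at rates 1e-3 / 1e-4. Three of these choices deserve justification.

* *Encoder depth.* The toy encoder ends at a 2^3 spatial grid (L = 8,
  E = 16), reproducing the full-size geometry, where the attended
  sequence is short (L = 2) and the mean reduction loses little. A
  shallower desk encoder that stops at a 6^3 grid makes L = 216, and
  averaging 216 positions into 16 numbers discards nearly all spatial
  information — a scaling artifact that cripples the fused variants
  relative to the flatten-everything baselines and misrepresents the
  full-size model.
* *Phase-2 budget and rate.* At full size the tiny shared learning rate
  makes phase 2 a near-infinitesimal alignment of an already-trained
  source model. Re-running phase 2 at the desk phase-1 rate instead
  re-trains the network and destroys the source solution, for an
  identifiable reason: the consistency loss compares the current source
  sample with a cycling target sample, so cross-class pairs are pulled
  together and class structure erodes if the joint phase runs long. The
  desk preset therefore uses a 10x smaller phase-2 rate and stops at
  the plateau of the joint losses (about 5 desk-scale epochs, visible
  in the recorded loss history: the consistency term does most of its
  work by then while the source classification loss starts to rise).
  This unpaired-consistency pathology is a property of the method as
  specified (no pairing rule exists), documented here rather than
  patched.
* *Learning rate.* 1e-3 is the conventional Adam rate for a network of
  this size; the full-size 9e-7 would not move a desk-scale model
  perceptibly within the epoch budget.

## What the synthetic generator emulates

Subjects are smooth ellipsoidal volumes carrying four Gaussian blobs at
fixed canonical positions. Blob amplitudes differ in mean by
`class_effect` between classes with alternating sign (an
atrophy/hypometabolism caricature); per-subject amplitude fluctuations
split into a component shared between MRI and PET (weight
`modality_correlation`) and modality-private parts, so the two channels
carry correlated but non-identical class signal — giving both the
fusion module and the cross-modal correlation loss real structure.
Target-domain volumes are additionally blurred (`shift_smooth`
voxels), intensity-scaled (`shift_gain`) and modulated by a seeded
degree-2 polynomial bias field, then voxel noise is added. The
defaults (class effect 1, correlation 0.7, gain 1.5, blur 1, noise 0.1)
make the class signal learnable by small CNNs, the domain gap trivially
detectable from mean intensity (a one-threshold domain classifier
exceeds 0.9 accuracy, so the adaptation task is non-vacuous), and the
target transfer initially mis-calibrated for a source-trained model.

What it does **not** emulate: brain anatomy, scanner physics,
registration error, class imbalance, longitudinal structure, or any of
the preprocessing chain real cohorts pass through. Passing tests show
the machinery — encoders, fusion, losses, adversarial loop, metrics —
behaves as specified on data with known ground truth; they say nothing
about clinical performance.

## Numerical choices and degenerate inputs

* All backward passes are hand-derived and verified against central
  finite differences (encoders end to end, attention, losses, heads).
* Batch normalisation with batch size 1 normalises over the spatial
  axes per channel; running statistics (momentum 0.1, unbiased
  variance) serve eval-mode inference, so prediction is deterministic
  and per-sample. Conv biases are redundant under batch norm (their
  gradient is exactly zero in training mode) but retained for
  configuration fidelity.
* Softmax is computed with row-max subtraction; the correlation loss
  guards its logarithm with epsilon = 1e-6; non-finite losses abort
  training with the offending component named.
* Degenerate metric denominators (no positives / no negatives) yield
  `NA`, never a silent 0; AUC requires both classes.
* The train/validation/test split assigns round(0.30 n) to test, then
  round(0.30 (n − test)) to validation, stratified by label with
  largest-remainder allocation so the global counts are exact
  (n = 100 → 30 / 21 / 49).
* Seeds: dataset generation, weight initialisation, epoch shuffling and
  dropout all derive from configured seeds through an isolated RNG
  scope (`withr::with_seed`), so identical configurations reproduce
  identical arrays byte for byte.

## Problem sizes used by the checks

The test-suite trains only desk-scale models: 32^3 (and smaller)
volumes, 4-16 subjects per class, two-to-three-layer encoders, at most
40 + 5 epochs; the adaptation comparison averages five seeded
replicates of MMDDA vs SDA. The one full-size computation is a single
forward pass of the full-size encoder + fusion path on a
113 x 137 x 113 volume pair, which verifies the 256-dimensional fused
vector and is also what `scripts/acceptance.R` recomputes.

## Known limitations

* Binary tasks only; multi-class heads are out of scope.
* The correlation loss is inert at large feature dimension with
  sigma = 1 (see above); choosing a dimension-aware bandwidth would
  change the published objective and is deliberately not done.
* No early stopping or checkpoint selection: fixed epochs, final-epoch
  checkpoint; the validation split exists for configuration selection
  (e.g. head counts) only.
* Batch-norm statistics of the target branch update during phase 2
  (not frozen); this is config-exposed behaviour, chosen because the
  target branch is the one evaluated.
* Pure-R + Rcpp training is CPU-bound; the full-size configuration is
  practical for forward passes, not for full training runs.
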