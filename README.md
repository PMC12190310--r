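# mmdda

Multi-modal adversarial domain adaptation for neuroimaging
classification in R.

`mmdda` trains a binary Alzheimer's-stage classifier from paired,
co-registered structural MRI and FDG-PET volumes on a **labelled source
cohort** and transfers it to an **unlabelled target cohort** (e.g. two
ADNI waves acquired on different scanners). It is aimed at researchers
who want a self-contained, inspectable implementation of adversarial
multi-modal domain adaptation — every layer, loss and gradient is in
this package (3D conv/pool kernels in C++ via Rcpp, the rest in R) —
plus a seeded synthetic paired-volume generator so the whole pipeline
runs and is tested without access-restricted clinical data.

## The model

Four parallel 3D CNN encoders (MRI/PET × source/target; nine valid
3×3×3 conv layers, channels 8,8,16,16,32,32,64,64,128, BN + leaky ReLU,
stride-2 max pooling after layers 2/4/6/8) produce per-modality feature
maps F ∈ ℝ^{B×C×D×H×W}. Per domain, the two maps are concatenated
along channels, reshaped to a sequence (L = D·H·W, E = 2C) and fused by
one application of multi-head attention,

    head_i = softmax(Q_i K_i' / √d_k) V_i,   d_k = E/h,

then reduced over L to a fused vector F ∈ ℝ^d (d = 256 at full size).
Training minimises the unweighted sum

    L_total = L_cor^S + L_cor^T + L_mse + L_cls + L_dom

where L_cor is a Gaussian-kernel cross-modal correlation loss
(−Σ_ij K(x_i,y_j)·log(K(x_i,y_j)+10⁻⁶), σ = 1), L_mse the
source–target fused-feature consistency, L_cls the source
classification cross-entropy, and L_dom the cross-entropy of a domain
discriminator that reaches the encoders through a gradient-reversal
layer (forward identity, backward × −0.1). Phase 1 (150 epochs at full
size) trains the source branch on L_cor^S + L_cls; the weights are then
shared with the target branch and phase 2 (50 epochs) trains everything
jointly — without ever reading target labels. Ablation variants `SDA`
(MRI only), `MSDA` (concatenation fusion), `M3HF` (attention, no
correlation loss) and `MMDDA` (full model) share the pipeline.

## Worked example

Desk-scale end-to-end run on synthetic data (32³ volumes, 8 subjects
per class and domain, intensity-scaled + blurred + bias-field-shifted
target domain):

```r
library(mmdda)

ds   <- generate_dataset(synthetic_config(seed = 2))
dom  <- vapply(ds, `[[`, "", "domain")
data <- list(source = ds[dom == "source"], target = ds[dom == "target"])

describe_dataset(ds)
#>   domain label n  mean_mri  mean_pet
#> 1 source     0 8 0.4495643 0.4489523
#> 2 source     1 8 0.4453228 0.4454807
#> 3 target     0 8 0.6437545 0.6587670
#> 4 target     1 8 0.6646079 0.6838739

model <- fit_mmdda(data, desk_config(seed = 2))   # ~35 s on one CPU
evaluate_model(model, data$target, "target")
#> Metric report (n = 16)
#>   ACC 1.0000  SEN 1.0000  SPE 1.0000  AUC 1.0000  F1 1.0000
#>   TP 8  TN 8  FP 0  FN 0
```

The target-domain mean intensity sits ~1.5× above the source (the
injected scanner shift — a one-threshold domain classifier separates
the domains at >0.9 accuracy), yet the source-trained, phase-2-aligned
classifier recovers the held-out target labels. `run_variant()`
compares the ablation variants and `head_sweep()` re-trains across
attention head counts {1, 4, 8, 16}.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mmdda.R", package = "mmdda"))')
Rscript $CLI simulate    --config cfg.yaml --out runs/sim
Rscript $CLI train       --config cfg.yaml --manifest runs/sim/manifest.csv --out runs/fit
Rscript $CLI evaluate    --checkpoint runs/fit/checkpoint.rds \
                         --manifest runs/sim/manifest.csv \
                         --labels runs/sim/target_labels.csv --out runs/eval
Rscript $CLI ablate      --config cfg.yaml --out runs/ablation
Rscript $CLI sweep-heads --config cfg.yaml --heads 1,4,8,16 --out runs/sweep
```

Real data enter through a CSV manifest
(`subject_id,mri_path,pet_path,label,domain`) pointing at NIfTI volume
pairs on a common voxel grid; `make_split()` provides the stratified
70/30 train/test split with a 30% validation carve-out.

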