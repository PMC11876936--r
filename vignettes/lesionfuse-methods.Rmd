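---
title: "lesionfuse: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lesionfuse: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`lesionfuse` implements a multi-task framework for predicting a binary
per-study label (modelled on atrial-fibrillation status) from a 3-D
intensity volume with a lesion mask (modelled on diffusion-weighted MRI of
acute ischemic stroke). Two ideas are combined:

1. **Segmentation-guided attention.** A 3D U-Net-style segmentation branch
   learns a voxelwise lesion probability map. Its encoder ("subsampling")
   activations generate *prior attention* maps — the sigmoid-squashed
   channel mean at each scale — which multiplicatively modulate the
   matching scale of a parallel 3D CNN classification branch as
   `features * (1 + attention)`. The residual form means attention can
   emphasize a region but never extinguish it (or its gradients); a zero
   activation yields a neutral flat map of 0.5. The injection mechanism is
   a design choice of this package (the alternatives — additive or
   concatenative injection — are equally defensible; multiplicative
   modulation keeps the classification features in their original scale).
2. **Radiomics fusion.** Handcrafted radiomics features are extracted from
   the lesion region of interest (ROI) and passed through a light
   self-attention module: per-feature scores `a + g * z` (both learnable,
   zero-initialized so the weights start uniform) are softmax-normalized
   into simplex weights, and the weighted feature vector is concatenated
   with the CNN's 64-d semantic vector for a fusion MLP. The weights
   double as the feature-significance-ranking (FSR) signal.

Three softmax heads are trained: radiomics-only, CNN-only, and the
combined MLP. Their final layers are zero-initialized so an untrained
model outputs (0.5, 0.5) from every head.

### Losses and the two-stage regime

Segmentation uses the soft Dice loss
`1 - (2·Σ p·t + ε) / (Σ p + Σ t + ε)` with `ε = 1e-6`; classification uses
two-class cross-entropy (softmax heads, so "sparse categorical"
cross-entropy labels index the softmax directly). Training is two-staged:

* **Stage 1 (feature extraction):** loss = Dice loss + CNN-head
  cross-entropy, training both branch extractors and the CNN head. The
  segmentation term is the Dice *loss* (one minus the Dice coefficient):
  the composition "(1 − L_seg) + L_cnn" is only coherent when `L_seg` is
  read as the Dice coefficient, since minimizing one-minus-Dice-loss would
  reward bad segmentation.
* **Stage 2 (classification):** extractors frozen; loss = radiomics-head +
  combined-head cross-entropy, training the feature attention, the
  radiomics head and the fusion MLP. Semantic vectors are precomputed once
  per study without augmentation (with frozen extractors, augmentation
  would only inject label-independent noise). Radiomics features do not
  participate in stage 1.

The optimizer is Adam (β = 0.9/0.999) with the exponential schedule
`lr(t) = lr0 · 0.98^t`, decay applied per epoch and continuing across the
stage boundary; defaults are `lr0 = 1e-4` and 25 + 25 of 50 total epochs
with batch size 8. Per fold, the checkpoint with minimum validation loss
(the stage-appropriate composite) over all epochs of the current stage is
kept. Model selection, augmentation order and initialization all flow
through named seeds, so a fold run is a pure function of (cohort, fold
plan, config).

### Protocol

Patients are randomly partitioned into five folds (sizes differing by at
most 1); each fold's model trains on the other four. Feature
standardization (z-scaling) is fitted on the training folds only and
applied to validation/held-out data — the no-leakage contract is asserted
by the test suite. Held-out cohorts are scored by averaging the class-1
probabilities of the five fold models per head ("cross-fold ensembling").
Augmentation during stage 1 samples axis flips (p = 0.5 each) and
in-plane 90-degree rotations (uniform over 0–3 quarter turns), applied
identically to volume and mask; the identity transform has positive
probability, and inference never augments.

## Architecture details

The architecture sizes are this package's own (the two-branch structure
fixes only the topology). Defaults, chosen for single-CPU desk scale:

* A shared 2×2×2 average-pooling **stem** in front of both branches, so
  the three encoder scales run at half the input resolution. The stem is
  itself a subsampling layer; prior attention is generated and injected
  per scale exactly as above.
* Encoder: three levels of one 3×3×3 convolution + ReLU with 8/16/32
  channels (`base_channels` scales all three; 16/32/64 is one knob away),
  2×2×2 average pooling between levels.
* Decoder: nearest-neighbour upsampling with 1×1×1 refinement convolutions
  and *additive* encoder skips — full-resolution 3×3×3 decoder
  convolutions dominate CPU cost and are not needed for blob-shaped
  lesions.
* Segmentation head: a 1×1×1 convolution on the upsampled decoder output
  plus a small full-resolution refinement path (3×3×3 convolution on the
  raw input, 4 channels — the finest skip) so boundaries resolve at voxel
  level; the head's combination weights start at zero and its bias at −2,
  a sparse-lesion prior that makes the initial map uniformly low instead
  of 0.5.
* Classification branch: mirrors the encoder scales, global average
  pooling, a dense layer to the 64-d semantic vector, then the heads;
  fusion MLP is (64 + 36) → 64 → 2.

All forward/backward passes are hand-derived and verified against central
finite differences on every parameter group (tolerance 1e-4 relative); the
conv/pool/upsample kernels are C++ (im2col + BLAS GEMM) with the tensors
channel-last internally. The public tensor contracts remain channel-first.

## Preprocessing

Input volumes are min–max rescaled to [0, 1] per study (scale invariance
across acquisition/intensity jitter; a constant volume degenerates to
zeros with a warning), zero-padded *centred* into the canonical
(32, 256, 256) grid (offsets recorded, so padding is invertible; inputs
larger than canonical are an error — no cropping is defined), and
downsampled 4× in-plane to the (32, 64, 64) model input by block averaging
(exact, testable arithmetic rather than interpolation), the mask following
by majority vote with ties counted as foreground. Volumes already at the
model-input shape pass through directly. NIfTI metadata is round-tripped
untouched; no reorientation, skull stripping or bias correction is
performed.

## Radiomics

Six families are computed from their definitions inside the ROI (never
wrapped from another library), each with a brute-force oracle in the test
suite: first order (12), shape (6), GLCM (5), GLDM (4), GLSZM (4), NGTDM
(5) — 36 features in a fixed, documented order. Conventions that needed a
decision:

* **Discretization**: equal-width binning into `n_levels = 32` fixed bins
  (bin *count*, not bin width — the phantoms are scale-free after
  normalization); ROI minimum → level 1, right-closed top bin.
* **Neighbourhoods**: 26-connectivity at distance 1 everywhere; GLCM uses
  the 13 unique directions, per-direction normalized matrices averaged
  over directions with at least one in-ROI pair.
* **GLDM**: dependence is the raw count d of neighbours within
  `|Δlevel| ≤ α` (an isolated voxel has d = 0); emphasis weights use the
  group size d + 1 so small-dependence emphasis is defined at d = 0.
* **NGTDM**: `s_i = Σ |i − mean of in-ROI neighbours|` over voxels of
  level i that have at least one in-ROI neighbour; coarseness returns 1e6
  when its denominator is zero (a common implementation convention).
* **Shape**: surface area by face counting; elongation and flatness are
  the anisotropy ratios `sqrt(λ1/λ2)` and `sqrt(λ1/λ3)` of the ordered
  second-moment eigenvalues (≥ 1, larger = more anisotropic — the inverse
  of some libraries' convention, chosen so that a rod scores higher than a
  cube); each axis is augmented by the voxel's own extent variance
  `s²/12`, which keeps single-voxel and collinear masks finite and makes a
  single voxel exactly isotropic.
* **First order**: entropy on a 32-bin histogram; population-moment
  skewness/kurtosis, defined as 0 at zero variance.

## The phantom generator

Synthetic studies stand in for clinical volumes, which are unavailable by
design. A phantom is a brain-scale grid (default 32×64×64, the model-input
size) containing 1–2 ellipsoidal lesions (nominal radius 4–8 voxels,
volume-preserving elongation along a random in-plane axis) of elevated
base intensity 0.7 over a 0.1 background, plus additive Gaussian noise
(SD 0.05) and a per-study multiplicative intensity jitter (0.8–1.25)
emulating scanner scale variation. The class recipes differ in exactly the
properties the model should exploit:

* class 1 ("AF-like"): a voxel-wise alternating ±0.4 checkerboard inside
  the lesion — maximal neighbourhood gray-tone contrast (NGTDM/GLCM
  driven) — and elongation 2;
* class 0: low-pass-filtered Gaussian texture of matched nominal
  amplitude (smooth) and a near-spherical shape.

With noise off, the class-separating texture statistic has non-overlapping
supports, so labels are recoverable in principle; with the default noise
the classes remain strongly separable (deliberately: the end-to-end
recovery tests are about the *machinery*, not about clinical difficulty).
Metadata (sex, age, NIHSS, CHA2DS2-VASc) is sampled from plausible
stroke-cohort marginals, independent of the label by default, with an
option to enrich age and CHA2DS2-VASc in class 1 so the subgroup
machinery can be tested under both a null and an enriched regime.

What the phantoms do **not** emulate: anatomy (no atlas, no DWI physics,
no b-values), multi-channel acquisitions (supported but defaulting to one
channel, since the clinical channel inventory is not public), inter-rater
segmentation noise, or any realistic overlap between class distributions.
A passing recovery test therefore demonstrates that the pipeline can
learn, rank and localize a texture/shape signal end-to-end — not that it
would reach any particular clinical performance.

## Evaluation and interpretability

AUC is the Mann–Whitney statistic (ties counted ½); its 95% CI is a
stratified bootstrap percentile interval (2000 resamples by default,
seeded; resampling within class keeps both classes in every resample).
The operating point maximizes sensitivity + specificity over midpoints of
adjacent distinct scores, ties broken toward higher specificity, and is
chosen on the evaluated scores themselves (a fold-internal-cutoff mode is
available via the `cutoff` argument). Rates are percentages;
zero-denominator rates are `NA` markers. Subgroup reports stratify by
sex, age ≤ 70 / > 70, NIHSS ≤ 4 / > 4 and CHA2DS2-VASc ≤ 3 / > 3, marking
single-class strata not-evaluable.

Grad-CAM: channel weights are the global average of the gradient of the
target class logit with respect to the last modulated convolutional
activation of the classification branch; with global average pooling
directly above that layer the gradient is spatially constant and the
method reduces to classic CAM. Maps are ReLU-ed, trilinear-upsampled to
the model grid and min–max normalized; a constant map is returned as
all-zeros with a degenerate flag. FSR significance is defined as the
cohort mean of the attention-weight simplex rows — the attention weight
is the operative definition of "significance" in this package — reported
overall and per predicted class, on held-out studies by default.

## Desk-scale training choices and known limitations

The reduced configuration used by `synthetic_experiment()` (and the
acceptance script) is 32 training studies per class, fivefold CV, 3
stage-1 + 20 stage-2 epochs, batch 8, `lr0 = 1e-3` with the 0.98 decay,
8/16/32 channels, and a 20-per-class held-out cohort.
`fsr_experiment()` is the companion feature-recovery run: because the
default cohort's classes differ in texture *and* shape *and* marginal
intensity statistics (so many feature families are genuinely
discriminative), the question "does the attention gate surface the
neighbourhood-texture families?" is posed under `texture_only_params()` —
both classes are ±0.4 checkerboards with identical marginal distribution
and identical spherical shape, differing only in cell period (1 vs 4
voxels) — with one briefly-extracted fold and a long (200-epoch) stage 2
so the softmax gate actually sharpens (Adam moves the score parameters by
roughly lr per step, so a couple of hundred steps are needed before
weight ratios leave the near-uniform regime). The clinical-scale
defaults (`lf_config()`) keep 50 epochs at `lr0 = 1e-4`; the short
schedule uses a proportionally larger base rate, a standard compensation
when cutting the step count by an order of magnitude.

Two limitations are worth stating plainly:

* **Segmentation maturity.** The Dice term descends much more slowly than
  the classification terms: the overfit-capacity test drives it near zero
  in a few hundred steps, but the 4-epoch acceptance schedule (tens of
  steps) leaves the selected min-validation-loss checkpoint with a low
  Dice coefficient. The classification results do not depend on a mature
  segmentation (prior attention helps but the intensity contrast
  suffices), so the acceptance run reports the Dice it actually achieves
  rather than hiding it. A user who cares about the segmentation output
  should train the default 25 + 25 schedule.
* **Nearly-uniform attention weights.** With strongly separable phantoms
  the heads can classify before the attention gate sharpens much, so FSR
  differences over the 36 features are small in absolute terms; the
  *ranking* is still informative (the texture features that differ by
  class rise to the top), which is what the recovery test asserts.

## Reproducibility

Every stochastic step — phantom cohorts, fold assignment, initialization,
data order, augmentation, bootstrap — derives from explicit integer seeds,
and deterministic kernels are the only mode; re-running any fold or the
whole pipeline with the same inputs is bit-identical, which the test suite
asserts. Checkpoints embed a config hash and ensembling refuses mixed
hashes.
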