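---
title: "Dual-phase fusion segmentation: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-phase fusion segmentation: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hepatocellular carcinoma (HCC) appears hypointense against enhancing liver
parenchyma in the hepatobiliary phase (HBP) of gadoxetate-enhanced MRI, while
the portal-venous phase (PVP) carries complementary contrast. A single phase
is often ambiguous: other structures can be as dark as tumor in the HBP, and
cirrhotic parenchyma can blur the lesion boundary. `dfnseg` implements a
segmentation family that exploits both phases and, optionally, a rough
radiologist-drawn region of interest (ROI):

* **DCNN-F** — a single-phase encoder-decoder network applied to full-size
  HBP slices;
* **DFN-F** — a deep fusion network: one sub-network per phase, their score
  maps combined by a small fusion block, applied to full-size slices;
* **DFN-R** — the same fusion network trained and applied only inside a 3D
  ROI box built from three planar rectangles, with predictions pasted back
  into the full grid.

## Network architecture

The per-phase network follows the fully-convolutional/U-Net family. The
contracting path has six 3×3 conv blocks (conv + batch normalization +
ReLU), with a 2×2 stride-2 max pooling after every two blocks — three
pooling stages in total — and two 1×1 conv blocks at the bottleneck. The
expansive path has three deconv blocks, each an upsampling, a 2×2 conv, a
skip concatenation with the matching contracting feature map, and two 3×3
conv blocks. A 1×1 conv with a sigmoid produces a per-pixel tumor
probability (score map) the same size as the input, which therefore must be
divisible by 8.

Choices the architecture description leaves open, fixed here as defaults:

* **Channel schedule**: `base_channels` (default 32; 8 at desk scale) in the
  first block, doubled after each pooling stage, 8× at the bottleneck.
* **Head activation**: sigmoid, because the Dice loss consumes
  probabilities for a single foreground class.
* **Head bias**: initialized to −2 rather than 0. Tumor occupies a small
  fraction of a slice; starting from a sparse-foreground prior removes the
  early plateau in which the soft-Dice denominator is dominated by a
  half-gray prediction. This mattered more than any learning-rate choice in
  our desk-scale runs.
* **Fusion block**: elementwise **sum** of the two sub-network score maps
  (the fusion formula is an explicit elementwise sum; a concatenation
  variant is available behind `fusion_config(fusion_input = "concat")` for
  ablation), followed by two 3×3 conv+BN+ReLU layers, a 1×1 conv and a
  sigmoid. Its depth/width is nowhere specified; two convs of 8 channels is
  a declared choice.
* **Fusion initialization**: approximate *mean-vote* pass-through. The
  first conv's first filter is a center-tap identity on the summed map plus
  small noise, and the readout is initialized so the decision boundary sits
  near a summed score of 1 (both sub-networks at 0.5). An initialization
  with the boundary at 0.5 makes the untrained fusion act like an OR of the
  sub-networks, which inherits every single-phase false positive; the
  mean-vote start makes it act like an average vote, which is the behavior
  the fusion is meant to converge to and which short fine-tuning schedules
  can then refine.

The Dice loss is the soft form `1 − (2Σpt + s)/(Σp + Σt + s)` with
smoothing constant `s` (default 1; 0 allowed for exact unit tests). The
fusion network trains under the composite loss
`α₁L₁ + α₂L₂ + L_fusion` with `α = (0.5, 0.5)` by default, every term a
Dice loss against the same ground truth.

All layers, their gradients, and the Adam/SGD optimizers are implemented in
the package (compute kernels in C++ via Rcpp/RcppArmadillo); the backward
pass is verified against finite differences in the test suite.

## Training protocol

The per-phase network trains in three stages: (1) the contracting path on
non-augmented data, (2) the whole network on the same data, (3) fine-tuning
on augmented data. The mechanism for stage 1 is not fully specified by the
protocol description; here a temporary head (1×1 conv + sigmoid + ×8
nearest upsampling on the bottleneck) trains the encoder against the masks
and is then discarded. This is the minimal mechanism that lets an encoder
train on a segmentation target and is flagged as an interpretation.

The fusion network uses a two-subset protocol: the training cases are split
into two equal **case-level** subsets (never slice-level, to avoid leakage);
subset A trains the two sub-networks with the staged protocol, subset B then
trains the assembled network under the composite loss. By default all
weights update in the second phase (the composite loss contains sub-network
terms, implying sub-network gradients); `fusion_config(freeze_subnets =
TRUE)` restricts updates to the fusion block, in which case the sub-networks
run in inference mode and remain bit-identical.

The reference optimizer settings are the defaults of `train_config()`: Adam at
1e-4 for the per-phase network, SGD at 1e-7 for the fusion stage, batch
size 8. Epoch budgets are not part of the reference protocol (only
wall-clock time is); defaults
are (20, 40, 40) per stage. The desk-scale experiment presets override
these to values at which the scaled-down models actually move — Adam 3e-3
with epochs (3, 6, 6), and SGD 0.05 with momentum 0.9 for 10 fusion epochs —
because 1e-7 SGD performs no measurable update within any desk-scale budget.

Augmentation applies one shared geometric draw (rotation −20°..20°, scaling
0.9..1.1, horizontal mirroring) to both phases and the mask (mask
nearest-neighbour), and independent photometric draws (contrast offset
−5..5, noise) to the images only. The contrast range carries no units in
the protocol description; it is read as an additive offset on a 0–255
scale (≈ ±2% of dynamic range), with a multiplicative variant available.
Noise is additive Gaussian, default σ = 0.01 of the dynamic range.

Evaluation is leave-one-out cross-validation at the patient level, with one
confusion triple (TP, FP, FN) per case over the full 3D volume —
per-slice averaging is deliberately not used. `DSC = 2TP/(FP + 2TP + FN)`,
`precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`; when ground truth and
prediction are both empty all three are defined as 1, and a ratio whose
denominator alone is zero is 0 (these conventions never trigger on
phantoms with lesions). Model comparisons use a two-sided paired t-test on
per-case DSC; summary tables report mean ± sample (n−1) SD, median and
range.

## Preprocessing and registration

Phase 2 is registered onto the phase-1 grid with a cubic B-spline free-form
deformation: coarse-to-fine control grids (default spacings 16 then 8
voxels), a mean-squared-intensity metric on z-scored images (the z-scoring
removes the global intensity offset between phases), an analytic gradient,
L-BFGS-B, and a mean-squared-second-difference penalty on the control
coefficients (weight 3e-3) that regularizes the field where the images have
no gradient information. Registration is performed on 3D volumes before 2D
slice pairing — the only reading under which a "co-registered phase-2
slice" is well defined when native slice thicknesses differ (5 mm vs 2 mm).
Per-slice 2D alignment is the noted alternative.

Tumor-bearing slices are selected (exactly the z-slices with ≥1 foreground
voxel), resampled to the network input size (256×256 at clinical scale;
bilinear for images, nearest-neighbour for masks), and min-max normalized
per slice (constant slices map to zero). Min-max rather than z-score keeps
inputs bounded, matching the sigmoid-headed score maps.

Displacement is only identifiable where the image has intensity structure,
so the registration residual against the phantom's known field is evaluated
over the liver region (`registration_residual(field, truth, liver_mask)`);
on flat background the truth itself is unconstrained by the data. The known
field maps the fixed grid to the moving grid, i.e. it is the exact
fixed-point inverse of the warp used to generate the observed phase 2, which
is also the field the registration estimates — so the two are directly
comparable. Typical desk-scale recovery is ~0.35 voxel mean residual from a
2-voxel deformation whose no-registration residual is ~0.49.

## ROI geometry

A 3D ROI box is built from three rectangles on the x-y, x-z and y-z planes.
Each axis is constrained by two rectangles; the box takes the **union** of
the two intervals per axis, plus a margin (default 2 voxels), clipped to the
volume. Union rather than intersection is the conservative reading of the
requirement that the lesion be completely included: a radiologist's sloppy
rectangle should never exclude tumor. Coordinates are 0-based half-open
everywhere, including the JSON schema.

ROI-constrained inference crops both phases to the box, resamples each
block slice to the network input size, applies the fusion network,
resamples the score maps back (bilinear, *before* thresholding, avoiding
blocky masks), binarizes, and pastes into a zero full-grid mask. A
full-volume box therefore reduces DFN-R to DFN-F bit-for-bit — an invariant
the tests assert. Since no human is in the loop, training and test boxes are
ground-truth bounding boxes jittered by ±2 voxels per face plus the margin,
standing in for "roughly contoured" rectangles. Whether ROI crops should be
fed at native size or resampled to the network input is an open choice;
resampling was chosen (flagged as such).

## The phantom generator

No public cohort exists for this method (the original 51-patient MRI data
are private), so validation runs on synthetic dual-phase phantoms that
reproduce the statistical structure the method assumes:

* a liver-like ellipsoid (intensity 0.62 phase 1 / 0.55 phase 2) with a
  smooth random texture field (σ = 0.04) on a dark background (0.12), all
  intensities in [0, 1];
* lesions shaped as ellipsoids whose radius is modulated by low-frequency
  radial noise (lobulated, not trivially learnable), hypointense in phase 1
  (offset −0.35) with an independent phase-2 contrast (−0.18). The
  magnitudes are free parameters chosen once to resemble the visual
  contrast of hepatobiliary-phase lesions; they are not calibrated to
  contrast-agent physics;
* confounders mirroring the two failure modes the method is meant to
  address: `organ_mimic` plants a second structure drawn from exactly the
  lesion distribution (same shape process, same placement rule, same
  phase-1 intensity and texture) but with normal liver intensity in
  phase 2 — phase 1 alone carries no intensity, shape or positional cue
  separating it from tumor, phase 2 does. Exchangeability matters: if the
  mimic were placed or shaped differently from lesions, a contextual model
  could reject it from phase 1 alone and the confounder would not
  confound; `unclear_boundary` blends each phase with a smoothed
  copy near the lesion border (σ = 1.8), cutting the boundary gradient by
  roughly a factor of 3;
* a smooth inter-phase deformation: Gaussian-smoothed random bumps (σ =
  (6, 6, 3)) centred inside the liver, rescaled to a configured maximum
  amplitude kept below half the smoothing scale so the warp remains
  invertible in practice; the exact fixed-point inverse is stored as ground
  truth for registration tests;
* additive Gaussian noise (default σ = 0.01); Rician noise is a documented
  extension, not implemented.

Everything is a deterministic function of (spec, seed), byte-for-byte.

What the phantoms do *not* emulate: acquisition physics (relaxometry,
k-space, bias fields), anatomy beyond one organ, partial-volume effects,
inter-patient variability in organ shape, or radiologist behaviour. Passing
phantom tests therefore demonstrates that the pipeline's machinery behaves
as designed — not that clinical-cohort accuracies transfer.

## Scaled-down study sizes

Desk-scale runs use 8 phantom cases per cohort. The default desk preset
(`desk_experiment_config()`) renders 64×64×16 volumes with 32×32 network
input and 8 base channels; the smallest preset
(`mini_experiment_config()`), used where many repeated LOOCV runs are
needed (the seed-robustness checks and the acceptance script), renders
48×48×12 volumes with 24×24 input. Epoch budgets are (3, 6, 6) + 10 fusion
epochs. These sizes were chosen so that a full three-model LOOCV comparison
completes in minutes on one CPU core while each model still reaches
training Dice ≥ 0.8 on easy phantoms.

The headline qualitative property at this scale is the ordering
`mean DSC(DCNN-F) ≤ mean DSC(DFN-F) ≤ mean DSC(DFN-R)` on organ-mimic
phantoms across master seeds: the phase-1-only model cannot beat the
mimic-induced ceiling, the fusion model can reject phase-1-only false
positives, and the ROI-constrained model additionally excludes everything
outside the box. Absolute DSC values at this scale are far below the
values reported on clinical cohorts and are not comparable to them; only
the
direction of the comparisons is.

## Numerical choices and degenerate inputs

* Binarization threshold 0.5 with the `>=` tie rule.
* Dice smoothing constant 1.0 in training (avoids 0/0 on empty slices);
  0 allowed in tests for exact arithmetic.
* Batch-norm: batch statistics in training, running moments (momentum 0.1)
  at inference; a frozen sub-network advances neither.
* Min-max normalization maps constant slices to zero rather than erroring.
* An empty mask yields an empty slice list (not an error) in slice
  selection, and a degenerate (flagged) ROI box.
* Case-level subset splitting puts the odd case in subset A.
* All derived seeds stay below 2^31; every stochastic step (phantom
  rendering, shuffling, augmentation draws, jitter) is reproducible from
  the master seed, and the experiment output directory is a pure function
  of its configuration.

## Known limitations

* 2D slice-wise networks only; 3D convolutions are out of scope.
* The mean-squared metric (even z-scored) is a crude cross-phase
  similarity; mutual information would be the standard choice for strongly
  differing contrasts.
* Networks are trained only on tumor-bearing slices but evaluated on whole
  volumes, so tumor-free slices are a systematic false-positive source for
  the full-size models — visible in desk-scale precision values. This
  mirrors the behaviour of the original full-size models and is one reason
  the ROI-constrained variant wins.
* Desk-scale budgets under-train the models by design; conclusions are
  directional, not absolute.
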