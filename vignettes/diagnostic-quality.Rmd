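---
title: "Visual versus diagnostic quality of accelerated MRI reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual versus diagnostic quality of accelerated MRI reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(diagqm)
```

## The problem

Accelerated MRI acquires fewer phase-encoding lines of k-space and pays for
the speed with aliasing. Learned reconstruction models remove the visible
artefacts well enough that conventional image-quality metrics (SSIM, PSNR)
— and often readers — are satisfied. But a reconstruction optimised to look
right can hallucinate: smooth over a small lesion, or synthesise lesion-like
texture where there is none. Reader studies large enough to catch such rare
events are impractical, so `diagqm` uses a *detection model as the measuring
instrument*: the same lesion detector, trained once on fully sampled images
and deliberately never retrained per condition, is run on every
reconstruction, and the change in its free-response operating characteristic
is the diagnostic-quality metric.

## The pipeline and its model

For each patient volume (a 3D magnitude image):

1. **Undersampling.** Each 2D slice is Fourier transformed with the DC
   component shifted to the centre; a binary mask over the phase-encoding
   lines is applied; the inverse shift and inverse FFT give the aliased
   magnitude image. Because the inputs are magnitude images, the phase is
   zero by construction and full sampling round-trips exactly. Undersampling
   is strictly per-slice and one-dimensional: slice thickness is never
   undersampled.
2. **Mask design.** With acceleration R, `round(n/R)` lines are kept. A
   contiguous band of 20% of the *sampled* lines sits on the DC line (low
   frequencies dominate contrast and SNR); the remaining 80% are drawn
   without replacement from the periphery with probability proportional to
   `exp(-d / s)`, `d` the distance to DC. The e-folding scale `s` defaults
   to `n/6`, which reproduces the characteristic density taper while leaving
   the k-space edges reachable; it is exposed in `mask_config()` because no
   single value is canonical. Rounding is always half-away-from-zero, and an
   odd central band puts its extra line on the +k side — fixed tie-breaks so
   masks are reproducible integers, never floating-point accidents.
3. **Reconstruction.** Either naive (the masked inverse FFT as-is) or a
   learned residual encoder–decoder trained with loss `1 − SSIM`, using the
   *same* Gaussian-window SSIM as the evaluation metric, so training and
   evaluation cannot drift apart. The network's output layer is
   zero-initialised: the untrained model is exactly the identity, and
   training can only improve on the naive input (best-epoch weights on a
   held-out validation split, early stopping).
4. **Detection.** A convolutional detector maps the z-normalised volume to a
   voxelwise csPCa likelihood in [0, 1]. It trains with weighted binary
   cross-entropy (0.05 background / 0.95 lesion) under patient-level
   cross-validation folds nested in the training side of an 80/20 patient
   split; the held-out 20% is the only evaluation set. The fold models are
   averaged at inference. The detectors are **frozen across acceleration
   conditions** — retraining per condition would let the detector normalise
   hallucinations away, which is exactly what must be measured.
5. **FROC / pAUC.** Candidates are extracted from the heatmap by iterative
   peak extraction (floor 0.10, region growth at 0.40 × peak, at most 10
   candidates, ≥ 3 voxels); matching to ground truth is greedy in descending
   confidence at ≥ 10% intersection-over-union. Duplicate hits on an
   already-matched lesion are discarded rather than counted as false
   positives — standard FROC practice that avoids penalising split
   detections. The diagnostic metric is the trapezoidal partial area under
   lesion sensitivity versus false positives per patient on the *linear* FP
   axis restricted to 0.1–2.5 (maximum 2.4); FROC figures display a log
   axis, but integration is linear. Confidence intervals come from
   patient-level bootstrap resampling.
6. **Inference.** SSIM is compared between paired conditions with a
   two-sided Wilcoxon signed-rank test — exact (by convolution of the
   signed-rank generating function, which stays exact under tied midranks)
   up to 25 informative pairs, normal approximation with tie correction
   beyond. pAUC differences use a paired permutation test that swaps each
   patient's condition labels independently; when `2^n` does not exceed the
   permutation budget all patterns are enumerated and the p-value is exact.
   Patient-level ROC uses the maximum candidate confidence as the patient
   score, the Mann–Whitney rank statistic with midrank ties for the AUC, and
   an operating threshold chosen by the Youden index *on the fully sampled
   condition only*, then frozen — the degraded conditions are evaluated at
   the reference operating point, which is how a fixed clinical threshold
   would behave. Reader concordance uses Cohen's kappa on the
   consistent/minor/inconsistent ratings collapsed to binary
   ({consistent, minor} vs inconsistent; the three-level table is available
   with `collapse = "none"`), with the Fleiss–Cohen–Everitt asymptotic
   variance for the CI.

## The phantom: what it emulates and what it does not

The generator produces T2W-like prostate volumes: a bright peripheral-zone
ellipsoid around a darker transition-zone core (smoothstep edges), optional
hypointense ellipsoidal lesions with smooth margins, an oriented
high-spatial-frequency texture confined to one in-plane axis (so
undersampling that axis produces visible one-directional blur), a smooth
multiplicative bias field, and Rician noise — the correct noise model for
magnitude MR. Determinism is strict: per-case sub-seeds are derived from the
master seed by a counter, so case *i* is bit-identical regardless of cohort
size.

Default study conditions: 48% of patients carry 1–2 lesions (a
csPCa-suspected cohort rate), lesion semi-axes 2.5–5 mm, centre contrast
0.5, noise sigma 0.04 and texture amplitude 0.04 relative to
peripheral-zone intensity. These were chosen once, while designing the
generator–detector pair, so that the fully sampled detection task sits in
the clinically reported operating range (patient AUC near 0.9, lesion pAUC
well below its ceiling) instead of saturating; they were not revisited
afterwards. The default grid is (160, 160, 16) voxels at (0.5, 0.5, 3.0) mm
to match the detection chain; the package's own desk-scale studies use
(48, 48, 8) at (1, 1, 3) mm so that training and evaluation complete in
minutes on one CPU core.

What passing tests on phantoms do **not** show: anatomical realism (no
rectum, no capsule, no BPH nodules), multi-coil or complex-valued k-space
physics, scanner-specific artefacts, or the behaviour of full-scale trained
networks. The phantom validates the *evaluation machinery* and the
directional claims; absolute clinical numbers require clinical data.

## Desk-scale experiment design

`run_experiment()` draws **one mask realisation per patient acquisition**
(sub-seeded from the mask seed). At desk scale an R4 mask over 48 lines has
only ten random peripheral lines, and a single shared realisation makes the
cohort metric hostage to that one draw (cohort pAUC varied by ±0.5 across
mask seeds in design experiments); per-acquisition realisations are both
the realistic acquisition model and the variance-integrating one.

The learned models are intentionally tiny: one down/up-sampling level,
3 × 3 kernels, channel width given by `model_scale` (default 4), 2D
slice-wise convolutions. The reconstruction loss, augmentation menu
(rotation ±30°, additive/multiplicative noise, mirroring, with the
probabilities in the training configs) and optimiser (Adam) follow the
full-scale training protocol; epochs and widths are scaled to CPU budgets.
Within-fold best-epoch weights are selected by validation *loss* — at
desk-scale fold sizes a validation pAUC is a step function of a handful of
lesions and made selection unstable.

## Numerical choices and degenerate inputs

- SSIM: 11 × 11 Gaussian window (σ 1.5), K1 = 0.01, K2 = 0.03, constants
  linked to the reference image's data range, valid-window positions only,
  3D scored as the mean over 2D slices; every result records its settings.
  `ssim(x, x)` is exactly 1; a constant reference is an error.
- PSNR: `10·log10(range²/MSE)`; identical images return `Inf` as the
  documented sentinel.
- Min/max normalisation maps a constant volume to all zeros; z-normalisation
  applies a σ-floor of 1e-8 (zero-padded fixtures would otherwise divide by
  zero).
- Centre crop: odd margins take/add the extra voxel on the high-index side;
  labelmaps go through the same geometry with nearest-neighbour
  interpolation so image/label alignment is exact.
- FROC integration: the curve starts at the implicit (0 FP, 0 sensitivity)
  point, keeps the best sensitivity at duplicated FP rates, interpolates
  linearly, and extends right-constant past the last operating point; a
  curve entirely below the window integrates to 0 with a warning.
- Bootstrap resamples with no lesions are redrawn and counted; permutation
  p-values are never below `1/(n_used + 1)`; degenerate kappa marginals
  return `NA` with a warning.

## Known limitations

- The surrogate (centre-surround) detector is deliberately simple plumbing:
  a difference-of-smoothings blob filter gated by local tissue brightness.
  It validates the FROC machinery without training, but it does not reliably
  reproduce the acceleration-degradation ordering — blur removes the noise
  that fools it about as fast as the detail it uses, so its R4-vs-R1
  direction flips with the cohort seed. The degradation findings in the
  acceptance suite therefore use the trained detector, whose off-distribution
  behaviour on accelerated inputs is the mechanism under study.
- Volume I/O is NIfTI-only; no DICOM reader is bundled.
- 2D slice-wise convolutions only; a 3D-convolution variant would be the
  natural extension at GPU scale.
- The exponential decay rate of the peripheral sampling density and the
  candidate-extraction parameters are defaults with no canonical published
  value; both are exposed in their configs and recorded in results.
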