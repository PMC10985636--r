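---
title: "Artifact-robust lesion detection by targeted adversarial training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact-robust lesion detection by targeted adversarial training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep-learning detectors for clinically significant prostate cancer (csPCa)
on biparametric MRI (bpMRI: T2-weighted, high-b-value DWI, and ADC) degrade
near rectal susceptibility artifacts — signal distortions caused by gas in
the rectum that propagate into the adjacent peripheral zone (PZ). Worse,
*subtle* artifact-patterned noise that a radiologist cannot see can still
flip a detector's output. This package implements, at desk scale, a
vaccination-style defence: craft bounded, artifact-styled adversarial noise
against the current model, add the resulting proprietary adversarial
samples to training, and alternate noise regeneration with model updates
(targeted adversarial training, TPAS). Everything runs on synthetic
phantoms, so the full experiment — data, training, attack, and paired
statistics — is reproducible on one CPU in minutes.

## Synthetic cohorts

`phantom_config()` / `generate_cohort()` emulate the study conditions:

* **Geometry.** Axis-aligned ellipsoidal gland with an inner ellipsoidal
  transition zone (TZ); PZ = gland minus TZ; the rectum is a posterior tube
  separated from the gland by at most `rectum_gap_mm` (2 mm). Arrays are
  indexed `(z, y, x)` with y growing posterior; the default desk scale is a
  single 64 x 64 slice with 1 mm in-plane spacing (any `(z, y, x)` shape is
  supported; the models run per slice).
* **Intensities.** Per-channel affine ranges (arbitrary units): T2W
  [0, 1000], DWI [0, 800], ADC [400, 2400]; zone-wise tissue levels plus
  Gaussian noise with sigma = 4% of the channel range.
* **Lesions.** Ellipsoids of radius 2.5–5 mm placed inside the gland. csPCa
  lesions are offset by `contrast_margin` = 3 noise sigmas in the
  clinically consistent directions (low ADC, high DWI, low T2W); indolent
  lesions get one third of that offset. The margin is chosen so a small
  model can learn the task quickly; it is a study condition, not a tuning
  knob. Patient prevalence of csPCa is 0.5.
* **Artifacts.** The four-point severity scale is generative: grade 1 none;
  grade 2 affects under half of the PZ; grade 3 at least half without the
  TZ; grade 4 reaches the TZ. The forward model — alternating radial bands
  (8 mm period) decaying with distance from the rectum, plus random
  pile-up/dropout blobs, amplitude 25% of the channel range — is a
  stand-in: the literature grades artifact severity but does not publish a
  quantitative artifact forward model. The affected-voxel mask is selected
  as the exact closest-to-rectum fraction of PZ voxels, which makes
  `grade_artifact()` (the automated counterpart of the radiologists'
  score) an exact inverse of `apply_visible_artifact()` by construction —
  a property the test suite checks across all grades.

What the phantoms do **not** model: k-space/Bloch physics, inter-sequence
misregistration, anatomical variability beyond ellipsoids, scanner- and
site-specific intensity distributions. Passing tests on phantoms therefore
demonstrates the *mechanics* of the method (bounds, determinism, direction
of effects, calibration of the statistics), not clinical performance.

## The two-stage detection model

The clinical-scale backbone would be a 3D nnU-Net; the contribution under
test is the training strategy, not the backbone, so we pin a miniature
two-level U-Net (width 6–8, 3 x 3 convolutions, 2 x 2 average pooling,
nearest-neighbour upsampling, leaky ReLU with slope 0.1) written directly
in R with exact reverse-mode gradients — both for parameters (training) and
for inputs (the attack).

Stage 1 (`train_gland_segmenter()`) maps normalized T2W to
background/PZ/TZ with cross-entropy + soft Dice. Stage 2
(`train_lesion_detector()`) consumes five channels — T2W, DWI, ADC, and
the *predicted* TZ and PZ masks binarized at 0.5 (ground-truth masks are a
config switch for ablation) — and outputs a voxel-wise csPCa confidence.

Two numerical choices matter at desk scale and were fixed after the design
proved fragile without them:

* **Positive-class weighting.** With batch-1 Adam on 64 x 64 slices whose
  foreground is ~1% of voxels, a mean-reduced cross-entropy plus soft Dice
  reliably collapses into a saturated all-background predictor for many
  seeds. The detector's cross-entropy therefore weights lesion voxels by
  `ce_pos_weight` (default 16).
* **Prior output bias.** The detector's output bias starts at −4, encoding
  a low foreground prior, so early training refines lesion evidence
  instead of sweeping every logit down first. With leaky ReLU these make
  learning reproducible across seeds (verified on a 5-seed sweep).

Training is deterministic given the config seed: initialization, shuffling
and every downstream stage draw from seeds derived via `derive_seed()`
(a path-keyed mixer), so adding a stage never perturbs another stage's
randomness.

`crossval_select()` implements k-fold selection (default 5): the full
two-stage pipeline is trained per fold and the model with the highest
validation patient-level AUC is kept — the selection metric had to be
pinned and patient-level AUC is the primary endpoint. The shipped benchmark
trains a single model per arm instead of cross-validating, keeping the
experiment small; cross-validation is exercised in the test suite.

## From confidence map to decisions

`extract_candidates()` thresholds the confidence map at 0.45 (an operating
point on the ROC curve; configurable) and takes face-connected components
(6-connectivity in 3D, 4 in 2D) of at least `min_size` voxels; a
candidate's detection probability is the maximum confidence over its
voxels (maximum, not mean, because it is monotone under thresholding).
`patient_score()` is the maximum candidate probability (0 without
candidates). `match_lesions()` matches candidates to csPCa ground-truth
instances greedily in descending probability, each lesion used at most
once; the hit criterion is overlap at least 0.10, with overlap pinned to
intersection-over-union (the PI-CAI-style criterion; intersection over
ground-truth size is available via `mode = "gt_fraction"` since the
literature rarely states which is meant).

## Artifact-styled adversarial noise

`generate_noise()` crafts per-case, per-channel noise fields by minimizing

J(delta) = lambda_style * style + lambda_content * content − lambda_adv * task

* **Style** (`style_distance()`): squared Frobenius distance between
  position-normalized Gram matrices of the shallow feature maps of a
  severe-artifact exemplar and of the perturbed image. The feature
  extractor is a frozen, seeded three-block convolutional stack
  (`feature_extractor()`); blocks 1–2 are the style layers, block 3 the
  content layer. A pretrained VGG-16 would serve the same role at clinical
  scale; the extractor is pluggable, and the method's structure — not a
  specific pretrained network — is what is under test here.
* **Content** (`content_distance()`): mean squared difference of
  deep-layer features between the perturbed and original image, keeping
  lesion semantics intact.
* **Adversarial** (`adversarial_task_loss()`): the detector's own training
  loss, ascended.

The optimizer is projected signed-gradient descent (PGD-style): `iters` =
10 steps of size `alpha` = eps/4, each followed by projection onto
max|delta| <= eps x channel range (eps = 0.02 — small enough to be
imperceptible) and by `clip_to_bounds()`, which clamps the composed image
to the original per-channel min/max, exactly as an addition-then-clipping
sample generation demands. Because clipping moves a composed voxel toward
the original value, it can only shrink |delta|, so both amplitude
invariants hold exactly — the test suite asserts them without tolerance.
Noise support is restricted to the body region by default. The returned
sample is the best (lowest-J) iterate encountered, including the zero-noise
start, so the final composite objective never exceeds the initial one even
though fixed-step signed gradients are not monotone.

The weights (lambda_style 0.05, lambda_content 0.5, lambda_adv 1) were
chosen once so that the attack term dominates while the style term still
decreases over iterations (observed on development runs); they are config
parameters, not claims about any published values. Noise is generated
per case ("proprietary"), never shared across cases.

## Targeted adversarial training

`tpas_train()` alternates noise generation and model updates: after
`warmup` = 5 clean epochs, every `refresh` = 5 epochs the adversarial
samples are regenerated against the *current* detector for a randomly
chosen `rho` = 0.5 fraction of the training cases, and appended to each
subsequent epoch's stream (clean counterparts always remain; adversarial
samples come from training cases only). `control_train()` is the identical
pipeline with `rho = 0`, bit-identical to TPAS with an empty schedule under
the same seed — the equal-exposure audit in the tests hashes the per-epoch
clean streams of both arms. The default style exemplar is the first
training case with a grade-4 artifact imprinted.

## Evaluation statistics

* `roc_auc()`: Mann–Whitney AUC (ties count half), checked exactly against
  brute-force pair counting.
* `delong_test()`: correlated-AUC comparison from placement-value
  covariances, normal approximation, two-sided; degenerate variance
  (identical scorers) reports p = 1 rather than NaN. Cross-checked against
  an independent implementation, a jackknife variance, and a paired
  permutation oracle; its type-I error is verified to sit in the binomial
  99% band at alpha = 0.05 under a simulated null.
* `lesion_pr_auprc()`: average precision over cohort-pooled candidates
  (step interpolation, stable tie-break by probability, case id, candidate
  id); missed lesions enter only through the recall denominator.
* `bootstrap_auprc_diff()`: patients are resampled with replacement and
  both models are evaluated on the same resample (candidates of a patient
  stay together), percentile CI, two-sided p as twice the smaller tail
  mass around zero; B = 1000, seeded.
* `dice()`: 2|A∩B|/(|A|+|B|), with the both-empty convention 1.0 flagged
  via an attribute.
* `weighted_kappa()`: linear disagreement weights by default, quadratic by
  flag — the literature often says only "weighted kappa", so neither is
  asserted as canonical.
* `subgroup_report()` repeats AUC/AUPRC within artifact-grade and site
  strata; single-class strata are reported as NA, never dropped.

## The pinned benchmark

`run_benchmark(default_run_config())` executes the whole experiment: 60
grade-mixed training cases, 80 artifact-free test cases (the clean
external-set analogue), control and TPAS training (24 epochs), an attacked
twin of the test set, and `compare_models()`. The attack that builds the
attacked cohort is optimized against the **control** model and then applied
unchanged for both models — the attacked set is one fixed dataset, as an
externally constructed adversarial test set would be, and the TPAS model
faces it as a transfer attack. Problem sizes were chosen so the full
benchmark completes in minutes on one CPU; the global seed (20260101) is
shipped in the config, and two runs with the same config are byte-identical
in all numeric outputs (hash-manifested in `files.csv`).

Expected behaviour, which the acceptance tests assert directionally: both
models lose AUC and AUPRC on the attacked cohort; the TPAS model's declines
are strictly smaller; TPAS clean AUC stays within 0.05 of control. On
clean phantoms both models are near ceiling (patient AUC ≈ 1), so the
benchmark probes robustness, not clean-data discrimination.

## Known limitations

* Phantom realism is deliberately minimal (see above); absolute metric
  values on phantoms say nothing about clinical data.
* The 2D slice models process `(z, y, x)` volumes slice-wise; no 3D
  context.
* The artifact forward model and the noise-objective weights are package
  choices where the field offers no published quantitative reference.
* The feature extractor is randomly initialized, not pretrained; style
  Gram distances are therefore meaningful relatively (decreasing along an
  optimization) rather than as absolute perceptual quantities.
* The bootstrap uses the percentile method; BCa is not implemented.
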