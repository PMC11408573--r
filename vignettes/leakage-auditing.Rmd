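---
title: "Auditing patient-identity leakage in slice-based nodule classification"
author: "fairCAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing patient-identity leakage in slice-based nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A chest CT scan is a stack of slices, and a slice-level classifier that is
trained and evaluated after *image-wise* random shuffling will usually see
some slices of a patient during training and be tested on that patient's
remaining slices. Slices of one patient share far more than the nodule that
determines the label — scanner texture, anatomy, reconstruction noise — so
the classifier can recognise the *patient* rather than the *disease*. The
reported test accuracy is then inflated, and the model fails on genuinely
new patients. fairCAM rebuilds this failure mode end to end on a fully
synthetic phantom cohort, where the leakage channel is planted explicitly
and therefore known, and provides the tools to measure it:

* patient-wise ("fair") versus image-wise ("unfair") splitting, with a
  leakage audit;
* per-epoch Monte Carlo cross-validation (MCCV) at patient level;
* a small CPU-trainable convolutional classifier exposing the internals
  that class-activation mapping needs;
* gradient-weighted class-activation heat maps (Grad-CAM construction) and
  two interpretability scoring families: nodule locality (max and mean heat
  inside the ground-truth mask) and heatmap-mask shape correlation
  (Pearson and Spearman over the full image grid).

## The phantom cohort

Each synthetic patient is a multi-slice "scan" of a simplified thorax:
an elliptical body (intensity 0.55) with two darker lung fields
(0.20) on an air background (0.05), quantised to the 8-bit grid. Each slice
contains exactly one bright nodule (0.80) placed inside a lung:

* **benign** nodules are smooth disks with radius drawn from the benign
  range;
* **malignant** nodules are spiculated — a star-shaped boundary
  $r(\theta) = R\,(1 + 0.3\cos(k(\theta - \theta_0)))$ with $7 \le k \le 12$
  spikes — and a radius range that starts where the benign range ends.

The classes are therefore separable by size and shape *by construction*,
but deliberately subtly: the ranges are adjacent, so the generalisable
signal is learnable yet not trivial.

**The leakage channel.** Every patient carries an identity signature: a 2-D
sinusoid $a\,\sin(2\pi(f_x x + f_y y) + \varphi)$ with patient-specific
frequencies $f_x, f_y \sim U(0.08, 0.42)$ cycles/pixel and phase, added to
every slice of that patient across the *whole* slice at amplitude
`signatureStrength`. Covering the full slice — nodule included — is
deliberate: a texture restricted to the background would leak the nodule's
position through its complement (a signature-tracking model's rectified
heat map would peak exactly in the signature-free hole, i.e. on the
nodule), and we verified during design that this artifact inverts the
locality comparison. A whole-slice signature carries patient identity
while being spatially uninformative about the nodule, which is what lets
the interpretability scores separate "looking at the nodule" from
"looking at the patient". Setting `signatureStrength = 0` ablates the
channel entirely.

Per-nodule radiologist malignancy scores (1–5, default four raters) are
drawn around the class anchors (1 for benign, 5 for malignant) with sd
`scoreJitter`; the labelling rule requires at least three raters and
thresholds the exact average at $\le 1.5$ (benign) / $\ge 3.5$ (malignant),
excluding everything between. Threshold comparisons are done in integer
arithmetic on the score sum, so boundary averages are classified without
floating-point artifacts.

What the phantom does *not* emulate: Hounsfield-unit physics, 3-D
anatomical continuity between slices, scanner-dependent reconstruction
kernels, or the actual (unknown) patient-specific features of real CT
collections. The sinusoidal signature is a deliberate, controllable
surrogate for whatever slice-shared identity information real scans carry;
a passing experiment here shows the *pipeline* detects planted leakage, not
that any particular real dataset leaks.

## Splitting, MCCV, and the challenge set

`splitImagewise()` shuffles individual images, `splitPatientwise()`
shuffles whole patients; both stratify by class and apportion with the
largest-remainder method (ties toward train), so partition sizes are
conserved exactly. A challenge set of whole patients is carved out *before*
either split and is identical for both arms. `auditLeakage()` reports every
patient whose images span more than one partition: zero for every
patient-wise plan by construction, essentially always non-empty for
image-wise plans on multi-slice cohorts.

`mccvSchedule()` re-draws the validation patients independently every epoch
(unstratified, matching the combinatorics of drawing `val_fraction` of the
pool). Rotation augmentation (default ±2° and ±4°, bilinear, mask
re-binarised at 0.5) is applied before splitting; because augmented copies
belong to their source patient, fair splits keep them together
automatically, while image-wise splits may put a rotated copy of a training
image into the test set — a hazard reproduced deliberately, since it is
exactly what image-wise shuffling does to real data.

## The reference classifier

A deliberately small network, trained from scratch on one CPU: three 3×3
valid convolutions (8, 16, 16 channels) with ReLU, 2×2 max-pooling after
the first two, global average pooling, and a two-way softmax head. Adam,
weighted cross-entropy (inverse class frequency), per-epoch shuffling.
The learning rate is multiplied by `plateauFactor` (default 0.1) when the
best validation accuracy seen so far has not improved by more than 1e-4
for `plateauPatience` consecutive epochs, and the returned model is the
best-validation-accuracy snapshot seen during training.

The only input preprocessing is per-image mean centering. This matters
for interpretability: global slice brightness scales with nodule area, so
without centering a global-average-pooling network can classify through
overall brightness with a spatially *flat* heat map. Centering removes
that channel and forces class evidence to be localized.

Best-validation checkpointing interacts with the split in an instructive
way: under patient-wise MCCV the snapshot is selected on held-out
patients and favours the most generalizing epoch, whereas an image-wise
validation set shares patients with training and selects the memorizing
model. The selection signal is only as honest as the split behind it —
the same mechanism the whole study is about.

Two further numerical points deserve note:

* **Plateau patience under MCCV.** With per-epoch validation-patient
  redraws, the validation accuracy is a noisy, patient-correlated estimate;
  an early lucky draw can set an unbeatable "best" value and, with a short
  patience, collapse the learning rate long before a from-scratch network
  has converged. The package default (5) suits static validation sets; the
  paired experiment below uses a longer patience suited to from-scratch
  MCCV training, chosen as part of the study design.
* **Determinism.** All initialisation and shuffling flows from the config
  seed through an isolated RNG stream; with a fixed BLAS the full training
  history is bit-reproducible.

## Heat maps and interpretability scores

For a target class, the heat map is built from the last-conv activations
$A_k$ and the gradient of the class score with respect to them: neuron
weights $w_k$ are the spatial averages of the gradients, the weighted maps
$w_k A_k$ are reduced across channels by *average* and/or *maximum* (both
variants are computed and recorded, since either reading is defensible),
negative evidence is rectified by default, and the result is min-max
normalised and bilinearly upsampled to the image grid. Because bilinear
resampling can shift the extrema slightly, the normalisation is re-pinned
on the image grid so a non-degenerate map has min 0 and max 1 exactly. A
constant pre-normalisation map is flagged degenerate and scored 0
everywhere — an unfocused map is maximally uninformative, and the
convention keeps score tables total.

Locality scores are the max and mean heat inside the ground-truth mask;
shape correlations are Pearson and Spearman (midrank ties) between heat map
and binary mask over the *full* image grid, since the mask lives on the
image grid and occupies a small fraction of it (which is also why
correlations are numerically small even for well-focused maps).

## The paired experiment and its study conditions

`runFairUnfairExperiment()` runs both arms on the identical cohort,
challenge set, architecture, config and initialisation seed; only the split
mode differs. The fair arm uses patient-wise splitting with MCCV; the
unfair arm a single static image-wise split. Both arms are evaluated on
their own test partition and the shared challenge set, and interpretability
is scored for both models on one shared sample of eight fair-test slices
(patients unseen by the fair model, but — leakage — seen by the unfair
model during training).

The desk-scale study conditions used by the test suite and the acceptance
script are frozen in `leakageStudySpec()` / `leakageStudyConfig()` /
`leakageStudy()`:

* 20 benign + 20 malignant patients, 5 slices each, 64×64 px images
  (the generator default of 128 px is halved to keep a full paired study
  on one CPU core in minutes);
* benign radii 3.5–5 px, malignant 6–7.5 px, spiculation amplitude 0.3;
* `signatureStrength = 0.5` against `noiseSd = 0.05` — the strong-signature
  condition in which the leakage channel dominates the class signal;
* challenge set of 5 + 5 patients; fractions (0.5, 0.2, 0.3) — evaluation
  partitions are deliberately generous because accuracy estimates on few
  held-out patients are patient-correlated and noisy;
* Adam at learning rate 3e-3 for 50 epochs, batch 32, plateau patience 15
  (see above; from-scratch training needs most of the epoch budget).

Under these conditions the accuracy-side picture mirrors the fair/unfair
contrast on real data robustly: the unfair arm's test accuracy is inflated
far above its challenge accuracy (patient memorisation plus rotated
near-duplicates straddling train/test), the fair arm's test and challenge
accuracies agree to within patient-level noise, and ablating the signature
collapses the unfair gap to within noise.

The interpretability side is weaker, and honesty requires saying so. With
per-epoch MCCV, a patient in this epoch's validation set was trained on in
earlier epochs, so validation accuracy is itself contaminated by the
identity shortcut and cannot select a shortcut-free snapshot; both arms
therefore return models with similar internal reliance on the signature,
and their heat-map scores on the shared sample differ only marginally. In
our runs the nodule-locality direction (fair above unfair) holds while the
heatmap–mask Pearson correlations of the two arms are statistically
indistinguishable at this sample size. A leakage audit should therefore
lean on the accuracy-gap evidence and treat CAM-score comparisons as
corroborating, not primary — which is itself a finding about
locality-based CAM auditing at small scale.

## Design choices made where the design was open

* **Interface.** The package's functions, this vignette and the acceptance
  script are the interface; no shell CLI is shipped, as the intended use is
  programmatic.
* **Signature placement** outside the mask keeps the leakage channel
  spatially disjoint from the legitimate evidence, so locality scores can
  separate the two.
* **Pixel intensities are snapped to the 8-bit grid at generation**, making
  PNG round trips exactly lossless rather than lossless-up-to-quantisation.
* **Score sampling** uses fair-test slices (not challenge slices) to mirror
  the figure convention of scoring test images; these are precisely the
  images on which the unfair model has patient-identity information and the
  fair model does not.
* **Class weighting** is inverse-frequency; the default cohort is balanced,
  making it a no-op unless the user unbalances the spec.

## Known limitations

* Training a single small CNN is not an architecture benchmark; nothing
  here compares backbone families.
* Accuracy estimates on few held-out patients are patient-correlated and
  noisy; the paired design and seed medians mitigate but do not remove
  this.
* The phantom's leakage channel is one specific, stationary texture; real
  patient signatures are richer and may be harder or easier to exploit.
* IoU/Dice localisation metrics and attribution methods other than
  gradient-weighted CAM are out of scope.
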