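---
title: "Demographic-parity multi-quantification of maxillary basal-bone indices"
author: "parityQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic-parity multi-quantification of maxillary basal-bone indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Planning anterior-maxilla implant and orthodontic treatment requires
quantifying the alveolar basal bone on 2D sagittal sections through the
incisors: four lengths — from the alveolar crest (`LTAcb`) and the root apex
(`LTAab`) to the basal boundary along the tooth axis (TA), and the same two
along the bone axis (BA: `LBAcb`, `LBAab`) — and five bucco-palatal widths —
the full width 2 mm apical to the apex (`apical2mm`) and the buccal/palatal
contour-to-axis widths at the basal level of each axis (`WTAB`, `WTAP`,
`WBAB`, `WBAP`). Measuring nine indices per image by hand is slow, so an
end-to-end regression network predicting all nine at once is attractive. But
basal-bone morphology is demographically structured — male basal bone is
wider than female — and a single model trained on a demographically skewed
cohort can carry subgroup-dependent bias. `parityQuant` implements the whole
workflow: measurement operators on annotated geometry, a synthetic
sagittal-section generator with analytically exact ground truth, the
shared-backbone multi-head regressor, the per-stratum bias audit that
identifies the *sensitive attribute*, and the subdivide/retrain/pool parity
ensemble that mitigates the bias.

## Geometry and measurement conventions

A section is a `SagittalGeometry`: crest and apex landmarks, directed tooth
and bone axes (unit direction pointing apically), and three polylines — the
basal boundary (toward the nasal floor) and the buccal and palatal bone
contours — all in continuous millimetre coordinates with y increasing
apically. Validity requires the apex on the tooth axis (1e-6 mm), the
contours strictly on opposite sides of the tooth axis, and exactly one
basal-boundary crossing per axis.

Lengths are distances along an axis from the projection of a landmark to the
axis/basal crossing; widths are measured along the perpendicular to an axis
at a level, taking the crossing nearest the axis when a polyline is crossed
more than once. Conventions that the source material leaves open were fixed
as follows and are configurable through `measureConfig()`:

* the four axis-referenced widths are measured at the basal level (offset 0);
* `apical2mm` is taken 2 mm *beyond* the apex, away from the crown (the
  dental meaning of "apical");
* when no bone axis is annotated, `deriveBoneAxis()` uses the line through
  the contour midpoints at crest and basal level;
* image-space annotations use 0-based pixel centers at integer coordinates,
  converted by the pixel spacing, which avoids half-pixel ambiguity.

`WBAB` and `WBAP` are computed as two independent measurements even though
published summary tables often print identical values for them: on a
near-centered bone axis the two distances genuinely nearly coincide.

All nine indices are rigid-motion invariant (tested to 1e-9 mm) and scale
equivariant, and the polyline operators agree exactly with a brute-force
segment-enumeration oracle.

## The synthetic cohort generator

Clinical CBCT sections cannot be redistributed, so every downstream stage is
exercised on a generator whose geometry is *parametric*: axis tilts,
crest/apex/basal positions and straight-line contours are drawn from
truncated normal distributions, and the nine ground-truth values follow in
closed form from the parameters — independently of the polyline measurement
code, which lets the tests cross-check the two paths to 1e-6 mm.

The demographic structure emulates a 1,000-patient cohort: sex is Bernoulli
(default male fraction 0.388), age is truncated normal (36.15 ± 13.09 years,
minimum 18) cut into the 18–29 / 30–49 / 50+ groups, and each patient
contributes the four incisor sites #11, #12, #21, #22. Width-governing
parameters (buccal and palatal contour distances) are multiplied by
`sexEffect` (default 1.3) for males — male basal bone is wider — while age
and tooth site have no morphological effect by default, so the audit's
expected verdict on synthetic data is unambiguous. Distribution means were
chosen so the generated ranges bracket typical clinical values (`LTAcb`
around 17.6 ± 4 mm, `apical2mm` around 9.7 ± 2.4 mm, `WTAB` around 1.7 mm,
`WTAP` around 8 mm). Splits are patient-wise 6:2:2 by largest-remainder
apportionment (ties to train, then validation), so no patient spans splits.

Rendering paints background, low-contrast cancellous bone between the
contours, a bright cortical band along the basal boundary (the nasal-floor
cortical plate, which keeps the basal level sharply localizable), and a
bright tapering root, followed by Gaussian blur and noise. Left-side sites
(#21, #22) are mirrored, as anatomy is, so horizontal flip augmentation maps
the image population onto itself. Two deliberate realism features matter for
the fairness experiments:

* **Section distortion.** The rendered image derives from a slightly
  perturbed copy of the measured geometry (configurable SDs; default
  palatal-width SD 1.4 mm), emulating out-of-plane averaging: a single
  section only partially determines the measured indices, which caps the
  achievable image-based accuracy in the same range as published clinical
  correlations (r roughly 0.5–0.9 per index) instead of letting a network
  read the phantom perfectly.
* **Tooth-centered section window.** The frame places the crest a fixed
  palatal margin (default 10.5 mm) from the image border, as tooth-centered
  clinical sections do; unusually wide (mostly male) palatal bone extends
  beyond the window and is censored. Width information is therefore
  systematically poorer for the wider-boned subgroup.

What the generator does *not* emulate: beam hardening and scatter, 3D
volume context, anatomy-correlated texture, and annotation error on the
ground truth (labels are exact by construction). Passing tests on this
phantom therefore demonstrate the correctness and the qualitative fairness
behavior of the pipeline, not clinical-grade accuracy.

## The multi-quantification network

The model is a residual-family backbone producing one shared feature vector
consumed by nine parallel scalar regression heads (fully shared trunk,
per-head parameters). The six standard deep backbones (ResNet-50/101,
ResNeXt-50/101 with cardinality 32, Wide-ResNet-50/101) are constructible
for fidelity runs; they are implemented as plain He-initialized residual
stacks without batch normalization, with the stem max-pool folded into the
first stage stride. The `small-resnet` desk backbone (3×3 stride-2 stem,
two basic residual stages, 32 features) trains in minutes on one CPU and is
what the test-suite uses.

Training choices the source material leaves open, fixed here:

* loss is the unweighted mean of the nine per-index squared errors on
  z-score-normalized labels (training-split statistics only; indices span
  roughly 1.7–22 mm, so raw-scale MSE would be dominated by the long
  lengths); predictions are de-normalized back to mm;
* the optimizer is Adam at the default learning rate 5e-4, batch size 4;
  the full-scale epoch default is 200, desk-scale runs use 10–50;
* flip augmentation flips the image only — all nine labels are invariant
  under bucco-palatal mirroring, widths being unsigned and lengths
  axis-wise (recorded as an assumption);
* "pretraining" means initializing the trunk from a saved checkpoint when
  one is supplied; the desk backbone trains from scratch, and the tests
  never download weights;
* after training, each head is re-centered so its mean residual on the
  validation split is zero (intercept calibration). A finitely trained
  network carries a global per-index offset; removing it makes the
  evaluation tables reflect model behavior rather than optimizer
  miscalibration. Being one global shift per index, this cannot absorb
  subgroup-differential bias — which is exactly what the audit measures.

Model selection trains each candidate (backbone x hyperparameters) and picks
the minimum final validation MSE, ties to the earlier candidate, retaining
the full selection table.

Grad-CAM for a regression head weights the final convolutional feature map
by the spatially averaged gradient of that head's scalar output (for a
linear head over global average pooling, the head weight divided by the map
area), rectifies, upsamples bilinearly, and min-max normalizes (an all-zero
map stays zero).

## Agreement statistics

The statistical engine implements exactly the conventions used throughout:

* **Paired Wilcoxon signed-rank.** Differences are prediction minus ground
  truth; zeros are dropped; tied absolute differences get mid-ranks; for
  effective n ≤ 25 the two-sided p comes from the exact null of the
  positive-rank sum over all 2^n sign assignments (computed by
  generating-function convolution on the doubled-rank lattice), otherwise
  from the normal approximation with tie and continuity corrections; all
  differences zero gives p = 1.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures — computed from the two-way mean squares. This one form is used
  both for model-vs-truth agreement and for rater-vs-rater comparison;
  degenerate variance yields `NA`, not an error.
* **Bland–Altman**: bias and bias ± 1.96 SD of the differences.
* The difference sign is *prediction minus ground truth* everywhere, chosen
  for internal consistency (published tables are inconsistent about it).
* Per-test alpha 0.05 with no multiple-testing correction across indices or
  strata — faithful to the audited workflow, and a known limitation: with
  27 stratum tests per attribute family, occasional spurious
  significant-index clusters are expected even for an unbiased model.

## The audit and the parity ensemble

`subgroupAudit()` runs the paired Wilcoxon per attribute (sex, age group,
tooth site), per level, per index on the test split. Strata under 5 records
are flagged underpowered and excluded. An attribute's *disparity* is the
spread (max − min) of significant-index counts over its levels; the
*sensitive attribute* is the argmax, ties broken by the larger total count
and then by attribute order. This makes the by-inspection judgement of the
original workflow deterministic and testable. When no attribute reaches the
disparity threshold (default 2) the report says so explicitly.

`subdivideManifest()` splits the cohort by the sensitive attribute and
re-draws a fresh patient-wise 6:2:2 split within each level; submodels
inherit the primary architecture and hyperparameters unchanged, with
per-level seeds derived from the global seed. The ensemble is a *routing
pool*: each test record is scored by its own level's submodel on that
level's disjoint test set and the union is evaluated as one set — pooled MAE
is therefore exactly the record-count-weighted mean of the level MAEs. An
averaging mode is deliberately not provided; deployment routing requires the
attribute as input metadata (inferring sex from the image is out of scope).

Clinician comparison simulates raters as ground truth plus configurable
noise/bias, draws a single seeded 10% subsample of the test images, and
reports the ICC(2,1) matrix per index for every rater pair.

## Why the parity effect reproduces on synthetic data

Under the default biased scenario (sexEffect 1.3, male fraction 0.388) the
pooled model is trained mostly on female-range anatomy while male widths are
both shifted and more heavily censored by the section window. A finitely
trained network under these conditions regresses width predictions toward
the population it has seen, leaving a subgroup-differential residual bias
concentrated in the width indices; the audit detects it as a sex-level
disparity in significant-index counts. Retraining per sex restores each
submodel's correct population prior, so the pooled routing ensemble's
per-stratum significant-bias count drops — the qualitative signature of the
parity strategy. A fully converged model on fully informative images would
not show this (a mean-squared-error optimum is conditionally unbiased on
anything it can see), which is why the desk-scale experiments deliberately
operate in the partially converged, partially informative regime that
matches the published per-index correlations.

## Problem sizes and numerical choices

Desk-scale experiment sizes used by the test-suite and the acceptance
script, chosen as this package's study conditions: 150 patients (600
images), 64 px at 0.5 mm/px, the `small-resnet` backbone, 12 epochs, and
10 Monte-Carlo seeds for the fairness/null experiments (6 in the acceptance
script). Tolerances: geometric identities at 1e-9 mm, generator-vs-operator
ground truth at 1e-6 mm, statistical oracles at 1e-10 or exact. Degenerate
inputs (missing crossings, out-of-view geometry, zero-variance agreement)
raise classed errors or return `NA` markers as documented rather than
propagating nonsense.

Null-calibration caveat, measured and documented rather than hidden: with
three attributes, nine strata and nine correlated per-index tests at
uncorrected alpha 0.05, the probability that *some* stratum shows two or
more spurious significant indices in a given run is substantial even for an
ideally calibrated model; occasional disparity-2 false flags in null
scenarios are an inherent property of the uncorrected count-disparity
audit, not an implementation defect.

## Limitations

* The phantom is stylized; no claim of clinical accuracy transfers from it.
* The deep backbone variants are architectural stand-ins without batch
  normalization and are impractical to train on CPU.
* The audit's count-disparity rule inherits the multiplicity behavior of
  the uncorrected per-test alpha discussed above.
* Ground-truth labels are exact; real specialist annotations carry
  intra-rater variability (reported intra-rater ICCs around 0.89–0.98),
  which the rater-simulation utilities can emulate but the generator's
  labels do not include.
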