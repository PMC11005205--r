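---
title: "Automated gray-white matter ratio measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated gray-white matter ratio measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After resuscitation from cardiac arrest, hypoxic-ischemic encephalopathy
manifests on non-contrast head CT as cerebral edema and loss of the normal
attenuation difference between gray and white matter. The gray-white
matter ratio (GWR) quantifies that difference. `gwrct` computes two
variants from deep-brain regions of interest:

* basal-ganglia GWR: `GWR_b = (CN + PU) / (CC + PIC)`
* simplified GWR: `GWR_s = PU / PIC`

where CN, PU, PIC and CC are the mean attenuations (HU) of the caudate
nucleus, putamen, posterior limb of the internal capsule and corpus
callosum. CN and PU are gray matter, PIC and CC white matter; in a healthy
adult the ratio is near 1.3, and it falls toward 1 as differentiation is
lost. A value computed automatically and reproducibly, minutes after the
scan, is the use case: manual measurement needs a radiology workstation
and is observer-dependent.

The automated pipeline has four stages: deformable registration of the
native CT to an ROI-bearing template, K-means tissue segmentation of the
registered scan, morphological refinement of the atlas ROI masks by their
tissue class, and inverse mapping of the refined ROIs to native space
where the HU statistics and the two ratios are computed. A quality-control
stage excludes scans with low registration accuracy or missing ROI
segmentations.

## Registration

`register()` estimates a template-to-native *pull* mapping
`m(w) = A(w + v(w))`: `A` is a rigid/affine world matrix and `v` a smooth
displacement field on the template grid.

* **Initialisation** aligns intensity centroids (head mass centres).
* **Rigid and affine stages** maximise similarity directly with
  Nelder-Mead over a two-level pyramid (shrink factors 4 and 2), with one
  simplex restart per level; the restart recovers from premature simplex
  shrinkage and makes recovery of a known pose reproducibly accurate to a
  few tenths of a degree.
* **Similarity.** The default metric is global normalized
  cross-correlation (NCC) over a soft-tissue mask of the template
  (`metric_window`, default HU in (-200, 150)) with a 2-voxel dilated
  bone shell removed. Both choices matter: CT-to-CT registration is
  same-modality, where NCC is smooth and discriminative, while mutual
  information (available as `metric = "nmi"`) plateaus on small pyramid
  levels; and the bright skull edge is nearly elliptically symmetric, so
  voxels whose interpolated samples can mix bone contribute
  pose-sensitive aliasing rather than pose information — leaving them in
  biases the optimum by about two degrees on the phantom.
* **The affine stage** is ridge-penalised toward the rigid result and
  accepted only if it improves the masked similarity: smooth anatomy
  leaves the similarity nearly flat along small shears, and an
  unpenalised 12-parameter search drifts along that valley.
* **The deformable stage** is a demons-style iteration at the finest
  pyramid level: the intensity-difference force
  `(F - M_w) grad(M_w) / (|grad|^2 + (F - M_w)^2 / s^2)` with Gaussian
  smoothing (sigma 1 voxel) of both the update and the field, 30 sweeps
  by default, keeping the best-scoring field. An intensity-difference
  force is appropriate because both images are in calibrated HU.
* **Inversion.** The inverse map needed to carry ROIs back to native
  space solves `x + v(x) = z` by fixed-point iteration (at most 50
  iterations, tolerance 0.1 voxel). The generator's deformations are
  low-frequency sinusoids with gradient well below 1, so the field is
  invertible by construction and the round-trip error stays below one
  voxel on average.

The registration accuracy score is the Dice overlap between the brain
extracted from the warped scan and the template brain mask. "Low
registration accuracy" has no canonical score; this Dice criterion
(exclusion below 0.90 by default) is this package's operational
definition and is configurable. Its known limitation:
a brain outline is nearly ellipsoidal, so a badly rotated but
outline-aligned scan can score well — such scans are still excluded,
because their internal structures miss the ROI masks (the missing-ROI
codes fire), which mirrors how improper head orientation actually
presents: poor registration leading to incorrect segmentation.

## Tissue segmentation and ROI refinement

`brain_extract()` thresholds the warped scan to a soft-tissue window
([0, 80] HU), removes the one-voxel shell adjacent to bone (>= 200 HU),
keeps the largest 6-connected component, closes with radius 2, fills
cavities, and finally grows one voxel back into the soft-tissue window
capped at 45 HU. The cap is the top of the normal parenchymal range: it
recovers the brain surface the bone-adjacency exclusion removed without
readmitting CSF-bone partial-volume blends, which would otherwise form a
spurious bright class in the clustering.

`kmeans_tissues()` assigns CSF, white and gray matter in a nested way:

1. CSF is separated by an attenuation threshold (default < 20 HU),
   echoing the low-HU filters used by earlier registration-only GWR
   methods to remove CSF and artifact.
2. K-means (k-means with 10 restarts, 300 iterations, fixed seed) splits
   the remaining parenchyma into white and gray matter. Centroids are
   fitted on *interior* parenchyma voxels — those not bordering CSF or
   the mask edge — because the boundary layer is partial-volume blend
   that skews the class boundary; every voxel is then classified by
   nearest centroid.
3. The split's explained-variance fraction (between-SS over total-SS) is
   compared with `contrast_min` (default 0.62). A 2-means split of
   unimodal noise explains about 0.60 of the variance regardless of its
   SD, so a value at that level means gray-white differentiation is
   genuinely absent; the result is flagged `low_contrast`.

A flat 3-means over all brain voxels — the obvious alternative — fails
exactly when the measurement matters most: with contrast collapsed, the
third cluster latches onto the CSF-parenchyma partial-volume tail and
every white-matter ROI empties.

`refine_rois()` intersects each atlas structure with the mask of its
tissue class (combined parenchyma when `low_contrast` is set), then
closes (radius 2), opens (radius 1), clips back to the atlas footprint
and drops connected components under 5 voxels. Structures retaining less
than 10% of their atlas volume are emptied and flagged missing — the
operational definition of "missing ROI segmentation". Three of these
choices deserve justification:

* **Closing radius 2.** When the class masks are noise-driven speckle
  (no contrast), closing must bridge speckle gaps so that refinement
  degrades gracefully toward the atlas prior; radius 1 leaves thin
  structures (the PIC) bistable between near-full and near-empty.
* **Clipping to the atlas footprint** keeps the closing margin — which
  lies in neighbouring tissue — out of the HU means.
* **The low-contrast fallback** makes the measured GWR tend to 1 when
  differentiation is absent, which is the clinically correct reading,
  instead of ratioing two arbitrary halves of the noise distribution
  (which biases the ratio upward by 0.02-0.03).

## GWR computation

Structure HU values are means over pooled bilateral voxels (CC pooled
over genu, body and splenium), computed in **native** space after
nearest-neighbour inverse mapping — not on the warped image — so that
interpolation never smooths the HU entering the ratio. Per-side and
per-part means are retained, so the alternative convention (mean of side
means) stays computable. An optional HU inclusion window
(`hu_window_preset()` gives (15, 100)) reproduces the voxel filter of
earlier approaches; it is off by default because the refinement stage is
designed to replace it. A missing required structure or a non-positive
denominator yields an undefined GWR, flagged rather than thrown.

`manual_circle_mean()` reproduces the manual protocol's primitive — the
mean over an approximately 10 mm^2 circle on one axial slice — for
method-comparison studies.

## Quality control

`evaluate_case()` emits `REG_LOW_ACCURACY` when the accuracy score falls
below threshold (default 0.90) and `MISSING_ROI_{CC,CN,PU,PIC}` when any
member of a structure group was emptied by refinement; any code excludes
the case, and excluded cases carry no GWR values. Physician-side
exclusion categories (hemisphere asymmetry, hemorrhage, severe atrophy,
artifact) are *generated* by the phantom (`lesion = "hyperdense"`,
`"asymmetry"`) but deliberately not detected: that adjudication is a
physician's task in clinical workflows.

## The phantom

`make_template()` / `make_subject()` build a fully analytic head: nested
ellipsoids for scalp (40 HU), skull (900), CSF rim (8), a cortical gray
ribbon (38) over a white-matter interior (30), paired ventricles, and
the nine ROI structures as ellipsoids (paired CN, PU, PIC; midline genu,
body, splenium of the CC) at anatomically plausible positions. With
WM = 30 and GM = 38 the healthy GWR is 38/30 = 1.267, near the
guideline-cited normal of about 1.3.

* **Severity** `s` collapses contrast linearly:
  `GM(s) = 38 - 8 s`, so the analytic `GWR_s = (38 - 8 s) / 30` is known
  exactly and reaches 1 at `s = 1`.
* **Pose and deformation**: a rigid rotation/translation (default drawn
  within ±8°, ±8 mm) composed with a sum of low-frequency sinusoidal
  displacements (default amplitude 2 mm, wavelengths 130-150 mm), whose
  gradient is far below 1, keeping the map diffeomorphic and analytically
  evaluable. Subjects are rasterised *exactly* by evaluating compartment
  geometry at mapped native coordinates — no interpolation — so native
  ground-truth masks are crisp.
* **Acquisition model**: Gaussian noise (default SD 2 HU) injected before
  a Gaussian reconstruction blur (sigma 0.4 voxel), the physical order;
  at 2 mm voxels this matches the mild smoothing of a soft-tissue CT
  kernel.
* **Corruptions**: CC and/or CN ablation to CSF attenuation (with a 3 mm
  margin) reproduce missing-ROI failures; an extreme field-of-view
  truncating malposition reproduces registration collapse; hyperdense
  and asymmetry lesions emulate physician-excluded scans.

The phantom deliberately omits cortical folding, beam hardening, streak
artifact and scanner-specific noise texture. Passing its suites
demonstrates the pipeline's internal consistency, geometric correctness
and failure handling — not clinical accuracy on hospital data.

`simulate_cohort()` generates the statistics layer's inputs without
volumes: severity-driven true GWR, observed manual/automated readings
(manual noisier, SD 0.06 vs 0.025, reflecting small 2-D circular ROIs),
and clinical covariates whose outcome associations follow the directions
seen in post-arrest cohorts (older age, higher epinephrine dose, lower
diastolic pressure in poor outcome). The favorable-outcome label is
drawn from a logistic model with stated standardized coefficients
(`default_outcome_model()`; GWR coefficient 2.0, intercept -1.2 giving
roughly one-third favorable prevalence).

## Evaluation statistics

The positive class is the *favorable* outcome, predicted by GWR above a
cutoff. AUC is the Mann-Whitney concordance (ties count one half) with
DeLong placement-value variance for CIs and for the paired two-sided
test between correlated AUCs. The Youden cutoff maximises
sensitivity + specificity - 1 over midpoints between adjacent observed
scores, breaking ties toward the higher cutoff (higher specificity).
Diagnostic proportions carry exact Clopper-Pearson 95% CIs. Univariate
screening uses Student's equal-variance t for continuous and chi-square
for categorical variables at p < 0.1; the logistic model reports
`exp(coef)` with Wald CIs and in-sample AUC, runs complete-case with a
reported dropped count, and raises a typed error on perfect separation.
The derivation/validation split is stratified on sex by age-quartile
cells with a fixed seed — the operational reading of a split "based on
age and sex".

## Numerical choices and problem sizes

Defaults chosen once and used everywhere: grid 96 x 96 x 80 at 2 mm
isotropic (the tests and the acceptance script run at this size; a full
single-case pipeline takes a few seconds on one CPU); K-means seed
20240409; registration pyramid (4, 2) with 500/250/30 iteration caps;
demons smoothing sigma 1 voxel; field inversion tolerance 0.1 voxel;
component connectivity 6 (face adjacency) with ties broken by smallest
minimum linear index; ball structuring elements in voxel units (radius 1
is the 6-neighbour cross). Degenerate inputs produce typed errors
(constant image at registration, empty brain mask, fewer distinct HU
values than clusters, all-equal scores at cutoff search) rather than
silent results.

## Known limitations

* The Dice-based registration accuracy score cannot flag rotations that
  preserve the brain outline; such failures surface as missing ROIs.
* The refinement's atlas-footprint clip assumes registration is at worst
  a few voxels off; gross misregistration must be (and is) caught by QC.
* The low-contrast fallback trades a small underestimate of residual
  contrast near complete collapse (severity above roughly 0.85 under the
  phantom's noise model) for unbiasedness at collapse.
* Phantom realism bounds what green tests mean: no claim is made about
  performance on clinical scans, scanner artifacts or pediatric anatomy.
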