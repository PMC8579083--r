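---
title: "Methods: automated detection, segmentation and response assessment of brain metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated detection, segmentation and response assessment of brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`metrano` implements a computer-aided detection (CAD) pipeline for brain
metastases (BM) on contrast-enhanced 3D T1-weighted MRI and automates
treatment-response assessment under modified RANO-BM criteria.  The chain
is:

1. intensity normalization anchored on a gray-matter reference;
2. brain masking and cropping;
3. aspect-preserving resampling to an isotropic cube;
4. coarse lesion detection with a 3D encoder-decoder under a Dice loss;
5. per-lesion bounding boxes, high-resolution 2D refinement of each box's
   axial slices, and stitching back to the native grid;
6. per-lesion volumetry and longest axial diameter;
7. similarity registration of serial scans, lesion-level matching, and
   CR/PR/SD/PD categorization (one-dimensional and volumetric).

Because clinical MRI cannot be bundled, the package ships a seeded phantom
generator producing longitudinal synthetic brains with exact lesion ground
truth.  Every stage's contract is exercised against that ground truth.

# Intensity normalization

Scanner units are arbitrary, so intensities are mapped to $[0, 1]$ by

$$v \mapsto \mathrm{clip}\!\left(\frac{v}{2\,g},\, 0,\, 1\right),$$

where $g$ is the gray-matter reference intensity; the reference thus lands
at 0.5 and enhancing lesions (brighter than gray matter) occupy the upper
half of the range.  The literature this follows describes only "0 to 1
scaling anchored on a manually selected gray-matter position"; the
$v/(2g)$ convention is this package's explicit, invertible choice.  In an
automated run the anchor defaults to the median intensity of the brain
mask (`gm_reference = "auto"`); a known reference (the phantom's true
value) can be passed instead.  Background voxels — outside the brain mask,
or below 2% of the 99th intensity percentile when no mask is given — are
forced to exactly 0.

# Brain masking and cropping

The default mask is an Otsu threshold followed by retention of the single
largest 26-connected component and slice-wise hole filling; a trained
segmenter can be plugged in through the same interface.  The threshold
fallback ships so the whole pipeline runs without any training step.  The
brain bounding box (default margin 2 voxels) is recorded so all later
results map back to native coordinates by integer bookkeeping.

# Resampling to the detection cube

One global scale factor, `size / max(physical extent)`, is applied to all
three axes, preserving the aspect ratio; the content is centered in the
cube and the remainder is zero padding.  Intensities are trilinear,
labels nearest-neighbor, and the resampling record stores the scale and
offsets so cube-space detections map back exactly.  The full-scale
profile uses a 192-voxel cube; the `tiny` profile (used throughout the
tests) uses 64.

# The trainable segmenter

No deep-learning framework is part of this package's dependency set, so
the 2D/3D encoder-decoder is implemented in-package: im2col convolutions
evaluated as single-precision BLAS matrix products, ReLU activations,
2x max-pooling, nearest-neighbor upsampling with skip concatenation (a
1x1 convolution reduces the concatenated channels before each decoder
block), and a final 1x1 convolution with a sigmoid.  Training minimizes
the soft Dice loss

$$L = 1 - \frac{2\sum_i p_i t_i}{\sum_i p_i + \sum_i t_i + \varepsilon},
\qquad \varepsilon = 10^{-6},$$

with Adam at batch size 1.  The reference training recipe is 300 epochs
with learning rate $10^{-3}$, dropped to $10^{-4}$ after epoch 100 and
$10^{-5}$ after epoch 250; the `tiny` profile uses 20 epochs at
$3\times10^{-3}$ (dropped tenfold for the final quarter), which is where
the phantom task converges.  Two choices matter for fast Dice
convergence and are fixed:

* He initialization with the **output bias set to $-2$**, so initial
  probabilities are near 0.12 rather than 0.5 — with foreground a small
  minority, this makes the Dice gradient informative from the first
  epoch;
* backward-pass gradients were verified against central finite
  differences (the single-precision forward limits agreement to about
  $10^{-3}$ relative, which the unit checks respect).

The architecture descriptor (dimensionality, depth, base channels) is
configuration: the tiny profile trains depth-1 networks with 2 base
channels, which is sufficient for hyperintense quasi-spherical phantom
lesions; real data would use the full-scale profile (deeper, wider, 192
cube, 512 patches) at GPU-scale cost.  A pretrained encoder for the 2D
refiner is supported conceptually but off by default: requiring
downloaded weights would break the self-contained build, and the phantom
task does not need it.

Determinism: weight initialization, the train/validation split (default
90:10), shuffling and augmentation all derive from the configured seed;
refitting with identical data and seed reproduces the loss history
bit-for-bit.  Augmentation (off by default for the tiny profile, whose
cohorts are already diverse) uses flips, rotations, translations and
scale; the 2D path exposes the 16 deterministic
flip x flip x rotation x scale combinations.

# Coarse-to-fine segmentation

Detection runs on the normalized cube; the probability map is thresholded
at 0.5, 26-connected components are labeled, and components below 2
voxels are dropped (both configurable — the threshold and minimum size
are neutral defaults, not tuned values).  Each component's bounding box,
expanded by 25% per axis, is cropped and every axial slice it intersects
is resampled to a square patch (512 px full-scale, 128 px tiny)
preserving the in-plane aspect ratio with zero padding.  The 2D refiner
segments every slice; per-slice masks are inverse-mapped (by the stored
geometric record, so there is no drift) and unioned in 3D.  The refiner
may veto a detection by returning an empty mask.  Overlapping refined
masks are merged by voxelwise OR and relabeled.  Whether the original
system refined one slice or all slices per lesion is not documented;
refining all slices of the box is this package's choice, since the union
reconstructs the 3D extent that volumetry needs.

# Quantification

Volume is the voxel count times the voxel volume ($s_x s_y s_z$), exact
arithmetic.  The longest axial diameter is, per axial slice, the maximal
pairwise distance between in-plane voxel centers (computed on the convex
hull; an all-pairs scan is the test oracle) plus the mean in-plane
spacing as an outer-edge correction, maximized over slices.  The
correction gives a single voxel a nonzero diameter and makes the 5 mm
measurability cutoff behave sensibly at 1 mm resolution; no measurement
convention is stated in the source literature, so this one is declared
and used consistently.  Volumes are reported in mm^3 throughout.

# Registration and lesion matching

Serial scans are aligned with a 7-parameter similarity transform: three
Euler rotations (fixed XYZ order, degrees), three translations (mm) and
one isotropic scale, about the brain centroid of the fixed image.  The
clinical description calls this step "rigid" while listing scale among
its parameters; the package implements the similarity interpretation and
provides `rigid = TRUE` to freeze the scale.  The metric is the mean
squared intensity difference (appropriate for same-modality serial
scans), optimized by Nelder-Mead over a 3-level multi-resolution pyramid
(factors 4, 2, 1) with a quasi-Newton (BFGS) polish at the finest level
(the simplex reliably stalls short of the optimum in 7 dimensions).
Both inputs receive six passes of separable binomial smoothing first:
without smoothing, voxel noise measurably displaces the rotational
optimum itself (verified by comparing the metric at the recovered and
true parameters), and a smooth near-ellipsoidal brain carries little
rotational information of its own — the phantom's brain semi-axes are
pairwise distinct by construction for the same reason.  With smoothing
and polish, known transforms are recovered to about 0.3 degrees,
0.05 mm and 0.0005 scale on tiny-profile phantoms.  A metric that
worsens across a level aborts with the trace.  The pipeline's internal
registration (whose product is only lesion matching at millimeter
scale) runs fewer simplex iterations and skips the polish.

Lesion matching maps baseline centroids through the transform and gates
candidate pairs at `max(5 mm, r_b + r_f)` (equivalent-sphere radii);
gated pairs are assigned one-to-one by minimal total distance with an
O(n^3) Hungarian solver (cross-checked against brute-force permutation in
the tests).  Unmatched follow-up lesions are "new", unmatched baseline
lesions "disappeared".

# Response assessment

Targets are up to five measurable lesions (longest axial diameter >= 5 mm
— the modified measurability cutoff appropriate for 1 mm-slice 3D
imaging), sorted by diameter (ties: volume, then id).  Targets are
selected on the baseline only and tracked forward through the match set;
disappeared targets contribute 0.  With $S$ the sum of target diameters:

* any new lesion, regardless of size, gives **PD**;
* $S_f = 0$ with no remaining measurable lesion gives **CR**;
* $\Delta = (S_f - S_b)/S_b \le -30\%$ gives **PR**;
* $\Delta \ge +20\%$ gives **PD**;
* otherwise **SD**.

Volumetric assessment applies the same structure to summed target
volumes with cutoffs 0.343 and 1.728 — the cubes of $0.70$ and $1.20$ —
so that an isotropic diameter change classifies identically on both
bases.  The exact volumetric cutoffs of the modified volumetric criteria
are not restated in the source text; the cube convention is declared here
and configurable (`pr_ratio`, `pd_ratio`).  All boundaries are inclusive
and compared with a $10^{-9}$ slack so that printed boundary values
(e.g. a ratio of exactly 1.728 computed as $1.2^3$ in floating point)
classify inclusively.  Corticosteroid dosing and neurological status —
part of full RANO-BM — are out of scope.

# Evaluation statistics

* Detection: a truth lesion is detected iff at least one predicted voxel
  overlaps it (any-voxel criterion; a centroid-inside-truth flag is
  available); each predicted component overlapping no truth lesion is one
  false positive.  Sensitivity is reported overall, per size bin
  (default edges 0, 3, 5, 10, 20 mm) and for the >= 5 mm aggregate.
* Segmentation: Dice similarity coefficient per matched lesion.
* Agreement: weighted Cohen's kappa on the 4x4 CR/PR/SD/PD table with
  **linear** weights $w_{ij} = 1 - |i-j|/3$ by default.  Linear weights
  reproduce the packaged reference tables' published agreement values
  (0.52 one-dimensional, 0.68 volumetric; observed agreement 0.800 and
  chance agreement 0.580 for the first), which fixes the otherwise
  ambiguous "weighted kappa"; quadratic weights are available.
* Proportion intervals: exact Clopper-Pearson by default (it reproduces
  the published 74.0%–99.9% bounds for 18 of 19), Wilson score by flag.
  The published intervals are not all consistent with a single method, so
  both are provided rather than asserting one.

# The phantom generator

The generator emulates exactly the features the pipeline contracts
consume: an ellipsoidal brain (semi-axes 0.80/0.65/0.72 of the half grid
extent — deliberately anisotropic so rotations are identifiable) on an
exactly-zero background; smooth linear intensity gradients (up to
8%) around a known gray-matter level (100); quasi-spherical hyperintense
lesions with contrast drawn from 1.5–3.0x gray matter (enhancing
metastases are hyperintense on post-contrast T1; the exact contrast is
unspecified in the literature, so a plausible range is fixed); additive
Gaussian noise (sigma 5, i.e. 5% of gray matter) inside the brain only.
Lesion counts are 3–8 per case and diameters are drawn log-uniformly from
3–15 mm, giving a median near 6.7 mm — small nodules dominate, as in
clinical series where the reported median is about 6.5 mm.  Placement
leaves 40% radius headroom so follow-up growth up to 1.4x can neither
merge lesions nor cross the brain boundary, keeping the ground truth
bookkeeping exact.

Follow-up scans evaluate the baseline anatomy through the inverse of a
known similarity transform (so registering baseline to follow-up recovers
the transform exactly), apply per-lesion radius factors in the baseline
frame, and instantiate new lesions in the follow-up frame.  Truth
records map centers through the transform and scale radii by the
transform's isotropic scale times the change factor.  One simplification
is documented: follow-up lesions are re-instantiated axis-aligned rather
than rotated with the anatomy — for quasi-spherical lesions under the
moderate rotations used (<= 6 degrees) the in-plane diameter error this
introduces is far below one voxel.

What the phantom does **not** emulate: gyral/sulcal anatomy, CSF,
bias fields, partial-volume effects beyond linear interpolation, rim
enhancement, necrosis, leptomeningeal or dural disease.  Passing tests
on phantoms therefore demonstrate that the pipeline's geometry,
bookkeeping, optimization and rule logic are correct — not that the tiny
trained networks would transfer to clinical MRI, which would require the
full-scale profile and real training data.

# Problem sizes and determinism

The shipped tests and the acceptance script run entirely at the tiny
profile: 64^3 phantoms at 1 mm, 20-pair longitudinal cohorts for the
oracle end-to-end and matching checks, 20 training + 6 held-out volumes
for the trained-model check, and 3 pairs for registration parameter
recovery.  These sizes are the package's reference conditions for
desk-scale reproduction; the `full` profile (160x192x160 phantoms,
192^3 cube, 512 px patches, 300-epoch schedule) is configuration
supported by the same code paths.  Every stochastic step takes an
explicit seed, and cohort/case seeds are derived from the run seed by a
fixed integer hash, so reruns are bit-identical.

# Known limitations

* The volumetric response cutoffs rest on the cube convention, not on an
  independently verified external table.
* The registration metric is MSD only by default; mutual information is
  not implemented (same-modality serial scans do not need it here).
* The refiner processes axial slices independently; no 3D refinement.
* Diameters are in-plane only (no slice-spanning 3D diameters), matching
  the axial-plane measurement convention.
* Published real-data sensitivities/DSCs are not reproducible without
  the private clinical data and GPU-scale training; the phantom-based
  property checks are the stated substitute.
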