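---
title: "Measuring the nasal airway in CBCT: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the nasal airway in CBCT: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volumetric assessment of the nasal airway from cone beam CT (CBCT) is harder
than pharyngeal airway volumetry: the nasal cavity is a thin, folded space
bounded by turbinates and the septum, and it communicates with the paranasal
sinuses through openings that a segmentation can silently leak through. A
usable tool therefore needs (a) an anatomically defined region of interest,
(b) a way to close sinus connections reproducibly, (c) a seeded
region-growing segmentation restricted to air, and (d) a validation design
in which the true volume is known independently of any image.

`nasovol` implements all four as a scriptable library plus CLI. Because real
gold standards for airway volume require physical models (hollow printed
shells whose internal volume is measured by filling them with water), the
package ships a *digital phantom generator* whose cavity volumes are known
in closed form, so the whole validation loop can run at desk scale.

## The segmentation pipeline

`segment_nasal_airway()` runs five steps:

1. **Smoothing** (`smooth_volume`): a cubic median filter (half-width
   `median_radius` voxels, default 1) followed by a Gaussian of physical
   sigma `gaussian_sigma` mm (default 0.4, one voxel at the reference
   0.4 mm spacing). Both default parameters are minimal noise reduction;
   either can be 0 (identity). Smoothing precedes thresholding so that
   isolated bright noise voxels cannot stop the region growth.
2. **Air thresholding** (`binarize_air`): air is low grayscale; a voxel is
   air iff intensity `<= T` (closed on `T` for deterministic ties). CBCT
   grayscale is treated as an arbitrary signed scalar - no Hounsfield
   calibration is assumed, because CBCT scanners generally are not
   calibrated that way.
3. **ROI restriction** (`build_roi_mask`): see below.
4. **Blocking** (`apply_blocks`): each block is a disk-slab (center, unit
   normal, radius, thickness) whose enclosed voxel centers are forced to
   tissue. This replaces interactive painting of sinus openings with a
   first-class, JSON-serializable, hashable artifact, so an editing session
   is reproducible and versionable. A slab must be at least one voxel
   diagonal thick, otherwise its rasterization could leak diagonally.
5. **Region growing + volumetry** (`region_grow`, `measure_volume`): the
   connected component of the air mask containing the seed, under
   6-connectivity by default; volume is `voxel_count * sx*sy*sz`, exactly.

Default connectivity is 6 because 18/26-adjacency can leak through a
one-voxel wall contact diagonally; 18 and 26 remain available for
sensitivity analysis. Left and right airways are measured by running the
pipeline once per side with a per-side seed - the nasal septum itself
separates the two components, no explicit midline cut is applied.

## The region of interest

The ROI is defined by five craniometric landmarks (LPS world frame, mm):
basion, nasion, the most posterior-inferior ethmoid point, the most
anterior point of the posterior septal border, and the most posterior point
of the anterior nares. The anterior and posterior boundaries are coronal
planes (constant y) through the last two points. The superior boundary is a
natural cubic spline `z_sup(y)` through the midsagittal (y, z) positions of
nasion, the ethmoid point and basion, extruded along x; inferiorly and
laterally no geometric cut is applied - the palate and cavity walls bound
the airway through the tissue mask.

Choices worth recording:

* "Vertical plane" is read as a scanner-frame coronal plane; the package
  does not re-orient heads (no Frankfort alignment).
* A natural cubic spline with exactly three knots is the minimal-curvature,
  fully reproducible interpretation of "a spline through three points";
  outside the knot span it continues linearly. It is evaluated through
  `stats::splinefun(method = "natural")` and is tested against a direct
  tridiagonal solve.
* Voxel membership is decided by the voxel **center** (voxel `(i,j,k)`
  occupies `[origin + i*s, origin + (i+1)*s)`), and boundary ties use `<=`.
  This makes voxel-count volumetry and ROI rasterization mutually exact.

## The threshold-selection rule

For accuracy testing against a hollow shell, the threshold is not free: it
is *the highest threshold at which the shell's inner space remains
disconnected from the outside air* (`max_disconnecting_threshold`). Both
seed-airness and inner-outer connectivity are monotone in `T`, so an exact
binary search over the volume's sorted unique intensities finds `T*` with
`O(log n)` connectivity checks; tests verify it against an exhaustive scan.
A shell with a pinhole has no separating threshold and is reported as such
rather than returning a garbage value.

This rule has a physical consequence that drives the whole accuracy story:
`T*` sits just below the weakest point of the blurred wall, which is
generally *above* the 50% air-tissue crossing. Thresholding at `T*`
therefore pushes the segmented boundary slightly **outside** the true
surface - the partial-volume overestimation seen when such tools are
validated against printed shells.

## The digital phantom

`generate_phantom()` builds a CBCT-like volume from parametric shapes with
closed-form volumes (ellipsoids, capsules, disjoint unions), wrapped in a
soft-tissue-level shell produced by morphological ball dilation, with
optional sinus chambers connected through cylindrical channels, a
bone-level slab, Gaussian blur (partial-volume emulation), and additive
Gaussian noise - in that order (blur then noise: resolution loss happens in
the scanner optics, detector noise afterwards). Ground truth volumes are
analytic, never rasterized, reproducing the separation between a physical
gold standard and an image-derived measurement.

Stated-world defaults and why:

* **Grayscale levels** air −1000, soft-tissue mimic 300, cortical bone 800:
  the levels such a phantom (skull + clay + resin shell) shows in CBCT.
* **Spacing** 0.4 mm isotropic: the reference acquisition protocol.
* **Noise sd** 40 grayscale: moderate CBCT detector noise; large enough to
  matter for the threshold search, far too small to perforate a wall.
* **Wall** 2 mm bulk with one thin **weak patch** (2.25 voxels thick,
  radius 3 mm) per cavity at its apex. A printed shell is not uniformly
  thick, and the disconnecting-threshold rule keys precisely on the weakest,
  barely resolved region of the wall; the bulk wall elsewhere controls how
  far the boundary can overshoot. Tying the patch thickness and the blur
  (one voxel) to the spacing keeps the phantom self-similar when the
  resolution changes, which is what makes the measured error shrink with
  voxel size.
* **Accuracy preset** (`nasal_pair_phantom_spec`): a left/right ellipsoid
  pair with analytic volumes 1220 and 830 mm^3 - the scale of a scaled-down
  printed nasal-airway pair - elongated anteroposteriorly and flattened
  laterally like a nasal fossa.

The accuracy experiment (`phantom_accuracy_experiment`) smooths with the
median filter only before finding `T*` and segmenting. The phantom already
carries the scanner PSF; the median filter suppresses detector noise while
preserving the wall ridge, whereas stacking a second Gaussian on the
already-blurred data flattens a thin wall's ridge toward the 50% crossing
and erases the overestimation mechanism the validation is supposed to
exercise. An erf model of the blurred wall predicts `T*` around −260 +- 80
and a boundary overshoot of 0.05-0.15 mm, i.e. +1 to +7% for these
surface-to-volume ratios; the package's acceptance tests assert the
resulting band (100-110% of truth, always an overestimate).

What a green full-loop test does **not** establish: the phantom has no beam
hardening, scatter, rings, or printing artifacts; its cavities are smooth
ellipsoids, not turbinate-folded spaces; examiner variability in landmark
and block placement is out of its scope (it is simulated separately, see
below). The loop validates the algorithmic chain, not the scanner or the
human.

## Reliability statistics

`simulate_measurement_sessions()` emulates repeated measurement sessions:
`value = true + session_bias + N(0, error_sd)`. The reliability module
computes, from two paired sessions:

* the classical paired t-test with 95% CI (`df = n - 1`; a zero-variance
  nonzero difference is flagged degenerate with `t = +-Inf, p = 0`);
* the **random error** `sd(differences)/sqrt(2)` - the per-measurement
  error implied by duplicate sessions;
* the single-measure **ICC**, in two models: two-way random with absolute
  agreement (default - session biases count as disagreement, which is the
  right question for reproducibility) and one-way random. Both are provided
  because reliability tables produced by common statistics packages do not
  always say which model was used; sample SDs use the n−1 denominator
  throughout, matching those packages.

Volumes are interchangeably expressed as voxel counts or mm^3 via
`voxel_mm3_convert` (15.625 counts per mm^3 at 0.4 mm voxels, kept exact in
floating point by converting one axis at a time); accuracy is reported as
`percent_of_gs`, rounded to 1 decimal as such tables print it.

## Meshes and STL

`mask_to_mesh()` extracts the 0.5 isosurface of the binary mask (sampled at
voxel centers, one-voxel zero padding so the surface always closes) by
marching tetrahedra on the conforming 6-tet cube decomposition. This choice
over classic marching cubes is deliberate: there are no ambiguous cases and
no large case tables, the mesh is watertight by construction, and on binary
data the surface passes through the same edge midpoints, so enclosed
volumes agree with voxel counting to well within the tolerances used here
(0.7% on a 10-voxel cube, 0.4% on a radius-20 sphere). The isosurface of an
*isolated* voxel is the small polyhedron through its edge midpoints
(0.5 mm^3 at unit spacing), not the full voxel cube - single-voxel debris
is not meaningfully meshable at this sampling, and no midpoint isosurface
method renders it at its voxel volume.

`mesh_volume()` is the divergence-theorem signed-tetrahedron sum and
demands a watertight, outward-oriented mesh (every undirected edge shared
by exactly two faces, once per direction); it is the package's independent
oracle for all volumetry. STL output is binary little-endian (what printers
consume); ASCII STL is accepted on read. `hollow_shell()` thickens a cavity
into a printable wall by ball dilation.

## Numerical and degenerate-input policy

* Filters handle borders by edge replication; Gaussian kernels are
  truncated at 4 sigma and renormalized.
* The threshold search operates on the discrete set of intensities actually
  present - no step-size parameter, bit-reproducible results.
* Empty pipelines fail loudly and name the stage that emptied the mask;
  seeds falling on tissue report their position and intensity.
* All randomness (phantom noise, simulated sessions) flows through explicit
  integer seeds; two runs with equal seeds are bit-identical.
* File formats: MetaImage (.mha) is the canonical lossless container
  (float64 voxels); NIfTI-1 is written and read (gzipped accepted on read);
  DICOM support is deliberately narrow - single-series, axial,
  explicit-VR-little-endian, int16 - which covers CBCT exports, and rejects
  anything else (mixed series, non-uniform gaps, missing spacing) rather
  than guessing.

## Known limitations

* No automatic landmarking; ROI quality is the operator's landmark quality.
* The ROI roof is extruded laterally from a midsagittal spline; no lateral
  clip is applied at the ethmoid region.
* ICC supports exactly two sessions (the reliability design implemented
  here); multi-rater generalizations are out of scope.
* The digital phantom's gold standard is analytic geometry; it cannot stand
  in for a physically printed and water-weighed model when qualifying a
  real scanner.
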