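---
title: "Auditing SEEG electrode-vessel conflicts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing SEEG electrode-vessel conflicts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegconflict)
```

## The problem

Stereoelectroencephalography (SEEG) implants a dozen or so depth
electrodes through the skull to localize epileptogenic cortex. The
dominant surgical risk is hemorrhage from an electrode transgressing a
blood vessel, so trajectories are planned against a vascular
segmentation and a safety margin (SM, 3 mm here) is enforced between
each planned path and the segmented vasculature. How well that works
depends entirely on which vessels the chosen imaging modality can
actually resolve: catheter digital subtraction angiography (DSA)
resolves sub-millimetre vessels, whereas MR venography (MRV) and
gadolinium-enhanced T1 (T1+Gad) mostly show the larger trunks.

`seegconflict` implements the retrospective *audit* of implanted
electrodes against multi-modal vascular imaging:

1. segment tubular vessels from each vascular volume;
2. reconstruct each implanted electrode from its post-implantation CT
   contacts and linearly interpolate the trajectory between them;
3. compute an exact Euclidean distance field to the segmentation and
   profile each trajectory against it;
4. detect conflicts (overlap of the electrode with the segmentation),
   and characterize each one by vessel diameter, depth below the
   cortical entry point, and sulcal membership;
5. build a gray-matter sulcal exclusion model by ray-cast cortical
   thickness estimation and world-metric erosion;
6. score per-modality detection sensitivity / false-negative /
   false-positive rates against a reference conflict set and compare
   modalities with chi-squared tests under Bonferroni correction.

No patient imaging ships with the package. Instead a synthetic phantom
generator produces seed-reproducible multi-modal volumes with planted,
analytically verifiable ground truth, so every stage of the pipeline is
testable end to end.

## Geometry conventions

All images are `volume_grid` objects: a 3-D array plus a 4x4 affine
mapping 0-based voxel indices to world millimetres, with the voxel
center as its position. Every distance in the package is computed in
world mm, which makes anisotropic acquisitions (e.g. 0.43 x 0.43 x
0.75 mm rotational angiography grids) exact rather than approximate.
Registration *solving* is out of scope: rigid transforms are inputs
(`rigid_transform`), applied by `resample_to_reference`; the phantom
volumes are generated directly in the reference frame with identity
transforms. Out-of-field samples return a documented background value
(0) instead of erroring, because probe-eye review routinely runs off
the volume edge.

## Vessel model

`vesselness_filter` is the standard multiscale Hessian tube measure:
at each Gaussian scale $\sigma$ (mm) the scale-normalized Hessian
$\sigma^2 H$ is assembled from central differences of the smoothed
volume and its eigenvalues $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$
enter the three-ratio bright-tube response

$$V_\sigma = \left(1 - e^{-R_A^2/2\alpha^2}\right)\,
             e^{-R_B^2/2\beta^2}\,
             \left(1 - e^{-S^2/2c^2}\right),
  \qquad \lambda_2,\lambda_3 < 0,$$

with $R_A = |\lambda_2|/|\lambda_3|$ (plate rejection),
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blob rejection) and
$S = \lVert\lambda\rVert_2$ (structure strength). Defaults:
$\alpha=\beta=0.5$; $c$ is half the volume's intensity range, which
makes the response invariant to constant intensity offsets; scales
{0.25, 0.5, 1, 1.5, 2} mm, combined by voxelwise maximum. Scales below
half the smallest voxel dimension carry no information and are dropped
with a warning. The response is in [0, 1] by construction; a
rasterized 1 mm-radius cylinder peaks at the 1 mm scale, and a plate
of equal contrast scores zero.

`segment_vessels` thresholds the response (default 0.05, chosen once
so that two-voxel-diameter tubes at the phantom's contrast survive)
and removes connected components below `min_component_voxels`
(default 5, a noise guard).

`distance_field` is an exact anisotropy-aware Euclidean distance
transform (three-pass separable lower-envelope algorithm, implemented
in C++), zero exactly on the mask and 1-Lipschitz in the world metric.
An empty segmentation yields an all-infinite field carrying an
explicit `empty` flag that downstream code reports as "no
vasculature", never as distance 0. The signed variant
(`signed = TRUE`) negates interior distances; the audit uses it so
that the deepest penetration of a crossed vessel stays localizable
inside the mask.

`local_diameter` estimates the vessel calibre at a conflict site as
an inscribed-sphere diameter: from the mask voxel nearest the site it
climbs the interior distance-to-boundary field to a local maximum (a
medial-axis voxel) and doubles that distance. The climb keeps the
estimate on the vessel actually crossed rather than a thicker
structure passing within the capture radius (default 2 mm, which also
tolerates grazing conflicts just off the mask). Against analytic
capsules at 0.5 mm voxels the estimator is unbiased to about half a
voxel; no half-voxel correction is applied because the overshoot of
voxel-center distances past the boundary and the offset of the
sampled voxel from the true medial axis cancel on average. The
estimate is voxel-resolution-limited by design; sub-voxel lumen
modelling is out of scope.

## Electrode model

`segment_contacts` labels supra-threshold CT components (26-connected)
and returns intensity-weighted centroids. `group_into_electrodes`
assembles centroids into electrodes by greedy collinear chaining: the
line (seeded by a centroid pair) collecting the longest
spacing-consistent chain wins, is refined by principal axis, and its
contacts leave the pool. Two safeguards matter where electrodes cross:
contacts whose axial projections collide keep only the
closer-to-axis point, and gaps must sit on the contact-spacing grid
(1-3 spacings, tolerating up to two contacts lost to merged blobs).
When the contacts-per-electrode count is known from the implant
record, over-long chains are trimmed from their ends. Unassignable
centroids are reported, never silently dropped.

`interpolate_trajectory` densifies the piecewise-linear contact chain
(electrode bending is honored only at contacts, matching how
implanted electrodes are reviewed; no spline) at a uniform arc-length
step (default 0.5 mm, about the finest voxel dimension of the
acquisitions this emulates) and extends it proximally to the brain
mask, where `arc = 0` defines the cortical entry from which every
depth is measured. The brain-mask boundary is the operative
definition of "cortical surface". A contact chain spanning most of
its chord is geometrically ambiguous about which end is the tip; the
pipeline resolves orientation with the planned entry point from the
implantation record (`entry_hint`), as clinical workflows do
implicitly, and falls back to a mask-depth heuristic otherwise.

Distances to vasculature are measured from the electrode *surface*:
the field value minus the electrode radius (default 0.4 mm,
configurable to 0 for pure-axis behaviour).

## Conflict audit

Two thresholds are deliberately distinct. A *conflict* is overlap
between the electrode and the vascular segmentation
(`conflict_threshold = 0`); the *safety margin* (3 mm) is a planning
quantity used in risk scoring and review displays. `detect_conflicts`
reports maximal below-threshold runs, merging runs separated by less
than `merge_gap` (default 2 mm) so one obliquely crossed vessel is not
double-counted; within a run, distinct penetration minima separated
by a rise of at least `split_prominence` (default 0.5 mm, one voxel)
are separate events — two vessels crossed back to back never surface
above the conflict threshold between them, but their penetration
profile has two prominent dips. Each event localizes at its deepest
penetration (plateau centers resolve to their middle).

`characterize_conflicts` completes each event with the diameter at the
site, the depth (its arc length from entry), and whether it falls
inside the sulcal model. In the phantom pipeline, calibre is measured
on the raw image's half-maximum segmentation rather than on the
vesselness mask: the filter's mask width is a property of the filter,
not of the lumen, and the clinical measurement this mirrors was made
on raw angiography.

`risk_metrics` summarizes a trajectory with its intracerebral length,
the drilling angle to the skull surface at entry (90 degrees =
orthogonal, the planning ideal), the gray/white sampling ratio, the
minimum distance from vasculature, and a cumulative risk score

$$\mathrm{risk} = \frac{1}{N}\sum_{i=1}^{N}
  \max\!\left(0, \frac{SM - d_i}{SM}\right) \in [0, 1],$$

zero iff the whole profile respects the margin and one iff the
electrode tracks the vasculature throughout. This score preserves the
"cumulative distance from the vasculature" semantics of published
trajectory-risk metrics but is not any published formula; treat it as
a documented stand-in when comparing numbers across tools.

## Sulcal exclusion model

Deep-brain stimulation series report an order-of-magnitude higher
hemorrhage risk when an electrode transgresses a sulcus, which
motivates excluding sulcal gray matter at planning time.
`estimate_thickness` casts rays inward from points sampled uniformly
on the brain surface, along normals from the smoothed-mask gradient
(sigma = 1 voxel); each ray's thickness is its chord through the
gray-matter mask from first entry to first exit, rays never entering
gray matter are excluded and counted, and sampling is seeded. Rays
start half a voxel outside the surface voxel center so cortex that
reaches the surface is entered rather than started inside — without
this the estimate biases low by about half a voxel.

`build_sulcal_model` erodes the intracerebral mask by a world-metric
ball of radius `margin_factor x mean thickness` and intersects with
gray matter. Erosion is implemented as thresholding the exact
distance-to-surface field (correct under anisotropic voxels, where
iterated structuring elements are not), with the distance taken as
the voxel-center distance to the complement minus half a voxel (the
boundary lies between voxel centers). "Below the gyral crown" is
operationalized as erosion by exactly one mean cortical thickness
(`margin_factor = 1`): the construction order is fixed by the method
this reimplements, the depth itself is exposed and logged. On an
unfolded spherical shell the model is empty (no gray matter deeper
than one thickness); on folded phantoms it equals the brute-force
depth-thresholded gray-matter set exactly.

## Modality comparison

`match_conflicts` scores a detector's events against the reference
conflict set by greedy nearest-pair matching within 3 mm (one safety
margin; the clinical cross-referencing was manual and stated no
tolerance). The phantom pipeline matches per electrode — a reference
conflict can only be claimed by an event on the trajectory it belongs
to, as in manual per-trajectory review. `detection_metrics` keeps the
clinical accounting's mixed denominators: sensitivity and
false-negative rate over *reference* conflicts, false-positive rate
over *flagged* events, raw-vs-segmentation false-negative rate over
*raw-visible* conflicts. Percentages round to integers except when
the value sits within 0.05 of halfway, where one decimal is kept
(44/166 prints as 26.5). `chi_square_compare` is the 2x2 test on
detected/missed counts without continuity correction (a Yates toggle
exists; the standard `N(ad-bc)^2` closed form is the test oracle),
and `compare_modalities` Bonferroni-corrects over the number of
pairwise comparisons actually run, which is reported in the output.
`sulcal_union` adds the exclusion zone: a conflict is covered if the
segmentation detected it *or* it lies inside the sulcal model, so
coverage never decreases.

## The phantom: what it emulates, and what it does not

`phantom_spec`/`generate_phantom` build one synthetic "patient" on an
isotropic reference grid (default 128^3 at 0.5 mm, a scaled-down
head):

* **Anatomy.** A spherical brain (radius 0.45 x the grid extent, about
  29 mm at default size), a skull shell, and a cortical sheet of
  constant 3 mm thickness folded sinusoidally
  (`fold_wavelength = 30 mm`, `fold_amplitude = 8 mm`), so the gyral
  crown and sulcal depths are closed-form; a `single`-groove mode
  exists for exact sulcal-model oracles and `none` for degenerate
  cases.
* **Vessels.** `n_vessels = 60` capsule-segment roots with radii drawn
  lognormal(median 1.3 mm, IQR 1.0-1.5 mm) — the size structure of
  conflicting vessels this package is designed to audit — with one
  bifurcation generation at radius decay 0.79 (the cube-root
  flow-splitting value). Sub-1.3 mm-diameter roots are placed in the
  folded cortical band (sulcal vessels run small; superficial cortical
  vessels run larger). Segments shorter than 1 mm after clipping are
  dropped.
* **Modalities.** A vessel segment renders into a modality volume iff
  its diameter reaches that modality's visibility threshold: DSA-like
  0.5 mm, MRV-like 2.0 mm, T1+Gad-like 2.5 mm, chosen to reproduce
  the qualitative ordering DSA >> MRV > T1+Gad rather than any exact
  percentage. Rendering is anti-aliased over one voxel with additive
  Gaussian noise (sd 1 against vessel intensity 100); an optional
  `vessel_dilation` inflates the DSA-like rendering to emulate an
  extraction filter that dilates segmentations beyond the lumen (the
  clinical source of false positives; no published dilation amount
  exists, so the default is 0).
* **Electrodes.** Eight electrodes of 8 contacts at 5 mm spacing
  (within the published 8-12 contact range; 8 keeps the 35 mm span
  inside the phantom brain's chords). Each targets one vessel: a
  conflict depth is drawn lognormal(median 31 mm, IQR 14.3-45 mm),
  clamped to the geometrically feasible interval, the entry point is
  solved on the smooth brain sphere, and the recorded depth equals
  the arc length from entry to the closest approach exactly. Planting
  enforces a transverse crossing (>= 25 degrees to the target axis),
  rejects paths that run lengthwise inside any vessel, and places the
  conflict point where the target vessel is locally isolated from
  other segments: a point conflict with a well-defined depth and
  diameter presupposes a transverse crossing of one identifiable
  vessel — a grazing pass has no conflict point, and a point buried
  in an overlapping larger vessel has no diameter of its own.
  Contacts render as Gaussian blobs (sigma = half voxel) in the
  CT-like volume.
* **Ground truth.** The manifest records every vessel segment with
  per-modality visibility, the planted conflicts, and additionally
  *every incidental* electrode-vessel touch (closest approach below
  the touching distance), flagged `planted = FALSE` — so detector
  events at real incidental crossings score as detections, not false
  positives. All manifest geometry is checkable by analytic
  point-to-segment distance, and identical specs (including the seed;
  all randomness flows from one `set.seed`) reproduce the phantom bit
  for bit.

What the phantom does **not** emulate: contrast kinetics or any real
MR/CT physics, deformable anatomy, arterial/venous distinction,
electrode bending (phantom electrodes are straight; the audit's
piecewise-linear interpolation is exercised, its necessity is not),
registration error (identity transforms), or the texture of real
angiographic backgrounds. Passing phantom tests therefore validates
the geometry, accounting and statistics of the audit — not
segmentation performance on clinical images.

## Study sizes and reproducibility

The end-to-end recovery checks pool three phantoms (three "patients",
24 planted conflicts) at the default 128^3 / 0.5 mm conditions, the
same way the clinical analysis pools patients; single-phantom medians
over 8 conflicts are fragile to one merged event. On one CPU a full
phantom study runs in about half a minute, and the three-phantom
acceptance run in about two minutes. Tests that need only geometry
use smaller grids (48-72 voxels per axis) chosen for sharp oracles,
not speed alone: brute-force distance checks are exact there.

Median recovery accuracy at these conditions: planted-versus-recovered
conflict depth agrees to well under 1 mm and diameter to under one
voxel, with at least 95% of planted conflicts of diameter >= 2 voxels
detected — these are the quantities `scripts/acceptance.R` recomputes,
alongside the worked detection-rate arithmetic from the published
counts.

## Known limitations

* Diameters are inscribed-sphere estimates on a voxel grid: accuracy
  is about half a voxel at best, and overlapping capsules at
  bifurcations read larger than either branch.
* The greedy electrode grouping assumes straight-ish electrodes with
  a known nominal spacing; heavily bent electrodes would need a
  curve-growing formulation.
* The risk score is a documented stand-in, not a published formula.
* Conflict depth for near-parallel electrode-vessel passes is
  ill-defined; the generator avoids planting them, and real grazing
  geometries would surface as extended events whose single reported
  depth is arbitrary within the run.
* Patient-level percentages from the clinical study are not
  reproducible here (the imaging is not public); the package
  reproduces the *arithmetic* of those statistics and the *behaviour*
  of the pipeline on phantoms with the same size and depth structure.
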