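# seegconflict

Auditing stereoelectroencephalography (SEEG) depth electrodes for
conflicts with intracranial blood vessels.

SEEG implants 7–14 depth electrodes to localize epileptogenic cortex;
the main surgical risk is hemorrhage where an electrode transgresses a
vessel. Trajectories are planned against a vascular segmentation with
a 3 mm safety margin, so everything hinges on which vessels the
imaging modality can resolve: catheter angiography (DSA) shows
sub-millimetre vessels, MR venography (MRV) and gadolinium-enhanced T1
(T1+Gad) mostly the larger trunks. This package implements the
retrospective audit of implanted electrodes against multi-modal
vascular imaging, and a fully synthetic phantom generator so the whole
pipeline is testable without patient data.

The pipeline:

* **Vessels** — multiscale Hessian vesselness
  `V = (1 − e^{−R_A²/2α²}) · e^{−R_B²/2β²} · (1 − e^{−S²/2c²})`
  over the scale-normalized Hessian eigenvalues, thresholded and
  size-filtered; exact anisotropy-aware Euclidean distance fields;
  inscribed-sphere vessel diameters at conflict sites.
* **Electrodes** — contact centroids from post-implantation CT,
  greedy collinear grouping with spacing-grid gating, piecewise-linear
  trajectory interpolation with depth measured from the brain-mask
  entry point.
* **Conflicts** — distance profiles (field value minus electrode
  radius) along each trajectory; a conflict is overlap (distance ≤ 0),
  localized at the deepest penetration; events are characterized by
  diameter, depth, and sulcal membership; per-electrode risk metrics
  (intracerebral length, drilling angle, cumulative margin-violation
  score, gray/white sampling ratio).
* **Sulcal model** — ray-cast mean cortical thickness, world-metric
  erosion of the intracerebral mask below the gyral crown, intersected
  with gray matter, used as an exclusion zone.
* **Statistics** — per-modality sensitivity / false-negative /
  false-positive accounting against a reference conflict set
  (sensitivity = detected/reference, FP rate = spurious/flagged), χ²
  comparisons of modalities with Bonferroni correction, and the
  sulcal-union uplift.

## Worked example

Generate one synthetic patient and audit it end to end:

```r
library(seegconflict)

spec  <- phantom_spec(grid_shape = 96, voxel_size = 0.5,
                      n_vessels = 40, n_electrodes = 6, seed = 7)
study <- run_phantom_study(spec)

study$tables$DSA
#> <detection_table DSA segmentation> detected 19/37, flagged 19 (0 spurious)
study$tables$MRV
#> <detection_table MRV segmentation> detected 17/37, flagged 17 (0 spurious)

rep <- study$report
sprintf("conflicts: %d | median diameter %.2f mm | median depth %.1f mm",
        rep$n_conflicts, rep$diameter[["median"]], rep$depth[["median"]])
#> "conflicts: 19 | median diameter 3.16 mm | median depth 21.0 mm"

study$comparisons[1, c("a", "b", "chi_square", "p_value", "bonferroni_m")]
#>                  a                b chi_square   p_value bonferroni_m
#> 1 DSA segmentation MRV segmentation  0.2163743 0.6418165            3

study$risks[[1]]
#> <risk_metrics> length 39.0 mm | angle 65 deg | risk 0.502 | G/W 0.16 | min dist 0.00 mm
```

The ground-truth manifest records 37 true electrode–vessel touches
(targeted and incidental); the DSA-like segmentation detects 19 of
them with no spurious events, the MRV-like modality (blind to vessels
under 2 mm diameter) 17. `study$report` summarizes the detected
conflicts: the medians above are the recovered vessel calibre and the
depth of conflict below the cortical entry point; the first risk line
says that electrode runs 39 mm intracerebrally, enters at 65° to the
skull surface, and touches the segmented vasculature (min dist 0).

At the default study conditions (128³ grid, 0.5 mm voxels, vessel
radii lognormal with median 1.3 mm, planted conflict depths with
median 31 mm), pooled over three phantoms, every planted conflict of
diameter ≥ 2 voxels is detected and the recovered depth and diameter
medians agree with the planted ones to well under 1 mm and one voxel
respectively.

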