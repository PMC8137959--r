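# nucmorph

Nuclear morphometry and survival validation for histopathology
segmentation masks.

Pathologists have long suspected that the shapes of tumor-cell nuclei in
diffuse large B-cell lymphoma (DLBCL) carry prognostic information, but
morphologic criteria have been hard to quantify reproducibly. Deep
segmentation models now deliver one binary mask per tumor nucleus from
H&E-stained tissue-microarray cores, which turns the question into a
measurement problem: compute well-defined geometric descriptors per
nucleus, summarize them per patient, and ask whether they predict overall
survival. `nucmorph` implements that measurement chain for R users:
per-nucleus geometry, per-patient aggregation, and an internally
validated Cox survival analysis — plus a synthetic-data generator so
every stage can be exercised and tested without access to a real
dataset.

## What it computes

For each binary nucleus mask (a 2-D NPY array), after boundary tracing
and convex-hull construction:

* the **minimum-area rotated rectangle** (rotating calipers; rotation
  angle reported in [−90°, 0), where −90° is axis-aligned and the angle
  grows toward 0° as the rectangle rotates clockwise),
* the **least-squares fitted ellipse** (direct algebraic conic fit with
  ellipse constraint) with center, axis lengths, area πab and Ramanujan
  perimeter,
* the **maximum and minimum Feret diameters** (caliper distances between
  parallel supporting tangents) with their angles in [−180°, 180°],
* the **convex-hull area**, and
* six derived shape factors:

  ```
  esf        = shortAxis / longAxis
  csf        = 4π · ellip_area / ellip_perimt²
  sf1        = shortAxis / maxDiameter
  sf2        = minDiameter / maxDiameter
  elongation = maxDiameter / minDiameter
  convexity  = √(ellip_area / hull_area)
  ```

  All of esf, csf, sf1, sf2 and elongation equal 1 for a perfect circle;
  csf falls toward 0 as nuclei become more elliptical.

Per patient, the mean and standard deviation of each feature across all
nuclei form the geometric feature vector. Cox proportional-hazards
models (Efron ties) are fitted on clinical features, geometric features,
or both, and scored with Harrell's C-index. Internal validation uses the
bootstrap optimism correction: refit on each with-replacement replicate,
record the drop from replicate-evaluated to original-evaluated C, and
subtract the average drop from the apparent C, with percentile
confidence intervals.

## Worked example

One synthetic nucleus, an ellipse with half-axes 24 and 15 px rotated
30°:

```r
library(nucmorph)
m <- gen_mask(shape_spec("ellipse", a = 24, b = 15, theta = 30))
f <- compute_features(m)
```

prints, via `f[c("esf","csf","sf1","sf2","elongation","convexity")]`:

```
esf 0.619  csf 0.919  sf1 0.611  sf2 0.619  elongation 1.616  convexity 0.989
```

`esf` ≈ 15/24 = 0.625 recovers the axis ratio from the rasterized mask;
`elongation` = 1/sf2 measures the same anisotropy through the Feret
diameters (47.7 / 29.5 px); `convexity` ≈ 1 says the fitted ellipse and
convex hull nearly coincide, as they must for a true ellipse.

The full pipeline on a simulated cohort — 120 patients, 5 nuclei each,
survival drawn from a Cox model whose first covariate also drives
nuclear elongation:

```r
sim <- cohort_config(n_patients = 120, nuclei_per_patient = 5, seed = 77)
cfg <- pipeline_config(out_dir = "run1", n_bootstrap = 40, seed = 5)
run_pipeline(cfg, simulate = sim)
```

```
[features]  computing geometric features for 600 nuclei
[aggregate] aggregating 600 nuclei over 120 patients
[survival]  both: corrected C = 0.680 ..., 0 failed replicates
[survival]  clinical: corrected C = 0.719 ..., 0 failed replicates
[survival]  geometric: corrected C = 0.674 ..., 0 failed replicates
```

A geometric-only corrected C-index well above 0.5 shows the shape signal
propagating end to end from masks to survival prediction;
`survival_report.json`, `cell_shapes.csv` and `patient_features.csv`
land in the output directory. Pointing `pipeline_config()` at a real
dataset laid out as `Cells/{patient}/{patch}/{cell}.npy` plus a cleaned
clinical CSV runs the same chain without simulation.

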