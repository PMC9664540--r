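# nodule4d

Quantitative spatiotemporal analysis of **in vitro bone nodule formation**
from two-channel 3D time-lapse two-photon imaging: an EGFP-like cell
fluorescence channel and a second-harmonic-generation (SHG) channel that
reports fibrillar collagen label-free. The package is aimed at bone
biologists and image analysts who want the full measurement chain —
from raw TIFF stacks to the statistics — as reproducible, scriptable code
instead of a sequence of interactive commercial-software steps.

## What it measures

* **Matrix production** — SHG surface segmentation (median filter + Otsu),
  volume `V_SHG` (voxel counting) and area `A_SHG` (watertight
  marching-tetrahedra mesh), per timepoint and as increments.
* **Cell morphometrics** — per-cell volume V, mesh surface area A, Wadell
  sphericity ψ = π^(1/3)(6V)^(2/3)/A, semi-axes a ≥ b ≥ c from second
  moments (axisᵢ = √(5λᵢ), exact for solid ellipsoids), and the flatness
  indices oblateness = 2(b−c)/(a+b−2c), prolateness = 2(a−b)/(2a−b−c).
  Cells with ψ ≥ 0.7 (inclusive) are "high sphericity".
* **Compartments** — IN/ON vs OUT: centroid inside the concave boundary
  polygon of the projected SHG surface *and* at or above the lowest SHG
  height; boundary ties count as inside.
* **Crowding** — mean Delaunay triangle area of IN/ON centroids (and the
  lacuna-spot control, extracted by regional minima inside the SHG mask).
* **Local coupling** — 4×4 = 16 subROIs: high-sphericity cell counts at t
  vs SHG increase t→t+1, Spearman ρ with the standard strength bands
  (little/weak/moderate/strong, inclusive lower bounds).
* **Bleb kinetics** — temporal minimum subtraction, thresholding,
  overlap-based track linking: per-bleb duration and maximum (FWHM) area;
  4D frame-difference spot extraction with host assignment and polar-angle
  histograms (θ_xy, θ_zy, θ_zx, 15° bins).
* **Motility** — nearest-centroid tracking, speeds in µm/h by compartment.
* **Treatment readouts** — SHG growth, IN/ON sphericity time course, and
  the binarized maximum-intensity-projection SHG/EGFP area ratio.
* **Statistics** — one-way ANOVA + Tukey HSD, Spearman with categories,
  paired and two-sample t-tests (α = 0.05), KS normality pre-check
  (flagged for its estimated-parameter bias).

Because the kind of raw data this targets is rarely public, the package
includes a first-class **synthetic scene generator**
(`generate_nodule_timecourse()`, `generate_bleb_movie()`,
`generate_bio_experiment()`) that renders calibrated two-channel 4D
stacks — logistic nodule growth, schedule-driven cell flattening
(first-timepoint mean sphericity 0.7026), carved lacuna voids, log-normal
bleb durations (mean 27 s) with gamma maximum areas (mean 5 µm²),
hemisphere-constrained bleb polarity, and two-group motility — together
with an exact `GroundTruth` table for every rendered object. All
estimators are validated against that ground truth and against
closed-form oracles; see `vignettes/nodule4d-methods.Rmd`.

## Worked example

```r
library(nodule4d)

# calibrated default bleb time lapse: 15-s frames, ~9 cells, >= 80 events
gen <- generate_bleb_movie(scene_config("bleb", seed = 7))
det <- detect_blebs_2d(gen$stack)
nrow(det$tracks)                 # 80
mean(det$tracks$duration_s)      # 26.06
mean(det$tracks$max_area_um2)    # 4.95
```

The detected population recovers the configured kinetics (27 s mean
duration, 5 µm² mean maximum area) from the rendered movie alone: 80
tracks, mean duration 26.06 s, mean maximum area 4.95 µm² — within the
sampling error of the 84 rendered ground-truth events. The nodule example
below recovers the day-7 SHG volume within 6% of ground truth and the
IN/ON sphericity population mean within 0.013 of the configured 0.7026.

```r
# nodule time course: days 7/10/14/21, dome-shaped SHG, cells on and off
nod <- generate_nodule_timecourse(scene_config("nodule", seed = 1))
surf <- segment_shg(nod$stack, "SHG", t = 1)
surf$volume_um3                  # 42446 (ground truth: 40175)
cells <- segment_cells(nod$stack, "EGFP", t = 1)
rec <- classify_compartment(measure_cells(cells), surf)
inon <- rec$compartment == "IN/ON" & !rec$clipped
mean(rec$sphericity[inon])       # 0.6904 (configured population mean 0.7026)
```

## Command line

```sh
Rscript inst/cli/nodule4d simulate --scenario nodule --seed 1 --out out/
Rscript inst/cli/nodule4d run --scenario bleb --seed 7 --out out/
```

`simulate` writes the stack as a multi-page TIFF plus ground-truth CSVs
and the config JSON; `run` additionally executes the full pipeline
(`run_pipeline()`) and writes the report tables.

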