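---
title: "nodule4d: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nodule4d: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Differentiating osteoblasts in culture deposit a collagenous bone nodule
that can be followed label-free through second harmonic generation (SHG)
while the cells themselves are followed by fluorescence (EGFP). `nodule4d`
implements the complete quantification chain for such two-channel 3D
time-lapse data: how much matrix is produced (SHG volume and area over
days), how cell shape evolves on the matrix (Wadell sphericity,
oblateness, prolateness), where matrix growth happens relative to
cuboidal, high-sphericity cells (subROI correlation), how crowded the
cells are (Delaunay triangle areas), how membrane blebs behave on the
seconds scale (duration, maximum area, polar distribution), how motile
cells are on versus off the matrix, and how everything responds to a
Wnt-activating treatment. Because the original microscopy data are not
publicly deposited, the package ships a ground-truthed synthetic scene
generator that emulates each experiment at desk scale; every downstream
estimator is validated against that generator's exact ground truth or
against closed-form oracles.

# The measurement model

## Stacks and geometry

All images travel as an `ImageStack`: a T×Z×C×Y×X voxel grid with voxel
sizes in micrometres and an explicit frame interval and unit (seconds for
bleb movies, days for nodule series — units are always declared, never
inferred). Physical coordinates use the voxel-centre convention,
`(index - 1) * spacing`, and Z increases away from the substrate so the
dish bottom is the plane z = 0. This orientation is what "above the lowest
point of the SHG surface" and "below the cells" refer to throughout.

## SHG surface: volume and area

The SHG channel is median-filtered, thresholded (Otsu per timepoint by
default — the published analysis used interactive surface creation in
commercial software, so a deterministic default is required and the
threshold is always recorded), and components smaller than 50 voxels are
discarded. Volume is mask voxel count × voxel volume. Area comes from a
triangle mesh, not voxel faces: voxel-face area overestimates smooth
surfaces by up to ~50% and would bias every sphericity-type statistic
downstream. The mesh is extracted by marching tetrahedra on the Kuhn
(6-tetrahedra) cube decomposition at the 0.5 level of the Gaussian-smoothed
(σ = 0.5 µm) binary mask, padded with zeros so the surface closes at the
stack border. The Kuhn decomposition is translation-compatible, so the
mesh is watertight and a divergence-theorem volume is available as a
consistency check against the voxel-count volume (they agree within a few
per mill for convex bodies; an invariant test enforces 10%).

The smoothing scale is a real trade-off, chosen once on rasterized
ellipsoids before any acceptance measurement: larger σ rounds the rim of
flat (bone-lining-cell-like) shapes and loses area; smaller σ leaves
staircase area inflation. σ = 0.5 µm balances the sphere (slight
overestimate) against flat plates (slight underestimate) at the package's
default voxel sizes (0.25–0.5 µm in XY, 1 µm in Z).

## Cell morphometrics

Cells are segmented from the fluorescence channel by Otsu threshold, 3-D
connected components, and a seeded watershed that splits touching cells:
seeds are local maxima of the Gaussian-smoothed exact Euclidean distance
transform (anisotropy-aware), flooding happens on the negative distance.
Per cell: V = voxel count × voxel volume; A = marching-tetrahedra mesh
area of the region mask; Wadell sphericity ψ = π^(1/3) (6V)^(2/3) / A.
Semi-axes come from the second moments of the solid region: the covariance
eigenvalues of a solid ellipsoid satisfy λᵢ = axisᵢ²/5, so axisᵢ =
√(5λᵢ) is exact for the generator's cell model; diag(d²/12) is added to
the covariance to restore the within-voxel variance lost by using voxel
centres. Whether the original analysis derived its flatness indices from
moment eigenvalues or from a fitted ellipsoid is not stated; the moment
route is pinned here because it is closed-form and parameter-free.

The oblateness/prolateness formulas are likewise not printed in the
source analysis chain, so they are pinned by their limit behaviour:

* oblateness = 2(b − c)/(a + b − 2c): sphere → 0, disk → 1, rod → 0
* prolateness = 2(a − b)/(2a − b − c): sphere → 0, disk → 0, rod → 1

with both defined as 0 for a = b = c, both scale-invariant, both in [0, 1].
Cells touching the stack border are flagged `clipped` and excluded from
population statistics by default (toggle in `population_summary()`).

High sphericity is ψ ≥ 0.7 with an inclusive boundary — "0.7 or above" —
and the threshold is exposed (`classify_high_sphericity(records, 0.7)`).

## Compartments, crowding, subROIs

A cell is IN/ON iff its centroid falls inside the concave boundary polygon
of the XY-projected SHG surface vertices *and* its centroid height is at
or above the lowest point of the SHG surface; otherwise OUT. The concave
boundary is an alpha-shape whose `shrink` parameter interpolates between
the convex hull (shrink = 0) and the tightest single, hole-free ring that
still encloses every point (shrink = 1), emulating the usual
boundary-function contract; the default 0.5 mirrors a default the source
analysis does not print, and the chosen alpha is recorded on the polygon.
Centroids exactly on the polygon edge count as inside — a deterministic
tie rule matching the inclusive height rule. The alpha-shape, the
Bowyer–Watson Delaunay triangulation beneath it, and the winding-number
point-in-polygon test are implemented in-package because no computational
geometry package is available in the target environment; each is tested
against an independent oracle (convex-hull area conservation to 1e-9,
brute-force ray casting, the empty-circumcircle property).

Crowding is the mean Delaunay triangle area of IN/ON centroids projected
to XY (2-D by design: the published crowding readout is planar).
Zero-area triangles are excluded; fewer than 3 non-collinear points is an
explicit error. The subROI analysis divides the field into a 4×4 = 16
grid (an error if the grid does not tile the voxel field exactly), counts
high-sphericity IN/ON cells per tile by centroid, attributes the SHG
increase from t to t+1 to tiles by voxel XY position, and reports Spearman
rho with the standard strength bands (inclusive lower bounds): [0, 0.2)
little, [0.2, 0.4) weak, [0.4, 0.6) moderate, [0.6, 0.8) strong. The
published band table stops at 0.8; |rho| ≥ 0.8 is labelled "very strong"
as an explicit extension and flagged in the output. Whether the "SHG
increase" is volume or area is ambiguous in the source; volume is the
default with an `use = "area"` toggle.

## Bleb kinetics and polarity

2-D time-lapse: temporal minimum subtraction (`out[t] = in[t] − min over
t`) suppresses static content; the result is thresholded and per-frame
components ≥ 1 µm² are linked across consecutive frames by mask overlap
(largest overlap wins, nearest centroid breaks ties). Track duration is
(frames spanned) × frame interval; the area reported per frame is refined
to the half-peak (FWHM) footprint because the detection threshold sits
above the blur half-maximum and would otherwise bias areas low — for a
blurred disk the half-peak contour is the true disk boundary.

Two numerical points deserve emphasis. First, plain Otsu fails on
min-subtracted movies: bleb pixels are a ~0.05% minority, so the
between-class optimum lands inside the background mode. The automatic
threshold therefore first strips background at median + 4×MAD of the
subtracted movie and runs Otsu on the remaining candidates only; if those
are constant the midpoint rule applies. Second, track linking is overlap
based, not Kalman: blebs are short-lived and nearly stationary relative to
their host cell, so motion models add failure modes without benefit.

4-D: frame-by-frame differences (clipped at zero) highlight appearing
structures; each difference frame is scanned by scale-matched
difference-of-Gaussians spot detection at the expected bleb radius, and
spots are assigned to the nearest segmented host cell within 1.5× the
host's equivalent radius (ties to the lower cell id — deterministic).
Polarity angles from the host centre use atan2 in degrees within
[−180, 180): θ_xy = atan2(dy, dx), θ_zy = atan2(dz, dy), θ_zx =
atan2(dz, dx); 15° bin histograms per plane plus the fraction of spots
below the host centre (dz < 0). The 4-D spot "area" is the circle of the
detection scale and is recorded as an approximation: the published area is
a 2-D quantity.

## Motility

Greedy nearest-centroid linking with a displacement gate; mean speed =
mean consecutive step length / frame interval, reported in µm/h. Group
labels (on-matrix vs off-matrix) are carried from the compartment column.
A warning fires when mean track length falls below 3 frames (gate likely
smaller than typical motion).

## Statistics

One-way ANOVA with Tukey HSD (studentized range, Tukey–Kramer for
unbalanced groups), Spearman with the band table above, paired and
pooled-variance two-sample t-tests (α = 0.05), all checked against
brute-force sums-of-squares / closed-form oracles to 1e-10. The
Kolmogorov–Smirnov normality pre-check standardizes by estimated mean and
SD and is therefore reported with an explicit Lilliefors-bias caveat — the
source names KS without detail. Treatment time courses are summarized as
mean ± SE, everything else as mean ± SD, matching the published
conventions.

# The synthetic world

`scene_config()` returns the calibrated stated world per scenario; the
defaults are set once and are not tuned per run.

**Nodule series** (days 7, 10, 14, 21; 160×160×40 µm at 0.5×0.5×1 µm
voxels): the nodule is a half-ellipsoid dome whose volume follows a
logistic curve (3 parameters: initial fraction 0.04 of the field volume,
rate 0.35/day, saturation 0.12) — monotone growth whose increments shrink
at late times, as observed. On-matrix cells are solid triaxial ellipsoids
(every morphometric has a closed form) riding the dome surface; their
per-timepoint mean sphericity follows the schedule 0.7026 → 0.65 → 0.58 →
0.50, i.e. the first timepoint is calibrated to the published population
average of 0.7026, with per-cell deviations (SD 0.06) centred so the
realized mean equals the schedule exactly. Shapes are solved by root
finding: given target ψ, volume (1200 ± 150 µm³) and in-plane aspect
(1–1.3), the flattening c/b is the unique root of ψ(q) computed with a
numerical-quadrature ellipsoid area (relative error < 1e-6). Off-matrix
cells are flat (ψ = 0.45) and sit on the dish outside the final nodule
footprint. Cells at sphericity 0.70 and volume 1200 µm³ are ~22 µm wide,
so a confluent nodule surface cannot host non-touching random placements;
on-matrix cells are therefore laid out on a jittered golden-angle
(sunflower) spiral over the first-day footprint — crowded, quasi-regular
coverage like a real nodule — and the seeded watershed handles the
residual contacts. A configured density that would force spacing below
8 µm fails with an explicit error, as does rejection placement for
off-matrix cells and lacunae.

Lacunae are spheres (radius 2.5 µm) carved out of the SHG signal at fixed
positions inside the first-day dome, fully covered by matrix (≥ 2 µm).
Fixed positions make the lacuna Delaunay control meaningful: the mean
triangle area of lacuna spots must stay flat over time while the cell
crowding measure changes. At the first (day-7-like) timepoint the dome is
small and shallow, and the extractor recovers only part of the set — the
same behaviour that led the original analysis to start lacuna
quantification at day 10; the recovery tests therefore probe the second
timepoint onward.

**Bleb movie** (96×96 µm, 0.25 µm pixels, 60 frames at 15 s): cells are
static ellipse footprints (drift-corrected clips); bleb events per cell
form a Poisson process with continuous, uniform birth instants. Durations
are log-normal with mean 27 s (sdlog 0.5), maximum areas gamma with mean
5 µm² (shape 4) — positive and right-skewed like the published histograms;
the exact families are free choices recorded in the config. A bleb holds
its maximum footprint for its whole lifetime (expansion and retraction are
fast relative to 15-s sampling) and is rendered tangent to the cell
boundary, fully protruding — a bleb is a membrane protrusion, and any part
overlapping the static cell body would be invisible to min-subtraction.
An event is rendered in exactly the frames whose sampling instants fall
inside [t₀, t₀ + duration); with uniform phase the expected rendered span
equals the true duration, so frame quantization is unbiased. Events whose
lifetime covers no sampling instant stay in the ground truth flagged
`rendered = FALSE` with a reason — skipped and logged, never silently
dropped. Concurrent blebs on one cell are capped (2) and kept ≥ 60° apart
so components never merge.

**4-D bleb stack** (64×64×30 µm — the published 30 µm Z-stack — 12 frames
at 20 s, within the "no more than 27 s" per-frame constraint): cells are
substrate-attached domes; bleb direction vectors are uniform on the unit
sphere outside the exclusion zone (default: the lower hemisphere,
modelling the substrate-contact surface), so ground-truth directions all
have uz ≥ 0.

**Drug-response experiment** (days 0, 3, 7, 14 after treatment): one call
generates one arm. The vehicle schedule keeps flat cells (ψ = 0.45); the
treated schedule rises to 0.70/0.68 at days 3 and 7 and returns to 0.46 at
day 14 (within the declared 0.03 baseline tolerance), while matrix growth
gets a rate ×1.8 and saturation ×1.25 boost anchored at the same day-0
volume, so treated SHG ≥ vehicle at every timepoint by construction. The
morphology change also drives the MIP SHG/EGFP area-ratio readout in the
right direction mechanically: cuboidal cells have smaller XY footprints.

**Optics and noise**: each channel is blurred with a small Gaussian
(0.3–0.5 µm — a simple stand-in, not a measured PSF), offset by a 0.02
background, optionally Poisson-resampled, and given additive Gaussian
noise (SD 0.03–0.04), then clamped nonnegative. The default SNR is chosen
so Otsu-style thresholding is reliable; the generator is a testbed for the
estimators, not a camera model.

**Determinism**: every generator call runs under a locally seeded RNG
(config seed), so identical config + seed reproduces stacks bit for bit
without disturbing the caller's random stream.

## What a green test does and does not establish

The generator produces smooth, parametric objects with stationary noise.
Green recovery tests establish that the estimators are unbiased and
correctly calibrated *on that world* — they do not establish robustness to
real-tissue artefacts the generator deliberately omits: depth-dependent
attenuation and scattering, anisotropic PSF tails, dendritic processes,
matrix texture, segmentation-relevant intensity heterogeneity within
cells, stage drift (the registration module is tested on constructed
shifts instead), or photobleaching. Those are documented non-goals.

# Numerical choices and degenerate inputs

* Thresholding: constant images have no Otsu threshold → empty masks, with
  the empty-SHG case warned as a valid early-timepoint outcome.
* Median filter / CLAHE edges: reflection; CLAHE is tile-local histogram
  equalization (256 bins) with a clip limit as a fraction of tile pixels,
  excess redistributed uniformly, bilinear blending between tiles; a
  constant tile maps to a constant.
* Registration is translation-only (FFT cross-correlation, integer
  voxels): the published correction was manual rigid adjustment; there is
  no evidence of rotation.
* Delaunay: exact duplicate points are collapsed; all-collinear input is
  an explicit error; the incircle test uses a relative 1e-12 tolerance,
  adequate for measurement coordinates (the suite checks hull-area
  conservation to 1e-9 and the empty-circumcircle property).
* Watershed flooding order is made deterministic by FIFO tie-breaking in
  the priority queue.
* t-tests on constant data return t = 0, p = 1 rather than erroring, so
  degenerate-but-valid pipeline outputs don't abort reports; ANOVA with
  zero between-group signal returns F = 0, p = 1.

# Known limitations

* Sphericity of very flat cells (ψ ≲ 0.5, thickness ~2 µm at 1 µm Z
  steps) is measured with a positive bias of a few hundredths — the
  thin-rim geometry is at the resolution limit; the acceptance-calibrated
  first-timepoint population (ψ ≈ 0.70) is well inside the accurate
  regime.
* The 2-D bleb tracker does not handle blebs that overlap the same pixels
  in immediately consecutive events; the generator's angular-separation
  rule mirrors the biological spacing but real movies may merge events.
* The alpha-shape parameterization emulates the usual boundary-function
  contract but is not a bug-for-bug copy of any specific implementation;
  its `shrink` default (0.5) is a package choice, exposed and logged.
* Embedded-osteocyte dendrites (qualitative in the source) are not
  modelled or measured.
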