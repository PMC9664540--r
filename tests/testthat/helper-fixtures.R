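# Shared fixtures, memoised so expensive synthetic scenes are generated once
# per test run, and small independent oracles used across files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_bleb_scene <- function() {
  memo("bleb", generate_bleb_movie(scene_config("bleb", seed = 7)))
}

default_bleb_detection <- function() {
  memo("bleb_det", detect_blebs_2d(default_bleb_scene()$stack))
}

default_nodule_scene <- function() {
  memo("nodule", generate_nodule_timecourse(scene_config("nodule", seed = 1)))
}

default_nodule_surfaces <- function() {
  memo("nodule_surf", {
    st <- default_nodule_scene()$stack
    lapply(1:2, function(t) segment_shg(st, "SHG", t))
  })
}

default_nodule_records_t1 <- function() {
  memo("nodule_rec1", {
    gen <- default_nodule_scene()
    cells <- segment_cells(gen$stack, "EGFP", 1)
    rec <- measure_cells(cells, t = 1)
    rec <- classify_compartment(rec, default_nodule_surfaces()[[1]])
    classify_high_sphericity(rec)
  })
}

default_bleb4d_scene <- function() {
  memo("bleb4d", generate_bleb_movie(scene_config("bleb4d", seed = 5)))
}

default_bleb4d_analysis <- function() {
  memo("bleb4d_an", {
    gen <- default_bleb4d_scene()
    cells <- segment_cells(gen$stack, "EGFP", 1)
    hosts <- measure_cells(cells)
    spots <- detect_blebs_4d(gen$stack, hosts)
    list(hosts = hosts, spots = spots,
         polarity = bleb_polarity(spots, hosts))
  })
}

default_bio_pair <- function() {
  memo("bio_pair", {
    lac <- list(density_per_um3 = 0, count = 4L, radius_um = 2.5,
                min_dist_um = 7)
    cfgT <- scene_config("bio", seed = 4, treatment = TRUE, lacunae = lac,
                         grid = c(T = 4L, Z = 32L, Y = 256L, X = 256L))
    cfgV <- scene_config("bio", seed = 4, treatment = FALSE, lacunae = lac,
                         grid = c(T = 4L, Z = 32L, Y = 256L, X = 256L))
    list(treated = generate_bio_experiment(cfgT),
         vehicle = generate_bio_experiment(cfgV),
         config = cfgT)
  })
}

# small scene configs for fast structural tests
tiny_nodule_config <- function(seed = 3, ...) {
  scene_config("nodule", seed = seed,
    grid = c(T = 2L, Z = 28L, Y = 160L, X = 160L),
    days = c(7, 10),
    cells = list(n_on = 5L, n_off = 3L, volume_um3 = 900, volume_sd = 100,
                 min_dist_um = 14, aspect_range = c(1, 1.2),
                 footprint_frac = 0.8, max_tries = 500L),
    morphology = list(psi_on = c(0.7026, 0.65), psi_off = 0.45,
                      psi_sd = 0.05, psi_clip = c(0.35, 0.96)),
    growth = list(init_frac = 0.05, rate = 0.35, sat_frac = 0.12,
                  aspect_b = 0.9, height_frac = 0.35),
    lacunae = list(density_per_um3 = 0, count = 0L, radius_um = 2.5,
                   min_dist_um = 7),
    ...)
}

small_bleb_config <- function(seed = 3, rate = 0.25, T = 20L, n_on = 3L,
                              ...) {
  scene_config("bleb", seed = seed,
    grid = c(T = T, Z = 1L, Y = 256L, X = 256L),
    cells = list(n_on = n_on, n_off = 0L, radius_range_um = c(5, 6),
                 aspect_range = c(1, 1.15), min_gap_um = 6,
                 max_tries = 1000L),
    blebs = list(rate_per_cell_frame = rate, duration_mean_s = 27,
                 duration_sdlog = 0.5, area_mean_um2 = 5, area_shape = 4,
                 exclusion = "none", min_angle_sep_deg = 60,
                 max_concurrent = 2L),
    ...)
}

# rasterize one axis-aligned-z ellipsoid into a fresh padded volume
raster_ellipsoid <- function(axes, vx = c(dx = 1, dy = 1, dz = 1), phi = 0,
                             pad = 4) {
  d <- c(ceiling(2 * (axes[1] + pad) / vx[["dy"]]),
         ceiling(2 * (axes[1] + pad) / vx[["dx"]]),
         ceiling(2 * (axes[3] + pad) / vx[["dz"]]))
  ctr <- c(d[2] / 2 * vx[["dx"]], d[1] / 2 * vx[["dy"]], d[3] / 2 * vx[["dz"]])
  vol <- array(0, dim = d)
  nodule4d:::add_ellipsoid(vol, vx, ctr, axes, phi, 1) > 0.5
}

# independent even-odd ray-casting point-in-polygon oracle (per point loop)
ray_cast_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}
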