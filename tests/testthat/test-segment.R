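# segment: SHG surface model, cell labeling with watershed, lacuna
# extraction, spot detection.

test_that("segment_shg on a rasterized ball recovers the closed-form volume and area", {
  vol <- array(0, dim = c(48, 48, 48))
  vol <- nodule4d:::add_ellipsoid(vol, c(dx = 1, dy = 1, dz = 1),
                                  c(24, 24, 24), c(20, 20, 20), 0, 1)
  surf <- segment_shg(vol, threshold = 0.5, median_radius = 0,
                      voxel_size = c(dx = 1, dy = 1, dz = 1))
  V_true <- 4 / 3 * pi * 20^3
  A_true <- 4 * pi * 400
  expect_lt(abs(surf$volume_um3 - V_true) / V_true, 0.05)
  expect_lt(abs(surf$area_um2 - A_true) / A_true, 0.10)
  # mesh-derived and voxel-count volumes agree for convex bodies
  expect_lt(abs(surf$mesh_volume_um3 / surf$volume_um3 - 1), 0.10)
  expect_equal(surf$z_min_um, 4)       # ball spans physical z in [4, 44]
  expect_equal(max(surf$height_map, na.rm = TRUE), 44)
})

test_that("empty SHG channel gives a zero surface with a warning", {
  z <- array(0, dim = c(16, 16, 8))
  expect_warning(surf <- segment_shg(z, median_radius = 0,
                                     voxel_size = c(dx = 1, dy = 1, dz = 1)),
                 "empty")
  expect_equal(surf$volume_um3, 0)
  expect_equal(surf$area_um2, 0)
})

test_that("volume and area estimators are consistent under voxel rescaling", {
  ax <- c(12, 9, 7)
  s1 <- segment_shg(raster_ellipsoid(ax, c(dx = 1, dy = 1, dz = 1)) * 1,
                    threshold = 0.5, median_radius = 0,
                    voxel_size = c(dx = 1, dy = 1, dz = 1))
  s2 <- segment_shg(raster_ellipsoid(ax, c(dx = 0.5, dy = 0.5, dz = 0.5)) * 1,
                    threshold = 0.5, median_radius = 0,
                    voxel_size = c(dx = 0.5, dy = 0.5, dz = 0.5))
  expect_lt(abs(s1$volume_um3 / s2$volume_um3 - 1), 0.05)
  expect_lt(abs(s1$area_um2 / s2$area_um2 - 1), 0.05)
})

test_that("measured SHG volume is nondecreasing over the synthetic series", {
  st <- default_nodule_scene()$stack
  v <- vapply(seq_len(stack_dim(st)[["T"]]), function(t)
    segment_shg(st, "SHG", t)$volume_um3, numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("segment_cells separates and splits cells", {
  vx <- c(dx = 1, dy = 1, dz = 1)
  two <- array(0, dim = c(64, 64, 24))
  two <- nodule4d:::add_ellipsoid(two, vx, c(18, 20, 12), c(9, 7, 5), 0.2, 1)
  two <- nodule4d:::add_ellipsoid(two, vx, c(46, 44, 12), c(8, 7, 6), 1.1, 1)
  lc <- segment_cells(two, threshold = 0.5, voxel_size = vx)
  expect_equal(length(lc$sizes), 2L)
  # ~10% overlapping pair still splits into two by the seeded watershed
  ov <- array(0, dim = c(64, 64, 24))
  ov <- nodule4d:::add_ellipsoid(ov, vx, c(24, 32, 12), c(8, 8, 6), 0, 1)
  ov <- nodule4d:::add_ellipsoid(ov, vx, c(38, 32, 12), c(8, 8, 6), 0, 1)
  lc2 <- segment_cells(ov, threshold = 0.5, voxel_size = vx)
  expect_equal(length(lc2$sizes), 2L)
  # zero cells allowed
  lc0 <- segment_cells(array(0, dim = c(16, 16, 4)), threshold = 0.5,
                       voxel_size = vx)
  expect_equal(length(lc0$sizes), 0L)
})

test_that("synthetic scene cell count is recovered within 10%", {
  gen <- default_nodule_scene()
  lc <- segment_cells(gen$stack, "EGFP", 1)
  n_true <- sum(gen$truth$cells$t == 1)
  expect_lte(abs(length(lc$sizes) - n_true), ceiling(0.1 * n_true))
})

test_that("lacuna voids are recovered at the paper's starting timepoint with matched centroids", {
  cfg <- scene_config("nodule", seed = 9)
  cfg$lacunae$count <- 12L
  gen <- memo("lacuna_scene", generate_nodule_timecourse(cfg))
  lac <- extract_lacunae(gen$stack, "SHG", t = 2)
  truth <- gen$truth$lacunae
  expect_gte(nrow(lac), 11L)
  expect_lte(nrow(lac), 13L)
  dmin <- vapply(seq_len(nrow(lac)), function(i)
    min(sqrt((truth$x - lac$x[i])^2 + (truth$y - lac$y[i])^2 +
             (truth$z - lac$z[i])^2)), numeric(1))
  expect_true(all(dmin <= 2))
  # without voids: empty list
  cfg0 <- tiny_nodule_config(seed = 6)
  gen0 <- memo("lacuna_free_scene", generate_nodule_timecourse(cfg0))
  lac0 <- extract_lacunae(gen0$stack, "SHG", t = 2)
  expect_equal(nrow(lac0), 0L)
})

test_that("dark spots outside the SHG mask are not lacunae", {
  vx <- c(dx = 1, dy = 1, dz = 1)
  vol <- array(0.05, dim = c(80, 80, 24))
  vol <- nodule4d:::add_ellipsoid(vol, vx, c(40, 40, 0), c(25, 25, 12), 0, 0.9)
  vol <- nodule4d:::carve_sphere(vol, vx, c(40, 40, 6), 3, 0)   # true void
  vol <- nodule4d:::carve_sphere(vol, vx, c(10, 10, 6), 3, 0)   # background dark spot
  set.seed(2)
  vol <- vol + array(rnorm(length(vol), 0, 0.02), dim = dim(vol))
  vol[vol < 0] <- 0
  lac <- extract_lacunae(vol, voxel_size = vx)
  expect_equal(nrow(lac), 1L)
  expect_lt(sqrt((lac$x - 40)^2 + (lac$y - 40)^2 + (lac$z - 6)^2), 2)
})

test_that("spot detection localizes Gaussian blobs to sub-voxel accuracy", {
  vx <- c(dx = 1, dy = 1, dz = 1)
  d <- c(40, 40, 20)
  grid_y <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  grid_x <- array(rep(rep(seq_len(d[2]), each = d[1]), d[3]), dim = d)
  grid_z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  blob <- function(cy, cx, cz, s)
    exp(-((grid_y - cy)^2 + (grid_x - cx)^2 + (grid_z - cz)^2) / (2 * s^2))
  r <- 3
  one <- blob(20, 22, 10, r / sqrt(3))
  sp <- detect_spots(one, r, vx)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x - 21), 0.5)       # (22 - 1) * dx
  expect_lt(abs(sp$y - 19), 0.5)
  expect_lt(abs(sp$z - 9), 0.5)
  # empty volume: no spots
  expect_equal(nrow(detect_spots(array(0, dim = d), r, vx)), 0L)
  # two blobs separated by 3x radius resolve as two spots
  two <- blob(20, 15, 10, r / sqrt(3)) + blob(20, 24, 10, r / sqrt(3))
  expect_equal(nrow(detect_spots(two, r, vx)), 2L)
  expect_error(detect_spots(one, -1, vx), "positive")
})
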