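# spatial: compartment classification, subROI correlation, MIP ratio,
# crowding controls.

make_surface <- function(mask, vx = c(dx = 1, dy = 1, dz = 1)) {
  # minimal SurfaceModel for constructed fixtures
  segment_shg(mask * 1, threshold = 0.5, median_radius = 0, voxel_size = vx)
}

test_that("classify_compartment applies the polygon rule and the height clause", {
  vx <- c(dx = 1, dy = 1, dz = 1)
  dome <- array(0, dim = c(60, 60, 24))
  # matrix slab floating between z = 8 and z = 15 so z_min is informative
  dome[20:40, 20:40, 9:16] <- 1
  surf <- make_surface(dome, vx)
  expect_equal(surf$z_min_um, 8)
  rec <- data.frame(id = 1:4, t = 1L,
                    x = c(29, 29, 5, 29),
                    y = c(29, 29, 5, 58),
                    z = c(12, 2, 12, 12))
  out <- classify_compartment(rec, surf, shrink = 0.3)
  expect_identical(out$compartment,
                   c("IN/ON",   # inside footprint, above z_min
                     "OUT",     # inside footprint but below z_min
                     "OUT",     # outside footprint
                     "OUT"))    # outside footprint, above z_min
  # empty surface: everything OUT with a warning
  suppressWarnings(empty <- segment_shg(array(0, dim = c(8, 8, 4)),
                                        median_radius = 0, voxel_size = vx))
  expect_warning(out2 <- classify_compartment(rec, empty), "empty")
  expect_true(all(out2$compartment == "OUT"))
})

test_that("IN/ON count is non-increasing in the boundary shrink parameter", {
  gen <- default_nodule_scene()
  surf <- default_nodule_surfaces()[[1]]
  rec <- default_nodule_records_t1()
  counts <- vapply(c(0, 0.5, 1), function(s)
    sum(classify_compartment(rec, surf, shrink = s)$compartment == "IN/ON"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("subROI partition is exactly 16 tiles and rejects non-tiling grids", {
  surfs <- default_nodule_surfaces()
  rec <- default_nodule_records_t1()
  sr <- subroi_correlation(rec, surfs[[1]], surfs[[2]])
  expect_equal(nrow(sr$table), 16L)
  expect_true(all(sr$table$n_high_sphericity >= 0))
  expect_error(subroi_correlation(rec, surfs[[1]], surfs[[2]],
                                  grid = c(3L, 7L)), "tile")
})

test_that("subROI correlation detects coupling and stays small under independence", {
  vx <- c(dx = 1, dy = 1, dz = 1)
  d <- c(64, 64, 8)
  base <- array(FALSE, dim = d)
  rho_coupled <- rho_null <- numeric(0)
  set.seed(17)
  for (rep in 1:15) {
    m0 <- base
    m1 <- base
    counts <- integer(16)
    k <- 0
    recs <- NULL
    for (r in 1:4) for (cl in 1:4) {
      k <- k + 1
      n_cells <- rpois(1, 2)
      counts[k] <- n_cells
      ys <- (r - 1) * 16 + seq_len(16)
      xs <- (cl - 1) * 16 + seq_len(16)
      m0[ys, xs, 1:2] <- TRUE
      # coupled growth: new matrix proportional to the cell count + noise
      grow <- min(6, n_cells + sample(0:1, 1))
      if (grow > 0) m1[ys, xs, 1:(2 + grow)] <- TRUE else
        m1[ys, xs, 1:2] <- TRUE
      if (n_cells > 0)
        recs <- rbind(recs, data.frame(
          x = runif(n_cells, min(xs) - 1, max(xs) - 1),
          y = runif(n_cells, min(ys) - 1, max(ys) - 1),
          z = 3, compartment = "IN/ON", high_sphericity = TRUE))
    }
    s0 <- make_surface(m0, vx)
    s1 <- make_surface(m1, vx)
    sr <- subroi_correlation(recs, s0, s1)
    rho_coupled <- c(rho_coupled, sr$rho)
    # independent growth: same counts, growth shuffled across tiles
    m1i <- base
    k <- 0
    grow_perm <- sample(counts)
    for (r in 1:4) for (cl in 1:4) {
      k <- k + 1
      ys <- (r - 1) * 16 + seq_len(16)
      xs <- (cl - 1) * 16 + seq_len(16)
      g <- min(6, grow_perm[k])
      m1i[ys, xs, 1:(2 + max(g, 0))] <- TRUE
    }
    sri <- subroi_correlation(recs, s0, make_surface(m1i, vx))
    rho_null <- c(rho_null, sri$rho)
  }
  expect_gte(mean(rho_coupled, na.rm = TRUE), 0.4)    # "moderate" band
  expect_lt(abs(mean(rho_null, na.rm = TRUE)), 0.2)   # "little" in expectation
})

test_that("mip_ratio: identical masks give 1, half coverage gives 0.5, empty EGFP errors", {
  arr <- array(0, dim = c(32, 32, 4, 2, 1))
  arr[9:24, 9:24, 2, 1, 1] <- 1        # EGFP square
  arr[9:24, 9:24, 3, 2, 1] <- 1        # identical SHG square
  st <- image_stack(arr, channels = c("EGFP", "SHG"))
  expect_equal(mip_ratio(st, threshold = 0.5), 1)
  arr2 <- arr
  arr2[, , , 2, ] <- 0
  arr2[9:24, 9:16, 3, 2, 1] <- 1       # SHG covers half the EGFP footprint
  st2 <- image_stack(arr2, channels = c("EGFP", "SHG"))
  expect_equal(mip_ratio(st2, threshold = 0.5), 0.5)
  arr3 <- arr
  arr3[, , , 1, ] <- 0
  st3 <- image_stack(arr3, channels = c("EGFP", "SHG"))
  expect_error(mip_ratio(st3, threshold = 0.5), "EGFP")
})

test_that("treated MIP ratio change dominates vehicle at intermediate timepoints and relaxes at the end", {
  pair <- default_bio_pair()
  mrT <- mip_ratio_series(pair$treated$stack)
  mrV <- mip_ratio_series(pair$vehicle$stack)
  expect_gt(mrT$change[2], mrV$change[2])
  expect_gt(mrT$change[3], mrV$change[3])
  expect_lt(mrT$change[4], max(mrT$change[2:3]))  # back toward baseline
})

test_that("lacuna crowding control: fixed lacuna positions give stable Delaunay means over time", {
  gen <- memo("lacuna_scene", {
    cfg <- scene_config("nodule", seed = 9)
    cfg$lacunae$count <- 12L
    generate_nodule_timecourse(cfg)
  })
  means <- vapply(2:4, function(t)
    delaunay_mean_area(extract_lacunae(gen$stack, "SHG", t = t))$mean_area,
    numeric(1))
  expect_lt((max(means) - min(means)) / mean(means), 0.10)
})
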