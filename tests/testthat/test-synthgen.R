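# synthgen: scene configuration contracts, determinism, ground-truth
# consistency, scenario-specific behavior.

test_that("scene_config validates invariants", {
  expect_s3_class(scene_config("nodule"), "SceneConfig")
  expect_error(scene_config("nodule", grid = c(T = 1L, Z = 4L, Y = 8L, X = 8L)),
               "T >= 2")
  expect_error(scene_config("nodule", voxel_size = c(dx = 0, dy = 1, dz = 1)),
               "positive")
  bad <- scene_config("nodule")
  bad$morphology$psi_on <- c(1.2, 0.6, 0.5, 0.4)
  expect_error(validate_scene_config(bad), "\\(0, 1\\]")
})

test_that("identical seed and config reproduce the stack bit-for-bit", {
  cfg <- tiny_nodule_config(seed = 13)
  g1 <- generate_nodule_timecourse(cfg)
  g2 <- generate_nodule_timecourse(cfg)
  expect_identical(g1$stack$data, g2$stack$data)
  expect_identical(g1$truth$cells, g2$truth$cells)
  g3 <- generate_nodule_timecourse(tiny_nodule_config(seed = 14))
  expect_false(identical(g1$stack$data, g3$stack$data))
})

test_that("nodule ground truth: monotone growth, calibrated first-timepoint sphericity, conservation", {
  gen <- default_nodule_scene()
  tp <- gen$truth$timepoints
  expect_true(all(diff(tp$shg_volume_um3) >= 0))
  cells <- gen$truth$cells
  inon1 <- cells[cells$t == 1 & cells$compartment == "IN/ON", ]
  expect_equal(mean(inon1$psi), 0.7026, tolerance = 1e-3)
  # schedule declines for on-matrix cells
  psi_by_t <- tapply(cells$psi[cells$compartment == "IN/ON"],
                     cells$t[cells$compartment == "IN/ON"], mean)
  expect_true(all(diff(psi_by_t) < 0))
  # conservation: every configured object appears exactly once per timepoint
  cfg <- gen$truth$config
  expect_equal(nrow(inon1), cfg$cells$n_on)
  expect_equal(sum(cells$t == 1), cfg$cells$n_on + cfg$cells$n_off)
  expect_equal(anyDuplicated(cells[, c("t", "id")]), 0L)
  # semi-axes sorted and psi consistent with the recorded V and A
  expect_true(all(cells$a >= cells$b & cells$b >= cells$c & cells$c > 0))
  expect_equal(cells$psi,
               wadell_sphericity(cells$volume_um3, cells$area_um2))
})

test_that("rendered SHG voxel volume matches ground truth within 10%", {
  gen <- default_nodule_scene()
  surf <- default_nodule_surfaces()[[1]]
  expect_lt(abs(surf$volume_um3 / gen$truth$timepoints$shg_volume_um3[1] - 1),
            0.10)
})

test_that("zero-cell config renders an SHG-only stack", {
  cfg <- tiny_nodule_config(seed = 5)
  cfg$cells$n_on <- 0L
  cfg$cells$n_off <- 0L
  gen <- generate_nodule_timecourse(cfg)
  expect_equal(nrow(gen$truth$cells), 0L)
  egfp <- get_frame(gen$stack, 1, "EGFP")
  shg <- get_frame(gen$stack, 1, "SHG")
  expect_lt(max(egfp), 0.3)            # background + noise only
  expect_gt(max(shg), 0.5)
})

test_that("overcrowded configs fail with an error naming the density", {
  cfg <- tiny_nodule_config(seed = 5)
  cfg$cells$n_off <- 80L
  expect_error(generate_nodule_timecourse(cfg), "density")
  cfg2 <- tiny_nodule_config(seed = 5)
  cfg2$cells$n_on <- 200L
  expect_error(generate_nodule_timecourse(cfg2), "density")
})

test_that("bleb movie: quiescent mode is static, kinetics match the configured sampler", {
  q <- small_bleb_config(seed = 3, rate = 0, T = 8L)
  gen <- generate_bleb_movie(q)
  expect_equal(nrow(gen$truth$blebs), 0L)
  mov <- get_movie(gen$stack, "EGFP")
  # static up to noise: every frame equals frame 1 within noise amplitude
  spread <- max(abs(mov[, , , 5] - mov[, , , 1]))
  expect_lt(spread, 8 * q$noise$gaussian_sd)
  # law of large numbers on the duration sampler (>= 100 events)
  gen2 <- default_bleb_scene()
  tr <- gen2$truth$blebs
  expect_gte(nrow(tr), 80)
  se <- sd(tr$duration_s) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$duration_s) - 27), 2 * se + 1e-9)
  # direct-sampling oracle for the same lognormal parameterization
  set.seed(99)
  oracle <- rlnorm(20000, log(27) - 0.5^2 / 2, 0.5)
  expect_lt(abs(mean(oracle) - 27) / 27, 0.02)
})

test_that("bleb events respect the exclusion zone and sub-frame events are flagged, not dropped", {
  gen <- default_bleb4d_scene()
  tr <- gen$truth$blebs
  expect_true(all(tr$uz >= 0))                   # lower hemisphere excluded
  norms <- sqrt(tr$ux^2 + tr$uy^2 + tr$uz^2)
  expect_equal(norms, rep(1, nrow(tr)), tolerance = 1e-12)
  # short-duration events: present in the table, flagged un-rendered
  cfg <- small_bleb_config(seed = 8, rate = 0.4, T = 15L)
  cfg$blebs$duration_mean_s <- 5        # mostly below the 15-s frame interval
  gen2 <- generate_bleb_movie(cfg)
  tr2 <- gen2$truth$blebs
  expect_gt(sum(!tr2$rendered), 0)
  expect_true(all(nzchar(tr2$skip_reason[!tr2$rendered])))
  expect_true(all(is.na(tr2$last_frame[!tr2$rendered])))
})

test_that("bio experiment: treated sphericity transient and matrix boost", {
  pair <- default_bio_pair()
  gt <- pair$treated
  gv <- pair$vehicle
  cfgT <- pair$config
  mpsi <- function(tr, t)
    mean(tr$cells$psi[tr$cells$t == t & tr$cells$compartment == "IN/ON"])
  # treated > vehicle at intermediate timepoints
  expect_gt(mpsi(gt$truth, 2), mpsi(gv$truth, 2))
  expect_gt(mpsi(gt$truth, 3), mpsi(gv$truth, 3))
  # final timepoint returns to baseline within the schedule tolerance
  tol <- cfgT$morphology$baseline_tol
  expect_lt(abs(mpsi(gt$truth, 4) - cfgT$morphology$psi_on[1]), tol)
  # boosted growth dominates at every timepoint
  expect_true(all(gt$truth$timepoints$shg_volume_um3 >=
                    gv$truth$timepoints$shg_volume_um3))
})
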