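# blebmot: 2-D bleb tracking, 4-D spot extraction, polarity, motility.

test_that("static movies yield zero bleb tracks, also when time-reversed", {
  set.seed(44)
  frame <- array(0, dim = c(64, 64, 1))
  frame <- nodule4d:::add_ellipsoid(frame, c(dx = 0.25, dy = 0.25, dz = 1),
                                    c(8, 8, 0), c(4, 4, 1), 0, 1)
  mov <- array(0, dim = c(64, 64, 1, 8))
  for (t in 1:8)
    mov[, , , t] <- frame + array(abs(rnorm(64 * 64, 0.02, 0.01)),
                                  dim = dim(frame))
  det <- detect_blebs_2d(mov, voxel_size = c(dx = 0.25, dy = 0.25, dz = 1),
                         frame_interval_s = 15)
  expect_equal(nrow(det$tracks), 0L)
  rev_det <- detect_blebs_2d(mov[, , , 8:1, drop = FALSE],
                             voxel_size = c(dx = 0.25, dy = 0.25, dz = 1),
                             frame_interval_s = 15)
  expect_equal(nrow(rev_det$tracks), 0L)
})

test_that("a constructed 5-frame bleb yields one track with duration 75 s", {
  vx <- c(dx = 0.25, dy = 0.25, dz = 1)
  base <- array(0, dim = c(96, 96, 1))
  base <- nodule4d:::add_ellipsoid(base, vx, c(10, 10, 0), c(5, 5, 1), 0, 1)
  bleb <- nodule4d:::add_ellipsoid(base, vx, c(16.5, 10, 0),
                                   c(1.26, 1.26, 1), 0, 1)
  mov <- array(0, dim = c(96, 96, 1, 12))
  for (t in 1:12) mov[, , , t] <- if (t %in% 4:8) bleb else base
  det <- detect_blebs_2d(mov, voxel_size = vx, frame_interval_s = 15)
  expect_equal(nrow(det$tracks), 1L)
  expect_equal(det$tracks$n_frames, 5L)
  expect_equal(det$tracks$duration_s, 75)
  expect_lt(abs(det$tracks$max_area_um2 - pi * 1.26^2) / (pi * 1.26^2), 0.25)
  # duration histogram invariant to frame re-indexing offsets
  mov2 <- mov[, , , c(3:12, 1:2), drop = FALSE]
  det2 <- detect_blebs_2d(mov2, voxel_size = vx, frame_interval_s = 15)
  expect_equal(sort(det2$tracks$duration_s), sort(det$tracks$duration_s))
})

test_that("default bleb movie: duration within 15% and good recall/precision against ground truth", {
  gen <- default_bleb_scene()
  truth <- gen$truth$blebs
  truth <- truth[truth$rendered, ]
  det <- default_bleb_detection()
  expect_lt(abs(mean(det$tracks$duration_s) - 27) / 27, 0.15)
  # spatiotemporal matching: a detection matches a true event if it
  # overlaps its frame span and sits within 4 um of the bleb position
  cells <- gen$truth$cells
  tr_pos <- gen$truth$tracks
  pos_of <- function(e) {
    cc <- cells[cells$id == e$cell, ]
    rb <- sqrt(e$max_area_um2 / pi)
    th <- atan2(e$uy, e$ux)
    c(cc$x + (cc$radius_um + rb) * cos(th),
      cc$y + (cc$radius_um + rb) * sin(th))
  }
  matched_truth <- logical(nrow(truth))
  matched_det <- logical(nrow(det$tracks))
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    p <- pos_of(e)
    cand <- which(!matched_det &
                    det$tracks$birth_frame <= e$last_frame + 2 &
                    (det$tracks$birth_frame + det$tracks$n_frames) >=
                      e$first_frame &
                    sqrt((det$tracks$x - p[1])^2 +
                         (det$tracks$y - p[2])^2) < 4)
    if (length(cand)) {
      matched_truth[i] <- TRUE
      matched_det[cand[1]] <- TRUE
    }
  }
  recall <- mean(matched_truth)
  precision <- mean(matched_det)
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
})

test_that("4-D bleb spots: none without events, host assignment, deterministic ties", {
  an <- default_bleb4d_analysis()
  gen <- default_bleb4d_scene()
  expect_gt(nrow(an$spots), 0)
  expect_true(all(!is.na(an$spots$cell)))
  # per-cell assignment recovers the host: most spots of the busiest cell
  busiest <- as.integer(names(which.max(table(gen$truth$blebs$cell))))
  truth_cell <- gen$truth$cells[busiest, ]
  near <- sqrt((an$spots$x - truth_cell$x)^2 +
               (an$spots$y - truth_cell$y)^2) < 1.6 * truth_cell$radius_um + 3
  agree <- an$spots$cell[near]
  host_xy <- an$hosts[match(agree, an$hosts$id), ]
  dd <- sqrt((host_xy$x - truth_cell$x)^2 + (host_xy$y - truth_cell$y)^2)
  expect_gte(mean(dd < 5), 0.8)
  # no cells segmented -> explicit error
  expect_error(detect_blebs_4d(gen$stack, hosts = data.frame()), "no cells")
  # tie-break: an appearing blob equidistant to two hosts goes to the
  # lower cell id
  vx <- c(dx = 1, dy = 1, dz = 1)
  d <- c(24, 24, 12)
  mov <- array(0, dim = c(d, 2))
  blob <- array(0, dim = d)
  blob <- nodule4d:::add_ellipsoid(blob, vx, c(11, 5, 5), c(1.4, 1.4, 1.4),
                                   0, 1)
  mov[, , , 2] <- blob
  hosts <- data.frame(id = c(7L, 2L), x = c(3, 19), y = c(5, 5), z = c(5, 5),
                      volume_um3 = rep(4 / 3 * pi * 6^3, 2))
  sp <- detect_blebs_4d(mov, hosts, voxel_size = vx, radius_um = 1.4)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$cell, 2L)
})

test_that("bleb polarity: axis convention, exclusion-zone recovery, isotropy, rotation equivariance", {
  hosts <- data.frame(id = 1L, x = 10, y = 10, z = 5)
  east <- data.frame(frame = 1L, x = 14, y = 10, z = 5, score = 1, cell = 1L)
  pol <- bleb_polarity(east, hosts)
  expect_equal(pol$angles$theta_xy, 0)
  # lower-hemisphere exclusion: detected below-centre fraction <= 5%
  an <- default_bleb4d_analysis()
  expect_lte(an$polarity$lower_fraction, 0.05)
  # isotropic spots: all three plane histograms uniform (chi-square, a = .01)
  set.seed(55)
  n <- 3000
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  iso <- data.frame(frame = 1L, x = 10 + 6 * v[, 1], y = 10 + 6 * v[, 2],
                    z = 5 + 6 * v[, 3], score = 1, cell = 1L)
  ip <- bleb_polarity(iso, hosts)
  for (h in ip$histograms) {
    p <- suppressWarnings(chisq.test(h$count)$p.value)
    expect_gt(p, 0.01)
  }
  # rotating the scene 90 degrees in XY shifts theta_xy by exactly 90
  rot <- iso
  rot$x <- 10 - (iso$y - 10)
  rot$y <- 10 + (iso$x - 10)
  rp <- bleb_polarity(rot, hosts)
  d <- (rp$angles$theta_xy - ip$angles$theta_xy + 180) %% 360 - 180
  expect_equal(max(abs(d - 90)[abs(d - 90) < 180]), 0, tolerance = 1e-9)
})

test_that("track_cells: stationary and arithmetic cases, group speed recovery", {
  stat <- data.frame(t = rep(1:5, each = 1), x = 3, y = 4)
  tr <- suppressWarnings(track_cells(stat, frame_interval = 0.5,
                                     time_unit = "h"))
  expect_equal(tr$speed_um_h, 0)
  # 10 um per frame at 0.5 h per frame = 20 um/h
  mv <- data.frame(t = 1:5, x = (0:4) * 10, y = 0)
  tr2 <- suppressWarnings(track_cells(mv, frame_interval = 0.5,
                                      time_unit = "h", gate_um = 15))
  expect_equal(tr2$speed_um_h, 20)
  # generator with on-matrix speed 2x off-matrix: ordering and p < 0.05
  cfg <- scene_config("bleb", seed = 2,
    grid = c(T = 16L, Z = 1L, Y = 640L, X = 640L),
    voxel_size = c(dx = 0.5, dy = 0.5, dz = 1),
    frame_interval = 1800,
    cells = list(n_on = 20L, n_off = 20L, radius_range_um = c(4.5, 6),
                 aspect_range = c(1, 1.15), min_gap_um = 6,
                 max_tries = 3000L),
    blebs = list(rate_per_cell_frame = 0, duration_mean_s = 27,
                 duration_sdlog = 0.5, area_mean_um2 = 5, area_shape = 4,
                 exclusion = "none", min_angle_sep_deg = 60,
                 max_concurrent = 2L),
    motility = list(speed_on_um_h = 8, speed_off_um_h = 4))
  gen <- generate_bleb_movie(cfg)
  det <- do.call(rbind, lapply(seq_len(16), function(t) {
    r <- measure_cells(segment_cells(gen$stack, "EGFP", t,
                                     min_volume = 100L), t = t)
    # group from the nearest true cell at this frame
    tt <- gen$truth$tracks[gen$truth$tracks$t == t, ]
    idx <- vapply(seq_len(nrow(r)), function(i)
      which.min((tt$x - r$x[i])^2 + (tt$y - r$y[i])^2), integer(1))
    r$group <- tt$group[idx]
    r
  }))
  trk <- track_cells(det, frame_interval = 0.5, time_unit = "h", gate_um = 8)
  trk <- trk[trk$n_frames >= 8, ]
  on <- trk$speed_um_h[trk$group == "on-matrix"]
  off <- trk$speed_um_h[trk$group == "off-matrix"]
  expect_gt(mean(on), mean(off))
  expect_lt(two_sample_t(on, off)$p, 0.05)
})
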