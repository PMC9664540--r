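# Ground-truthed synthetic 4D scene generator. Three scenarios are
# emulated: a multi-day nodule time course (saturating collagen growth,
# flattening on-matrix cells, lacuna voids), a seconds-scale bleb movie
# (transient membrane protrusions on free cell surfaces), and the
# drug-response experiment (flat cells transiently turned cuboidal with
# boosted matrix growth). Every rendered object is recorded in a
# GroundTruth table, the oracle for all recovery tests.

#' Build a scene configuration
#'
#' Returns the default stated world for one scenario, with any field
#' overridden by name. Defaults are calibrated once to the published
#' summary values (mean on-matrix sphericity 0.7026 at the first nodule
#' timepoint, mean bleb duration 27 s, mean bleb maximum area 5 um^2,
#' 15-s bleb frames, 1-um Z steps, 30-um 4D bleb stack) and otherwise to
#' magnitudes typical of two-photon osteoblast cultures.
#'
#' @param scenario `"nodule"`, `"bleb"`, `"bleb4d"` or `"bio"`.
#' @param ... named overrides of top-level config fields; list fields
#'   (`growth`, `cells`, `noise`, ...) are replaced wholesale when supplied.
#' @return a validated list of class `SceneConfig`.
#' @export
scene_config <- function(scenario = c("nodule", "bleb", "bleb4d", "bio"), ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    nodule = list(
      scenario = "nodule",
      grid = c(T = 4L, Z = 40L, Y = 320L, X = 320L),
      voxel_size = c(dx = 0.5, dy = 0.5, dz = 1),
      frame_interval = 1, time_unit = "d",
      days = c(7, 10, 14, 21),
      growth = list(init_frac = 0.04, rate = 0.35, sat_frac = 0.12,
                    aspect_b = 0.9, height_frac = 0.35),
      cells = list(n_on = 8L, n_off = 6L, volume_um3 = 1200,
                   volume_sd = 150, min_dist_um = 16, aspect_range = c(1, 1.3),
                   footprint_frac = 0.82, max_tries = 500L),
      morphology = list(psi_on = c(0.7026, 0.65, 0.58, 0.50),
                        psi_off = 0.45, psi_sd = 0.06,
                        psi_clip = c(0.35, 0.96)),
      lacunae = list(density_per_um3 = 3e-4, count = NULL, radius_um = 2.5,
                     min_dist_um = 7),
      noise = list(amplitude = 1, background = 0.02, gaussian_sd = 0.03,
                   poisson = FALSE, blur_sigma_um = 0.5),
      treatment = FALSE,
      seed = 1L),
    bleb = list(
      scenario = "bleb",
      grid = c(T = 60L, Z = 1L, Y = 384L, X = 384L),
      voxel_size = c(dx = 0.25, dy = 0.25, dz = 1),
      frame_interval = 15, time_unit = "s",
      cells = list(n_on = 9L, n_off = 0L, radius_range_um = c(5, 7),
                   aspect_range = c(1, 1.2), min_gap_um = 7,
                   max_tries = 500L),
      blebs = list(rate_per_cell_frame = 0.22, duration_mean_s = 27,
                   duration_sdlog = 0.5, area_mean_um2 = 5,
                   area_shape = 4, exclusion = "none",
                   min_angle_sep_deg = 60, max_concurrent = 2L),
      motility = list(speed_on_um_h = 0, speed_off_um_h = 0),
      noise = list(amplitude = 1, background = 0.02, gaussian_sd = 0.04,
                   poisson = FALSE, blur_sigma_um = 0.3),
      seed = 1L),
    bleb4d = list(
      scenario = "bleb4d",
      grid = c(T = 12L, Z = 30L, Y = 256L, X = 256L),
      voxel_size = c(dx = 0.25, dy = 0.25, dz = 1),
      frame_interval = 20, time_unit = "s",
      cells = list(n_on = 4L, n_off = 0L, radius_range_um = c(5, 6.5),
                   aspect_range = c(1, 1.15), min_gap_um = 8,
                   max_tries = 500L),
      blebs = list(rate_per_cell_frame = 0.55, duration_mean_s = 27,
                   duration_sdlog = 0.5, area_mean_um2 = 5,
                   area_shape = 4, exclusion = "lower",
                   min_angle_sep_deg = 60, max_concurrent = 2L),
      motility = list(speed_on_um_h = 0, speed_off_um_h = 0),
      noise = list(amplitude = 1, background = 0.02, gaussian_sd = 0.04,
                   poisson = FALSE, blur_sigma_um = 0.3),
      seed = 1L),
    bio = list(
      scenario = "bio",
      grid = c(T = 4L, Z = 40L, Y = 320L, X = 320L),
      voxel_size = c(dx = 0.5, dy = 0.5, dz = 1),
      frame_interval = 1, time_unit = "d",
      days = c(0, 3, 7, 14),
      growth = list(init_frac = 0.05, rate = 0.25, sat_frac = 0.10,
                    aspect_b = 0.9, height_frac = 0.35),
      growth_boost = list(rate_mult = 1.8, sat_mult = 1.25),
      cells = list(n_on = 8L, n_off = 6L, volume_um3 = 1200,
                   volume_sd = 150, min_dist_um = 16, aspect_range = c(1, 1.3),
                   footprint_frac = 0.82, max_tries = 500L),
      morphology = list(psi_on = c(0.45, 0.45, 0.45, 0.45),
                        psi_treated = c(0.45, 0.70, 0.68, 0.46),
                        psi_off = 0.45, psi_sd = 0.06,
                        psi_clip = c(0.35, 0.96), baseline_tol = 0.03),
      lacunae = list(density_per_um3 = 3e-4, count = NULL, radius_um = 2.5,
                     min_dist_um = 7),
      noise = list(amplitude = 1, background = 0.02, gaussian_sd = 0.03,
                   poisson = FALSE, blur_sigma_um = 0.5),
      treatment = FALSE,
      seed = 1L))
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  validate_scene_config(structure(base, class = "SceneConfig"))
}

#' Validate a SceneConfig
#' @param config a `SceneConfig`.
#' @return the config, invisibly-checked.
#' @export
validate_scene_config <- function(config) {
  g <- config$grid
  if (!all(c("T", "Z", "Y", "X") %in% names(g)))
    stop("grid must name T, Z, Y, X")
  if (any(g <= 0)) stop("grid sizes must be strictly positive")
  if (g[["T"]] < 2L) stop("config invariant violated: T >= 2")
  if (any(config$voxel_size <= 0)) stop("voxel sizes must be positive")
  stop_if_not_scalar_pos(config$frame_interval, "frame_interval")
  mo <- config$morphology
  if (!is.null(mo)) {
    sched <- c(mo$psi_on, mo$psi_treated, mo$psi_off)
    if (any(sched <= 0 | sched > 1))
      stop("morphology schedule values must lie in (0, 1]")
    if (!is.null(mo$psi_on) && length(mo$psi_on) != g[["T"]])
      stop("morphology$psi_on must have one value per timepoint")
  }
  if (!is.null(config$blebs)) {
    b <- config$blebs
    if (b$rate_per_cell_frame < 0) stop("bleb event rate must be >= 0")
    if (b$duration_mean_s <= 0 || b$area_mean_um2 <= 0)
      stop("bleb duration and area means must be positive")
  }
  config
}

# ---- geometric helpers -----------------------------------------------------

#' Surface area of a triaxial ellipsoid
#'
#' Numerical quadrature of the first-octant surface integral (relative
#' error around 1e-5 for the axis ratios used here); used both to
#' calibrate generated cell shapes and as the ground-truth surface area.
#'
#' @param a,b,c semi-axes (any order), micrometres.
#' @param n quadrature nodes per dimension.
#' @return surface area in um^2.
#' @export
ellipsoid_area <- function(a, b, c, n = 96L) {
  th <- (seq_len(n) - 0.5) * (pi / 2) / n     # midpoint rule in theta, phi
  ph <- th
  st <- sin(th); ct <- cos(th)
  sp <- sin(ph); cp <- cos(ph)
  f <- outer(st, rep(1, n)) * 0
  for (j in seq_len(n)) {
    g <- st * sqrt((b * c * st * cp[j])^2 + (a * c * st * sp[j])^2 +
                   (a * b * ct)^2)
    f[, j] <- g
  }
  8 * sum(f) * (pi / 2 / n)^2
}

#' Wadell sphericity from volume and surface area
#' @param volume volume (um^3).
#' @param area surface area (um^2).
#' @return dimensionless sphericity in (0, 1\] (up to estimator tolerance).
#' @export
wadell_sphericity <- function(volume, area) {
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

# Solve semi-axes (a = gamma*b >= b >= c) of an ellipsoid with given volume
# and target Wadell sphericity; flattening q = c/b is the free parameter.
solve_ellipsoid_shape <- function(psi_target, volume, gamma = 1) {
  psi_of_q <- function(q) {
    b <- (3 * volume / (4 * pi * gamma * q))^(1 / 3)
    a <- gamma * b; c <- q * b
    wadell_sphericity(volume, ellipsoid_area(a, b, c))
  }
  hi <- 1
  psi_hi <- psi_of_q(hi)
  if (psi_target >= psi_hi) {
    q <- hi
  } else {
    q <- stats::uniroot(function(q) psi_of_q(q) - psi_target,
                        lower = 0.02, upper = 1, tol = 1e-5)$root
  }
  b <- (3 * volume / (4 * pi * gamma * q))^(1 / 3)
  sort(c(gamma * b, b, q * b), decreasing = TRUE)
}

# rejection placement with a minimum pairwise distance; error names density
place_min_dist <- function(n, sampler, min_dist, max_tries, what) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3L))
  pts <- matrix(NA_real_, nrow = n, ncol = 3L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- sampler()
      if (i == 1L ||
          all(sqrt(rowSums((pts[seq_len(i - 1L), 1:2, drop = FALSE] -
                            matrix(cand[1:2], i - 1L, 2L, byrow = TRUE))^2)) >=
              min_dist)) {
        pts[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "%s placement failed after %d retries: %d objects at min spacing %.1f um exceed the configured placement density",
        what, max_tries, n, min_dist))
  }
  pts
}

# Add a solid triaxial ellipsoid (c axis vertical, in-plane rotation phi)
# into a (Y, X, Z) volume; intensities are set to at least `amp` inside.
add_ellipsoid <- function(vol, voxel, center, axes, phi, amp) {
  d <- dim(vol)
  dx <- voxel[["dx"]]; dy <- voxel[["dy"]]; dz <- voxel[["dz"]]
  a <- axes[1L]; b <- axes[2L]; cth <- axes[3L]
  r_xy <- max(a, b)
  ix <- seq(max(1L, floor((center[1L] - r_xy) / dx)),
            min(d[2L], ceiling((center[1L] + r_xy) / dx) + 1L))
  iy <- seq(max(1L, floor((center[2L] - r_xy) / dy)),
            min(d[1L], ceiling((center[2L] + r_xy) / dy) + 1L))
  iz <- seq(max(1L, floor((center[3L] - cth) / dz)),
            min(d[3L], ceiling((center[3L] + cth) / dz) + 1L))
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  X <- (ix - 1) * dx - center[1L]
  Y <- (iy - 1) * dy - center[2L]
  Z <- (iz - 1) * dz - center[3L]
  cphi <- cos(phi); sphi <- sin(phi)
  # rotate XY into the ellipsoid frame
  gy <- outer(Y, X, function(yy, xx) (-sphi * xx + cphi * yy) / b)
  gx <- outer(Y, X, function(yy, xx) (cphi * xx + sphi * yy) / a)
  g2 <- gx^2 + gy^2
  for (k in seq_along(iz)) {
    zz <- (Z[k] / cth)^2
    inside <- g2 + zz <= 1
    if (any(inside)) {
      sl <- vol[iy, ix, iz[k]]
      sl[inside] <- pmax(sl[inside], amp)
      vol[iy, ix, iz[k]] <- sl
    }
  }
  vol
}

# Dome (half-ellipsoid, flat base on z = 0) rendering and height map
add_dome <- function(vol, voxel, center_xy, Ra, Rb, h, amp) {
  add_ellipsoid(vol, voxel, c(center_xy, 0), c(Ra, Rb, h), 0, amp)
}

dome_height <- function(x, y, center_xy, Ra, Rb, h) {
  r2 <- ((x - center_xy[1L]) / Ra)^2 + ((y - center_xy[2L]) / Rb)^2
  h * sqrt(pmax(0, 1 - r2))
}

carve_sphere <- function(vol, voxel, center, radius, floor_val) {
  d <- dim(vol)
  dx <- voxel[["dx"]]; dy <- voxel[["dy"]]; dz <- voxel[["dz"]]
  ix <- seq(max(1L, floor((center[1L] - radius) / dx)),
            min(d[2L], ceiling((center[1L] + radius) / dx) + 1L))
  iy <- seq(max(1L, floor((center[2L] - radius) / dy)),
            min(d[1L], ceiling((center[2L] + radius) / dy) + 1L))
  iz <- seq(max(1L, floor((center[3L] - radius) / dz)),
            min(d[3L], ceiling((center[3L] + radius) / dz) + 1L))
  X <- (ix - 1) * dx - center[1L]
  Y <- (iy - 1) * dy - center[2L]
  Z <- (iz - 1) * dz - center[3L]
  g2 <- outer(Y^2, X^2, `+`)
  for (k in seq_along(iz)) {
    inside <- g2 + Z[k]^2 <= radius^2
    if (any(inside)) {
      sl <- vol[iy, ix, iz[k]]
      sl[inside] <- floor_val
      vol[iy, ix, iz[k]] <- sl
    }
  }
  vol
}

# optical blur + background + noise, clamped nonnegative
apply_optics_noise <- function(frame, voxel, noise) {
  d <- dim(frame)
  s <- noise$blur_sigma_um
  if (!is.null(s) && s > 0) {
    frame <- cpp_gauss3d(as.numeric(frame), d[1L], d[2L], d[3L],
                         s / voxel[["dy"]], s / voxel[["dx"]],
                         if (d[3L] > 1L) s / voxel[["dz"]] else 0)
    dim(frame) <- d
  }
  frame <- frame + noise$background
  if (isTRUE(noise$poisson)) {
    photons <- 200
    frame[] <- stats::rpois(length(frame), pmax(frame, 0) * photons) / photons
  }
  if (noise$gaussian_sd > 0)
    frame <- frame + stats::rnorm(length(frame), 0, noise$gaussian_sd)
  frame[frame < 0] <- 0
  frame
}

# centered per-cell sphericity deviations: the realized population mean at
# each timepoint equals the schedule value (up to rare clipping)
centered_deviations <- function(n, sd) {
  if (n == 0L) return(numeric(0))
  d <- stats::rnorm(n, 0, sd)
  d - mean(d)
}

logistic_volume <- function(days, init_frac, rate, sat_frac, total_vol) {
  d0 <- days[1L] + log(sat_frac / init_frac - 1) / rate
  sat_frac * total_vol / (1 + exp(-rate * (days - d0)))
}

# ---- nodule time course ----------------------------------------------------

#' Generate a synthetic multi-day nodule time course
#'
#' Renders a two-channel (EGFP cells, SHG collagen) stack over the
#' configured observation days: a dome-shaped collagen nodule whose true
#' volume follows a saturating logistic growth curve, on-matrix cells
#' riding the dome surface with sphericity following the morphology
#' schedule (declining by default), flat off-matrix cells on the dish
#' outside the final nodule footprint, and lacuna voids carved inside the
#' SHG signal at fixed positions.
#'
#' @param config a [scene_config()] with scenario `"nodule"` or `"bio"`.
#' @return list with `stack` (an [image_stack()]) and `truth`
#'   (a `GroundTruth` list of tables).
#' @export
generate_nodule_timecourse <- function(config = scene_config("nodule")) {
  config <- validate_scene_config(config)
  with_local_seed(config$seed, generate_nodule_impl(config))
}

generate_nodule_impl <- function(config) {
  g <- config$grid
  vx <- config$voxel_size
  nT <- g[["T"]]; nZ <- g[["Z"]]; nY <- g[["Y"]]; nX <- g[["X"]]
  Lx <- nX * vx[["dx"]]; Ly <- nY * vx[["dy"]]; Lz <- nZ * vx[["dz"]]
  days <- config$days
  gr <- config$growth
  mo <- config$morphology
  psi_on_sched <- if (isTRUE(config$treatment) && !is.null(mo$psi_treated))
    mo$psi_treated else mo$psi_on
  rate <- gr$rate; sat <- gr$sat_frac
  if (isTRUE(config$treatment) && !is.null(config$growth_boost)) {
    rate <- rate * config$growth_boost$rate_mult
    sat <- sat * config$growth_boost$sat_mult
  }
  vol_t <- logistic_volume(days, gr$init_frac, rate, sat, Lx * Ly * Lz)
  # dome semi-axes from volume: V = (2/3) * pi * Ra * Rb * h
  shape_f <- (2 / 3) * pi * gr$aspect_b * gr$height_frac
  Ra_t <- (vol_t / shape_f)^(1 / 3)
  Rb_t <- gr$aspect_b * Ra_t
  h_t <- gr$height_frac * Ra_t
  ctr <- c(Lx / 2, Ly / 2)

  # lacunae: fixed positions inside the first-day dome interior
  lc <- config$lacunae
  n_lac <- if (!is.null(lc$count)) lc$count
           else round(lc$density_per_um3 * vol_t[1L])
  lac <- place_min_dist(n_lac, function() {
    repeat {
      u <- stats::runif(2, -0.8, 0.8)
      x <- ctr[1L] + u[1L] * Ra_t[1L]
      y <- ctr[2L] + u[2L] * Rb_t[1L]
      # the whole void sphere must stay under the dome surface: check the
      # dome height over the void's lateral extent, not just its centre
      th8 <- seq(0, 2 * pi, length.out = 9L)[-9L]
      hcov <- min(dome_height(x + lc$radius_um * cos(th8),
                              y + lc$radius_um * sin(th8),
                              ctr, Ra_t[1L], Rb_t[1L], h_t[1L]))
      if (hcov > 2 * lc$radius_um + 4) {
        z <- stats::runif(1, lc$radius_um + 2, hcov - lc$radius_um - 2)
        return(c(x, y, z))
      }
    }
  }, lc$min_dist_um, 2000L, "lacuna")

  # cells: fixed ids and XY positions across timepoints
  ce <- config$cells
  n_on <- ce$n_on; n_off <- ce$n_off
  margin <- 12
  # on-matrix cells tile the first-day dome footprint in a jittered
  # golden-angle (sunflower) layout: crowded, quasi-regular coverage like a
  # confluent nodule surface, with guaranteed minimum spacing
  ff <- ce$footprint_frac %||% 0.82
  a_reg <- ff * Ra_t[1L]; b_reg <- ff * Rb_t[1L]
  spacing_est <- 0.95 * sqrt(pi * a_reg * b_reg / max(n_on, 1L))
  if (n_on > 0 && spacing_est < 8)
    stop(sprintf(
      "on-matrix cell placement infeasible: %d cells on a %.0f um2 footprint gives %.1f um spacing; reduce the on-matrix density",
      n_on, pi * a_reg * b_reg, spacing_est))
  on_pts <- if (n_on > 0) {
    k <- seq_len(n_on)
    rot <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt((k - 0.5) / n_on)
    th <- k * pi * (3 - sqrt(5)) + rot
    cbind(ctr[1L] + a_reg * rr * cos(th) + stats::rnorm(n_on, 0, 1),
          ctr[2L] + b_reg * rr * sin(th) + stats::rnorm(n_on, 0, 1),
          0)
  } else matrix(numeric(0), ncol = 3L)
  Ra_f <- Ra_t[nT]; Rb_f <- Rb_t[nT]
  off_pts <- place_min_dist(n_off, function() {
    repeat {
      x <- stats::runif(1, margin, Lx - margin)
      y <- stats::runif(1, margin, Ly - margin)
      if (((x - ctr[1L]) / (Ra_f + 10))^2 + ((y - ctr[2L]) / (Rb_f + 10))^2 > 1)
        return(c(x, y, 0))
    }
  }, ce$min_dist_um, ce$max_tries, "off-matrix cell")
  n_cells <- n_on + n_off
  cell_xy <- rbind(on_pts, off_pts)
  comp <- rep(c("IN/ON", "OUT"), c(n_on, n_off))
  vols <- pmax(600, stats::rnorm(n_cells, ce$volume_um3, ce$volume_sd))
  gammas <- stats::runif(n_cells, ce$aspect_range[1L], ce$aspect_range[2L])
  phis <- stats::runif(n_cells, 0, pi)
  dev_on <- centered_deviations(n_on, mo$psi_sd)
  dev_off <- centered_deviations(n_off, mo$psi_sd)

  arr <- array(0, dim = c(nY, nX, nZ, 2L, nT))
  tp <- data.frame(t = seq_len(nT), day = days, shg_volume_um3 = NA_real_,
                   shg_area_um2 = NA_real_)
  cells_tab <- NULL
  lac_tab <- if (n_lac > 0)
    data.frame(id = seq_len(n_lac), x = lac[, 1L], y = lac[, 2L],
               z = lac[, 3L], radius_um = lc$radius_um)
  else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), radius_um = numeric(0))

  for (t in seq_len(nT)) {
    shg <- array(0, dim = c(nY, nX, nZ))
    shg <- add_dome(shg, vx, ctr, Ra_t[t], Rb_t[t], h_t[t], 0.9)
    if (n_lac > 0)
      for (i in seq_len(n_lac))
        shg <- carve_sphere(shg, vx, lac[i, ], lc$radius_um, 0)
    lac_vol <- n_lac * 4 / 3 * pi * lc$radius_um^3
    lac_area <- n_lac * 4 * pi * lc$radius_um^2
    tp$shg_volume_um3[t] <- vol_t[t] - lac_vol
    tp$shg_area_um2[t] <- ellipsoid_area(Ra_t[t], Rb_t[t], h_t[t]) / 2 +
      pi * Ra_t[t] * Rb_t[t] + lac_area

    egfp <- array(0, dim = c(nY, nX, nZ))
    if (n_cells > 0) {
      psi_targets <- c(pmin(pmax(psi_on_sched[t] + dev_on, mo$psi_clip[1L]),
                            mo$psi_clip[2L]),
                       pmin(pmax(mo$psi_off + dev_off, mo$psi_clip[1L]),
                            mo$psi_clip[2L]))
      for (i in seq_len(n_cells)) {
        ax <- solve_ellipsoid_shape(psi_targets[i], vols[i], gammas[i])
        x <- cell_xy[i, 1L]; y <- cell_xy[i, 2L]
        z_surf <- if (comp[i] == "IN/ON")
          dome_height(x, y, ctr, Ra_t[t], Rb_t[t], h_t[t]) else 0
        z <- if (comp[i] == "IN/ON") z_surf + 0.35 * ax[3L]
             else ax[3L] + 1.2
        z <- min(z, Lz - ax[3L] - 2)
        egfp <- add_ellipsoid(egfp, vx, c(x, y, z), ax, phis[i], 1)
        area_i <- ellipsoid_area(ax[1L], ax[2L], ax[3L])
        cells_tab <- rbind(cells_tab, data.frame(
          t = t, id = i, x = x, y = y, z = z,
          a = ax[1L], b = ax[2L], c = ax[3L],
          volume_um3 = vols[i], area_um2 = area_i,
          psi = wadell_sphericity(vols[i], area_i),
          compartment = comp[i]))
      }
    }
    arr[, , , 1L, t] <- apply_optics_noise(egfp, vx, config$noise)
    arr[, , , 2L, t] <- apply_optics_noise(shg, vx, config$noise)
  }
  if (is.null(cells_tab))
    cells_tab <- data.frame(t = integer(0), id = integer(0), x = numeric(0),
                            y = numeric(0), z = numeric(0), a = numeric(0),
                            b = numeric(0), c = numeric(0),
                            volume_um3 = numeric(0), area_um2 = numeric(0),
                            psi = numeric(0), compartment = character(0))
  stack <- image_stack(arr, voxel_size = vx,
                       frame_interval = config$frame_interval,
                       time_unit = config$time_unit,
                       channels = c("EGFP", "SHG"))
  truth <- structure(list(timepoints = tp, cells = cells_tab,
                          lacunae = lac_tab,
                          blebs = empty_bleb_table(),
                          tracks = NULL, config = config),
                     class = "GroundTruth")
  n4d_log("nodule scene: %d timepoints, %d cells, %d lacunae", nT,
          n_cells, n_lac)
  list(stack = stack, truth = truth)
}

empty_bleb_table <- function() {
  data.frame(id = integer(0), cell = integer(0), t0_s = numeric(0),
             duration_s = numeric(0), max_area_um2 = numeric(0),
             first_frame = integer(0), last_frame = integer(0),
             ux = numeric(0), uy = numeric(0), uz = numeric(0),
             rendered = logical(0), skip_reason = character(0))
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("<GroundTruth> %d timepoints | %d cell records | %d lacunae | %d bleb events\n",
              nrow(x$timepoints %||% data.frame()),
              nrow(x$cells %||% data.frame()),
              nrow(x$lacunae %||% data.frame()),
              nrow(x$blebs %||% data.frame())))
  invisible(x)
}

# ---- bleb movies -----------------------------------------------------------

# z-centroid of an ellipsoid (centre m, vertical semi-axis c) clipped at
# z = 0: closed form from the parabolic slice-area profile
clipped_centroid_z <- function(m, c) {
  u0 <- max(-1, -m / c)
  I0 <- (1 - u0) - (1 - u0^3) / 3
  I1 <- (1 / 2 - 1 / 4) - (u0^2 / 2 - u0^4 / 4)
  m + c * I1 / I0
}

sample_bleb_direction <- function(exclusion, two_d) {
  if (two_d) {
    th <- stats::runif(1, -pi, pi)
    return(c(cos(th), sin(th), 0))
  }
  repeat {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (identical(exclusion, "lower") && v[3L] < 0) next
    return(v)
  }
}

#' Generate a synthetic membrane-bleb time lapse
#'
#' Renders cells (2-D footprints when the grid has a single Z slice,
#' substrate-attached domes otherwise) with transient bleb protrusions on
#' their free surfaces. Event birth times are continuous and uniform over
#' the movie, durations log-normal with the configured mean (seconds),
#' maximum areas gamma with the configured mean (um^2); a bleb holds its
#' maximum area for its whole lifetime (fast expansion and retraction
#' relative to the frame interval). Events whose lifetime covers no frame
#' sampling instant are kept in the ground truth flagged
#' `rendered = FALSE` with a `skip_reason`.
#'
#' @param config a [scene_config()] with scenario `"bleb"` or `"bleb4d"`.
#' @return list with `stack` and `truth` as in
#'   [generate_nodule_timecourse()]; `truth$blebs` lists every event,
#'   `truth$tracks` the per-frame true cell centroids and speeds.
#' @export
generate_bleb_movie <- function(config = scene_config("bleb")) {
  config <- validate_scene_config(config)
  with_local_seed(config$seed, generate_bleb_impl(config))
}

generate_bleb_impl <- function(config) {
  g <- config$grid
  vx <- config$voxel_size
  nT <- g[["T"]]; nZ <- g[["Z"]]; nY <- g[["Y"]]; nX <- g[["X"]]
  two_d <- nZ == 1L
  Lx <- nX * vx[["dx"]]; Ly <- nY * vx[["dy"]]
  dt_s <- config$frame_interval
  ce <- config$cells
  bl <- config$blebs
  n_on <- ce$n_on; n_off <- ce$n_off
  n_cells <- n_on + n_off
  if (n_cells < 1L && bl$rate_per_cell_frame > 0)
    stop("bleb movie requires at least one cell")
  radii <- stats::runif(n_cells, ce$radius_range_um[1L], ce$radius_range_um[2L])
  aspects <- stats::runif(n_cells, ce$aspect_range[1L], ce$aspect_range[2L])
  phis <- stats::runif(n_cells, 0, pi)
  margin <- if (n_cells) max(radii) + 5 else 10
  min_dist <- if (n_cells) 2 * max(radii) + ce$min_gap_um else 1
  pos0 <- place_min_dist(n_cells, function()
    c(stats::runif(1, margin, Lx - margin),
      stats::runif(1, margin, Ly - margin), 0), min_dist, ce$max_tries, "cell")
  group <- rep(c("on-matrix", "off-matrix"), c(n_on, n_off))
  speeds <- ifelse(group == "on-matrix", config$motility$speed_on_um_h,
                   config$motility$speed_off_um_h)

  # trajectories: constant step length speed*dt, random heading, reflective
  traj <- array(0, dim = c(n_cells, nT, 2L))
  if (n_cells > 0) {
    traj[, 1L, ] <- pos0[, 1:2]
    step <- speeds * dt_s / 3600
    for (t in 2:nT) {
      th <- stats::runif(n_cells, -pi, pi)
      nx_ <- traj[, t - 1L, 1L] + step * cos(th)
      ny_ <- traj[, t - 1L, 2L] + step * sin(th)
      nx_ <- pmin(pmax(nx_, margin), Lx - margin)
      ny_ <- pmin(pmax(ny_, margin), Ly - margin)
      traj[, t, 1L] <- nx_
      traj[, t, 2L] <- ny_
    }
  }

  # bleb events, per cell, Poisson in time with continuous birth instants
  area_scale <- bl$area_mean_um2 / bl$area_shape
  dur_meanlog <- log(bl$duration_mean_s) - bl$duration_sdlog^2 / 2
  events <- empty_bleb_table()
  ev_id <- 0L
  movie_len_s <- (nT - 1L) * dt_s
  for (ci in seq_len(n_cells)) {
    n_ev <- stats::rpois(1L, bl$rate_per_cell_frame * nT)
    if (n_ev == 0L) next
    t0 <- sort(stats::runif(n_ev, 0, movie_len_s))
    for (k in seq_len(n_ev)) {
      dur <- stats::rlnorm(1L, dur_meanlog, bl$duration_sdlog)
      amax <- stats::rgamma(1L, shape = bl$area_shape, scale = area_scale)
      dirv <- sample_bleb_direction(bl$exclusion, two_d)
      f0 <- ceiling(t0[k] / dt_s)              # first sampled frame (0-based)
      f1 <- ceiling((t0[k] + dur) / dt_s) - 1L # last sampled frame
      f1 <- min(f1, nT - 1L)
      rendered <- f1 >= f0
      reason <- ""
      if (!rendered) {
        reason <- "duration shorter than one frame interval (no sampling instant covered)"
        n4d_log("bleb event skipped (cell %d, t0=%.1fs, dur=%.1fs): %s",
                ci, t0[k], dur, reason)
      } else {
        # enforce angular separation from concurrently active blebs
        conc <- events$rendered &
          events$cell == ci &
          events$first_frame <= f1 + 2L & events$last_frame >= f0 - 2L
        if (any(conc)) {
          if (sum(conc) >= bl$max_concurrent) next
          angs <- atan2(events$uy[conc], events$ux[conc])
          if (two_d &&
              any(abs(((atan2(dirv[2L], dirv[1L]) - angs + pi) %% (2 * pi)) -
                      pi) < bl$min_angle_sep_deg * pi / 180))
            next
        }
      }
      ev_id <- ev_id + 1L
      events <- rbind(events, data.frame(
        id = ev_id, cell = ci, t0_s = t0[k], duration_s = dur,
        max_area_um2 = amax, first_frame = f0, last_frame = if (rendered) f1
        else NA_integer_, ux = dirv[1L], uy = dirv[2L], uz = dirv[3L],
        rendered = rendered, skip_reason = reason))
    }
  }

  # render
  arr <- array(0, dim = c(nY, nX, nZ, 2L, nT))
  shg_static <- array(0, dim = c(nY, nX, nZ))
  if (n_on > 0) {
    # faint static matrix pad under the on-matrix cells
    for (ci in seq_len(n_on))
      shg_static <- add_ellipsoid(shg_static, vx,
                                  c(pos0[ci, 1L], pos0[ci, 2L], 0),
                                  c(radii[ci] + 4, radii[ci] + 4,
                                    max(1.5, vx[["dz"]])), 0, 0.6)
  }
  tracks <- NULL
  for (t in seq_len(nT)) {
    egfp <- array(0, dim = c(nY, nX, nZ))
    for (ci in seq_len(n_cells)) {
      cx <- traj[ci, t, 1L]; cy <- traj[ci, t, 2L]
      if (two_d) {
        egfp <- add_ellipsoid(egfp, vx, c(cx, cy, 0),
                              c(aspects[ci] * radii[ci], radii[ci], 1),
                              phis[ci], 1)
      } else {
        egfp <- add_ellipsoid(egfp, vx, c(cx, cy, 0.45 * radii[ci]),
                              c(aspects[ci] * radii[ci], radii[ci],
                                0.8 * radii[ci]), phis[ci], 1)
      }
      tracks <- rbind(tracks, data.frame(cell = ci, t = t, x = cx, y = cy,
                                         z = if (two_d) 0 else 0.45 * radii[ci],
                                         group = group[ci],
                                         speed_um_h = speeds[ci]))
    }
    act <- events[events$rendered & events$first_frame <= t - 1L &
                    events$last_frame >= t - 1L, , drop = FALSE]
    for (k in seq_len(nrow(act))) {
      e <- act[k, ]
      ci <- e$cell
      rb <- sqrt(e$max_area_um2 / pi)
      cx <- traj[ci, t, 1L]; cy <- traj[ci, t, 2L]
      if (two_d) {
        th <- atan2(e$uy, e$ux)
        # footprint radius along th (rotated ellipse)
        ca <- cos(th - phis[ci]); sa <- sin(th - phis[ci])
        rcell <- 1 / sqrt((ca / (aspects[ci] * radii[ci]))^2 +
                          (sa / radii[ci])^2)
        bc <- c(cx + (rcell + rb) * cos(th),
                cy + (rcell + rb) * sin(th), 0)
        egfp <- add_ellipsoid(egfp, vx, bc, c(rb, rb, 1), 0, 1)
      } else {
        # anchor at the centroid of the rendered (substrate-clipped) dome so
        # that recovered directions are unbiased against the measured cell
        # centre; then step to the surface along u by exact line-ellipsoid
        # intersection
        axc <- c(aspects[ci] * radii[ci], radii[ci], 0.8 * radii[ci])
        cz_full <- 0.45 * radii[ci]
        origin <- c(cx, cy, clipped_centroid_z(cz_full, axc[3L]))
        u <- c(e$ux, e$uy, e$uz)
        o <- c(0, 0, cz_full - origin[3L])       # ellipsoid centre - origin
        q2 <- sum((u / axc)^2)
        q1 <- -2 * sum(u * o / axc^2)
        q0 <- sum((o / axc)^2) - 1
        s <- (-q1 + sqrt(q1^2 - 4 * q2 * q0)) / (2 * q2)
        bc <- origin + (s + rb) * u
        bc[3L] <- max(bc[3L], rb + 0.5)
        egfp <- add_ellipsoid(egfp, vx, bc, c(rb, rb, rb), 0, 1)
      }
    }
    arr[, , , 1L, t] <- apply_optics_noise(egfp, vx, config$noise)
    arr[, , , 2L, t] <- apply_optics_noise(shg_static, vx, config$noise)
  }
  stack <- image_stack(arr, voxel_size = vx,
                       frame_interval = config$frame_interval,
                       time_unit = config$time_unit,
                       channels = c("EGFP", "SHG"))
  truth <- structure(list(
    timepoints = data.frame(t = seq_len(nT), time_s = (seq_len(nT) - 1) * dt_s),
    cells = data.frame(id = seq_len(n_cells),
                       x = if (n_cells) pos0[, 1L] else numeric(0),
                       y = if (n_cells) pos0[, 2L] else numeric(0),
                       radius_um = radii, group = group),
    lacunae = NULL, blebs = events, tracks = tracks, config = config),
    class = "GroundTruth")
  n4d_log("bleb movie: %d cells, %d events (%d rendered)", n_cells,
          nrow(events), sum(events$rendered))
  list(stack = stack, truth = truth)
}

# ---- drug-response experiment ---------------------------------------------

#' Generate the synthetic drug-response (BIO) experiment
#'
#' One arm of the treatment experiment: with `config$treatment = TRUE` the
#' on-matrix sphericity schedule is replaced by the treated schedule
#' (flat cells transiently cuboidal, back to baseline at the final
#' timepoint) and matrix growth is boosted by `config$growth_boost`; with
#' `treatment = FALSE` the flat vehicle schedule is used. Run twice with
#' the same seed for a paired treated/vehicle comparison.
#'
#' @param config a [scene_config()] with scenario `"bio"`.
#' @return as [generate_nodule_timecourse()].
#' @export
generate_bio_experiment <- function(config = scene_config("bio")) {
  if (is.null(config$morphology$psi_treated))
    stop("bio experiment config requires a post-treatment schedule (morphology$psi_treated)")
  generate_nodule_timecourse(config)
}
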