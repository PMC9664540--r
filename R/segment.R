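# Segmentation: SHG surface model, labeled cells, lacuna voids, generic
# spot detection.

#' Otsu threshold
#'
#' Maximizes between-class variance over a 256-bin histogram. Deterministic
#' default used wherever an automatic global threshold is called for.
#'
#' @param x numeric vector/array of intensities.
#' @param nbins histogram bins.
#' @return threshold value; `NA` for a constant input.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) return(NA_real_)
  h <- tabulate(pmin(nbins, floor((v - lo) / (hi - lo) * nbins) + 1L), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  lo + (k / nbins) * (hi - lo)
}

resolve_threshold <- function(x, threshold) {
  if (is.numeric(threshold)) return(threshold)
  method <- if (is.null(threshold)) "otsu" else match.arg(threshold, "otsu")
  otsu_threshold(x)
}

# fill interior cavities of a 3-D mask: background components not connected
# to the stack border are holes
fill_holes3d <- function(mask) {
  d <- dim(mask)
  lab <- cpp_label3d(as.logical(!mask), d[1L], d[2L], d[3L], 6L)
  dim(lab) <- d
  border <- unique(c(lab[1L, , ], lab[d[1L], , ], lab[, 1L, ], lab[, d[2L], ],
                     lab[, , 1L], lab[, , d[3L]]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# triangle mesh of the 0.5 isosurface of a lightly smoothed binary mask,
# zero-padded so the surface closes at stack borders; vertices in um
mask_to_mesh <- function(mask, voxel_size, smooth_sigma_um = 0.5) {
  d <- dim(mask)
  pad <- 2L
  vol <- array(0, dim = d + 2L * pad)
  vol[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])] <-
    as.numeric(mask)
  dx <- voxel_size[["dx"]]; dy <- voxel_size[["dy"]]; dz <- voxel_size[["dz"]]
  if (smooth_sigma_um > 0) {
    dd <- dim(vol)
    # at least 0.7 voxel of smoothing per axis, else the binary staircase
    # dominates the mesh area at coarse voxel sizes
    vol <- cpp_gauss3d(as.numeric(vol), dd[1L], dd[2L], dd[3L],
                       max(smooth_sigma_um / dy, 0.7),
                       max(smooth_sigma_um / dx, 0.7),
                       max(smooth_sigma_um / dz, 0.7))
    dim(vol) <- dd
  }
  dd <- dim(vol)
  cpp_marching_tets(as.numeric(vol), dd[1L], dd[2L], dd[3L], 0.5,
                    dy, dx, dz, -pad * dy, -pad * dx, -pad * dz)
}

#' Segment the SHG (collagen) channel into a surface model
#'
#' Global threshold (Otsu by default) on the median-filtered SHG frame,
#' small components below `min_size` voxels removed, isosurface mesh of the
#' mask. Volume is mask voxel count times voxel volume; area is the mesh
#' area (voxel-face areas overestimate and would bias sphericity-style
#' statistics downstream).
#'
#' @param stack an [image_stack()] (or a (Y, X, Z) array plus `voxel_size`).
#' @param channel SHG channel label or index.
#' @param t timepoint; `NULL` processes every timepoint and returns a list.
#' @param threshold `"otsu"` (default) or a fixed numeric value.
#' @param min_size minimum component size in voxels.
#' @param median_radius median prefilter radius in voxels (0 disables; the
#'   SHG channel is noise-filtered with a median before thresholding).
#' @param voxel_size calibration when `stack` is a plain array.
#' @return a `SurfaceModel`: mask, mesh (`vertices`, `faces`),
#'   `volume_um3`, `area_um2`, `mesh_volume_um3`, `z_min_um`, `height_map`
#'   (per-XY-column top surface height, NA outside the footprint).
#' @export
segment_shg <- function(stack, channel = "SHG", t = NULL, threshold = NULL,
                        min_size = 50L, median_radius = 1L,
                        voxel_size = NULL) {
  if (inherits(stack, "ImageStack")) {
    vx <- stack$voxel_size
    if (is.null(t)) {
      nT <- stack_dim(stack)[["T"]]
      if (nT > 1L)
        return(lapply(seq_len(nT), function(tt)
          segment_shg(stack, channel, tt, threshold, min_size, median_radius)))
      t <- 1L
    }
    frame <- get_frame(stack, t, channel)
  } else {
    vx <- voxel_size %||% c(dx = 1, dy = 1, dz = 1)
    frame <- stack
    if (length(dim(frame)) == 2L) dim(frame) <- c(dim(frame), 1L)
  }
  if (median_radius > 0) frame <- median_filter(frame, median_radius)
  d <- dim(frame)
  thr <- resolve_threshold(frame, threshold)
  mask <- if (is.na(thr)) array(FALSE, d) else frame > thr
  if (any(mask)) {
    lab <- cpp_label3d(as.logical(mask), d[1L], d[2L], d[3L], 26L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_size)
    mask <- array(lab %in% keep & lab > 0L, d)
  }
  n_vox <- sum(mask)
  voxel_vol <- prod(vx)
  if (n_vox == 0L) {
    warning("segment_shg: empty SHG mask (valid early-timepoint case)")
    sm <- list(mask = mask, mesh = NULL, volume_um3 = 0, area_um2 = 0,
               mesh_volume_um3 = 0, z_min_um = NA_real_,
               height_map = matrix(NA_real_, d[1L], d[2L]),
               voxel_size = vx, n_voxels = 0L, threshold = thr)
    return(structure(sm, class = "SurfaceModel"))
  }
  mesh <- mask_to_mesh(mask, vx)
  zidx <- which(mask, arr.ind = TRUE)
  z_min <- (min(zidx[, 3L]) - 1) * vx[["dz"]]
  hm <- matrix(NA_real_, d[1L], d[2L])
  top <- apply(mask, c(1L, 2L), function(col) {
    w <- which(col)
    if (length(w)) max(w) else NA_integer_
  })
  hm[] <- (top - 1) * vx[["dz"]]
  sm <- list(mask = mask, mesh = mesh[c("vertices", "faces")],
             volume_um3 = n_vox * voxel_vol, area_um2 = mesh$area,
             mesh_volume_um3 = mesh$volume, z_min_um = z_min,
             height_map = hm, voxel_size = vx, n_voxels = n_vox,
             threshold = thr)
  n4d_log("segment_shg: %d voxels, V=%.0f um3, A=%.0f um2", n_vox,
          sm$volume_um3, sm$area_um2)
  structure(sm, class = "SurfaceModel")
}

#' @export
print.SurfaceModel <- function(x, ...) {
  cat(sprintf("<SurfaceModel> %d voxels | V=%.1f um3 | A=%.1f um2 | z_min=%s um\n",
              x$n_voxels, x$volume_um3, x$area_um2,
              format(x$z_min_um)))
  invisible(x)
}

#' Segment and label cells in the fluorescence channel
#'
#' Automatic global threshold, 3-D connected components, then a seeded
#' watershed split of touching cells using smoothed Euclidean-distance
#' maxima as seeds. Components below `min_volume` voxels are discarded and
#' labels compacted to 1..K.
#'
#' @inheritParams segment_shg
#' @param channel cell channel label or index.
#' @param min_volume minimum cell size in voxels.
#' @param seed_sigma_um Gaussian smoothing of the distance map before
#'   seed detection.
#' @param seed_min_dist_um minimum separation between watershed seeds.
#' @return a `LabeledCells` object: integer `labels` array, per-label
#'   `sizes` (voxels), `channel`, `voxel_size`.
#' @export
segment_cells <- function(stack, channel = "EGFP", t = 1L, threshold = NULL,
                          min_volume = 200L, seed_sigma_um = 1.2,
                          seed_min_dist_um = 5, voxel_size = NULL) {
  if (inherits(stack, "ImageStack")) {
    vx <- stack$voxel_size
    frame <- get_frame(stack, t, channel)
  } else {
    vx <- voxel_size %||% c(dx = 1, dy = 1, dz = 1)
    frame <- stack
    if (length(dim(frame)) == 2L) dim(frame) <- c(dim(frame), 1L)
  }
  d <- dim(frame)
  thr <- resolve_threshold(frame, threshold)
  mask <- if (is.na(thr)) array(FALSE, d) else frame > thr
  out <- structure(list(labels = array(0L, d), sizes = integer(0),
                        channel = channel, voxel_size = vx, threshold = thr),
                   class = "LabeledCells")
  if (!any(mask)) return(out)
  dist <- cpp_edt3d(as.logical(mask), d[1L], d[2L], d[3L],
                    vx[["dy"]], vx[["dx"]], vx[["dz"]])
  dim(dist) <- d
  sm <- cpp_gauss3d(as.numeric(dist), d[1L], d[2L], d[3L],
                    seed_sigma_um / vx[["dy"]], seed_sigma_um / vx[["dx"]],
                    if (d[3L] > 1L) seed_sigma_um / vx[["dz"]] else 0)
  dim(sm) <- d
  r_seed <- max(1L, ceiling(seed_min_dist_um / min(vx[["dx"]], vx[["dy"]])))
  maxima <- cpp_local_maxima(as.numeric(sm), d[1L], d[2L], d[3L], r_seed,
                             0.5, as.logical(mask))
  if (!any(maxima)) maxima <- sm == max(sm[mask]) & mask
  seed_lab <- cpp_label3d(as.logical(maxima), d[1L], d[2L], d[3L], 26L)
  lab <- cpp_watershed3d(as.numeric(-sm), seed_lab, as.logical(mask),
                         d[1L], d[2L], d[3L], 6L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_volume)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab_arr <- array(0L, d)
  pos <- lab > 0L
  lab_arr[pos] <- remap[lab[pos]]
  out$labels <- lab_arr
  out$sizes <- sizes[keep]
  n4d_log("segment_cells: %d labels (threshold %.3g)", length(keep), thr)
  out
}

#' @export
print.LabeledCells <- function(x, ...) {
  cat(sprintf("<LabeledCells> %d labels from channel %s\n",
              length(x$sizes), x$channel))
  invisible(x)
}

#' Extract lacuna voids from the SHG channel
#'
#' Median filter, local contrast, then regional minima at a configured
#' h-minima depth; a median-filter cleanup pass removes speckle minima and
#' regions smaller than `min_voxels`. Only minima inside the SHG mask
#' become lacuna spots (dark background spots are excluded).
#'
#' @inheritParams segment_shg
#' @param h_depth h-minima depth as a fraction of the dynamic range.
#' @param min_voxels minimum minima-region size.
#' @param block,clip local-contrast parameters (see [local_contrast()]).
#' @return data.frame with one row per lacuna: centroid `x`, `y`, `z` (um),
#'   `radius_um` (equivalent sphere radius), `voxels`.
#' @export
extract_lacunae <- function(stack, channel = "SHG", t = 1L,
                            h_depth = 0.10, min_voxels = 30L,
                            median_radius = 1L, block = 32L, clip = 0.02,
                            voxel_size = NULL) {
  if (inherits(stack, "ImageStack")) {
    vx <- stack$voxel_size
    frame <- get_frame(stack, t, channel)
  } else {
    vx <- voxel_size %||% c(dx = 1, dy = 1, dz = 1)
    frame <- stack
    if (length(dim(frame)) == 2L) dim(frame) <- c(dim(frame), 1L)
  }
  filt <- median_filter(frame, median_radius)
  surf <- segment_shg(filt, t = NULL, min_size = 50L, median_radius = 0L,
                      voxel_size = vx)
  if (surf$n_voxels == 0L) return(lacuna_table())
  # lacunae are cavities: gate on the hole-filled SHG mask, and restrict the
  # morphological work to its bounding box
  filled_full <- fill_holes3d(surf$mask)
  bidx <- which(filled_full, arr.ind = TRUE)
  lo <- pmax(apply(bidx, 2L, min) - 2L, 1L)
  hi <- pmin(apply(bidx, 2L, max) + 2L, dim(frame))
  off <- lo - 1L
  filt <- filt[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  filled <- filled_full[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L],
                        drop = FALSE]
  d <- dim(filt)
  ctr <- local_contrast(filt, block = block, clip = clip)
  rng <- diff(range(ctr))
  if (!(rng > 0)) return(lacuna_table())
  marker <- ctr + h_depth * rng
  recon <- cpp_reconstruct_erosion(as.numeric(marker), as.numeric(ctr),
                                   d[1L], d[2L], d[3L], 6L)
  minima <- cpp_regional_minima(recon, d[1L], d[2L], d[3L], 26L)
  dim(minima) <- d
  # median cleanup of the minima mask removes speckle
  mm <- cpp_median3d(as.numeric(minima), d[1L], d[2L], d[3L], 1L, FALSE)
  minima <- array(mm > 0.5, d) & filled
  if (!any(minima)) return(lacuna_table())
  lab <- cpp_label3d(as.logical(minima), d[1L], d[2L], d[3L], 26L)
  dim(lab) <- d
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) return(lacuna_table())
  # lacunae are strictly interior cavities: discard minima touching the
  # lowest mask layer (dish-interface pockets, not lacunae)
  z_floor <- surf$z_min_um + 0.5 * vx[["dz"]]
  keep <- keep[vapply(keep, function(k) {
    zmin_k <- (min(which(lab == k, arr.ind = TRUE)[, 3L]) + off[3L] - 1L) *
      vx[["dz"]]
    zmin_k > z_floor
  }, logical(1))]
  if (!length(keep)) return(lacuna_table())
  voxel_vol <- prod(vx)
  res <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    ctr_um <- voxel_to_um(mean(idx[, 1L]) + off[1L], mean(idx[, 2L]) + off[2L],
                          mean(idx[, 3L]) + off[3L], vx)
    data.frame(x = ctr_um[1L, "x"], y = ctr_um[1L, "y"], z = ctr_um[1L, "z"],
               radius_um = (3 * sizes[k] * voxel_vol / (4 * pi))^(1 / 3),
               voxels = sizes[k])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n4d_log("extract_lacunae: %d spots", nrow(out))
  out
}

lacuna_table <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             radius_um = numeric(0), voxels = integer(0))
}

#' Scale-matched blob (spot) detection
#'
#' Laplacian-of-Gaussian contract implemented as a difference of Gaussians
#' at the scale of the expected radius; returns physical-unit centroids of
#' response maxima with their scores.
#'
#' @param volume (Y, X\[, Z\]) numeric array, single channel.
#' @param radius_um expected blob radius in micrometres.
#' @param voxel_size named `c(dx, dy, dz)`.
#' @param threshold_rel minimum response as a fraction of the maximum
#'   response.
#' @param threshold_abs optional absolute response floor overriding the
#'   relative rule.
#' @return data.frame `x`, `y`, `z` (um), `score`.
#' @export
detect_spots <- function(volume, radius_um, voxel_size = c(dx = 1, dy = 1, dz = 1),
                         threshold_rel = 0.25, threshold_abs = NULL) {
  stop_if_not_scalar_pos(radius_um, "radius_um")
  if (length(dim(volume)) == 2L) dim(volume) <- c(dim(volume), 1L)
  d <- dim(volume)
  vx <- voxel_size
  sigma <- radius_um / sqrt(3)
  g1 <- cpp_gauss3d(as.numeric(volume), d[1L], d[2L], d[3L],
                    sigma / vx[["dy"]], sigma / vx[["dx"]],
                    if (d[3L] > 1L) sigma / vx[["dz"]] else 0)
  g2 <- cpp_gauss3d(as.numeric(volume), d[1L], d[2L], d[3L],
                    1.6 * sigma / vx[["dy"]], 1.6 * sigma / vx[["dx"]],
                    if (d[3L] > 1L) 1.6 * sigma / vx[["dz"]] else 0)
  dog <- g1 - g2
  dim(dog) <- d
  mx <- max(dog)
  if (!(mx > 0)) return(data.frame(x = numeric(0), y = numeric(0),
                                   z = numeric(0), score = numeric(0)))
  floor_val <- threshold_abs %||% (threshold_rel * mx)
  r_win <- max(1L, ceiling(radius_um / min(vx[["dx"]], vx[["dy"]])))
  maxima <- cpp_local_maxima(as.numeric(dog), d[1L], d[2L], d[3L], r_win,
                             floor_val, logical(0))
  if (!any(maxima)) return(data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), score = numeric(0)))
  lab <- cpp_label3d(as.logical(maxima), d[1L], d[2L], d[3L], 26L)
  dim(lab) <- d
  ks <- sort(unique(lab[lab > 0L]))
  res <- lapply(ks, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    ctr_um <- voxel_to_um(mean(idx[, 1L]), mean(idx[, 2L]), mean(idx[, 3L]), vx)
    data.frame(x = ctr_um[1L, "x"], y = ctr_um[1L, "y"], z = ctr_um[1L, "z"],
               score = max(dog[idx[, 1L] + d[1L] * (idx[, 2L] - 1L) +
                                 d[1L] * d[2L] * (idx[, 3L] - 1L)]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(-out$score), , drop = FALSE]
}
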