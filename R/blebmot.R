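# Membrane-bleb detection and tracking (duration, maximum area, polarity)
# and cell motility quantification.

time_to_hours <- function(value, unit) {
  value * switch(unit, s = 1 / 3600, min = 1 / 60, h = 1, d = 24,
                 stop(sprintf("unknown time unit '%s'", unit)))
}

frame_components <- function(mask2d, min_px, values = NULL, floor_val = 0) {
  d <- dim(mask2d)
  lab <- cpp_label3d(as.logical(mask2d), d[1L], d[2L], 1L, 26L)
  dim(lab) <- d
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  comps <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    area_px <- sizes[k]
    if (!is.null(values)) {
      # refine to the half-peak (FWHM) area: the detection threshold sits
      # above the blur half-maximum and would bias areas low
      pk <- stats::quantile(values[idx], 0.75)   # robust plateau estimate
      href <- max(pk / 2, floor_val)
      ylo <- max(1L, min(idx[, 1L]) - 3L); yhi <- min(d[1L], max(idx[, 1L]) + 3L)
      xlo <- max(1L, min(idx[, 2L]) - 3L); xhi <- min(d[2L], max(idx[, 2L]) + 3L)
      sub <- values[ylo:yhi, xlo:xhi, drop = FALSE] >= href
      sl <- cpp_label3d(as.logical(sub), nrow(sub), ncol(sub), 1L, 26L)
      dim(sl) <- dim(sub)
      # the half-peak component containing this component's peak voxel
      pk_idx <- idx[which.max(values[idx]), ]
      kk <- sl[pk_idx[1L] - ylo + 1L, pk_idx[2L] - xlo + 1L]
      if (kk > 0L) area_px <- sum(sl == kk)
    }
    list(label = k, area_px = area_px,
         cy = mean(idx[, 1L]), cx = mean(idx[, 2L]))
  })
  list(lab = lab, keep = keep, comps = comps)
}

#' Detect and track membrane blebs in a 2-D time lapse
#'
#' The movie is background-suppressed by temporal minimum subtraction,
#' thresholded (Otsu over nonzero pixels by default), and per-frame
#' connected components at least `min_area_um2` large are linked across
#' consecutive frames by mask overlap (largest overlap wins; ties go to
#' the nearest centroid). Tracks spanning at least `min_frames` frames are
#' reported with duration `(last - first + 1) * frame interval` and the
#' maximum per-frame area.
#'
#' @param movie an [image_stack()] (uses `channel`) or (Y, X\[, 1\], T)
#'   array; frame interval in seconds.
#' @param channel channel for ImageStack input (default `"EGFP"`).
#' @param frame_interval_s frame interval override for array input.
#' @param voxel_size calibration override for array input.
#' @param min_area_um2 minimum bleb area.
#' @param min_frames minimum track length in frames.
#' @param threshold fixed threshold overriding Otsu.
#' @return list with `tracks` (one row per bleb: `id`, `birth_frame`,
#'   `n_frames`, `duration_s`, `max_area_um2`, centroid at maximum area)
#'   and `detections` (per frame, per component).
#' @export
detect_blebs_2d <- function(movie, channel = "EGFP", frame_interval_s = NULL,
                            voxel_size = NULL, min_area_um2 = 1,
                            min_frames = 1L, threshold = NULL) {
  if (inherits(movie, "ImageStack")) {
    vx <- movie$voxel_size
    dt_s <- movie$frame_interval *
      switch(movie$time_unit, s = 1, min = 60, h = 3600, d = 86400)
    arr <- get_movie(movie, channel)
  } else {
    vx <- voxel_size %||% c(dx = 1, dy = 1, dz = 1)
    dt_s <- frame_interval_s %||% 1
    arr <- as_yxzt(movie)
  }
  if (dim(arr)[3L] != 1L)
    stop("detect_blebs_2d expects a single-Z movie; use detect_blebs_4d")
  sub <- temporal_min_subtract(arr)
  nT <- dim(sub)[4L]
  px_area <- vx[["dx"]] * vx[["dy"]]
  min_px <- max(1L, round(min_area_um2 / px_area))
  if (is.numeric(threshold)) {
    thr <- threshold
  } else {
    # robust two-stage automatic threshold: bleb pixels are a tiny minority,
    # so plain Otsu over all pixels lands inside the background mode. First
    # strip the background (median + 4 MAD of the subtracted movie), then
    # run Otsu on the remaining candidate pixels.
    bg <- stats::median(sub)
    spread <- stats::mad(sub)
    floor_val <- bg + 4 * spread
    cand <- sub[sub > floor_val]
    if (!length(cand))
      return(list(tracks = empty_track_table(), detections = data.frame()))
    thr <- otsu_threshold(cand)
    if (is.na(thr)) thr <- (floor_val + max(cand)) / 2
    thr <- max(thr, floor_val)
  }
  prev <- NULL
  track_of <- list()     # per frame: map component label -> track id
  tracks <- list()
  det_rows <- list()
  next_track <- 0L
  bg_floor <- if (is.numeric(threshold)) threshold else thr / 2
  for (t in seq_len(nT)) {
    vals <- sub[, , 1L, t]
    m <- vals > thr
    fc <- frame_components(m, min_px, values = vals, floor_val = bg_floor)
    cur_map <- integer(0)
    claimed <- integer(0)
    if (!is.null(prev) && length(fc$comps)) {
      # overlap counts between current components and previous track labels
      cand <- list()
      for (ci in seq_along(fc$comps)) {
        comp <- fc$comps[[ci]]
        sel <- fc$lab == comp$label
        ov <- prev$lab[sel]
        ov <- ov[ov > 0L]
        if (!length(ov)) next
        tb <- table(ov)
        for (plab in names(tb)) {
          pl <- as.integer(plab)
          if (!pl %in% prev$keep) next
          pi <- match(pl, vapply(prev$comps, `[[`, integer(1), "label"))
          dd <- sqrt((comp$cy - prev$comps[[pi]]$cy)^2 +
                     (comp$cx - prev$comps[[pi]]$cx)^2)
          cand[[length(cand) + 1L]] <- c(ci = ci, plab = pl,
                                         ov = as.integer(tb[[plab]]), d = dd)
        }
      }
      if (length(cand)) {
        cm <- do.call(rbind, cand)
        cm <- cm[order(-cm[, "ov"], cm[, "d"]), , drop = FALSE]
        used_cur <- used_prev <- integer(0)
        for (k in seq_len(nrow(cm))) {
          ci <- cm[k, "ci"]; pl <- cm[k, "plab"]
          if (ci %in% used_cur || pl %in% used_prev) next
          tid <- prev$track_map[[as.character(pl)]]
          if (is.null(tid)) next
          cur_map[as.character(fc$comps[[ci]]$label)] <- tid
          used_cur <- c(used_cur, ci)
          used_prev <- c(used_prev, pl)
        }
      }
    }
    for (ci in seq_along(fc$comps)) {
      comp <- fc$comps[[ci]]
      key <- as.character(comp$label)
      tid <- if (key %in% names(cur_map)) cur_map[[key]] else {
        next_track <- next_track + 1L
        tracks[[next_track]] <- list(first = t, frames = integer(0),
                                     areas = numeric(0), cy = numeric(0),
                                     cx = numeric(0))
        cur_map[key] <- next_track
        next_track
      }
      tr <- tracks[[tid]]
      tr$frames <- c(tr$frames, t)
      tr$areas <- c(tr$areas, comp$area_px * px_area)
      tr$cy <- c(tr$cy, comp$cy)
      tr$cx <- c(tr$cx, comp$cx)
      tracks[[tid]] <- tr
      det_rows[[length(det_rows) + 1L]] <-
        data.frame(frame = t, track = tid, area_um2 = comp$area_px * px_area,
                   x = (comp$cx - 1) * vx[["dx"]],
                   y = (comp$cy - 1) * vx[["dy"]])
    }
    prev <- fc
    prev$track_map <- as.list(cur_map)
  }
  rows <- list()
  for (tid in seq_along(tracks)) {
    tr <- tracks[[tid]]
    if (length(tr$frames) < min_frames) next
    imax <- which.max(tr$areas)
    rows[[length(rows) + 1L]] <- data.frame(
      id = tid, birth_frame = min(tr$frames), n_frames = length(tr$frames),
      duration_s = length(tr$frames) * dt_s,
      max_area_um2 = max(tr$areas),
      x = (tr$cx[imax] - 1) * vx[["dx"]],
      y = (tr$cy[imax] - 1) * vx[["dy"]])
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_track_table()
  rownames(out) <- NULL
  n4d_log("detect_blebs_2d: %d tracks (threshold %.3g)", nrow(out), thr)
  list(tracks = out,
       detections = if (length(det_rows)) do.call(rbind, det_rows)
                    else data.frame())
}

empty_track_table <- function() {
  data.frame(id = integer(0), birth_frame = integer(0), n_frames = integer(0),
             duration_s = numeric(0), max_area_um2 = numeric(0),
             x = numeric(0), y = numeric(0))
}

#' Detect bleb spots in a 4-D (3-D + time) movie
#'
#' Frame-by-frame differences highlight appearing structures; each
#' difference frame is scanned by scale-matched spot detection and every
#' spot is assigned to the nearest segmented host cell within
#' `host_cap_factor` times the host's equivalent radius (ties broken
#' deterministically towards the lower cell id).
#'
#' @param movie an [image_stack()] or (Y, X, Z, T) array.
#' @param hosts host cell table: data.frame with `id`, `x`, `y`, `z` (um)
#'   and `volume_um3` (e.g. from [measure_cells()]).
#' @param channel channel for ImageStack input.
#' @param radius_um expected bleb radius.
#' @param voxel_size calibration for array input.
#' @param host_cap_factor assignment cap in units of host equivalent radius.
#' @param threshold_rel spot response floor relative to the strongest spot.
#' @return data.frame of spots: `frame` (difference-frame index, i.e.
#'   appearing between `frame` and `frame + 1`), `x`, `y`, `z`, `score`,
#'   `cell` (host id or NA), equivalent `area_um2` (circle of the detection
#'   scale - an approximation recorded as such).
#' @export
detect_blebs_4d <- function(movie, hosts, channel = "EGFP", radius_um = 1.3,
                            voxel_size = NULL, host_cap_factor = 1.5,
                            threshold_rel = 0.35) {
  if (is.null(hosts) || nrow(hosts) == 0L)
    stop("detect_blebs_4d: no cells segmented; host assignment impossible")
  if (inherits(movie, "ImageStack")) {
    vx <- movie$voxel_size
    arr <- get_movie(movie, channel)
  } else {
    vx <- voxel_size %||% c(dx = 1, dy = 1, dz = 1)
    arr <- as_yxzt(movie)
  }
  dif <- frame_difference(arr)
  req <- hosts$volume_um3 %||% rep(4 / 3 * pi * 8^3, nrow(hosts))
  host_r <- (3 * req / (4 * pi))^(1 / 3)
  # candidate spots per frame with a permissive floor; the decision
  # threshold is relative to the strongest response in the whole movie,
  # not per frame - otherwise event-free frames promote pure noise maxima
  cand <- list()
  for (t in seq_len(dim(dif)[4L])) {
    fr <- dif[, , , t, drop = FALSE]
    dim(fr) <- dim(dif)[1:3]
    sp <- detect_spots(fr, radius_um, vx, threshold_rel = 0.05)
    if (nrow(sp)) {
      sp$frame <- t
      cand[[length(cand) + 1L]] <- sp
    }
  }
  rows <- list()
  for (cf in cand) {
    sp <- cf[cf$score >= threshold_rel *
               max(vapply(cand, function(x) max(x$score), numeric(1))), ,
             drop = FALSE]
    if (!nrow(sp)) next
    t <- sp$frame[1L]
    for (k in seq_len(nrow(sp))) {
      dd <- sqrt((hosts$x - sp$x[k])^2 + (hosts$y - sp$y[k])^2 +
                 (hosts$z - sp$z[k])^2)
      within <- which(dd <= host_cap_factor * host_r + radius_um)
      cell <- if (length(within)) {
        best <- within[abs(dd[within] - min(dd[within])) < 1e-9]
        min(hosts$id[best])               # tie -> lower cell id
      } else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, x = sp$x[k], y = sp$y[k], z = sp$z[k], score = sp$score[k],
        cell = cell, area_um2 = pi * radius_um^2)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), score = numeric(0), cell = integer(0),
               area_um2 = numeric(0))
  rownames(out) <- NULL
  out
}

#' Bleb polarity relative to the host cell centre
#'
#' For each spot, the displacement vector from its host centroid gives the
#' angles `theta_xy = atan2(dy, dx)`, `theta_zy = atan2(dz, dy)` and
#' `theta_zx = atan2(dz, dx)` in degrees within \[-180, 180) (so a spot
#' due "east" of the centre has `theta_xy` = 0); 15-degree-bin histograms
#' are returned per plane together with the fraction of spots below the
#' host centre (`dz < 0`). Zero-displacement spots are skipped with a log
#' entry.
#'
#' @param spots data.frame from [detect_blebs_4d()] (needs `x`, `y`, `z`,
#'   `cell`).
#' @param hosts host table with `id`, `x`, `y`, `z`.
#' @param bin_deg histogram bin width in degrees.
#' @return list with `angles` (per spot), `histograms` (per plane) and
#'   `lower_fraction`.
#' @export
bleb_polarity <- function(spots, hosts, bin_deg = 15) {
  spots <- spots[!is.na(spots$cell), , drop = FALSE]
  hi <- match(spots$cell, hosts$id)
  dx <- spots$x - hosts$x[hi]
  dy <- spots$y - hosts$y[hi]
  dz <- spots$z - hosts$z[hi]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  zero <- r < 1e-9
  if (any(zero)) n4d_log("bleb_polarity: skipping %d zero-displacement spots",
                         sum(zero))
  dx <- dx[!zero]; dy <- dy[!zero]; dz <- dz[!zero]
  wrap <- function(a) ((a + 180) %% 360) - 180
  ang <- data.frame(theta_xy = wrap(atan2(dy, dx) * 180 / pi),
                    theta_zy = wrap(atan2(dz, dy) * 180 / pi),
                    theta_zx = wrap(atan2(dz, dx) * 180 / pi),
                    dz = dz)
  breaks <- seq(-180, 180, by = bin_deg)
  hist1 <- function(a) data.frame(
    bin_low = head(breaks, -1L), bin_high = tail(breaks, -1L),
    count = tabulate(cut(a, breaks, include.lowest = TRUE, labels = FALSE),
                     length(breaks) - 1L))
  list(angles = ang,
       histograms = list(xy = hist1(ang$theta_xy), zy = hist1(ang$theta_zy),
                         zx = hist1(ang$theta_zx)),
       lower_fraction = if (nrow(ang)) mean(ang$dz < 0) else NA_real_)
}

#' Track cells across timepoints and quantify motility
#'
#' Greedy nearest-centroid linking with a maximum-displacement gate.
#' Mean speed is the mean consecutive step length divided by the frame
#' interval, reported in micrometres per hour; the group label is carried
#' over from the compartment column when present.
#'
#' @param detections data.frame of per-timepoint cell centroids: columns
#'   `t`, `x`, `y` (optionally `z`, `compartment` or `group`).
#' @param frame_interval frame interval value.
#' @param time_unit `"s"`, `"min"`, `"h"` or `"d"`.
#' @param gate_um maximum displacement per frame interval.
#' @return data.frame of tracks: `track`, `n_frames`, `speed_um_h`,
#'   `group`.
#' @export
track_cells <- function(detections, frame_interval, time_unit = "h",
                        gate_um = 15) {
  if (!all(c("t", "x", "y") %in% names(detections)))
    stop("detections must have columns t, x, y")
  if (is.null(detections$z)) detections$z <- 0
  grp_col <- if ("group" %in% names(detections)) "group"
             else if ("compartment" %in% names(detections)) "compartment"
             else NULL
  dt_h <- time_to_hours(frame_interval, time_unit)
  ts <- sort(unique(detections$t))
  first <- detections[detections$t == ts[1L], , drop = FALSE]
  tracks <- lapply(seq_len(nrow(first)), function(i)
    list(pts = first[i, c("x", "y", "z")],
         group = if (is.null(grp_col)) NA_character_
                 else as.character(first[[grp_col]][i]),
         steps = numeric(0), last_t = ts[1L]))
  for (k in seq_along(ts)[-1L]) {
    cur <- detections[detections$t == ts[k], , drop = FALSE]
    if (!nrow(cur)) next
    open <- which(vapply(tracks, function(tr) tr$last_t == ts[k - 1L],
                         logical(1)))
    if (length(open)) {
      last_pts <- do.call(rbind, lapply(tracks[open], function(tr)
        tail(tr$pts, 1L)))
      dmat <- outer(seq_len(nrow(cur)), seq_along(open),
                    Vectorize(function(i, j)
                      sqrt((cur$x[i] - last_pts$x[j])^2 +
                           (cur$y[i] - last_pts$y[j])^2 +
                           (cur$z[i] - last_pts$z[j])^2)))
      pairs <- which(dmat <= gate_um, arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(dmat[pairs])
        used_i <- used_j <- integer(0)
        for (p in ord) {
          i <- pairs[p, 1L]; j <- pairs[p, 2L]
          if (i %in% used_i || j %in% used_j) next
          tid <- open[j]
          tr <- tracks[[tid]]
          tr$steps <- c(tr$steps, dmat[i, j])
          tr$pts <- rbind(tr$pts, cur[i, c("x", "y", "z")])
          tr$last_t <- ts[k]
          tracks[[tid]] <- tr
          used_i <- c(used_i, i)
          used_j <- c(used_j, j)
        }
        unmatched <- setdiff(seq_len(nrow(cur)), used_i)
      } else unmatched <- seq_len(nrow(cur))
    } else unmatched <- seq_len(nrow(cur))
    for (i in unmatched)
      tracks[[length(tracks) + 1L]] <- list(
        pts = cur[i, c("x", "y", "z")],
        group = if (is.null(grp_col)) NA_character_
                else as.character(cur[[grp_col]][i]),
        steps = numeric(0), last_t = ts[k])
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(tid) {
    tr <- tracks[[tid]]
    n <- nrow(tr$pts)
    data.frame(track = tid, n_frames = n,
               speed_um_h = if (length(tr$steps)) mean(tr$steps) / dt_h else 0,
               group = tr$group)
  }))
  if (mean(out$n_frames) < 3)
    warning("track_cells: mean track length < 3 frames; the gate may be smaller than typical motion")
  out
}
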