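# Preprocessing chain: median filter, local contrast, the two temporal
# operators behind bleb extraction, and rigid drift registration.
#
# All operators accept either an ImageStack (applied per timepoint and
# channel) or a plain numeric array: (Y, X), (Y, X, Z) or (Y, X, Z, T).

as_yxzt <- function(x) {
  d <- dim(x) %||% length(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-D, 3-D or 4-D array")
  x
}

apply_per_frame <- function(x, fn) {
  if (inherits(x, "ImageStack")) {
    for (ch in seq_along(x$channels)) {
      mov <- get_movie(x, ch)
      for (t in seq_len(dim(mov)[4L]))
        mov[, , , t] <- fn(mov[, , , t, drop = FALSE])
      x <- set_movie(x, ch, mov)
    }
    x
  } else {
    orig_dim <- dim(x)
    a <- as_yxzt(x)
    for (t in seq_len(dim(a)[4L]))
      a[, , , t] <- fn(a[, , , t, drop = FALSE])
    dim(a) <- orig_dim
    a
  }
}

#' Median filter
#'
#' Order-statistics filter with reflected edges, applied per timepoint and
#' channel. In-plane (2-D per Z slice) by default because Z sampling is
#' typically much coarser than XY; set `in_plane = FALSE` for a cubic
#' 3-D window.
#'
#' @param x an [image_stack()] or numeric array (Y, X\[, Z\[, T\]\]).
#' @param radius window radius in voxels (window size `2*radius + 1`).
#' @param in_plane logical; filter each Z slice independently (default).
#' @return same type and shape as `x`.
#' @export
median_filter <- function(x, radius = 1L, in_plane = TRUE) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1 voxel")
  apply_per_frame(x, function(fr) {
    d <- dim(fr)[1:3]
    if (2L * radius + 1L > d[1L] || 2L * radius + 1L > d[2L] ||
        (!in_plane && d[3L] > 1L && 2L * radius + 1L > d[3L]))
      stop(sprintf("median window %d exceeds an image axis (%s)",
                   2L * radius + 1L, paste(d, collapse = "x")))
    out <- cpp_median3d(as.numeric(fr), d[1L], d[2L], d[3L], radius, in_plane)
    dim(out) <- dim(fr)
    out
  })
}

#' Local contrast enhancement (CLAHE contract)
#'
#' Contrast-limited adaptive histogram equalization applied per Z slice:
#' tile-local histograms (256 bins), clip limit as a fraction of tile pixel
#' count with uniform redistribution of the excess, and bilinear blending of
#' tile mappings. Output intensities are in \[0, 1\]; a constant slice maps
#' to a constant.
#'
#' @inheritParams median_filter
#' @param block tile edge length in pixels (>= 8).
#' @param clip clip limit as a fraction of the tile pixel count.
#' @return same type and shape as `x`, intensities in \[0, 1\].
#' @export
local_contrast <- function(x, block = 32L, clip = 0.01) {
  block <- as.integer(block)
  if (block < 8L) stop("block size must be >= 8 pixels in-plane")
  stop_if_not_scalar_pos(clip, "clip")
  apply_per_frame(x, function(fr) {
    d <- dim(fr)[1:3]
    out <- fr
    for (z in seq_len(d[3L])) {
      sl <- cpp_clahe2d(as.numeric(fr[, , z, 1L]), d[1L], d[2L], block, clip)
      out[, , z, 1L] <- sl
    }
    out
  })
}

movie_input <- function(movie, channel = NULL) {
  if (inherits(movie, "ImageStack")) {
    ch <- channel_index(movie, channel %||% 1L)
    list(arr = get_movie(movie, ch), stack = movie, channel = ch)
  } else {
    a <- as_yxzt(movie)
    list(arr = a, stack = NULL, channel = NULL)
  }
}

#' Temporal minimum subtraction
#'
#' Subtracts each pixel's minimum intensity over time from every frame:
#' `out[t] = in[t] - min_t(in)`. Static content (cell bodies, matrix) is
#' suppressed to ~0 while transient structures such as membrane blebs are
#' retained. Applying the operator twice equals applying it once.
#'
#' @param movie an [image_stack()] (operates on `channel`) or a
#'   (Y, X\[, Z\], T) array with T >= 2.
#' @param channel channel label or index when `movie` is an ImageStack.
#' @return array of the same shape as the input movie.
#' @export
temporal_min_subtract <- function(movie, channel = NULL) {
  mi <- movie_input(movie, channel)
  a <- mi$arr
  nt <- dim(a)[4L]
  if (nt < 2L) stop("temporal_min_subtract is undefined for T = 1")
  mn <- a[, , , 1L]
  for (t in 2:nt) mn <- pmin(mn, a[, , , t])
  for (t in seq_len(nt)) a[, , , t] <- a[, , , t] - mn
  a
}

#' Frame-by-frame difference
#'
#' `out[t] = max(in[t+1] - in[t], 0)` for t = 1..T-1: appearing structures
#' are highlighted, disappearing ones clipped at zero.
#'
#' @inheritParams temporal_min_subtract
#' @return (Y, X, Z, T-1) array of forward differences.
#' @export
frame_difference <- function(movie, channel = NULL) {
  mi <- movie_input(movie, channel)
  a <- mi$arr
  nt <- dim(a)[4L]
  if (nt < 2L) stop("frame_difference is undefined for T = 1")
  out <- a[, , , 2:nt, drop = FALSE] - a[, , , 1:(nt - 1L), drop = FALSE]
  out[out < 0] <- 0
  out
}

# integer translation with zero fill; offset = c(dy, dx, dz) moves content
# towards larger indices
shift_array <- function(a, offset) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- dst <- list()
  for (k in 1:3) {
    o <- as.integer(offset[k])
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# integer translation of frame `b` relative to `a` maximizing circular
# cross-correlation, by FFT
estimate_shift <- function(a, b) {
  d <- dim(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  idx <- arrayInd(which.max(cc), d)
  sh <- idx - 1L
  sh <- ifelse(sh > d / 2, sh - d, sh)
  -as.integer(sh)   # content displacement of b relative to a
}

#' Correct XYZ stage drift in a time-lapse series
#'
#' Translation-only rigid registration, matching the manual XYZ adjustment
#' used for time-lapse acquisitions. In `"cross-correlation"` mode the
#' per-timepoint integer translation maximizing the circular
#' cross-correlation with the first timepoint is estimated (on `channel`
#' for ImageStack input) and removed; in `"manual"` mode the supplied
#' offsets are applied as-is. Offsets are `c(dy, dx, dz)` voxel
#' displacements of each frame's content relative to frame 1; the corrected
#' series shifts content by `-offset` with zero fill.
#'
#' @param series an [image_stack()] or (Y, X\[, Z\], T) array.
#' @param mode `"cross-correlation"` or `"manual"`.
#' @param offsets T-by-3 integer matrix (dy, dx, dz); required in manual
#'   mode. In manual mode rows are applied directly (content moved by
#'   `+offset`), so applying offsets and then their negation restores the
#'   interior of the original series.
#' @param channel registration channel for ImageStack input.
#' @return list with `series` (same type as input) and `offsets`
#'   (T-by-3 matrix).
#' @export
register_drift <- function(series, mode = c("cross-correlation", "manual"),
                           offsets = NULL, channel = NULL) {
  mode <- match.arg(mode)
  is_stack <- inherits(series, "ImageStack")
  mi <- movie_input(series, channel)
  a <- mi$arr
  nt <- dim(a)[4L]
  if (mode == "manual") {
    if (is.null(offsets)) stop("manual mode requires `offsets`")
    offsets <- matrix(as.integer(offsets), ncol = 3L)
    if (nrow(offsets) != nt) stop("offsets must have one row per timepoint")
    apply_off <- offsets
  } else {
    frame3 <- function(arr, t) {
      f <- arr[, , , t, drop = FALSE]
      dim(f) <- dim(arr)[1:3]
      f
    }
    ref <- frame3(a, 1L)
    offsets <- matrix(0L, nrow = nt, ncol = 3L)
    for (t in 2:nt) offsets[t, ] <- estimate_shift(ref, frame3(a, t))
    apply_off <- -offsets
  }
  colnames(offsets) <- c("dy", "dx", "dz")
  shift_movie <- function(mov) {
    for (t in seq_len(nt))
      if (any(apply_off[t, ] != 0L)) {
        f <- mov[, , , t, drop = FALSE]
        dim(f) <- dim(mov)[1:3]
        mov[, , , t] <- shift_array(f, apply_off[t, ])
      }
    mov
  }
  if (is_stack) {
    for (ch in seq_along(series$channels))
      series <- set_movie(series, ch, shift_movie(get_movie(series, ch)))
    list(series = series, offsets = offsets)
  } else {
    orig_dim <- dim(series)
    out <- shift_movie(a)
    dim(out) <- orig_dim
    list(series = out, offsets = offsets)
  }
}
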