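#' Construct an ImageStack
#'
#' The universal carrier between pipeline stages: a calibrated 5-D voxel grid
#' with canonical axes T (time), Z (depth), C (channel), Y, X. Physical
#' coordinates follow the voxel-center convention: voxel index `i` (1-based)
#' along an axis with spacing `d` sits at `(i - 1) * d` micrometres, and Z
#' increases away from the substrate, i.e. the dish bottom is the plane
#' z = 0. Internally voxels are stored as a numeric array with dimensions
#' `c(Y, X, Z, C, T)` so that in-plane slices are memory-contiguous; all
#' exported accessors speak the canonical TZCYX convention.
#'
#' @param data numeric array with dim `c(Y, X, Z, C, T)` (trailing axes of
#'   length 1 may be dropped; they are re-inserted).
#' @param voxel_size named numeric `c(dx, dy, dz)` in micrometres.
#' @param frame_interval numeric scalar, time between frames.
#' @param time_unit one of `"s"`, `"min"`, `"h"`, `"d"` - never inferred.
#' @param channels character vector of unique channel labels, e.g.
#'   `c("EGFP", "SHG")`.
#' @param dtype storage hint used when saving: `"float32"`, `"uint16"` or
#'   `"uint8"`.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, voxel_size = c(dx = 1, dy = 1, dz = 1),
                        frame_interval = 1, time_unit = "s",
                        channels = NULL, dtype = "float32") {
  if (!is.array(data)) data <- as.array(data)
  d <- dim(data)
  if (length(d) > 5L) stop("data has more than 5 axes")
  if (length(d) < 5L) dim(data) <- d <- c(d, rep(1L, 5L - length(d)))
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[4L]))
  if (length(channels) != d[4L]) stop("channel labels must match C axis")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  vs <- as.numeric(voxel_size)
  if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
    stop("voxel_size must be three strictly positive numbers (dx, dy, dz)")
  names(vs) <- c("dx", "dy", "dz")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  time_unit <- match.arg(time_unit, c("s", "min", "h", "d"))
  if (min(data) < 0) stop("intensities must be nonnegative")
  structure(list(data = data, voxel_size = vs,
                 frame_interval = frame_interval, time_unit = time_unit,
                 channels = as.character(channels), dtype = dtype),
            class = "ImageStack")
}

#' Canonical TZCYX dimensions of a stack
#' @param stack an `ImageStack`.
#' @return named integer vector `c(T, Z, C, Y, X)`.
#' @export
stack_dim <- function(stack) {
  d <- dim(stack$data)
  c(T = d[5L], Z = d[3L], C = d[4L], Y = d[1L], X = d[2L])
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf(
    "<ImageStack> T=%d Z=%d C=%d Y=%d X=%d | voxel %.3gx%.3gx%.3g um | dt=%g %s | channels: %s\n",
    d["T"], d["Z"], d["C"], d["Y"], d["X"], x$voxel_size["dx"],
    x$voxel_size["dy"], x$voxel_size["dz"], x$frame_interval, x$time_unit,
    paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Look up a channel index by label
#' @param stack an `ImageStack`.
#' @param channel channel label or 1-based index.
#' @return integer channel index.
#' @export
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(stack$channels))
      stop(sprintf("channel index %d out of range [1, %d]", ch,
                   length(stack$channels)))
    return(ch)
  }
  ch <- match(channel, stack$channels)
  if (is.na(ch))
    stop(sprintf("channel '%s' not found; available: %s", channel,
                 paste(stack$channels, collapse = ", ")))
  ch
}

#' Extract one 3-D frame (Y, X, Z) of one channel
#' @inheritParams channel_index
#' @param t 1-based timepoint.
#' @return numeric array with dim `c(Y, X, Z)`.
#' @export
get_frame <- function(stack, t, channel) {
  ch <- channel_index(stack, channel)
  d <- stack_dim(stack)
  if (t < 1L || t > d["T"]) stop("timepoint out of range")
  arr <- stack$data[, , , ch, t, drop = FALSE]
  dim(arr) <- dim(stack$data)[1:3]
  arr
}

#' Extract a whole-channel movie as a (Y, X, Z, T) array
#' @inheritParams get_frame
#' @return numeric array with dim `c(Y, X, Z, T)`.
#' @export
get_movie <- function(stack, channel) {
  ch <- channel_index(stack, channel)
  d <- dim(stack$data)
  arr <- stack$data[, , , ch, , drop = FALSE]
  dim(arr) <- d[c(1L, 2L, 3L, 5L)]
  arr
}

#' Replace one channel of a stack
#' @inheritParams get_frame
#' @param movie numeric array with dim `c(Y, X, Z, T)`.
#' @return the modified `ImageStack`.
#' @export
set_movie <- function(stack, channel, movie) {
  ch <- channel_index(stack, channel)
  d <- dim(stack$data)
  if (!identical(as.integer(dim(movie)), as.integer(d[c(1:3, 5L)])))
    stop("movie dimensions do not match the stack")
  stack$data[, , , ch, ] <- movie
  stack
}

# physical coordinates (um) of 1-based voxel indices; z = 0 at dish bottom
voxel_to_um <- function(iy, ix, iz, voxel_size) {
  cbind(x = (ix - 1) * voxel_size[["dx"]],
        y = (iy - 1) * voxel_size[["dy"]],
        z = (iz - 1) * voxel_size[["dz"]])
}
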