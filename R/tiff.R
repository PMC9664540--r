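# Minimal baseline TIFF 6.0 reader/writer (uncompressed, grayscale,
# multi-page). No TIFF library ships with this toolchain, so the subset of
# the format the pipeline needs is implemented here: 8/16-bit unsigned and
# 32-bit float samples, one sample per pixel, strip-based storage, both byte
# orders on read (little-endian on write). Stack-level metadata (axes,
# shape, calibration, channel labels) travels in the first page's
# ImageDescription tag as JSON, which third-party readers ignore gracefully.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

tiff_dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(bits = 8L,  fmt = 1L, what = "integer", size = 1L, signed = FALSE),
    uint16  = list(bits = 16L, fmt = 1L, what = "integer", size = 2L, signed = FALSE),
    float32 = list(bits = 32L, fmt = 3L, what = "double",  size = 4L, signed = TRUE),
    stop(sprintf("unsupported TIFF dtype '%s'", dtype)))
}

#' Write a multi-page TIFF
#'
#' Planes are written in T-major, then Z, then C order (the canonical TZCYX
#' layout); each page is one Y-by-X plane.
#'
#' @param stack an [image_stack()].
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write '%s': parent directory does not exist", path))
  d <- stack_dim(stack)
  if (d[["T"]] < 1L || prod(d) == 0L) stop("cannot write an empty stack")
  info <- tiff_dtype_info(stack$dtype)
  ny <- d[["Y"]]; nx <- d[["X"]]
  n_planes <- d[["T"]] * d[["Z"]] * d[["C"]]
  plane_bytes <- ny * nx * info$size
  meta <- jsonlite::toJSON(list(
    schema = "nodule4d-stack-1", axes = "TZCYX",
    shape = unname(as.integer(d[c("T", "Z", "C", "Y", "X")])),
    voxel_size_um = as.list(stack$voxel_size),
    frame_interval = list(value = stack$frame_interval,
                          unit = stack$time_unit),
    channels = stack$channels, dtype = stack$dtype),
    auto_unbox = TRUE, digits = NA)
  desc <- charToRaw(as.character(meta))
  desc_len <- length(desc) + 1L                 # ASCII tag is NUL-terminated
  desc_pad <- desc_len %% 2L
  desc_off <- 8L
  data_off <- desc_off + desc_len + desc_pad
  ifd_off0 <- data_off + n_planes * plane_bytes
  if (ifd_off0 %% 2L) ifd_off0 <- ifd_off0 + 1L
  n_entries <- function(first) if (first) 11L else 10L
  ifd_size <- function(first) 2L + n_entries(first) * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_off0, con, size = 4L, endian = "little")
  writeBin(desc, con)
  writeBin(0L, con, size = 1L)                  # NUL terminator
  if (desc_pad) writeBin(0L, con, size = 1L)
  # plane data, TZC order, rows (Y) outer, X within a row
  for (t in seq_len(d[["T"]]))
    for (z in seq_len(d[["Z"]]))
      for (ch in seq_len(d[["C"]])) {
        plane <- stack$data[, , z, ch, t]       # Y x X matrix
        v <- as.vector(t(plane))                # row-major
        if (info$what == "integer") {
          v <- as.integer(round(v))
          writeBin(v, con, size = info$size, endian = "little")
        } else {
          writeBin(as.numeric(v), con, size = 4L, endian = "little")
        }
      }
  cur <- seek(con, NA)
  if (cur < ifd_off0) writeBin(raw(ifd_off0 - cur), con)
  # IFDs
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L && count == 1L) {            # SHORT inline, pad to 4
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  off <- ifd_off0
  for (p in seq_len(n_planes)) {
    first <- p == 1L
    strip_off <- data_off + (p - 1L) * plane_bytes
    next_off <- if (p == n_planes) 0L else off + ifd_size(first)
    writeBin(n_entries(first), con, size = 2L, endian = "little")
    entry(TIFF_TAGS["ImageWidth"], 4L, 1L, nx)
    entry(TIFF_TAGS["ImageLength"], 4L, 1L, ny)
    entry(TIFF_TAGS["BitsPerSample"], 3L, 1L, info$bits)
    entry(TIFF_TAGS["Compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["Photometric"], 3L, 1L, 1L)
    if (first) entry(TIFF_TAGS["ImageDescription"], 2L, desc_len, desc_off)
    entry(TIFF_TAGS["StripOffsets"], 4L, 1L, strip_off)
    entry(TIFF_TAGS["SamplesPerPixel"], 3L, 1L, 1L)
    entry(TIFF_TAGS["RowsPerStrip"], 4L, 1L, ny)
    entry(TIFF_TAGS["StripByteCounts"], 4L, 1L, plane_bytes)
    entry(TIFF_TAGS["SampleFormat"], 3L, 1L, info$fmt)
    writeBin(next_off, con, size = 4L, endian = "little")
    off <- off + ifd_size(first)
  }
  invisible(path)
}

read_tiff_value <- function(con, type, count, endian, base_offset = 0L) {
  sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
             `16` = 8L)
  raw4 <- readBin(con, "raw", 4L)      # value/offset field, always 4 bytes
  sz <- sizes[as.character(type)]
  if (is.na(sz) || type == 5L) return(NULL)   # unsupported types skipped
  nbytes <- sz * count
  if (nbytes > 4L) {
    off <- readBin(raw4, "integer", 1L, size = 4L, endian = endian)
    pos <- seek(con, NA)
    seek(con, off + base_offset)
    on.exit(seek(con, pos))
    buf <- readBin(con, "raw", nbytes)
  } else {
    buf <- raw4[seq_len(nbytes)]
  }
  if (type == 2L) {
    v <- rawToChar(buf[buf != as.raw(0)])
  } else if (type == 3L) {
    v <- readBin(buf, "integer", count, size = 2L, signed = FALSE,
                 endian = endian)
  } else if (type == 4L) {
    v <- readBin(buf, "integer", count, size = 4L, endian = endian)
  } else if (type == 1L) {
    v <- as.integer(buf)
  } else {
    v <- readBin(buf, "integer", count, size = 4L, endian = endian)
  }
  v
}

#' Read a multi-page TIFF into planes
#'
#' Low-level reader used by [load_stack()]. Supports uncompressed grayscale
#' pages with 8/16-bit unsigned or 32-bit float samples.
#'
#' @param path TIFF file path.
#' @return list with `planes` (list of Y-by-X matrices), `description`
#'   (character or `NULL`), and `bits`/`format` of the samples.
#' @export
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  endian <- switch(magic, II = "little", MM = "big",
                   stop(sprintf("'%s' is not a TIFF file", path)))
  fortytwo <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  if (fortytwo != 42L) stop(sprintf("'%s' is not a TIFF file", path))
  ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  planes <- list()
  description <- NULL
  bits <- fmt <- NA_integer_
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n <- readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n)) {
      tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                     endian = endian)
      type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                      endian = endian)
      count <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      tags[[as.character(tag)]] <- read_tiff_value(con, type, count, endian)
    }
    ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[tag])]]
      if (is.null(v)) default else v
    }
    if (!is.null(g("Compression")) && g("Compression") != 1L)
      stop("compressed TIFF pages are not supported")
    nx <- g("ImageWidth"); ny <- g("ImageLength")
    bits <- g("BitsPerSample", 8L)[1L]
    fmt <- g("SampleFormat", 1L)[1L]
    spp <- g("SamplesPerPixel", 1L)
    if (spp != 1L) stop("only single-sample (grayscale) TIFFs are supported")
    if (is.null(description)) description <- g("ImageDescription")
    offs <- g("StripOffsets"); cnts <- g("StripByteCounts")
    if (is.null(cnts)) cnts <- ny * nx * bits / 8L
    buf <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      buf <- c(buf, readBin(con, "raw", cnts[s]))
    }
    v <- if (fmt == 3L) {
      readBin(buf, "double", ny * nx, size = bits / 8L, endian = endian)
    } else {
      readBin(buf, "integer", ny * nx, size = bits / 8L,
              signed = bits >= 32L, endian = endian)
    }
    planes[[length(planes) + 1L]] <- matrix(v, nrow = ny, ncol = nx,
                                            byrow = TRUE)
  }
  list(planes = planes, description = description, bits = bits, format = fmt)
}
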