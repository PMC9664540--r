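# Stack and table IO: the stackio module surface.

#' Save an ImageStack to a multi-page TIFF
#'
#' Pages are ordered T, then Z, then C (canonical TZCYX); calibration,
#' channel labels and dtype go into the ImageDescription metadata so that
#' [load_stack()] round-trips voxels and calibration exactly.
#'
#' @param stack an [image_stack()].
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  n4d_log("save_stack: %s planes -> %s",
          paste(stack_dim(stack), collapse = "x"), path)
  write_tiff_stack(stack, path)
}

#' Load an ImageStack from a multi-page TIFF
#'
#' Axes are normalized to the canonical TZCYX order regardless of the
#' on-disk order; missing axes of length 1 are inserted. Files written by
#' [save_stack()] are self-describing; for foreign files `calibration` must
#' supply whatever the file lacks (`axes` of the page loop plus per-axis
#' sizes, voxel sizes, frame interval, channel labels).
#'
#' @param path TIFF file path.
#' @param calibration optional list with any of `axes` (string such as
#'   `"ZCYX"`, page-loop order, slowest axis first), `shape` (named sizes
#'   for the non-YX axes), `voxel_size`, `frame_interval`, `time_unit`,
#'   `channels`, `dtype`.
#' @return an [image_stack()].
#' @export
load_stack <- function(path, calibration = NULL) {
  pg <- read_tiff_pages(path)
  n_pages <- length(pg$planes)
  if (n_pages == 0L) stop(sprintf("'%s' contains no image pages", path))
  meta <- NULL
  if (!is.null(pg$description) && grepl("nodule4d-stack-1", pg$description,
                                        fixed = TRUE))
    meta <- tryCatch(jsonlite::fromJSON(pg$description), error = function(e) NULL)
  cal <- calibration %||% list()
  if (!is.null(meta)) {
    shp <- as.integer(meta$shape)               # T Z C Y X
    nT <- shp[1L]; nZ <- shp[2L]; nC <- shp[3L]
    vs <- unlist(meta$voxel_size_um)[c("dx", "dy", "dz")]
    fi <- meta$frame_interval$value
    tu <- meta$frame_interval$unit
    channels <- meta$channels
    dtype <- meta$dtype
    page_axes <- c("T", "Z", "C")
    page_dims <- c(T = nT, Z = nZ, C = nC)
  } else {
    ax <- cal$axes
    if (is.null(ax)) {
      if (n_pages == 1L) {
        ax <- "YX"
      } else {
        stop(sprintf(paste0(
          "'%s' has %d pages and no usable axis metadata; detected axes: ",
          "YX pages only. Supply calibration$axes (e.g. \"TZCYX\", ",
          "\"ZCYX\") and calibration$shape."), path, n_pages))
      }
    }
    ax_chars <- strsplit(toupper(ax), "")[[1L]]
    if (!all(ax_chars %in% c("T", "Z", "C", "Y", "X")))
      stop("calibration$axes may only contain T, Z, C, Y, X")
    page_axes <- setdiff(ax_chars, c("Y", "X"))
    shape <- cal$shape %||% c()
    page_dims <- vapply(page_axes, function(a)
      if (a %in% names(shape)) as.integer(shape[[a]]) else 1L, integer(1))
    if (length(page_axes)) names(page_dims) <- page_axes
    if (prod(page_dims) != n_pages) {
      # a single unsized page axis can be inferred from the page count
      unsized <- page_axes[!(page_axes %in% names(shape))]
      if (length(unsized) == 1L) {
        known <- prod(page_dims[page_axes %in% names(shape)])
        if (n_pages %% known == 0L)
          page_dims[unsized] <- n_pages %/% known
      }
      if (prod(page_dims) != n_pages)
        stop(sprintf(
          "page count %d does not match calibration axes %s with sizes (%s)",
          n_pages, paste(page_axes, collapse = ""),
          paste(page_dims, collapse = ", ")))
    }
    pick <- function(a) if (a %in% names(page_dims)) page_dims[[a]] else 1L
    nT <- pick("T"); nZ <- pick("Z"); nC <- pick("C")
    vs <- cal$voxel_size %||% c(dx = 1, dy = 1, dz = 1)
    fi <- cal$frame_interval %||% 1
    tu <- cal$time_unit %||% "s"
    channels <- cal$channels
    dtype <- cal$dtype %||% if (pg$format == 3L) "float32"
            else if (pg$bits == 16L) "uint16" else "uint8"
  }
  # allow calibration to override metadata fields it explicitly provides
  if (!is.null(cal$voxel_size)) vs <- cal$voxel_size
  if (!is.null(cal$frame_interval)) fi <- cal$frame_interval
  if (!is.null(cal$time_unit)) tu <- cal$time_unit
  if (!is.null(cal$channels)) channels <- cal$channels
  ny <- nrow(pg$planes[[1L]]); nx <- ncol(pg$planes[[1L]])
  arr <- array(0, dim = c(ny, nx, nZ, nC, nT))
  # decompose page index along page_axes (first axis slowest)
  sizes <- vapply(page_axes, function(a)
    as.integer(switch(a, T = nT, Z = nZ, C = nC)), integer(1))
  for (p in seq_len(n_pages)) {
    idx <- p - 1L
    coord <- c(T = 1L, Z = 1L, C = 1L)
    for (k in rev(seq_along(page_axes))) {      # last axis varies fastest
      coord[page_axes[k]] <- idx %% sizes[k] + 1L
      idx <- idx %/% sizes[k]
    }
    arr[, , coord[["Z"]], coord[["C"]], coord[["T"]]] <- pg$planes[[p]]
  }
  image_stack(arr, voxel_size = vs, frame_interval = fi, time_unit = tu,
              channels = channels, dtype = dtype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a records table to CSV with unit header comments
#'
#' @param records a data.frame, or a list of records (named lists /
#'   one-row data.frames) sharing one schema.
#' @param path output CSV path.
#' @param units optional named character vector documenting column units;
#'   written as `#`-prefixed header comments.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, units = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L) {
      df <- data.frame()
    } else {
      schema <- names(records[[1L]])
      for (i in seq_along(records)) {
        ni <- names(records[[i]])
        bad <- c(setdiff(ni, schema), setdiff(schema, ni))
        if (length(bad))
          stop(sprintf("record %d does not match the table schema: field '%s'",
                       i, bad[[1L]]))
      }
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
  } else stop("records must be a data.frame or a list of records")
  if (is.null(units)) units <- attr(records, "units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nodule4d table v1", con)
  for (nm in names(units))
    writeLines(sprintf("# column %s: %s", nm, units[[nm]]), con)
  if (ncol(df) > 0L || nrow(df) > 0L) {
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       qmethod = "double")
  }
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV path.
#' @return data.frame (comment lines skipped).
#' @export
read_table_csv <- function(path) {
  tryCatch(utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE),
           error = function(e) data.frame())   # header-only / empty table
}
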