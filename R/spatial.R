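# Spatial analysis: IN/ON vs OUT compartment classification, Delaunay
# crowding, subROI count-vs-growth correlation, and the binarized
# MIP SHG/EGFP area ratio.

#' Classify cells into IN/ON vs OUT compartments
#'
#' The SHG surface vertices are projected to the XY plane and enclosed by a
#' concave boundary polygon (`shrink = 0` gives the convex hull); a cell is
#' IN/ON iff its centroid lies inside the polygon (boundary points count as
#' inside) and its centroid height is at or above the lowest point of the
#' SHG surface. Everything else is OUT.
#'
#' @param records CellRecord data.frame with centroid columns `x`, `y`, `z`.
#' @param surface a `SurfaceModel` from [segment_shg()].
#' @param shrink boundary tightening in \[0, 1\]; see [concave_boundary()].
#' @param max_boundary_points deterministic subsampling cap on the mesh
#'   vertices used for the boundary polygon.
#' @return `records` with `compartment` set to `"IN/ON"` or `"OUT"`.
#' @export
classify_compartment <- function(records, surface, shrink = 0.5,
                                 max_boundary_points = 400L) {
  if (nrow(records) == 0L) return(records)
  if (is.null(surface$mesh) || surface$n_voxels == 0L) {
    warning("classify_compartment: empty SHG surface; all cells OUT")
    records$compartment <- "OUT"
    return(records)
  }
  v <- surface$mesh$vertices
  if (nrow(v) > max_boundary_points) {
    step <- ceiling(nrow(v) / max_boundary_points)
    v <- v[seq(1L, nrow(v), by = step), , drop = FALSE]
  }
  poly <- concave_boundary(v[, 1:2, drop = FALSE], shrink = shrink)
  inside <- point_in_polygon(cbind(records$x, records$y), poly)
  above <- records$z >= surface$z_min_um
  records$compartment <- ifelse(inside & above, "IN/ON", "OUT")
  attr(records, "boundary_polygon") <- poly
  n4d_log("classify_compartment: %d IN/ON, %d OUT",
          sum(inside & above), sum(!(inside & above)))
  records
}

#' Mean Delaunay triangle area of a 2-D point set
#'
#' Triangulates the XY positions (typically IN/ON cell centroids) and
#' returns the triangle areas and their mean, the inverse-crowding measure:
#' sparser cells give larger triangles. Degenerate zero-area triangles are
#' excluded.
#'
#' @param points n-by-2 matrix (or data.frame with `x`, `y`) of XY
#'   positions in micrometres.
#' @return list with `mean_area`, `areas`, `triangles` (index matrix) and
#'   `points`.
#' @export
delaunay_mean_area <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("Delaunay crowding requires >= 3 points")
  dt <- delaunay_triangulate(points)
  list(mean_area = mean(dt$areas), areas = dt$areas,
       triangles = dt$triangles, points = points)
}

#' SubROI correlation of high-sphericity counts with matrix increase
#'
#' Divides the field into a `grid` of subROIs (default 4 x 4 = 16), counts
#' high-sphericity IN/ON cells per subROI at timepoint t (centroid rule)
#' and the SHG increase per subROI from t to t+1 (voxel XY position rule),
#' and reports the Spearman correlation across subROIs with the standard
#' strength category.
#'
#' @param records CellRecords at timepoint t, already passed through
#'   [classify_compartment()] and [classify_high_sphericity()].
#' @param surface_t,surface_t1 `SurfaceModel`s at t and t+1 (registered to
#'   the same field).
#' @param grid `c(rows, cols)`; must tile the voxel grid exactly.
#' @param use measure of SHG increase: `"volume"` (default) or `"area"`
#'   (footprint area of the new SHG columns).
#' @return list with `table` (one row per subROI: `row`, `col`,
#'   `n_high_sphericity`, `delta_shg`), `rho`, `p`, `category`.
#' @export
subroi_correlation <- function(records, surface_t, surface_t1,
                               grid = c(4L, 4L), use = c("volume", "area")) {
  use <- match.arg(use)
  d <- dim(surface_t$mask)
  if (!identical(dim(surface_t1$mask), d))
    stop("surfaces must share one voxel grid")
  gy <- grid[1L]; gx <- grid[2L]
  if (d[1L] %% gy != 0L || d[2L] %% gx != 0L)
    stop(sprintf("grid %dx%d does not tile the %dx%d field exactly",
                 gy, gx, d[1L], d[2L]))
  vx <- surface_t$voxel_size
  ty <- d[1L] %/% gy; tx <- d[2L] %/% gx
  vox_vol <- prod(vx)
  cell_ok <- records$compartment == "IN/ON" & records$high_sphericity %in% TRUE
  rows <- list()
  for (r in seq_len(gy)) for (cl in seq_len(gx)) {
    ys <- ((r - 1L) * ty + 1L):(r * ty)
    xs <- ((cl - 1L) * tx + 1L):(cl * tx)
    if (use == "volume") {
      dv <- (sum(surface_t1$mask[ys, xs, ]) - sum(surface_t$mask[ys, xs, ])) *
        vox_vol
    } else {
      foot1 <- apply(surface_t1$mask[ys, xs, , drop = FALSE], c(1, 2), any)
      foot0 <- apply(surface_t$mask[ys, xs, , drop = FALSE], c(1, 2), any)
      dv <- (sum(foot1) - sum(foot0)) * vx[["dx"]] * vx[["dy"]]
    }
    x_lo <- (xs[1L] - 1L) * vx[["dx"]]; x_hi <- xs[length(xs)] * vx[["dx"]]
    y_lo <- (ys[1L] - 1L) * vx[["dy"]]; y_hi <- ys[length(ys)] * vx[["dy"]]
    n_high <- sum(cell_ok & records$x >= x_lo & records$x < x_hi &
                    records$y >= y_lo & records$y < y_hi)
    rows[[length(rows) + 1L]] <- data.frame(row = r, col = cl,
                                            n_high_sphericity = n_high,
                                            delta_shg = dv)
  }
  tab <- do.call(rbind, rows)
  sp <- tryCatch(
    spearman_with_category(tab$n_high_sphericity, tab$delta_shg),
    error = function(e) list(rho = NA_real_, p = NA_real_,
                             category = NA_character_))
  list(table = tab, rho = sp$rho, p = sp$p, category = sp$category)
}

#' Binarized SHG/EGFP area ratio from maximum intensity projections
#'
#' Projects each channel along Z by maximum intensity, binarizes both with
#' the automatic threshold policy, and returns the ratio of SHG-positive to
#' EGFP-positive area.
#'
#' @param stack an [image_stack()] with both channels.
#' @param t timepoint.
#' @param shg,egfp channel labels.
#' @param threshold `"otsu"` or fixed numeric (applied to both MIPs).
#' @return the area ratio (dimensionless).
#' @export
mip_ratio <- function(stack, t = 1L, shg = "SHG", egfp = "EGFP",
                      threshold = NULL) {
  f_shg <- get_frame(stack, t, shg)
  f_egfp <- get_frame(stack, t, egfp)
  mip <- function(a) apply(a, c(1L, 2L), max)
  m_shg <- mip(f_shg); m_egfp <- mip(f_egfp)
  thr_s <- resolve_threshold(m_shg, threshold)
  thr_e <- resolve_threshold(m_egfp, threshold)
  area_s <- if (is.na(thr_s)) 0 else sum(m_shg > thr_s)
  area_e <- if (is.na(thr_e)) 0 else sum(m_egfp > thr_e)
  if (area_e == 0L)
    stop("mip_ratio: empty EGFP mask; ratio undefined")
  area_s / area_e
}

#' SHG/EGFP MIP ratio time series
#'
#' @inheritParams mip_ratio
#' @return data.frame with `t`, `ratio`, and `change` (ratio relative to
#'   the first timepoint, the pre-treatment reference).
#' @export
mip_ratio_series <- function(stack, shg = "SHG", egfp = "EGFP",
                             threshold = NULL) {
  nT <- stack_dim(stack)[["T"]]
  ratio <- vapply(seq_len(nT), function(t)
    mip_ratio(stack, t, shg, egfp, threshold), numeric(1))
  data.frame(t = seq_len(nT), ratio = ratio, change = ratio / ratio[1L])
}

#' Per-timepoint summary of an SHG surface series
#'
#' @param surfaces list of `SurfaceModel`s ordered by timepoint.
#' @return data.frame with `t`, `volume_um3`, `area_um2` and the since-last
#'   observation increments (`NA` at the first timepoint).
#' @export
surface_series_summary <- function(surfaces) {
  v <- vapply(surfaces, function(s) s$volume_um3, numeric(1))
  a <- vapply(surfaces, function(s) s$area_um2, numeric(1))
  data.frame(t = seq_along(surfaces), volume_um3 = v, area_um2 = a,
             delta_volume_um3 = c(NA, diff(v)),
             delta_area_um2 = c(NA, diff(a)))
}
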