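# 2-D computational geometry primitives: Delaunay triangulation
# (Bowyer-Watson), alpha-shape concave boundary with a shrink parameter,
# and point-in-polygon by winding number (boundary points count as inside).

tri_circum <- function(p, tri) {
  ax <- p[tri[, 1L], 1L]; ay <- p[tri[, 1L], 2L]
  bx <- p[tri[, 2L], 1L]; by <- p[tri[, 2L], 2L]
  cx <- p[tri[, 3L], 1L]; cy <- p[tri[, 3L], 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax * ax + ay * ay
  b2 <- bx * bx + by * by
  c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  cbind(ux = ux, uy = uy, r2 = r2)
}

#' Delaunay triangulation of 2-D points (Bowyer-Watson)
#'
#' @param points n-by-2 numeric matrix. Exact duplicates are collapsed.
#' @return list with `triangles` (m-by-3 matrix of 1-based row indices into
#'   `points`), `areas` (triangle areas), and `points` (the input).
#'   Degenerate (zero-area) triangles are excluded.
#' @export
delaunay_triangulate <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n-by-2 matrix")
  uniq <- !duplicated(points)
  idx_map <- which(uniq)
  p <- points[uniq, , drop = FALSE]
  n <- nrow(p)
  if (n < 3L) stop("Delaunay triangulation requires >= 3 distinct points")
  ctr <- colMeans(p)
  ext <- max(apply(p, 2L, function(v) diff(range(v))), 1e-12)
  # far super-triangle; the incircle predicate below is the translated
  # 3x3 determinant, which stays well-conditioned for these mixed
  # (real + super) triangles, unlike circumcenter containment
  big <- 1e6 * ext
  super <- rbind(c(ctr[1L] - 2 * big, ctr[2L] - big),
                 c(ctr[1L] + 2 * big, ctr[2L] - big),
                 c(ctr[1L], ctr[2L] + 2 * big))
  pp <- rbind(p, super)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3L)
  incircle_bad <- function(tris, px, py) {
    ax <- pp[tris[, 1L], 1L] - px; ay <- pp[tris[, 1L], 2L] - py
    bx <- pp[tris[, 2L], 1L] - px; by <- pp[tris[, 2L], 2L] - py
    cx <- pp[tris[, 3L], 1L] - px; cy <- pp[tris[, 3L], 2L] - py
    det <- (ax * ax + ay * ay) * (bx * cy - by * cx) -
           (bx * bx + by * by) * (ax * cy - ay * cx) +
           (cx * cx + cy * cy) * (ax * by - ay * bx)
    orient <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    det * sign(orient) > 0
  }
  for (i in seq_len(n)) {
    bad <- which(incircle_bad(tris, pp[i, 1L], pp[i, 2L]))
    if (!length(bad)) next                    # duplicate-grade degeneracy
    # boundary of the cavity: edges of bad triangles appearing exactly once
    e <- rbind(tris[bad, c(1L, 2L), drop = FALSE],
               tris[bad, c(2L, 3L), drop = FALSE],
               tris[bad, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    single <- key %in% names(which(table(key) == 1L))
    eb <- e[single, , drop = FALSE]
    new_tris <- cbind(i, eb)
    keep <- setdiff(seq_len(nrow(tris)), bad)
    tris <- rbind(tris[keep, , drop = FALSE], new_tris)
  }
  real <- tris[apply(tris <= n, 1L, all), , drop = FALSE]
  if (nrow(real) == 0L)
    stop("Delaunay triangulation is degenerate (points are collinear)")
  areas <- triangle_areas(p, real)
  keep <- areas > 0
  real <- real[keep, , drop = FALSE]
  areas <- areas[keep]
  if (nrow(real) == 0L)
    stop("Delaunay triangulation is degenerate (points are collinear)")
  tri_orig <- matrix(idx_map[real], ncol = 3L)
  list(triangles = tri_orig, areas = areas, points = points)
}

triangle_areas <- function(p, tri) {
  abs((p[tri[, 2L], 1L] - p[tri[, 1L], 1L]) *
      (p[tri[, 3L], 2L] - p[tri[, 1L], 2L]) -
      (p[tri[, 3L], 1L] - p[tri[, 1L], 1L]) *
      (p[tri[, 2L], 2L] - p[tri[, 1L], 2L])) / 2
}

#' Shoelace area of a polygon
#' @param poly m-by-2 matrix of ordered vertices (open ring).
#' @return nonnegative area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Winding-number test; points lying on a polygon edge (within a relative
#' tolerance) are classified inside, the deterministic tie rule used by the
#' compartment classifier.
#'
#' @param pts n-by-2 matrix of query points.
#' @param poly m-by-2 matrix of ordered polygon vertices (open ring).
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  px <- pts[, 1L]; py <- pts[, 2L]
  m <- nrow(poly)
  wn <- integer(length(px))
  on_edge <- logical(length(px))
  scale <- max(abs(poly)) + 1
  eps <- 1e-9 * scale
  for (k in seq_len(m)) {
    x1 <- poly[k, 1L]; y1 <- poly[k, 2L]
    j <- if (k == m) 1L else k + 1L
    x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    up <- (y1 <= py) & (y2 > py) & (is_left > 0)
    dn <- (y2 <= py) & (y1 > py) & (is_left < 0)
    wn <- wn + up - dn
    seg2 <- (x2 - x1)^2 + (y2 - y1)^2
    tpar <- ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / max(seg2, eps^2)
    near <- abs(is_left) <= eps * sqrt(max(seg2, eps^2)) &
      tpar >= -1e-12 & tpar <= 1 + 1e-12
    on_edge <- on_edge | near
  }
  wn != 0L | on_edge
}

alpha_valid <- function(n_pts, tri, radii, alpha) {
  keep <- which(radii <= alpha)
  if (!length(keep)) return(NULL)
  kt <- tri[keep, , drop = FALSE]
  if (!all(seq_len(n_pts) %in% kt)) return(NULL)
  # edge table
  e <- rbind(kt[, c(1L, 2L), drop = FALSE], kt[, c(2L, 3L), drop = FALSE],
             kt[, c(3L, 1L), drop = FALSE])
  key <- pmin(e[, 1L], e[, 2L]) * (n_pts + 1) + pmax(e[, 1L], e[, 2L])
  tab <- table(key)
  if (any(tab > 2L)) return(NULL)
  # connectivity of kept triangles through shared edges (union-find)
  parent <- seq_len(nrow(kt))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tri_of_edge <- split(rep(seq_len(nrow(kt)), 3L), key)
  for (g in tri_of_edge)
    if (length(g) == 2L) {
      a <- find(g[1L]); b <- find(g[2L])
      if (a != b) parent[a] <- b
    }
  if (length(unique(vapply(seq_len(nrow(kt)), find, integer(1)))) != 1L)
    return(NULL)
  # boundary edges must form a single closed cycle
  bkey <- as.numeric(names(tab)[tab == 1L])
  b2 <- cbind(floor(bkey / (n_pts + 1)), bkey %% (n_pts + 1))
  verts <- c(b2[, 1L], b2[, 2L])
  deg <- table(verts)
  if (any(deg != 2L)) return(NULL)
  # walk the cycle
  adj <- split(c(b2[, 2L], b2[, 1L]), c(b2[, 1L], b2[, 2L]))
  start <- b2[1L, 1L]
  ring <- start
  prev <- -1L
  cur <- start
  repeat {
    nb <- adj[[as.character(cur)]]
    nxt <- nb[nb != prev][1L]
    if (nxt == start) break
    ring <- c(ring, nxt)
    prev <- cur
    cur <- nxt
    if (length(ring) > nrow(b2)) return(NULL)
  }
  if (length(ring) != nrow(b2)) return(NULL)
  list(ring = as.integer(ring), keep = keep)
}

#' Concave boundary polygon of a 2-D point set
#'
#' Alpha-shape boundary with a `shrink` parameter emulating the common
#' boundary-function contract: `shrink = 0` gives the convex hull and
#' increasing values tighten the envelope (the enclosed area is
#' non-increasing in `shrink`), while the polygon always stays a single
#' closed ring enclosing every input point.
#'
#' @param points n-by-2 matrix.
#' @param shrink tightening factor in \[0, 1\].
#' @return ordered polygon vertex matrix (open ring) with attribute
#'   `"alpha"` (the circumradius threshold used).
#' @export
concave_boundary <- function(points, shrink = 0.5) {
  if (shrink < 0 || shrink > 1) stop("shrink must be in [0, 1]")
  points <- as.matrix(points)
  uniq <- !duplicated(points)
  p <- points[uniq, , drop = FALSE]
  dt <- delaunay_triangulate(p)
  cc <- tri_circum(p, dt$triangles)
  radii <- sqrt(cc[, 3L])
  cand <- sort(unique(radii))
  # smallest alpha keeping a single, hole-free region covering all points
  valid_at <- function(alpha) alpha_valid(nrow(p), dt$triangles, radii, alpha)
  lo <- 1L; hi <- length(cand)
  # binary search for the smallest valid candidate (validity is monotone in
  # practice; a linear fallback guards against the rare non-monotone case)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (!is.null(valid_at(cand[mid]))) hi <- mid else lo <- mid + 1L
  }
  i_min <- lo
  while (i_min <= length(cand) && is.null(valid_at(cand[i_min])))
    i_min <- i_min + 1L
  usable <- cand[i_min:length(cand)]
  target <- usable[round((1 - shrink) * (length(usable) - 1L)) + 1L]
  res <- valid_at(target)
  k <- match(target, usable)
  while (is.null(res) && k < length(usable)) {
    k <- k + 1L
    res <- valid_at(usable[k])
  }
  poly <- p[res$ring, , drop = FALSE]
  attr(poly, "alpha") <- target
  poly
}
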