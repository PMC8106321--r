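# Planar geometry kernel.
#
# Polygons are two-column matrices (x_km, y_km) holding an *open* ring:
# the first vertex is not repeated at the end.  All administrative
# polygons produced by the synthetic generator are convex (rectangles and
# Voronoi cells of rectangles), so the clipping routines assume convex
# clip regions; this keeps every operation exact up to floating point.

#' Signed and absolute polygon area
#'
#' Shoelace formula.  Positive sign means counter-clockwise orientation.
#'
#' @param poly Two-column matrix of vertices (open ring).
#' @return `polygon_area()` returns the absolute area; `polygon_area_signed()`
#'   the signed area.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' @rdname polygon_area
#' @export
polygon_area_signed <- function(poly) {
  p <- as.matrix(poly)
  if (nrow(p) < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Ensure counter-clockwise orientation.
ccw <- function(poly) {
  if (polygon_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Point-in-polygon test for convex polygons
#'
#' Boundary points count as inside (within `tol`).
#'
#' @param pt Length-2 numeric vector.
#' @param poly Convex polygon (open ring).
#' @param tol Slack, in squared-km-free units of the cross product.
#' @return Logical.
#' @export
point_in_convex_polygon <- function(pt, poly, tol = 1e-9) {
  p <- ccw(as.matrix(poly))
  n <- nrow(p)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- (xn - x) * (pt[2L] - y) - (yn - y) * (pt[1L] - x)
  all(cr >= -tol)
}

# Clip a polygon by the half-plane { z : (z - a) . nrm <= 0 }.
# Sutherland-Hodgman step; returns a matrix with 0 rows when empty.
clip_halfplane <- function(poly, a, nrm, tol = 1e-12) {
  p <- as.matrix(poly)
  n <- nrow(p)
  if (n == 0L) return(p)
  d <- (p[, 1L] - a[1L]) * nrm[1L] + (p[, 2L] - a[2L]) * nrm[2L]
  inside <- d <= tol
  if (all(inside)) return(p)
  if (!any(inside)) return(p[0L, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, p[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, p[i, ] + t * (p[j, ] - p[i, ]))
    }
  }
  dedup_ring(out)
}

# Drop consecutive (near-)duplicate vertices produced by clipping.
dedup_ring <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 2L) return(poly)
  nxt <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  keep <- rowSums(abs(poly - nxt)) > tol
  keep[!any(keep)] <- TRUE
  poly[keep, , drop = FALSE]
}

#' Intersection of a polygon with a convex polygon
#'
#' Clips `poly` successively by the edges of the convex polygon `clip`.
#'
#' @param poly Subject polygon (open ring).
#' @param clip Convex clip polygon (open ring).
#' @return The clipped polygon; zero rows when the intersection is empty.
#' @export
clip_polygon_convex <- function(poly, clip) {
  cl <- ccw(as.matrix(clip))
  n <- nrow(cl)
  out <- as.matrix(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    v1 <- cl[i, ]; v2 <- cl[j, ]
    # outward normal of a CCW edge
    nrm <- c(v2[2L] - v1[2L], -(v2[1L] - v1[1L]))
    out <- clip_halfplane(out, v1, nrm)
    if (nrow(out) == 0L) break
  }
  out
}

#' Do two convex polygons intersect?
#'
#' Boundary touching counts as intersecting (conservative candidate
#' inclusion for the spatial-overlay step).
#'
#' @param a,b Convex polygons (open rings).
#' @return Logical.
#' @export
convex_polygons_intersect <- function(a, b) {
  nrow(clip_polygon_convex(a, b)) >= 1L
}

#' Voronoi (Thiessen) cells clipped to a convex boundary
#'
#' Computes, for each generating point, the intersection of its Voronoi
#' cell with the boundary polygon by iterated bisector half-plane
#' clipping.  Exact for convex boundaries; cells partition the boundary.
#' Duplicate generating points are perturbed by a deterministic epsilon
#' offset with a warning.
#'
#' @param points Two-column matrix of generating points inside `boundary`.
#' @param boundary Convex polygon (open ring).
#' @return List of polygons, one per point, in input order.
#' @export
voronoi_cells <- function(points, boundary) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) stop("need at least one generating point", call. = FALSE)
  bnd <- ccw(as.matrix(boundary))
  key <- paste(signif(pts[, 1L], 12L), signif(pts[, 2L], 12L))
  dup <- duplicated(key)
  if (any(dup)) {
    warning("duplicate generating points perturbed by epsilon", call. = FALSE)
    idx <- which(dup)
    eps <- 1e-6 * max(diff(range(bnd[, 1L])), diff(range(bnd[, 2L])), 1)
    ang <- 2 * pi * seq_along(idx) / (length(idx) + 1)
    pts[idx, 1L] <- pts[idx, 1L] + eps * cos(ang)
    pts[idx, 2L] <- pts[idx, 2L] + eps * sin(ang)
  }
  n <- nrow(pts)
  if (n == 1L) return(list(bnd))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- bnd
    d2 <- (pts[, 1L] - pts[i, 1L])^2 + (pts[, 2L] - pts[i, 2L])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      # once half the distance to the next point exceeds the cell radius,
      # no remaining bisector can cut the cell
      r2 <- max((cell[, 1L] - pts[i, 1L])^2 + (cell[, 2L] - pts[i, 2L])^2)
      if (d2[j] / 4 > r2) break
      mid <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[j, ] - pts[i, ]
      cell <- clip_halfplane(cell, mid, nrm)
      if (nrow(cell) == 0L) break
    }
    cells[[i]] <- cell
  }
  cells
}

#' Rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax Corners, in km.
#' @return A 4-vertex open-ring polygon (counter-clockwise).
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
         ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

#' Regular polygon approximating a disc
#'
#' Used for cluster buffers.  An inscribed regular `n_segments`-gon has
#' area `n/2 * r^2 * sin(2*pi/n)`, within 0.16% of `pi * r^2` at 64
#' segments.
#'
#' @param center Length-2 numeric vector.
#' @param radius Radius in km, must be positive.
#' @param n_segments Number of edges, default 64.
#' @return Polygon matrix (open ring, counter-clockwise).
#' @export
disc_polygon <- function(center, radius, n_segments = 64L) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("'radius' must be positive", call. = FALSE)
  }
  ang <- 2 * pi * (seq_len(n_segments) - 1L) / n_segments
  cbind(x = center[1L] + radius * cos(ang),
        y = center[2L] + radius * sin(ang))
}
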