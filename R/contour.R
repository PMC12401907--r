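# Closed planar contours (intima / media / EEM) and the polygon primitives
# every cross-sectional index is built from.  All coordinates are
# frame-local Cartesian millimetres.

#' Construct a vessel-wall contour
#'
#' A contour is an ordered closed simple polygon (the last vertex connects
#' back to the first) tagged with the wall structure it delineates.
#' Vertices are normalized to counterclockwise orientation on construction.
#'
#' @param vertices numeric matrix (or coercible 2-column object) of `(x, y)`
#'   vertex coordinates in mm, at least 3 rows.
#' @param role one of `"intima"`, `"media"`, `"eem"`.
#' @param check_simple verify that the polygon is non-self-intersecting
#'   (`O(n^2)`; generators building star-shaped contours may skip it).
#' @return an object of class `oct_contour`: a list with `vertices`
#'   (n x 2 matrix, counterclockwise) and `role`.
#' @export
contour <- function(vertices, role = c("intima", "media", "eem"),
                    check_simple = TRUE) {
  role <- match.arg(role)
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    abort_oct("contour vertices must be a numeric n x 2 matrix",
              "octbias_invalid_contour")
  }
  # drop a duplicated closing vertex if the caller supplied one
  n <- nrow(v)
  if (n >= 2L && all(abs(v[n, ] - v[1, ]) < 1e-12)) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) {
    abort_oct("contour needs at least 3 distinct vertices",
              "octbias_invalid_contour")
  }
  if (anyNA(v) || any(!is.finite(v))) {
    abort_oct("contour vertices must be finite", "octbias_invalid_contour")
  }
  a <- signed_area(v)
  if (abs(a) < 1e-12) {
    abort_oct("degenerate (zero-area) contour", "octbias_invalid_contour")
  }
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  if (check_simple && !is_simple_polygon(v)) {
    abort_oct("self-intersecting contour", "octbias_invalid_contour")
  }
  structure(list(vertices = v, role = role), class = "oct_contour")
}

#' @export
print.oct_contour <- function(x, ...) {
  cat(sprintf("<oct_contour role=%s, %d vertices, area %.4f mm^2>\n",
              x$role, nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

# Shoelace signed area (positive for counterclockwise vertex order).
signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Pairwise proper-intersection scan over non-adjacent edges.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  p1 <- v
  p2 <- v[c(2:n, 1), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1L) &
               !(outer(seq_len(n), seq_len(n),
                       function(i, j) i == 1L & j == n)),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) return(TRUE)
  a1 <- p1[idx[, 1], , drop = FALSE]; a2 <- p2[idx[, 1], , drop = FALSE]
  b1 <- p1[idx[, 2], , drop = FALSE]; b2 <- p2[idx[, 2], , drop = FALSE]
  o <- function(p, q, r) {
    (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) -
      (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  }
  d1 <- o(a1, a2, b1); d2 <- o(a1, a2, b2)
  d3 <- o(b1, b2, a1); d4 <- o(b1, b2, a2)
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  # collinear overlap (touching at shared coordinates) also breaks simplicity
  eps <- 1e-12
  coll <- abs(d1) < eps & abs(d2) < eps & abs(d3) < eps & abs(d4) < eps
  if (any(coll)) {
    ov <- vapply(which(coll), function(k) {
      rx <- range(a1[k, 1], a2[k, 1]); ry <- range(a1[k, 2], a2[k, 2])
      sx <- range(b1[k, 1], b2[k, 1]); sy <- range(b1[k, 2], b2[k, 2])
      rx[1] <= sx[2] && sx[1] <= rx[2] && ry[1] <= sy[2] && sy[1] <= ry[2]
    }, logical(1))
    if (any(ov)) return(FALSE)
  }
  !any(proper)
}

#' Polygon area of a contour
#'
#' Shoelace area of the closed polygon, positive regardless of stored
#' orientation.  Realizes the luminal area (LA) index when applied to the
#' intima contour and the EEM cross-sectional area when applied to the EEM.
#'
#' @param x an [contour()] object.
#' @return area in mm^2.
#' @export
polygon_area <- function(x) {
  stopifnot(inherits(x, "oct_contour"))
  abs(signed_area(x$vertices))
}

#' Area centroid of a contour
#'
#' The polygon (area) centroid; used as the "center point of the vessel" /
#' "center point of the lumen" for chord and bias-direction constructions.
#'
#' @param x an [contour()] object.
#' @return numeric length-2 `(x, y)` in mm.
#' @export
centroid <- function(x) {
  stopifnot(inherits(x, "oct_contour"))
  v <- x$vertices
  xs <- v[, 1]; ys <- v[, 2]
  xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
  cr <- xs * yn - xn * ys
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    abort_oct("degenerate (zero-area) contour", "octbias_invalid_contour")
  }
  c(sum((xs + xn) * cr), sum((ys + yn) * cr)) / (6 * a)
}

#' Is a point strictly inside a contour?
#'
#' Even-odd (crossing-number) test.
#'
#' @param pt numeric length-2 `(x, y)` in mm.
#' @param x an [contour()] object.
#' @return logical scalar.
#' @export
point_in_contour <- function(pt, x) {
  stopifnot(inherits(x, "oct_contour"))
  v <- x$vertices
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  cross <- ((y1 > pt[2]) != (y2 > pt[2])) &
    (pt[1] < (x2 - x1) * (pt[2] - y1) / (y2 - y1) + x1)
  sum(cross) %% 2L == 1L
}

# Distances from `origin` along rays at `angles_deg` to the first boundary
# crossing of `cont`.  Vectorized over angles x edges; returns Inf where a
# ray never crosses (cannot happen for an interior origin).
ray_distances <- function(origin, angles_deg, cont) {
  v <- cont$vertices
  n <- nrow(v)
  p <- v
  d <- v[c(2:n, 1), , drop = FALSE] - v
  w1 <- p[, 1] - origin[1]
  w2 <- p[, 2] - origin[2]
  rad <- angles_deg * pi / 180
  u1 <- cos(rad); u2 <- sin(rad)
  denom <- outer(u1, d[, 2]) - outer(u2, d[, 1])          # cross(u, d)
  cross_wd <- w1 * d[, 2] - w2 * d[, 1]                   # cross(w, d)
  tmat <- t(cross_wd / t(denom))                          # k x n
  smat <- (outer(u2, w1) - outer(u1, w2)) / denom         # cross(w, u)/denom
  # s tolerance keeps rays through a shared vertex from being missed on
  # both adjacent edges; the duplicate hit is harmless under the min
  bad <- !is.finite(tmat) | smat < -1e-9 | smat >= 1 + 1e-9 |
    tmat <= 1e-9 | abs(denom) < 1e-14
  tmat[bad] <- Inf
  do.call(pmin, as.data.frame(tmat))
}

#' Distance from an interior point to a contour along a ray
#'
#' Nearest intersection of the ray from `origin` in direction `direction`
#' (degrees, counterclockwise from +x) with the polygon boundary.  This is
#' the primitive behind the catheter-to-intima / catheter-to-media distance
#' indices.
#'
#' @param origin numeric length-2 point strictly inside the contour.
#' @param direction angle in degrees.
#' @param x an [contour()] object.
#' @return distance in mm (finite, > 0).
#' @export
ray_contour_distance <- function(origin, direction, x) {
  stopifnot(inherits(x, "oct_contour"))
  if (!point_in_contour(origin, x)) {
    abort_oct("ray origin must lie strictly inside the contour",
              "octbias_precondition")
  }
  d <- ray_distances(origin, direction, x)
  if (!is.finite(d)) {
    abort_oct("ray does not intersect the contour boundary",
              "octbias_precondition")
  }
  d
}
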