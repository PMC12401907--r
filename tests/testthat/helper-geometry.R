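# Geometry fixtures and independent brute-force oracles.  Oracles here are
# coded from first principles (scalar loops, linear solves, rasterization)
# so they share no code path with the package's vectorized primitives.

circle_pts <- function(r = 1, center = c(0, 0), n = 256) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

make_circle <- function(r = 1, center = c(0, 0), n = 256, role = "intima") {
  contour(circle_pts(r, center, n), role)
}

ellipse_pts <- function(a, b, center = c(0, 0), n = 256, rot = 0) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  x <- a * cos(th); y <- b * sin(th)
  rr <- rot * pi / 180
  cbind(center[1] + x * cos(rr) - y * sin(rr),
        center[2] + x * sin(rr) + y * cos(rr))
}

make_ellipse <- function(a, b, center = c(0, 0), n = 256, rot = 0,
                         role = "intima") {
  contour(ellipse_pts(a, b, center, n, rot), role)
}

# Random star-shaped polygon about `center`: radii at jittered sorted
# angles.  Star-shaped => simple, and its area has the exact polar sector
# closed form used as the area oracle.
random_star <- function(n = 12, r_range = c(0.5, 1.5), center = c(0, 0)) {
  # jittered full-circle grid: every angular gap stays below pi, which
  # keeps the star polygon simple and the sector formula valid
  th <- (seq_len(n) - 1 + runif(n, 0.05, 0.95)) * 2 * pi / n
  r <- runif(n, r_range[1], r_range[2])
  list(pts = cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
       r = r, th = th)
}

# Exact area of a star polygon from its polar parametrization: sum of
# triangle areas (C, P_i, P_{i+1}) = r_i r_{i+1} sin(dtheta) / 2.
star_area_oracle <- function(star) {
  r <- star$r; th <- star$th
  r2 <- c(r[-1], r[1])
  dth <- c(diff(th), 2 * pi - (th[length(th)] - th[1]))
  sum(r * r2 * sin(dth)) / 2
}

# Pixel-counting area oracle on a centered grid of the given step.
raster_area_oracle <- function(ct, step = 0.002) {
  v <- ct$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- seq(xr[1] - step, xr[2] + step, by = step)
  ys <- seq(yr[1] - step, yr[2] + step, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  n <- nrow(v)
  crossings <- integer(length(gx))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    hit <- ((y1 > gy) != (y2 > gy)) &
      (gx < (x2 - x1) * (gy - y1) / (y2 - y1) + x1)
    crossings <- crossings + hit
  }
  sum(crossings %% 2L == 1L) * step^2
}

# Fan-triangulation centroid oracle (signed-area weighted triangle
# centroids, fanned from the first vertex).
fan_centroid_oracle <- function(ct) {
  v <- ct$vertices
  n <- nrow(v)
  a_tot <- 0
  cx <- cy <- 0
  for (i in 2:(n - 1)) {
    p1 <- v[1, ]; p2 <- v[i, ]; p3 <- v[i + 1, ]
    a <- ((p2[1] - p1[1]) * (p3[2] - p1[2]) -
            (p2[2] - p1[2]) * (p3[1] - p1[1])) / 2
    a_tot <- a_tot + a
    cx <- cx + a * (p1[1] + p2[1] + p3[1]) / 3
    cy <- cy + a * (p1[2] + p2[2] + p3[2]) / 3
  }
  c(cx, cy) / a_tot
}

# Scalar brute-force ray/polygon distance: loop over edges, solve each
# 2x2 linear system with solve().
ray_dist_bf <- function(origin, ang_deg, ct) {
  v <- ct$vertices
  n <- nrow(v)
  u <- c(cos(ang_deg * pi / 180), sin(ang_deg * pi / 180))
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- v[j, ] - v[i, ]
    A <- cbind(u, -d)
    if (abs(det(A)) < 1e-14) next
    ts <- solve(A, v[i, ] - origin)
    if (ts[1] > 1e-9 && ts[2] >= -1e-9 && ts[2] < 1 + 1e-9) {
      best <- min(best, ts[1])
    }
  }
  best
}

# Rigid motion: rotate by ang_deg about the origin, then translate.
rt_pts <- function(pts, ang_deg = 0, shift = c(0, 0)) {
  r <- ang_deg * pi / 180
  cbind(pts[, 1] * cos(r) - pts[, 2] * sin(r) + shift[1],
        pts[, 1] * sin(r) + pts[, 2] * cos(r) + shift[2])
}

rt_contour <- function(ct, ang_deg = 0, shift = c(0, 0)) {
  if (is.null(ct)) return(NULL)
  contour(rt_pts(ct$vertices, ang_deg, shift), ct$role, check_simple = FALSE)
}

rt_cross_section <- function(cs, ang_deg = 0, shift = c(0, 0)) {
  cross_section(cs$frame_id, cs$z,
                rt_contour(cs$intima, ang_deg, shift),
                catheter_pose(rt_pts(rbind(cs$catheter$center),
                                     ang_deg, shift)[1, ],
                              cs$catheter$radius),
                media = rt_contour(cs$media, ang_deg, shift),
                eem = rt_contour(cs$eem, ang_deg, shift),
                calcium_arcs = cs$calcium_arcs,
                dissection = cs$dissection, check = FALSE)
}

# A small fully annotated synthetic frame (circular lumen, offset
# catheter, media + EEM) for composition tests.
demo_frame <- function(r_lumen = 2, off = 0.5, t_im = 0.25, t_me = 0.15,
                       n = 256) {
  cross_section(1L, 0,
                intima = make_circle(r_lumen, n = n),
                catheter = catheter_pose(c(off, 0)),
                media = make_circle(r_lumen + t_im, n = n, role = "media"),
                eem = make_circle(r_lumen + t_im + t_me, n = n, role = "eem"))
}
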