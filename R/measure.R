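# Per-frame measurement operators: the eleven cross-sectional indices and
# the bias-quadrant construction.

#' Bias geometry of a frame
#'
#' The bias direction is the ray from the vessel center (area centroid of
#' the intima contour) through the catheter center; the bias quadrant is
#' the 90-degree sector about that ray (+/- 45 degrees), anchored at the
#' vessel center.
#'
#' @param cs an [cross_section()].
#' @param eps_bias mm; below this catheter-to-centroid offset the bias
#'   direction is declared undefined (concentric catheter) rather than
#'   numerically unstable.
#' @return list of class `oct_bias` with `vessel_center`, `bias_angle`
#'   (degrees), `quadrant` (angular interval) and `offset` (mm).
#' @export
bias_geometry <- function(cs, eps_bias = 0.05) {
  stopifnot(inherits(cs, "oct_cross_section"))
  vc <- centroid(cs$intima)
  d <- cs$catheter$center - vc
  off <- sqrt(sum(d^2))
  if (off < eps_bias) {
    abort_oct(sprintf(
      "catheter offset %.4f mm < eps_bias %.3f mm: bias direction undefined",
      off, eps_bias), "octbias_bias_undefined")
  }
  ang <- deg_norm(atan2(d[2], d[1]) * 180 / pi)
  structure(list(vessel_center = vc, bias_angle = ang,
                 quadrant = deg_norm(c(ang - 45, ang + 45)), offset = off),
            class = "oct_bias")
}

#' Catheter-to-wall distance indices
#'
#' Distances from the catheter center along the bias ray (`*_b`) and its
#' opposite (`*_o`) to the first crossing of the intima and media contours:
#' `d_cib`, `d_cio`, `d_cmb`, `d_cmo`.  Media-based values are `NA` when no
#' media contour is segmented.
#'
#' @param cs an [cross_section()].
#' @param bias an [bias_geometry()] result for the same frame.
#' @return named numeric vector `c(d_cib, d_cio, d_cmb, d_cmo)` in mm.
#' @export
distance_indices <- function(cs, bias) {
  stopifnot(inherits(cs, "oct_cross_section"), inherits(bias, "oct_bias"))
  o <- cs$catheter$center
  ang <- c(bias$bias_angle, bias$bias_angle + 180)
  di <- ray_distances(o, ang, cs$intima)
  dm <- if (is.null(cs$media)) c(NA_real_, NA_real_) else {
    ray_distances(o, ang, cs$media)
  }
  c(d_cib = di[1], d_cio = di[2], d_cmb = dm[1], d_cmo = dm[2])
}

#' Touch angle: arc of catheter-intima contact
#'
#' Rays from the catheter center are sampled every `dtheta` degrees; a
#' direction is in contact where the distance to the intima does not exceed
#' the catheter radius plus `gap_tol`.  The reported touch angle is the
#' length of the largest contiguous contact run (wrap-around handled);
#' `mode = "sum"` instead sums all disjoint contact arcs.
#'
#' @param cs an [cross_section()].
#' @param gap_tol mm of radial clearance still counted as contact
#'   (default 0.02 mm, about two OCT pixels).
#' @param dtheta angular sampling step in degrees.
#' @param mode `"largest_run"` (default) or `"sum"`.
#' @return contact arc in degrees, 0 if no contact.
#' @export
touch_angle <- function(cs, gap_tol = 0.02, dtheta = 0.5,
                        mode = c("largest_run", "sum")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cs, "oct_cross_section"), gap_tol >= 0, dtheta > 0)
  ang <- seq(0, 360 - dtheta, by = dtheta)
  d <- ray_distances(cs$catheter$center, ang, cs$intima)
  contact <- is.finite(d) & d <= cs$catheter$radius + gap_tol
  k <- length(contact)
  if (!any(contact)) return(0)
  if (all(contact)) return(360)
  if (mode == "sum") return(sum(contact) * dtheta)
  r <- rle(contact)
  runs <- r$lengths[r$values]
  # wrap-around: merge the first and last run if both are contact
  if (contact[1] && contact[k]) {
    nr <- length(r$lengths)
    runs <- c(runs[-c(1, length(runs))], r$lengths[1] + r$lengths[nr])
  }
  max(runs) * dtheta
}

#' Minimal and maximal lumen diameters
#'
#' Chords through the lumen area centroid, swept every `dtheta` degrees
#' over half a turn; each chord is the sum of the two opposite ray
#' distances from the centroid.
#'
#' @param x an [contour()] object.
#' @param dtheta angular step in degrees.
#' @return named numeric `c(min_ld, max_ld)` in mm.
#' @export
lumen_diameters <- function(x, dtheta = 0.5) {
  stopifnot(inherits(x, "oct_contour"), dtheta > 0)
  ctr <- centroid(x)
  if (!point_in_contour(ctr, x)) {
    abort_oct("contour centroid falls outside the contour; chord sweep undefined",
              "octbias_precondition")
  }
  # anchor the sweep to the shape (direction of the first vertex about the
  # centroid) so the sampled chord set is rigid-motion equivariant
  v1 <- x$vertices[1, ] - ctr
  th0 <- deg_norm(atan2(v1[2], v1[1]) * 180 / pi)
  th <- th0 + seq(0, 180 - dtheta, by = dtheta)
  chords <- ray_distances(ctr, th, x) + ray_distances(ctr, th + 180, x)
  c(min_ld = min(chords), max_ld = max(chords))
}

#' Lumen eccentricity
#'
#' `(max_ld - min_ld) / max_ld`, in `[0, 1)`.
#'
#' @param min_ld,max_ld diameters in mm, `0 < min_ld <= max_ld`.
#' @return dimensionless eccentricity.
#' @export
eccentricity <- function(min_ld, max_ld) {
  if (!is.numeric(min_ld) || !is.numeric(max_ld) ||
      max_ld <= 0 || min_ld <= 0 || min_ld > max_ld) {
    abort_oct("need 0 < min_ld <= max_ld", "octbias_domain")
  }
  (max_ld - min_ld) / max_ld
}

#' EEM cross-sectional area and average vessel diameter
#'
#' `eem_csa` is the polygon area of the EEM contour; `avd` is the mean of
#' the minimal and maximal EEM diameters through the EEM centroid.
#'
#' @param cs an [cross_section()].
#' @param dtheta angular step in degrees for the diameter sweep.
#' @return named numeric `c(eem_csa, avd)`; both `NA` when the EEM contour
#'   is absent.
#' @export
eem_metrics <- function(cs, dtheta = 0.5) {
  stopifnot(inherits(cs, "oct_cross_section"))
  if (is.null(cs$eem)) return(c(eem_csa = NA_real_, avd = NA_real_))
  ld <- lumen_diameters(cs$eem, dtheta = dtheta)
  c(eem_csa = polygon_area(cs$eem), avd = unname((ld[1] + ld[2]) / 2))
}

#' Burr-to-vessel ratio
#'
#' @param final_burr_size burr diameter in mm.
#' @param reference_vessel_diameter reference vessel diameter in mm.
#' @return dimensionless ratio.
#' @export
compute_btv <- function(final_burr_size, reference_vessel_diameter) {
  if (!is.numeric(final_burr_size) || !is.numeric(reference_vessel_diameter) ||
      any(final_burr_size <= 0) || any(reference_vessel_diameter <= 0)) {
    abort_oct("burr size and reference diameter must be > 0", "octbias_domain")
  }
  final_burr_size / reference_vessel_diameter
}

#' Measure all cross-sectional indices of one frame
#'
#' Assembles the full measurement record: the four catheter-to-wall
#' distances, touch angle, lumen area, min/max lumen diameters,
#' eccentricity, EEM metrics and the bias geometry.  Media/EEM-based fields
#' are `NA` where the contour is absent.  Frames with an undefined bias
#' direction (concentric catheter) yield `NA` for all bias-dependent fields
#' with a classed warning.
#'
#' @param cs an [cross_section()].
#' @param gap_tol,dtheta,eps_bias tolerances passed to the individual
#'   operators.
#' @return list of class `oct_measurement`.
#' @export
measure_frame <- function(cs, gap_tol = 0.02, dtheta = 0.5, eps_bias = 0.05) {
  stopifnot(inherits(cs, "oct_cross_section"))
  bias <- tryCatch(bias_geometry(cs, eps_bias = eps_bias),
                   octbias_bias_undefined = function(e) {
                     warn_oct(sprintf("frame %d: %s", cs$frame_id,
                                      conditionMessage(e)),
                              "octbias_bias_undefined")
                     NULL
                   })
  dist <- if (is.null(bias)) {
    c(d_cib = NA_real_, d_cio = NA_real_, d_cmb = NA_real_, d_cmo = NA_real_)
  } else distance_indices(cs, bias)
  ta <- touch_angle(cs, gap_tol = gap_tol, dtheta = dtheta)
  la <- polygon_area(cs$intima)
  ld <- lumen_diameters(cs$intima, dtheta = dtheta)
  le <- eccentricity(ld[["min_ld"]], ld[["max_ld"]])
  em <- eem_metrics(cs, dtheta = dtheta)
  dis <- cs$dissection
  structure(list(
    frame_id = cs$frame_id, z = cs$z,
    d_cib = unname(dist[["d_cib"]]), d_cio = unname(dist[["d_cio"]]),
    d_cmb = unname(dist[["d_cmb"]]), d_cmo = unname(dist[["d_cmo"]]),
    touch_angle = ta, la = la,
    min_ld = unname(ld[["min_ld"]]), max_ld = unname(ld[["max_ld"]]),
    le = le,
    eem_csa = unname(em[["eem_csa"]]), avd = unname(em[["avd"]]),
    bias = bias,
    dissection_present = !is.null(dis) && dis$present
  ), class = "oct_measurement")
}

#' @export
as.data.frame.oct_measurement <- function(x, ...) {
  data.frame(frame_id = x$frame_id, z_mm = x$z,
             d_cib = x$d_cib, d_cio = x$d_cio,
             d_cmb = x$d_cmb, d_cmo = x$d_cmo,
             touch_angle_deg = x$touch_angle, la_mm2 = x$la,
             min_ld_mm = x$min_ld, max_ld_mm = x$max_ld, le = x$le,
             eem_csa_mm2 = x$eem_csa, avd_mm = x$avd,
             bias_angle_deg = if (is.null(x$bias)) NA_real_ else x$bias$bias_angle,
             dissection_present = x$dissection_present)
}
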