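# A cross-section bundles one frame's segmented contours, the imaging
# catheter pose, and annotations (calcium arcs, dissection).

#' Imaging-catheter pose
#'
#' @param center numeric length-2 `(x, y)` in mm.
#' @param radius catheter radius in mm.  The default 0.45 mm is the radius
#'   of a 2.7F OCT imaging catheter.
#' @return an object of class `oct_catheter`.
#' @export
catheter_pose <- function(center, radius = 0.45) {
  if (!is.numeric(center) || length(center) != 2L || anyNA(center)) {
    abort_oct("catheter center must be numeric (x, y)", "octbias_domain")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort_oct("catheter radius must be > 0", "octbias_domain")
  }
  structure(list(center = as.numeric(center), radius = radius),
            class = "oct_catheter")
}

#' Dissection annotation for a frame
#'
#' @param present logical flag.
#' @param arc angular interval `c(start, end)` in degrees about the vessel
#'   center (half-open, wrap-around), or `NULL` when absent.
#' @param depth one of `"intimal"`, `"medial"`, `"adventitial"`,
#'   `"intramural_hematoma"`.  Only intimal dissections are the analysis
#'   endpoint; deeper classes are carried as labels.
#' @param catheter_subintimal is the catheter trapped beneath the flap
#'   (subintimal space)?
#' @return an object of class `oct_dissection`.
#' @export
dissection <- function(present, arc = NULL,
                       depth = c("intimal", "medial", "adventitial",
                                 "intramural_hematoma"),
                       catheter_subintimal = FALSE) {
  depth <- match.arg(depth)
  if (present && (is.null(arc) || length(arc) != 2L)) {
    abort_oct("a present dissection needs an angular arc", "octbias_domain")
  }
  if (!is.null(arc)) arc <- deg_norm(as.numeric(arc))
  structure(list(present = isTRUE(present), arc = arc, depth = depth,
                 catheter_subintimal = isTRUE(catheter_subintimal)),
            class = "oct_dissection")
}

#' Construct a cross-sectional frame
#'
#' @param frame_id integer frame identifier.
#' @param z position along the pullback, mm (>= 0).
#' @param intima intima [contour()] (required).
#' @param catheter an [catheter_pose()].
#' @param media,eem optional [contour()] objects; a missing media or EEM is
#'   a first-class missing value (the media is often unrecognizable at the
#'   bias site behind attenuating plaque).
#' @param calcium_arcs list of angular intervals (degrees, about the vessel
#'   center) flagged as calcified.
#' @param dissection optional [dissection()] annotation.
#' @param check check the catheter-inside-lumen invariant (skipped when the
#'   annotation says the catheter is subintimal).
#' @return an object of class `oct_cross_section`.
#' @export
cross_section <- function(frame_id, z, intima, catheter,
                          media = NULL, eem = NULL,
                          calcium_arcs = list(), dissection = NULL,
                          check = TRUE) {
  stopifnot(inherits(intima, "oct_contour"), inherits(catheter, "oct_catheter"))
  if (!is.null(media)) stopifnot(inherits(media, "oct_contour"))
  if (!is.null(eem)) stopifnot(inherits(eem, "oct_contour"))
  if (!is.numeric(z) || z < 0) abort_oct("z must be >= 0", "octbias_domain")
  subintimal <- !is.null(dissection) && isTRUE(dissection$catheter_subintimal)
  if (check && !subintimal && !point_in_contour(catheter$center, intima)) {
    abort_oct("catheter center must lie inside the intima contour",
              "octbias_precondition")
  }
  structure(list(frame_id = as.integer(frame_id), z = as.numeric(z),
                 intima = intima, media = media, eem = eem,
                 catheter = catheter,
                 calcium_arcs = calcium_arcs, dissection = dissection),
            class = "oct_cross_section")
}

#' @export
print.oct_cross_section <- function(x, ...) {
  cat(sprintf(
    "<oct_cross_section frame %d @ z=%.2f mm; media:%s eem:%s dissection:%s>\n",
    x$frame_id, x$z,
    if (is.null(x$media)) "-" else "+",
    if (is.null(x$eem)) "-" else "+",
    if (!is.null(x$dissection) && x$dissection$present) "+" else "-"))
  invisible(x)
}
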