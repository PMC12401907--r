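# Angular conventions used throughout the package: degrees, measured
# counterclockwise from +x; angular intervals are half-open [start, end)
# with wrap-around at 360.  An interval is a length-2 numeric c(start, end);
# its length is (end - start) %% 360, so c(350, 20) spans 30 degrees.

#' Normalize an angle to [0, 360)
#'
#' @param a angle(s) in degrees.
#' @return angle(s) reduced modulo 360 into `[0, 360)`.
#' @export
deg_norm <- function(a) {
  r <- a %% 360
  # tiny negative inputs can round to exactly 360 under %%
  r[r >= 360] <- 0
  r
}

#' Length of a circular angular interval
#'
#' @param arc length-2 numeric `c(start, end)` in degrees, half-open with
#'   wrap-around (so `c(350, 20)` spans 30 degrees).
#' @return span in degrees, in `[0, 360)`.
#' @export
arc_length <- function(arc) {
  stopifnot(is.numeric(arc), length(arc) == 2L)
  (arc[2] - arc[1]) %% 360
}

#' Membership of an angle in a circular interval
#'
#' @inheritParams arc_length
#' @param theta angle(s) in degrees.
#' @return logical, `TRUE` where `theta` lies in `[start, end)` modulo 360.
#' @export
arc_contains <- function(arc, theta) {
  ((theta - arc[1]) %% 360) < arc_length(arc)
}

#' Do two circular angular intervals overlap?
#'
#' Overlap means a non-empty (positive-length) intersection; intervals that
#' merely share an endpoint do not overlap because both are half-open.
#'
#' @param a,b length-2 numeric intervals `c(start, end)` in degrees.
#' @return logical scalar.
#' @export
arcs_overlap <- function(a, b) {
  if (arc_length(a) == 0 || arc_length(b) == 0) return(FALSE)
  arc_contains(a, b[1]) || arc_contains(b, a[1])
}

# Midpoint of a circular interval.
arc_midpoint <- function(arc) deg_norm(arc[1] + arc_length(arc) / 2)
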