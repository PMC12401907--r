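# Landmark-based alignment of pre- and post-procedure pullbacks, 1-mm
# frame pairing, and the bias-quadrant / dissection coincidence summaries.

#' Construct a pullback
#'
#' @param patient_id patient identifier (character or integer).
#' @param phase `"pre"` or `"post"` (relative to the atherectomy run).
#' @param frames list of [cross_section()] objects, strictly increasing in
#'   `z`.
#' @param landmark_z mm; z-position of the fiduciary side branch used for
#'   manual coregistration.
#' @param analysis_span length-2 numeric `(z_start, z_end)` in mm bounding
#'   the analyzable segment (the burr movement segment); usually carried on
#'   the pre phase.
#' @return an object of class `oct_pullback`.
#' @export
pullback <- function(patient_id, phase = c("pre", "post"), frames,
                     landmark_z, analysis_span = NULL) {
  phase <- match.arg(phase)
  stopifnot(is.list(frames), length(frames) >= 1L)
  z <- vapply(frames, function(f) f$z, numeric(1))
  if (is.unsorted(z, strictly = TRUE)) {
    abort_oct("pullback frames must be strictly increasing in z",
              "octbias_domain")
  }
  if (!is.null(analysis_span)) {
    stopifnot(length(analysis_span) == 2L)
    if (diff(analysis_span) <= 0) {
      abort_oct("analysis_span must be non-empty", "octbias_domain")
    }
  }
  if (!is.null(landmark_z) &&
      (landmark_z < min(z) - 1e-9 || landmark_z > max(z) + 1e-9)) {
    abort_oct("landmark_z must lie within the pullback frame range",
              "octbias_domain")
  }
  structure(list(patient_id = patient_id, phase = phase, frames = frames,
                 landmark_z = landmark_z, analysis_span = analysis_span),
            class = "oct_pullback")
}

#' @export
print.oct_pullback <- function(x, ...) {
  z <- vapply(x$frames, function(f) f$z, numeric(1))
  cat(sprintf("<oct_pullback %s/%s: %d frames, z %.2f..%.2f mm>\n",
              x$patient_id, x$phase, length(x$frames), min(z), max(z)))
  invisible(x)
}

#' Landmark offset between two pullbacks
#'
#' Fiduciary side-branch alignment: the returned offset maps post-phase z
#' into pre-phase coordinates (`z_post + offset` is comparable to `z_pre`).
#'
#' @param pre,post [pullback()] objects carrying `landmark_z`.
#' @return offset in mm (`pre$landmark_z - post$landmark_z`).
#' @export
align <- function(pre, post) {
  stopifnot(inherits(pre, "oct_pullback"), inherits(post, "oct_pullback"))
  if (is.null(pre$landmark_z) || is.null(post$landmark_z)) {
    abort_oct("both pullbacks need a fiduciary landmark_z",
              "octbias_unalignable")
  }
  pre$landmark_z - post$landmark_z
}

# Nearest frame to target z within tol; ties broken toward the earlier
# frame.  Returns index or NA.
nearest_frame <- function(z, target, tol = 0.5) {
  d <- abs(z - target)
  i <- which(d <= tol + 1e-9)
  if (length(i) == 0L) return(NA_integer_)
  i[which.min(d[i])]  # which.min takes the first (earlier) on ties
}

#' Pair pre/post frames on a common 1-mm grid
#'
#' Lays a 1-mm grid over the intersection of the two phases' covered spans
#' (post z mapped into pre coordinates by `offset`) restricted to the pre
#' phase's `analysis_span`, then attaches the nearest frame of each phase
#' within `tol` mm of every grid point.  Grid points lacking a frame in
#' either phase are dropped and counted.
#'
#' @param pre,post [pullback()] objects.
#' @param offset mm, from [align()].
#' @param tol nearest-frame tolerance in mm (default 0.5, half the grid
#'   step); ties go to the earlier frame.
#' @param measure_pre compute the pre-frame measurement record for each
#'   pair (set `FALSE` to pair geometry only).
#' @param ... passed to [measure_frame()].
#' @return list of class `oct_paired_frames`: `pairs` (list of pair
#'   records with `grid_z`, `pre`, `post`, `pre_measure`,
#'   `post_dissection`), `n_dropped`, `grid`.
#' @export
resample_pairs <- function(pre, post, offset = align(pre, post), tol = 0.5,
                           measure_pre = TRUE, ...) {
  stopifnot(inherits(pre, "oct_pullback"), inherits(post, "oct_pullback"))
  z_pre <- vapply(pre$frames, function(f) f$z, numeric(1))
  z_post <- vapply(post$frames, function(f) f$z, numeric(1)) + offset
  lo <- max(min(z_pre), min(z_post))
  hi <- min(max(z_pre), max(z_post))
  if (!is.null(pre$analysis_span)) {
    lo <- max(lo, pre$analysis_span[1])
    hi <- min(hi, pre$analysis_span[2])
  }
  if (hi - lo < -1e-9) {
    abort_oct("pullbacks do not overlap within the analysis span",
              "octbias_no_overlap")
  }
  grid <- lo + seq(0, floor(hi - lo + 1e-9))
  pairs <- list()
  n_dropped <- 0L
  for (g in grid) {
    i <- nearest_frame(z_pre, g, tol)
    j <- nearest_frame(z_post, g, tol)
    if (is.na(i) || is.na(j)) {
      n_dropped <- n_dropped + 1L
      next
    }
    pcs <- pre$frames[[i]]
    qcs <- post$frames[[j]]
    pm <- if (measure_pre) measure_frame(pcs, ...) else NULL
    pd <- qcs$dissection
    pairs[[length(pairs) + 1L]] <- list(
      grid_z = g, pre = pcs, post = qcs, pre_measure = pm,
      post_dissection = if (is.null(pd)) dissection(FALSE) else pd)
  }
  structure(list(patient_id = pre$patient_id, pairs = pairs,
                 n_dropped = n_dropped, grid = grid, offset = offset),
            class = "oct_paired_frames")
}

# Pull the dissection-positive pairs out of one or more paired-frame sets.
dissection_pairs <- function(pairs) {
  if (inherits(pairs, "oct_paired_frames")) pairs <- pairs$pairs
  Filter(function(p) isTRUE(p$post_dissection$present), pairs)
}

#' Bias-quadrant / dissection coincidence rate
#'
#' Over dissection-positive paired frames, the percentage whose post-phase
#' dissection arc overlaps (non-empty angular intersection, default) the
#' pre-phase catheter bias quadrant.  `mode = "midpoint"` instead requires
#' the arc midpoint to fall inside the quadrant.
#'
#' @param pairs an `oct_paired_frames` object or a plain list of pair
#'   records.
#' @param mode `"overlap"` (default) or `"midpoint"`.
#' @return list with `rate` (percent, `NA` if there are no
#'   dissection-positive pairs) and `n_dissection`.
#' @export
quadrant_coincidence <- function(pairs, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  dp <- dissection_pairs(pairs)
  if (length(dp) == 0L) return(list(rate = NA_real_, n_dissection = 0L))
  hit <- vapply(dp, function(p) {
    if (is.null(p$pre_measure) || is.null(p$pre_measure$bias)) {
      abort_oct("dissection-positive pair lacks a pre-phase bias quadrant",
                "octbias_precondition")
    }
    q <- p$pre_measure$bias$quadrant
    a <- p$post_dissection$arc
    if (mode == "overlap") arcs_overlap(a, q) else arc_contains(q, arc_midpoint(a))
  }, logical(1))
  list(rate = 100 * mean(hit), n_dissection = length(dp))
}

#' Catheter entrapment rate among dissected frames
#'
#' Percentage of dissection-positive paired frames whose post-phase
#' catheter is flagged subintimal (trapped beneath the flap).
#'
#' @inheritParams quadrant_coincidence
#' @return percent, or `NA` if there are no dissection-positive pairs.
#' @export
entrapment_rate <- function(pairs) {
  dp <- dissection_pairs(pairs)
  if (length(dp) == 0L) return(NA_real_)
  100 * mean(vapply(dp, function(p) isTRUE(p$post_dissection$catheter_subintimal),
                    logical(1)))
}
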