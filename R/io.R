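# Versioned pullback JSON schema and the measurement / paired CSV writers.
#
# Schema (version "1.0"):
# {
#   "schema_version": "1.0", "patient_id": ..., "phase": "pre"|"post",
#   "landmark_z_mm": ..., "analysis_span_mm": [a, b], "seed": ...,
#   "frames": [
#     {"frame_id": ..., "z_mm": ..., "catheter": {"cx":..,"cy":..,"r":..},
#      "contours": {"intima": [[x,y],...], "media": ..., "eem": ...},
#      "calcium_arcs": [[lo,hi],...],
#      "dissection": {"present":..,"arc":[lo,hi],"depth":..,
#                     "catheter_subintimal":..}}
#   ]
# }

OCT_SCHEMA_VERSION <- "1.0"

#' Write a pullback to JSON
#'
#' @param pb an [pullback()].
#' @param path output file.
#' @param seed optional integer recorded in the file metadata.
#' @return `path`, invisibly.
#' @export
write_pullback_json <- function(pb, path, seed = NULL) {
  stopifnot(inherits(pb, "oct_pullback"))
  frames <- lapply(pb$frames, function(cs) {
    fr <- list(frame_id = cs$frame_id, z_mm = cs$z,
               catheter = list(cx = cs$catheter$center[1],
                               cy = cs$catheter$center[2],
                               r = cs$catheter$radius),
               contours = Filter(Negate(is.null), list(
                 intima = unname(cs$intima$vertices),
                 media = if (is.null(cs$media)) NULL else
                   unname(cs$media$vertices),
                 eem = if (is.null(cs$eem)) NULL else
                   unname(cs$eem$vertices))))
    if (length(cs$calcium_arcs)) {
      fr$calcium_arcs <- lapply(cs$calcium_arcs, as.numeric)
    }
    d <- cs$dissection
    if (!is.null(d)) {
      fr$dissection <- list(present = d$present,
                            arc = if (is.null(d$arc)) NULL else as.numeric(d$arc),
                            depth = d$depth,
                            catheter_subintimal = d$catheter_subintimal)
      fr$dissection <- Filter(Negate(is.null), fr$dissection)
    }
    fr
  })
  doc <- list(schema_version = OCT_SCHEMA_VERSION,
              patient_id = pb$patient_id, phase = pb$phase,
              landmark_z_mm = pb$landmark_z,
              analysis_span_mm = pb$analysis_span,
              frames = frames)
  if (!is.null(seed)) doc$seed <- seed
  doc <- Filter(Negate(is.null), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 6,
                       null = "null")
  invisible(path)
}

schema_fail <- function(path, what) {
  abort_oct(sprintf("malformed pullback JSON at %s: %s", path, what),
            "octbias_schema")
}

#' Read a pullback from JSON
#'
#' Validates the schema, rebuilds contours (normalized counterclockwise,
#' simplicity-checked) and all annotations.
#'
#' @param path JSON file written by [write_pullback_json()] or conforming
#'   to the documented schema.
#' @return an [pullback()].
#' @export
read_pullback_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = TRUE),
                  error = function(e) schema_fail(path, conditionMessage(e)))
  for (f in c("schema_version", "patient_id", "phase", "frames")) {
    if (is.null(doc[[f]])) schema_fail(path, paste("missing field", f))
  }
  if (!identical(doc$schema_version, OCT_SCHEMA_VERSION)) {
    schema_fail(path, paste("unsupported schema_version", doc$schema_version))
  }
  frames <- lapply(seq_along(doc$frames), function(i) {
    fr <- doc$frames[[i]]
    where <- sprintf("frames[%d]", i)
    for (f in c("frame_id", "z_mm", "catheter", "contours")) {
      if (is.null(fr[[f]])) schema_fail(path, paste(where, "missing", f))
    }
    if (is.null(fr$contours$intima)) {
      schema_fail(path, paste(where, "missing intima contour"))
    }
    mk <- function(v, role) {
      m <- if (is.matrix(v)) v else do.call(rbind, v)
      tryCatch(contour(m, role),
               octbias_error = function(e) {
                 schema_fail(path, paste(where, role, conditionMessage(e)))
               })
    }
    cal <- if (is.null(fr$calcium_arcs)) list() else {
      lapply(if (is.matrix(fr$calcium_arcs)) {
        split(fr$calcium_arcs, row(fr$calcium_arcs)[, 1])
      } else fr$calcium_arcs, as.numeric)
    }
    ann <- if (is.null(fr$dissection)) NULL else {
      dissection(isTRUE(fr$dissection$present),
                 arc = fr$dissection$arc,
                 depth = if (is.null(fr$dissection$depth)) "intimal" else
                   fr$dissection$depth,
                 catheter_subintimal = isTRUE(fr$dissection$catheter_subintimal))
    }
    cross_section(fr$frame_id, fr$z_mm,
                  intima = mk(fr$contours$intima, "intima"),
                  catheter = catheter_pose(c(fr$catheter$cx, fr$catheter$cy),
                                           fr$catheter$r),
                  media = if (is.null(fr$contours$media)) NULL else
                    mk(fr$contours$media, "media"),
                  eem = if (is.null(fr$contours$eem)) NULL else
                    mk(fr$contours$eem, "eem"),
                  calcium_arcs = cal, dissection = ann)
  })
  pullback(doc$patient_id, doc$phase, frames,
           landmark_z = doc$landmark_z_mm,
           analysis_span = if (is.null(doc$analysis_span_mm)) NULL else
             as.numeric(doc$analysis_span_mm))
}

# Stable measurement CSV column order.
MEASUREMENT_COLS <- c("patient_id", "phase", "frame_id", "z_mm",
                      "d_cib", "d_cio", "d_cmb", "d_cmo",
                      "touch_angle_deg", "la_mm2", "min_ld_mm", "max_ld_mm",
                      "le", "eem_csa_mm2", "avd_mm", "bias_angle_deg",
                      "dissection_present")

#' Write a measurement table to CSV
#'
#' One row per frame in the stable documented column order.
#'
#' @param df measurement data.frame from [run_measure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(df, path) {
  missing_cols <- setdiff(MEASUREMENT_COLS, names(df))
  for (mc in missing_cols) df[[mc]] <- NA
  utils::write.csv(df[, MEASUREMENT_COLS], path, row.names = FALSE)
  invisible(path)
}
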