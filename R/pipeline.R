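# Orchestration: measure pullbacks, pair phases, and produce the
# discrimination report (univariate + ROC table, DeLong comparison of the
# top predictors, coincidence/entrapment summaries, cluster bootstrap).

#' Measure every frame of one or more pullbacks
#'
#' Produces one measurement row per frame.  Frames whose bias direction is
#' undefined keep their bias-independent indices and are counted, not
#' dropped; the counts are attached as the `"log"` attribute
#' (`n_total`, `n_analyzable`, `n_bias_undefined`).
#'
#' @param pullbacks an [pullback()] or list of them.
#' @param ... passed to [measure_frame()] (`gap_tol`, `dtheta`, `eps_bias`).
#' @return data.frame in the stable measurement column order.
#' @export
run_measure <- function(pullbacks, ...) {
  if (inherits(pullbacks, "oct_pullback")) pullbacks <- list(pullbacks)
  n_bias_undef <- 0L
  rows <- list()
  for (pb in pullbacks) {
    for (cs in pb$frames) {
      m <- withCallingHandlers(
        measure_frame(cs, ...),
        octbias_bias_undefined = function(w) {
          n_bias_undef <<- n_bias_undef + 1L
          invokeRestart("muffleWarning")
        })
      row <- as.data.frame(m)
      row$patient_id <- pb$patient_id
      row$phase <- pb$phase
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    as.data.frame(stats::setNames(rep(list(logical(0)),
                                      length(MEASUREMENT_COLS)),
                                  MEASUREMENT_COLS))
  }
  for (mc in setdiff(MEASUREMENT_COLS, names(df))) df[[mc]] <- NA
  df <- df[, MEASUREMENT_COLS]
  rownames(df) <- NULL
  n_total <- nrow(df)
  attr(df, "log") <- list(n_total = n_total,
                          n_analyzable = n_total - n_bias_undef,
                          n_bias_undefined = n_bias_undef)
  df
}

#' Pair all patients of a study
#'
#' Aligns each patient's pre/post pullbacks by their landmarks and pairs
#' frames on the 1-mm grid.
#'
#' @param pre,post lists of [pullback()] objects (matched by
#'   `patient_id`), or an `oct_study` passed as `pre`.
#' @param tol nearest-frame tolerance in mm.
#' @param ... passed to [measure_frame()].
#' @return list of class `oct_paired_study`: `by_patient` (list of
#'   `oct_paired_frames`), `table` (flat paired data.frame), `n_dropped`.
#' @export
pair_study <- function(pre, post = NULL, tol = 0.5, ...) {
  if (inherits(pre, "oct_study")) {
    post <- pre$post
    pre <- pre$pre
  }
  ids_pre <- vapply(pre, function(p) as.character(p$patient_id), character(1))
  ids_post <- vapply(post, function(p) as.character(p$patient_id), character(1))
  by_patient <- lapply(seq_along(pre), function(i) {
    j <- match(ids_pre[i], ids_post)
    if (is.na(j)) abort_oct(sprintf("no post pullback for patient %s",
                                    ids_pre[i]), "octbias_unalignable")
    resample_pairs(pre[[i]], post[[j]], tol = tol, ...)
  })
  tabs <- lapply(by_patient, paired_table)
  structure(list(by_patient = by_patient,
                 table = do.call(rbind, tabs),
                 n_dropped = sum(vapply(by_patient, function(p) p$n_dropped,
                                        integer(1)))),
            class = "oct_paired_study")
}

# Flatten one patient's paired frames to a data.frame.
paired_table <- function(pf) {
  stopifnot(inherits(pf, "oct_paired_frames"))
  rows <- lapply(pf$pairs, function(p) {
    m <- as.data.frame(p$pre_measure)
    d <- p$post_dissection
    cbind(data.frame(patient_id = pf$patient_id, grid_z = p$grid_z,
                     pre_frame_id = p$pre$frame_id,
                     post_frame_id = p$post$frame_id),
          m[, setdiff(names(m), c("frame_id", "dissection_present"))],
          data.frame(dissection_present = isTRUE(d$present),
                     dissection_lo = if (is.null(d$arc)) NA_real_ else d$arc[1],
                     dissection_hi = if (is.null(d$arc)) NA_real_ else d$arc[2],
                     dissection_depth = if (isTRUE(d$present)) d$depth else
                       NA_character_,
                     catheter_subintimal = isTRUE(d$catheter_subintimal)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Table-level coincidence / entrapment, so the analysis stage can run from
# a flat paired CSV.  Equivalent to quadrant_coincidence()/entrapment_rate()
# on the pair objects.
coincidence_from_table <- function(df, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  dp <- df[df$dissection_present, , drop = FALSE]
  if (nrow(dp) == 0L) {
    return(list(rate = NA_real_, n_dissection = 0L,
                entrapment = NA_real_))
  }
  if (anyNA(dp$bias_angle_deg)) {
    abort_oct("dissection-positive pair lacks a pre-phase bias angle",
              "octbias_precondition")
  }
  hit <- mapply(function(b, lo, hi) {
    q <- deg_norm(c(b - 45, b + 45))
    a <- c(lo, hi)
    if (mode == "overlap") arcs_overlap(a, q) else
      arc_contains(q, arc_midpoint(a))
  }, dp$bias_angle_deg, dp$dissection_lo, dp$dissection_hi)
  list(rate = 100 * mean(hit), n_dissection = nrow(dp),
       entrapment = 100 * mean(dp$catheter_subintimal))
}

# Display names and table order of the reported predictors.
TABLE2_VARS <- data.frame(
  variable = c("D_cib", "D_cio", "D_cmb", "D_cmo", "Final burr size",
               "Touch angle", "MinLD", "MaxLD"),
  column = c("d_cib", "d_cio", "d_cmb", "d_cmo", "final_burr_size",
             "touch_angle_deg", "min_ld_mm", "max_ld_mm"),
  stringsAsFactors = FALSE)

#' Discrimination analysis of a paired study
#'
#' For each candidate predictor (the four catheter-to-wall distances,
#' final burr size, touch angle, minimal and maximal lumen diameter, in
#' that fixed order) against the post-phase intimal-dissection flag:
#' univariate rank correlation, empirical ROC with DeLong CI, and the
#' Youden-optimal cutoff with sensitivity/specificity.  Adds a DeLong
#' pairwise comparison of the two largest AUCs, the bias-quadrant
#' coincidence and catheter-entrapment summaries, and a cluster-bootstrap
#' sensitivity block for the top predictor.
#'
#' @param paired an `oct_paired_study` from [pair_study()], or its flat
#'   `table` data.frame.
#' @param meta per-patient data.frame with `patient_id` and
#'   `final_burr_size` (replicated across that patient's frames).
#' @param B bootstrap replicates for the clustering sensitivity block.
#' @param seed seed for the bootstrap.
#' @param cor_method `"spearman"` or `"pearson"` for the univariate stage.
#' @return list of class `oct_analysis`: `table` (the per-variable
#'   report), `delong`, `coincidence`, `entrapment`, `bootstrap`, `n`.
#' @export
run_analysis <- function(paired, meta = NULL, B = 2000, seed = 1L,
                         cor_method = "spearman") {
  df <- if (inherits(paired, "oct_paired_study")) paired$table else paired
  stopifnot(is.data.frame(df), nrow(df) > 0)
  if (!is.null(meta)) {
    df <- merge(df, meta[, c("patient_id", "final_burr_size")],
                by = "patient_id", sort = FALSE)
  } else if (!"final_burr_size" %in% names(df)) {
    df$final_burr_size <- NA_real_
  }
  y <- as.integer(df$dissection_present)
  if (length(unique(y)) < 2L) {
    abort_oct("outcome has a single class: analysis impossible",
              "octbias_single_class")
  }
  rows <- list()
  rocs <- list()
  for (i in seq_len(nrow(TABLE2_VARS))) {
    cn <- TABLE2_VARS$column[i]
    x <- df[[cn]]
    row <- data.frame(variable = TABLE2_VARS$variable[i],
                      r = NA_real_, p_r = NA_real_, auc = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      cutoff = NA_real_, youden = NA_real_,
                      direction = NA_character_, n = sum(!is.na(x)),
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      ur <- univariate_r(x, y, method = cor_method)
      roc <- empirical_roc(x, y)
      yc <- youden_cutoff(roc)
      list(ur = ur, roc = roc, yc = yc)
    }, octbias_error = function(e) NULL)
    if (!is.null(res)) {
      row$r <- res$ur$r; row$p_r <- res$ur$p
      row$auc <- res$roc$auc
      row$ci_low <- res$roc$ci_low; row$ci_high <- res$roc$ci_high
      row$sensitivity <- res$yc$sensitivity
      row$specificity <- res$yc$specificity
      row$cutoff <- res$yc$cutoff; row$youden <- res$yc$youden
      row$direction <- res$roc$direction
      rocs[[TABLE2_VARS$variable[i]]] <- res$roc
    }
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  # DeLong comparison of the two best AUCs (complete pairwise cases)
  delong <- NULL
  ord <- order(tab$auc, decreasing = TRUE)
  ord <- ord[!is.na(tab$auc[ord])]
  if (length(ord) >= 2L) {
    v1 <- TABLE2_VARS$column[ord[1]]; v2 <- TABLE2_VARS$column[ord[2]]
    delong <- tryCatch({
      dt <- delong_test(df[[v1]], df[[v2]], y)
      c(list(var1 = tab$variable[ord[1]], var2 = tab$variable[ord[2]]), dt)
    }, octbias_degenerate_test = function(e) {
      list(var1 = tab$variable[ord[1]], var2 = tab$variable[ord[2]],
           auc1 = tab$auc[ord[1]], auc2 = tab$auc[ord[2]],
           z = NA_real_, p = NA_real_,
           note = "degenerate: zero variance of the AUC difference")
    })
  }
  co <- coincidence_from_table(df)
  # clustering sensitivity for the top predictor (GEE surrogate)
  boot <- NULL
  if (length(ord) >= 1L && length(unique(df$patient_id)) >= 2L) {
    v1 <- TABLE2_VARS$column[ord[1]]
    boot <- tryCatch(
      c(list(variable = tab$variable[ord[1]],
             method = "cluster bootstrap (GEE surrogate)"),
        cluster_bootstrap_auc(df[[v1]], y, df$patient_id, B = B,
                              seed = seed)),
      octbias_error = function(e) NULL)
  }
  structure(list(table = tab, delong = delong,
                 coincidence = list(rate = co$rate,
                                    n_dissection = co$n_dissection),
                 entrapment = co$entrapment,
                 bootstrap = boot,
                 n = nrow(df)),
            class = "oct_analysis")
}

#' @export
print.oct_analysis <- function(x, ...) {
  cat(sprintf("Discrimination analysis over %d paired frames (%d dissected)\n",
              x$n, x$coincidence$n_dissection))
  print(transform(x$table,
                  r = round(r, 3), p_r = signif(p_r, 3), auc = round(auc, 3),
                  ci_low = round(ci_low, 3), ci_high = round(ci_high, 3),
                  sensitivity = round(sensitivity, 1),
                  specificity = round(specificity, 1),
                  cutoff = round(cutoff, 3), youden = round(youden, 3)),
        row.names = FALSE)
  if (!is.null(x$delong)) {
    cat(sprintf("DeLong %s vs %s: AUC %.3f vs %.3f, p = %s\n",
                x$delong$var1, x$delong$var2, x$delong$auc1, x$delong$auc2,
                if (is.na(x$delong$p)) paste0("NA (", x$delong$note, ")")
                else signif(x$delong$p, 3)))
  }
  cat(sprintf("Bias-quadrant coincidence: %s%% of %d dissected frames; catheter entrapment: %s%%\n",
              format(x$coincidence$rate), x$coincidence$n_dissection,
              format(x$entrapment)))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("Cluster bootstrap (%s, B=%d): AUC %.3f (%.3f-%.3f)\n",
                x$bootstrap$variable, x$bootstrap$B, x$bootstrap$auc,
                x$bootstrap$ci_low, x$bootstrap$ci_high))
  }
  invisible(x)
}

#' Reproduce the full synthetic pipeline
#'
#' Generate a synthetic study, write its pullbacks as JSON, measure every
#' pre-phase frame, pair the phases, run the discrimination analysis, and
#' write the measurement CSV, paired CSV, report CSV and a JSON stats
#' bundle under `out_dir`.
#'
#' @param config an [generator_config()].
#' @param out_dir output directory (created if needed).
#' @param B bootstrap replicates for the sensitivity block.
#' @return list with `study`, `measurements`, `paired`, `analysis` and
#'   `paths`.
#' @export
reproduce_study <- function(config = generator_config(),
                            out_dir = tempfile("octbias_run_"), B = 2000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(config)
  paths <- list()
  for (i in seq_along(study$pre)) {
    id <- study$pre[[i]]$patient_id
    paths[[paste0(id, "_pre")]] <-
      write_pullback_json(study$pre[[i]],
                          file.path(out_dir, sprintf("%s_pre.json", id)),
                          seed = config$seed)
    paths[[paste0(id, "_post")]] <-
      write_pullback_json(study$post[[i]],
                          file.path(out_dir, sprintf("%s_post.json", id)),
                          seed = config$seed)
  }
  meas <- run_measure(study$pre)
  paths$measurements <- write_measurements_csv(
    meas, file.path(out_dir, "measurements.csv"))
  paired <- pair_study(study)
  utils::write.csv(paired$table, file.path(out_dir, "paired.csv"),
                   row.names = FALSE)
  paths$paired <- file.path(out_dir, "paired.csv")
  analysis <- run_analysis(paired, meta = study$meta, B = B,
                           seed = config$seed)
  utils::write.csv(analysis$table, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  paths$report <- file.path(out_dir, "report.csv")
  bundle <- list(seed = config$seed,
                 n_paired = analysis$n,
                 table = analysis$table,
                 delong = analysis$delong,
                 coincidence = analysis$coincidence,
                 entrapment = analysis$entrapment,
                 bootstrap = analysis$bootstrap,
                 log = attr(meas, "log"),
                 n_dropped_grid_points = paired$n_dropped)
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, null = "null")
  paths$report_json <- file.path(out_dir, "report.json")
  list(study = study, measurements = meas, paired = paired,
       analysis = analysis, paths = paths)
}
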