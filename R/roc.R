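# Empirical ROC analysis: trapezoidal AUC, DeLong variance and CI,
# Youden-optimal cutoff, and the paired DeLong test.

check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) abort_oct("y must be coded 0/1", "octbias_domain")
  if (length(unique(y)) < 2L) {
    abort_oct("both outcome classes must be present", "octbias_single_class")
  }
}

# Placement values of the DeLong decomposition.  `s` is the score oriented
# so that larger values indicate the positive class.  Returns V10 (one per
# positive) and V01 (one per negative); mean(V10) == mean(V01) == AUC.
delong_placements <- function(s, y) {
  sp <- s[y == 1]; sn <- s[y == 0]
  m <- length(sp); n <- length(sn)
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       auc = mean(cmp), m = m, n = n)
}

#' Empirical ROC curve with DeLong confidence interval
#'
#' Computes the empirical ROC over all distinct thresholds of `x`, the
#' trapezoidal AUC (equal to the normalized concordant-pair count), and a
#' normal-approximation confidence interval from the DeLong variance,
#' truncated to `[0, 1]`.
#'
#' With `direction = "auto"` the orientation is chosen so that the reported
#' AUC is at least 0.5; `"lower_positive"` means smaller `x` indicates the
#' positive class (as for catheter-to-media distance), `"higher_positive"`
#' the reverse (as for touch angle).
#'
#' @param x numeric predictor.
#' @param y binary outcome coded 0/1.
#' @param direction `"auto"`, `"lower_positive"` or `"higher_positive"`.
#' @param conf_level confidence level for the AUC interval.
#' @return object of class `oct_roc`: `auc`, `ci_low`, `ci_high`,
#'   `direction`, `curve` (data.frame of `fpr`, `tpr` from (0,0) to (1,1)),
#'   `x`, `y`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(x, y,
                          direction = c("auto", "lower_positive",
                                        "higher_positive"),
                          conf_level = 0.95) {
  direction <- match.arg(direction)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) abort_oct("need at least 2 observations", "octbias_domain")
  check_binary(y)
  score_for <- function(dir) if (dir == "lower_positive") -x else x
  if (direction == "auto") {
    a_hi <- delong_placements(x, y)$auc
    direction <- if (a_hi >= 0.5) "higher_positive" else "lower_positive"
  }
  s <- score_for(direction)
  pl <- delong_placements(s, y)
  v <- if (pl$m > 1 && pl$n > 1) {
    stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  } else NA_real_
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(v)) c(NA_real_, NA_real_) else {
    pmin(1, pmax(0, pl$auc + c(-1, 1) * zq * sqrt(v)))
  }
  # curve over distinct thresholds, from all-negative to all-positive calls
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(s[y == 0] >= t), numeric(1)))
  structure(list(auc = pl$auc, ci_low = ci[1], ci_high = ci[2],
                 var_auc = v, direction = direction,
                 curve = data.frame(fpr = fpr, tpr = tpr),
                 x = x, y = y, n_pos = pl$m, n_neg = pl$n),
            class = "oct_roc")
}

#' @export
print.oct_roc <- function(x, ...) {
  cat(sprintf("<oct_roc AUC %.3f (%.3f-%.3f), %s, %d pos / %d neg>\n",
              x$auc, x$ci_low, x$ci_high, x$direction, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' Scans candidate cutoffs at the midpoints between consecutive sorted
#' distinct predictor values and returns the one maximizing the Youden
#' index `J = sensitivity + specificity - 1`.  Ties in `J` are broken
#' toward higher specificity, then toward the lower cutoff.
#'
#' @param roc an [empirical_roc()] result (its stored data and direction
#'   are used).
#' @return list with `cutoff` (predictor units), `sensitivity` and
#'   `specificity` (percent), and `youden`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "oct_roc"))
  x <- roc$x; y <- roc$y
  xs <- sort(unique(x))
  if (length(xs) < 2L) {
    abort_oct("need at least 2 distinct predictor values", "octbias_domain")
  }
  cand <- (xs[-1] + xs[-length(xs)]) / 2
  lower_pos <- roc$direction == "lower_positive"
  res <- vapply(cand, function(c0) {
    pos_call <- if (lower_pos) x <= c0 else x >= c0
    sens <- mean(pos_call[y == 1])
    spec <- mean(!pos_call[y == 0])
    c(sens, spec, sens + spec - 1)
  }, numeric(3))
  j <- res[3, ]
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1L) {
    sp <- res[2, best]
    best <- best[sp > max(sp) - 1e-12]
    best <- best[which.min(cand[best])]
  }
  list(cutoff = cand[best], sensitivity = 100 * res[1, best],
       specificity = 100 * res[2, best], youden = res[3, best])
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two predictors measured on the same samples using
#' the DeLong covariance of the paired placement values; two-sided p from
#' the normal z statistic.
#'
#' @param x1,x2 numeric predictors on the same samples.
#' @param y binary outcome coded 0/1.
#' @param direction1,direction2 orientation passed to [empirical_roc()]
#'   for each predictor.
#' @return list with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_test <- function(x1, x2, y, direction1 = "auto", direction2 = "auto") {
  if (length(x1) != length(x2) || length(x1) != length(y)) {
    abort_oct("x1, x2 and y must have equal length", "octbias_domain")
  }
  ok <- !is.na(x1) & !is.na(x2) & !is.na(y)
  x1 <- x1[ok]; x2 <- x2[ok]; y <- y[ok]
  check_binary(y)
  r1 <- empirical_roc(x1, y, direction = direction1)
  r2 <- empirical_roc(x2, y, direction = direction2)
  s1 <- if (r1$direction == "lower_positive") -x1 else x1
  s2 <- if (r2$direction == "lower_positive") -x2 else x2
  p1 <- delong_placements(s1, y)
  p2 <- delong_placements(s2, y)
  d10 <- p1$v10 - p2$v10
  d01 <- p1$v01 - p2$v01
  vd <- stats::var(d10) / p1$m + stats::var(d01) / p1$n
  if (!is.finite(vd) || vd < 1e-14) {
    abort_oct("zero variance of the AUC difference: DeLong test degenerate",
              "octbias_degenerate_test")
  }
  z <- (p1$auc - p2$auc) / sqrt(vd)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
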