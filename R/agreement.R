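# Inter-/intra-observer agreement statistics.

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' The conventional inter-rater form for continuous measurements repeated
#' by two readers, computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param ratings numeric matrix, one row per subject, one column per
#'   rater (>= 5 subjects, >= 2 raters, no missing cells).
#' @return the ICC estimate (a scalar <= 1).
#' @export
icc_2_1 <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) abort_oct("ratings must have no missing cells", "octbias_domain")
  n <- nrow(m); k <- ncol(m)
  if (n < 5L || k < 2L) {
    abort_oct("need >= 5 subjects and >= 2 raters", "octbias_domain")
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (abs(denom) < 1e-14) {
    abort_oct("zero between-subject variance: ICC undefined", "octbias_domain")
  }
  (msr - mse) / denom
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement between two categorical labelings:
#' `(po - pe) / (1 - pe)`.
#'
#' @param l1,l2 equal-length vectors of categorical labels.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(l1, l2) {
  if (length(l1) != length(l2)) {
    abort_oct("labelings must have equal length", "octbias_domain")
  }
  lev <- sort(unique(c(as.character(l1), as.character(l2))))
  if (length(lev) < 2L) {
    abort_oct("a single shared category leaves kappa undefined",
              "octbias_domain")
  }
  t1 <- factor(as.character(l1), levels = lev)
  t2 <- factor(as.character(l2), levels = lev)
  tab <- table(t1, t2) / length(l1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-14) {
    abort_oct("degenerate marginals: kappa undefined", "octbias_domain")
  }
  (po - pe) / (1 - pe)
}
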