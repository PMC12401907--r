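# Univariate correlation, group comparison, and the cluster-bootstrap
# sensitivity analysis for the AUC.

#' Univariate correlation of a predictor with a binary outcome
#'
#' Rank (Spearman) correlation by default, since the cross-sectional
#' indices are non-normally distributed; `method = "pearson"` gives the
#' point-biserial (product-moment) coefficient.  The p-value is the
#' asymptotic two-sided test from [stats::cor.test()].
#'
#' @param x numeric predictor.
#' @param y binary outcome coded 0/1.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r` and `p`.
#' @export
univariate_r <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(x) & is.finite(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort_oct("need at least 3 pairs", "octbias_domain")
  check_binary(y)
  if (stats::sd(x) == 0) {
    abort_oct("constant predictor: correlation undefined", "octbias_domain")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups.  The p-value
#' is exact when `n_a * n_b <= 400` and there are no ties, and uses the
#' tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `U` (the statistic for sample `a`) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort_oct("both groups must be non-empty", "octbias_domain")
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Cluster-bootstrap confidence interval for the AUC
#'
#' Sensitivity analysis for within-patient clustering: patients (clusters)
#' are resampled with replacement `B` times and the empirical AUC is
#' recomputed on each replicate; the CI is the percentile interval.  This
#' is a surrogate for a GEE-type clustered analysis.  Replicates missing
#' one outcome class are redrawn (at most 100 retries each).
#'
#' @param x numeric predictor.
#' @param y binary outcome coded 0/1.
#' @param cluster_ids cluster (patient) identifier per observation;
#'   at least 2 distinct clusters.
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the resampling RNG.
#' @param direction passed to [empirical_roc()]; the default fixes the
#'   orientation once from the pooled data so replicates are comparable.
#' @param conf_level confidence level.
#' @return list with `auc` (pooled point estimate), `ci_low`, `ci_high`,
#'   `B`, `n_clusters`.
#' @export
cluster_bootstrap_auc <- function(x, y, cluster_ids, B = 2000, seed = 1L,
                                  direction = NULL, conf_level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; cluster_ids <- cluster_ids[ok]
  check_binary(y)
  cl <- unique(cluster_ids)
  if (length(cl) < 2L) {
    abort_oct("need at least 2 clusters", "octbias_precondition")
  }
  pooled <- empirical_roc(x, y, direction = if (is.null(direction)) "auto"
                          else direction)
  dir_fixed <- pooled$direction
  idx_by_cl <- split(seq_along(x), cluster_ids)
  aucs <- numeric(B)
  local_rng(seed, {
    for (b in seq_len(B)) {
      for (try in seq_len(100L)) {
        pick <- sample(length(idx_by_cl), replace = TRUE)
        idx <- unlist(idx_by_cl[pick], use.names = FALSE)
        if (length(unique(y[idx])) == 2L) break
        if (try == 100L) {
          abort_oct("could not draw a two-class bootstrap replicate",
                    "octbias_domain")
        }
      }
      aucs[b] <- empirical_roc(x[idx], y[idx], direction = dir_fixed)$auc
    }
  })
  alpha <- 1 - conf_level
  qs <- stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  list(auc = pooled$auc, ci_low = qs[1], ci_high = qs[2], B = B,
       n_clusters = length(cl))
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's
# random state afterwards.
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
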