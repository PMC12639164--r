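#' Mean ascending rank across models
#'
#' Normalizes each model's scores through an ascending rank transform (tied
#' scores receive the average rank) and averages the ranks per lesion. The
#' mean rank is a distribution-free consensus of model-perceived risk that is
#' robust to arbitrary monotone differences between model output scales.
#'
#' @param score_matrix Numeric matrix or data frame, lesions in rows and
#'   models in columns; no missing scores allowed (no imputation is done).
#' @return An object of class `rank_aggregate`: list with `ranks` (matrix of
#'   per-model ranks) and `mean_rank` (numeric vector, one entry per lesion).
#' @export
mean_ascending_rank <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (!is.numeric(m)) stopf("score_matrix must be numeric")
  if (nrow(m) < 2) stopf("need at least 2 lesions")
  if (ncol(m) < 1) stopf("need at least 1 model")
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stopf("missing score for lesion row %d; scores must be complete", bad)
  }
  ranks <- apply(m, 2, rank, ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = ncol(m))
  structure(list(ranks = ranks, mean_rank = rowMeans(ranks)),
            class = "rank_aggregate")
}

#' Spearman association of lesion features with consensus risk rank
#'
#' Correlates each continuous lesion characteristic with the mean ascending
#' risk rank from [mean_ascending_rank()], using Spearman's rank correlation.
#' The returned table is sorted by the correlation (most negative first) so
#' it can be drawn directly as a waterfall plot.
#'
#' @param features Numeric vector, or data frame/matrix of numeric feature
#'   columns aligned with the lesions of `rank_aggregate`.
#' @param rank_aggregate A `rank_aggregate` object, or a numeric vector of
#'   mean ranks.
#' @return For a single feature vector, Spearman's rho (NA for a constant
#'   feature). Otherwise a data frame with columns `feature`, `rho`, `n`,
#'   sorted by `rho`.
#' @export
feature_risk_correlation <- function(features, rank_aggregate) {
  mr <- if (inherits(rank_aggregate, "rank_aggregate")) {
    rank_aggregate$mean_rank
  } else {
    as.numeric(rank_aggregate)
  }
  rho_one <- function(x) {
    ok <- is.finite(x) & is.finite(mr)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(x[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], mr[ok], method = "spearman")
  }
  if (is.numeric(features) && is.null(dim(features))) {
    if (length(features) != length(mr)) stopf("features must align with ranks")
    return(rho_one(features))
  }
  fm <- as.data.frame(features)
  if (nrow(fm) != length(mr)) stopf("features must align with ranks")
  rho <- vapply(fm, function(x) rho_one(as.numeric(x)), numeric(1))
  n <- vapply(fm, function(x) sum(is.finite(as.numeric(x)) & is.finite(mr)),
              numeric(1))
  out <- data.frame(feature = names(fm), rho = rho, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$rho), , drop = FALSE]
}

#' Compare risk-score distributions between two lesion subclasses
#'
#' Two-sample Kolmogorov-Smirnov comparison of the score distributions of two
#' diagnostic subclasses (e.g. actinic keratosis vs squamous cell carcinoma),
#' asking whether a model perceives the two subclasses differently.
#'
#' @param scores Numeric risk scores.
#' @param subclass Character/factor vector of subclass labels per lesion.
#' @param class_a,class_b The two subclass labels to compare.
#' @return List with `statistic` (KS D), `p_value`, and group sizes.
#' @export
subclass_score_comparison <- function(scores, subclass, class_a, class_b) {
  a <- scores[subclass == class_a]
  b <- scores[subclass == class_b]
  if (length(a) == 0) stopf("no lesions with subclass '%s'", class_a)
  if (length(b) == 0) stopf("no lesions with subclass '%s'", class_b)
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b))
}
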