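#' Empirical ROC curve with tied scores merged
#'
#' Builds the empirical receiver operating characteristic curve of a score
#' vector against binary labels. Lesions sharing a score are merged into a
#' single threshold step (the simultaneous-threshold convention), so the
#' result is independent of input order and tied blocks appear as single
#' diagonal segments of the piecewise-linear curve.
#'
#' @param scores Numeric vector; higher means more malignant-looking.
#' @param labels 0/1 vector, 1 = malignant.
#' @return A data frame with columns `fpr` and `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both nondecreasing.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  scores <- check_scores(scores, labels)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # last index of each tied block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l)[last]
  fp <- (last - cumsum(l)[last])
  data.frame(fpr = c(0, fp / neg), tpr = c(0, tp / pos))
}

#' Partial AUC above a true-positive-rate floor
#'
#' Area under the empirical ROC curve restricted to operating points with
#' sensitivity above `tpr_floor`, computed as the integral of
#' `max(TPR(f) - tpr_floor, 0)` over the false positive rate `f`. This is the
#' raw (non-standardized) partial area: with the default floor of 0.8 the
#' value lies in \[0, 0.2\], attaining 0.2 only when every positive outscores
#' every negative, and 0.02 for an uninformative (diagonal) ROC curve.
#'
#' @inheritParams roc_curve
#' @param tpr_floor Sensitivity floor in \[0, 1); default 0.8.
#' @return A single number in \[0, 1 - tpr_floor\].
#' @examples
#' partial_auc_above_tpr(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 0.2
#' @export
partial_auc_above_tpr <- function(scores, labels, tpr_floor = 0.8) {
  if (!is.numeric(tpr_floor) || length(tpr_floor) != 1 ||
      tpr_floor < 0 || tpr_floor >= 1) {
    stopf("tpr_floor must be a single value in [0, 1)")
  }
  rc <- roc_curve(scores, labels)
  f <- rc$fpr
  t <- rc$tpr
  area <- 0
  for (i in seq_len(nrow(rc) - 1)) {
    f0 <- f[i]; f1 <- f[i + 1]
    t0 <- t[i]; t1 <- t[i + 1]
    df <- f1 - f0
    if (df <= 0) next
    if (t1 <= tpr_floor) next
    if (t0 >= tpr_floor) {
      area <- area + df * ((t0 + t1) / 2 - tpr_floor)
    } else {
      # segment crosses the floor once (TPR nondecreasing along the curve)
      frac <- (t1 - tpr_floor) / (t1 - t0)
      area <- area + (df * frac) * (t1 - tpr_floor) / 2
    }
  }
  area
}

#' Area under the full ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, with tied pairs counted one half. Identical to the
#' trapezoidal area under [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  scores <- check_scores(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Number needed to triage at a target sensitivity
#'
#' The average number of lesions that must be flagged for expert evaluation
#' per detected malignancy, when the score threshold is the highest cutoff
#' whose sensitivity reaches `target_se` (i.e. the fewest-lesions-triaged
#' qualifying threshold). When score ties make the exact target unattainable,
#' the nearest attainable sensitivity at or above the target is used and
#' reported in the attributes.
#'
#' @inheritParams roc_curve
#' @param target_se Target sensitivity in (0, 1\].
#' @return NNT (>= 1), with attributes `attained_sensitivity` (the sensitivity
#'   actually realized at the chosen threshold), `threshold`, and `exact`
#'   (`TRUE` when the attained sensitivity equals the target).
#' @export
nnt_at_sensitivity <- function(scores, labels, target_se) {
  labels <- check_binary_labels(labels)
  scores <- check_scores(scores, labels)
  if (!is.numeric(target_se) || length(target_se) != 1 ||
      target_se <= 0 || target_se > 1) {
    stopf("target_se must be a single value in (0, 1]")
  }
  n_pos <- sum(labels == 1)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- which(c(s[-1] != s[-length(s)], TRUE))  # tied blocks collapse
  tp <- cumsum(l)[last]
  n_triaged <- last
  sens <- tp / n_pos
  idx <- which(sens >= target_se - 1e-12)[1]
  nnt <- n_triaged[idx] / tp[idx]
  structure(nnt,
            attained_sensitivity = sens[idx],
            threshold = s[last][idx],
            exact = isTRUE(abs(sens[idx] - target_se) <= 1e-12))
}

#' Sensitivity when reviewing each patient's top-k lesions
#'
#' Evaluates the hypothetical triage task of sending only the `k`
#' highest-scoring lesions of every patient for expert review. Each diseased
#' patient contributes equally, so patients carrying several malignancies do
#' not dominate the estimate.
#'
#' Two aggregation modes are provided because patient-level phrasing is
#' ambiguous between detection and exhaustiveness:
#' \describe{
#'   \item{`"patient"`}{fraction of diseased patients with at least one
#'     malignancy among their top-k lesions (detection; the default).}
#'   \item{`"macro"`}{mean over diseased patients of the fraction of their
#'     malignancies captured in the top k.}
#' }
#' Ties at rank k are broken by descending score, then lexicographic lesion
#' id, so the reviewed set always has at most k lesions and is reproducible.
#'
#' @inheritParams roc_curve
#' @param patient_ids Vector assigning each lesion to a patient.
#' @param k Number of lesions reviewed per patient (default 15).
#' @param mode `"patient"` or `"macro"`; see Details.
#' @param lesion_ids Optional lesion identifiers used only to break score
#'   ties at rank k deterministically; defaults to input position.
#' @return Sensitivity in \[0, 1\].
#' @export
sensitivity_top_k <- function(scores, labels, patient_ids, k = 15,
                              mode = c("patient", "macro"),
                              lesion_ids = NULL) {
  mode <- match.arg(mode)
  labels <- check_binary_labels(labels)
  scores <- check_scores(scores, labels)
  if (length(patient_ids) != length(scores)) {
    stopf("patient_ids must align with scores")
  }
  if (k < 1) stopf("k must be >= 1")
  if (is.null(lesion_ids)) {
    lesion_ids <- sprintf("lesion_%09d", seq_along(scores))
  }
  diseased <- unique(patient_ids[labels == 1])
  if (length(diseased) == 0) stopf("no diseased patients")
  per_patient <- vapply(diseased, function(p) {
    in_p <- patient_ids == p
    o <- order(-scores[in_p], as.character(lesion_ids)[in_p])
    top <- o[seq_len(min(k, sum(in_p)))]
    caught <- sum(labels[in_p][top])
    total <- sum(labels[in_p])
    if (mode == "patient") as.numeric(caught > 0) else caught / total
  }, numeric(1))
  mean(per_patient)
}

#' Within-patient percentile placement of malignant lesions
#'
#' For each (optionally subclass-filtered) malignant lesion, computes its
#' ascending percentile among all lesions of the same patient (rank / n, with
#' tied scores given the maximum rank) and the number of lesions on that
#' patient scoring strictly higher. Aggregates summarize how often a
#' malignancy tops its patient's list and how far down it can sit.
#'
#' @inheritParams sensitivity_top_k
#' @param positive Logical vector marking the lesions to characterize
#'   (default: all lesions with `labels == 1`); use it to restrict to a
#'   subclass such as melanoma.
#' @return A list with `per_lesion` (data frame: patient, percentile,
#'   n_outscoring, n_lesions) and `stats`: `fraction_rank1` (no lesion
#'   strictly higher), `fraction_ge_p99`, `fraction_lt_p95`,
#'   `median_n_outscoring` and `mean_n_outscoring`.
#' @export
per_patient_percentiles <- function(scores, labels, patient_ids,
                                    positive = NULL) {
  labels <- check_binary_labels(labels)
  scores <- check_scores(scores, labels)
  if (is.null(positive)) positive <- labels == 1
  if (length(positive) != length(scores)) {
    stopf("positive filter must align with scores")
  }
  if (!any(positive)) stopf("no positive lesions after filtering")
  if (any(positive & labels != 1)) {
    stopf("positive filter selects non-malignant lesions")
  }
  idx <- which(positive)
  res <- lapply(idx, function(i) {
    in_p <- patient_ids == patient_ids[i]
    n <- sum(in_p)
    higher <- sum(scores[in_p] > scores[i])
    list(patient = patient_ids[i],
         percentile = (n - higher) / n,  # max rank for ties
         n_outscoring = higher,
         n_lesions = n)
  })
  per_lesion <- data.frame(
    patient = as.character(vapply(res, function(x) as.character(x$patient), character(1))),
    percentile = vapply(res, `[[`, numeric(1), "percentile"),
    n_outscoring = vapply(res, `[[`, numeric(1), "n_outscoring"),
    n_lesions = vapply(res, `[[`, numeric(1), "n_lesions"),
    stringsAsFactors = FALSE
  )
  stats <- list(
    fraction_rank1 = mean(per_lesion$n_outscoring == 0),
    fraction_ge_p99 = mean(per_lesion$percentile >= 0.99),
    fraction_lt_p95 = mean(per_lesion$percentile < 0.95),
    median_n_outscoring = stats::median(per_lesion$n_outscoring),
    mean_n_outscoring = mean(per_lesion$n_outscoring)
  )
  list(per_lesion = per_lesion, stats = stats)
}

#' Full triage metric report for one score set
#'
#' Convenience wrapper computing every evaluation statistic used by the
#' ablation study: partial AUC above the sensitivity floor, full AUC, number
#' needed to triage at each target sensitivity, top-k sensitivity in both
#' aggregation modes, and per-patient percentile placement.
#'
#' @inheritParams sensitivity_top_k
#' @param targets Sensitivities at which to report NNT (default 0.8, 0.9).
#' @param tpr_floor Floor for the partial AUC (default 0.8).
#' @param positive Optional logical filter passed to
#'   [per_patient_percentiles()].
#' @return An object of class `triage_metric_report` (a list).
#' @export
metric_report <- function(scores, labels, patient_ids, k = 15,
                          targets = c(0.8, 0.9), tpr_floor = 0.8,
                          positive = NULL) {
  nnt <- lapply(targets, function(t) nnt_at_sensitivity(scores, labels, t))
  names(nnt) <- sprintf("nnt_%d", round(100 * targets))
  out <- list(
    pauc_above_tpr = partial_auc_above_tpr(scores, labels, tpr_floor),
    tpr_floor = tpr_floor,
    auc = auc(scores, labels),
    nnt = lapply(nnt, as.numeric),
    nnt_detail = nnt,
    se_top_k_patient = sensitivity_top_k(scores, labels, patient_ids, k,
                                         mode = "patient"),
    se_top_k_macro = sensitivity_top_k(scores, labels, patient_ids, k,
                                       mode = "macro"),
    k = k,
    percentiles = per_patient_percentiles(scores, labels, patient_ids,
                                          positive = positive)$stats
  )
  class(out) <- "triage_metric_report"
  out
}

#' @export
print.triage_metric_report <- function(x, ...) {
  cat(sprintf("Triage metrics (floor %.0f%% TPR, top-%d review)\n",
              100 * x$tpr_floor, x$k))
  cat(sprintf("  pAUC>%.0f%%TPR : %.4f\n", 100 * x$tpr_floor, x$pauc_above_tpr))
  cat(sprintf("  AUC          : %.4f\n", x$auc))
  for (nm in names(x$nnt)) {
    cat(sprintf("  %-13s: %.2f\n", toupper(nm), x$nnt[[nm]]))
  }
  cat(sprintf("  SE_top-%d (patient): %.4f  (macro: %.4f)\n",
              x$k, x$se_top_k_patient, x$se_top_k_macro))
  p <- x$percentiles
  cat(sprintf("  rank-1 %.0f%% | >=p99 %.0f%% | <p95 %.0f%% | median outscoring %g (mean %.1f)\n",
              100 * p$fraction_rank1, 100 * p$fraction_ge_p99,
              100 * p$fraction_lt_p95, p$median_n_outscoring,
              p$mean_n_outscoring))
  invisible(x)
}
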