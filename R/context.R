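# Patient-contextual ("ugly duckling") feature engineering.

#' Patient-contextual features for every lesion
#'
#' Re-expresses each lesion measurement relative to the other lesions of the
#' same patient, mimicking how clinicians flag outlier ("ugly duckling")
#' lesions: per measurement a within-patient z-score and ratio-to-mean, a
#' within-patient percentile, plus the patient's lesion count and a robust
#' outlier distance of the lesion's standardized measurement vector from the
#' patient's median vector.
#'
#' Conventions: z-scores use the sample (n-1) standard deviation; singleton
#' patients and zero-variance measurements yield z = 0 rather than missing
#' values, so low-lesion-count patients do not flood the model with NA.
#' Percentiles are rank/n with ties averaged (1.0 for a singleton).
#' The ugly-duckling index is the Euclidean norm of the per-measurement
#' deviations from the patient median, each standardized by the patient MAD
#' (components with zero MAD contribute 0); a lesion equal to the median
#' vector scores exactly 0. Missing measurements propagate as NA in their own
#' derived features and are dropped from the distance, never imputed.
#'
#' All features are computed strictly within patient: lesions of one patient
#' can never influence features of another, and output is invariant to the
#' ordering of lesions within the input.
#'
#' @param measurements Data frame of numeric per-lesion measurements (one row
#'   per lesion); typically the `tbp_lv_*` columns or image-derived `img_*`
#'   columns.
#' @param patient_ids Vector aligned with rows of `measurements`.
#' @return Data frame with, per input measurement `m`, columns `ctx_z_m`,
#'   `ctx_ratio_m`, `ctx_pct_m`; plus `ctx_lesion_count` and
#'   `ctx_ugly_duckling`.
#' @export
contextualize <- function(measurements, patient_ids) {
  mdf <- as.data.frame(measurements)
  if (nrow(mdf) == 0) stopf("no lesions to contextualize")
  if (length(patient_ids) != nrow(mdf)) {
    stopf("patient_ids must align with measurement rows")
  }
  num <- vapply(mdf, is.numeric, logical(1))
  if (!all(num)) stopf("all measurement columns must be numeric")
  cols <- names(mdf)

  n <- nrow(mdf)
  out <- vector("list", length(cols) * 3 + 2)
  z_all <- matrix(NA_real_, n, length(cols))
  ratio_all <- matrix(NA_real_, n, length(cols))
  pct_all <- matrix(NA_real_, n, length(cols))
  count_all <- integer(n)
  ud_all <- numeric(n)

  for (idx in split(seq_len(n), as.character(patient_ids))) {
    block <- as.matrix(mdf[idx, , drop = FALSE])
    k <- length(idx)
    count_all[idx] <- k
    dev_std <- matrix(0, k, length(cols))  # MAD-standardized deviations
    for (j in seq_along(cols)) {
      x <- block[, j]
      ok <- is.finite(x)
      mu <- if (any(ok)) mean(x[ok]) else NA_real_
      sdv <- if (sum(ok) >= 2) stats::sd(x[ok]) else 0
      z <- rep(NA_real_, k)
      z[ok] <- if (is.finite(sdv) && sdv > 0) (x[ok] - mu) / sdv else 0
      ratio <- rep(NA_real_, k)
      if (is.finite(mu) && mu != 0) ratio[ok] <- x[ok] / mu
      pct <- rep(NA_real_, k)
      if (any(ok)) pct[ok] <- rank(x[ok], ties.method = "average") / sum(ok)
      z_all[idx, j] <- z
      ratio_all[idx, j] <- ratio
      pct_all[idx, j] <- pct
      med <- if (any(ok)) stats::median(x[ok]) else NA_real_
      madv <- if (any(ok)) stats::mad(x[ok]) else 0
      dj <- rep(0, k)
      if (is.finite(madv) && madv > 0) dj[ok] <- (x[ok] - med) / madv
      dev_std[, j] <- dj
    }
    ud_all[idx] <- sqrt(rowSums(dev_std^2))
  }

  res <- data.frame(row.names = NULL, matrix(nrow = n, ncol = 0))
  for (j in seq_along(cols)) res[[paste0("ctx_z_", cols[j])]] <- z_all[, j]
  for (j in seq_along(cols)) {
    res[[paste0("ctx_ratio_", cols[j])]] <- ratio_all[, j]
  }
  for (j in seq_along(cols)) res[[paste0("ctx_pct_", cols[j])]] <- pct_all[, j]
  res$ctx_lesion_count <- count_all
  res$ctx_ugly_duckling <- ud_all
  res
}
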