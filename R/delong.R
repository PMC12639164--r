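#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors evaluated on the
#' same lesions, using placement values to estimate the covariance of the two
#' empirical AUCs and a normal approximation for the two-sided p value.
#' When the variance of the AUC difference is (numerically) zero -- e.g. the
#' two score vectors are identical or related by a strictly increasing
#' transform -- the AUCs are equal and p = 1 by convention.
#'
#' @param scores_a,scores_b Paired score vectors on identical lesions.
#' @param labels 0/1 vector, 1 = malignant.
#' @return A list with `auc_a`, `auc_b`, `z`, and two-sided `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  scores_a <- check_scores(scores_a, labels)
  scores_b <- check_scores(scores_b, labels)

  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos)
  n <- length(neg)

  placements <- function(s) {
    # V10[i]: fraction of negatives scored below positive i (ties = 1/2)
    # V01[j]: fraction of positives scored above negative j (ties = 1/2)
    sp <- s[pos]
    sn <- s[neg]
    v10 <- vapply(sp, function(x) {
      (sum(sn < x) + 0.5 * sum(sn == x)) / n
    }, numeric(1))
    v01 <- vapply(sn, function(x) {
      (sum(sp > x) + 0.5 * sum(sp == x)) / m
    }, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }

  pa <- placements(scores_a)
  pb <- placements(scores_b)

  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n

  d <- pa$auc - pb$auc
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p_value = p)
}
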