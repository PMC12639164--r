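test_that("partial AUC handles perfect, uninformative and reversed rankings", {
  expect_equal(partial_auc_above_tpr(c(.9, .8, .7, .3, .2, .1),
                                     c(1, 1, 1, 0, 0, 0)), 0.2,
               tolerance = 1e-12)
  # all scores tied: ROC is the diagonal, integral_{0.8}^{1} (f - 0.8) df
  expect_equal(partial_auc_above_tpr(rep(1, 12),
                                     rep(c(1, 0), 6)), 0.02,
               tolerance = 1e-12)
  expect_equal(partial_auc_above_tpr(c(.1, .2, .9, .8), c(1, 1, 0, 0)), 0,
               tolerance = 1e-12)
  expect_error(partial_auc_above_tpr(c(.1, .2), c(1, 1)), "single-class")
  expect_error(partial_auc_above_tpr(c(.1, .2), c(1, 0), tpr_floor = 1),
               "tpr_floor")
})

test_that("partial AUC matches the exhaustive threshold oracle", {
  s <- c(0.9, 0.4, 0.8, 0.3, 0.2)
  l <- c(1, 1, 0, 0, 0)
  expect_equal(partial_auc_above_tpr(s, l), oracle_pauc(s, l),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, 0.125), n, replace = TRUE)  # force ties
    expect_equal(partial_auc_above_tpr(s, l), oracle_pauc(s, l),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the all-pairs Mann-Whitney count, ties counted half", {
  expect_identical(auc(c(.9, .8, .1), c(1, 1, 0)), 1)
  expect_identical(auc(c(.1, .2, .9), c(1, 1, 0)), 0)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- sample(1:6, n, replace = TRUE) / 6
    expect_equal(auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
  }
})

test_that("NNT picks the fewest-triaged threshold reaching the target", {
  expect_equal(as.numeric(nnt_at_sensitivity(c(.9, .8, .2, .1),
                                             c(1, 0, 0, 0), 1)), 1)
  expect_equal(as.numeric(nnt_at_sensitivity(c(.8, .9, .2, .1),
                                             c(1, 0, 0, 0), 1)), 2)
  # perfect classifier: only positives triaged at any target
  expect_equal(as.numeric(nnt_at_sensitivity(c(.9, .8, .1, .2),
                                             c(1, 1, 0, 0), 0.8)), 1)
  set.seed(11)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- sample(1:5, n, replace = TRUE) / 5
    tgt <- sample(c(0.5, 0.8, 0.9, 1), 1)
    expect_equal(as.numeric(nnt_at_sensitivity(s, l, tgt)),
                 oracle_nnt(s, l, tgt), tolerance = 1e-12)
  }
})

test_that("NNT flags unattainable exact sensitivities via attributes", {
  # tied block forces sensitivity to jump from 0 straight to 1
  v <- nnt_at_sensitivity(c(.5, .5, .5, .1), c(1, 1, 0, 0), 0.5)
  expect_false(attr(v, "exact"))
  expect_gte(attr(v, "attained_sensitivity"), 0.5)
})

test_that("NNT of a random classifier approaches 1/prevalence", {
  p <- 0.01
  nnts <- vapply(1:5, function(s) {
    set.seed(s)
    l <- c(1, 0, rbinom(5e4 - 2, 1, p))
    as.numeric(nnt_at_sensitivity(runif(5e4), l, 0.8))
  }, numeric(1))
  expect_equal(mean(nnts), 1 / p, tolerance = 0.12)
})

test_that("top-k sensitivity honours patient weighting and tie rules", {
  # every diseased patient has <= k lesions
  s <- c(.9, .1, .5, .4)
  l <- c(1, 0, 1, 0)
  pid <- c("a", "a", "b", "b")
  expect_equal(sensitivity_top_k(s, l, pid, k = 15), 1)
  expect_equal(sensitivity_top_k(s, l, pid, k = 15, mode = "macro"), 1)

  # one patient, malignancies at ranks 3 and 20 of 25
  n <- 25
  s1 <- seq(1, 0, length.out = n)
  l1 <- rep(0, n); l1[c(3, 20)] <- 1
  pid1 <- rep("p", n)
  expect_equal(sensitivity_top_k(s1, l1, pid1, k = 15), 1)
  expect_equal(sensitivity_top_k(s1, l1, pid1, k = 15, mode = "macro"), 0.5)

  # saturation: k = max lesions per patient
  expect_equal(sensitivity_top_k(s1, l1, pid1, k = n, mode = "macro"), 1)

  # matches brute-force enumeration incl. tie handling at rank k
  set.seed(3)
  for (i in 1:20) {
    n <- 60
    pid <- sample(sprintf("p%d", 1:4), n, replace = TRUE)
    l <- rbinom(n, 1, 0.2); l[1] <- 1; l[2] <- 0
    s <- sample(1:8, n, replace = TRUE) / 8
    k <- sample(2:10, 1)
    expect_equal(sensitivity_top_k(s, l, pid, k), oracle_topk(s, l, pid, k))
    expect_equal(sensitivity_top_k(s, l, pid, k, mode = "macro"),
                 oracle_topk(s, l, pid, k, mode = "macro"))
  }
})

test_that("top-k sensitivity is nondecreasing in k", {
  set.seed(5)
  n <- 200
  pid <- sample(sprintf("p%d", 1:5), n, replace = TRUE)
  l <- rbinom(n, 1, 0.1); l[1] <- 1; l[2] <- 0
  s <- runif(n)
  for (mode in c("patient", "macro")) {
    vals <- vapply(c(1, 2, 5, 10, 20, 50),
                   function(k) sensitivity_top_k(s, l, pid, k, mode = mode),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("per-patient percentiles follow the max-rank and strictness rules", {
  # positive is the unique top scorer in a 100-lesion patient
  s <- c(1, runif(99, 0, 0.9))
  l <- c(1, rep(0, 99))
  pp <- per_patient_percentiles(s, l, rep("p", 100))
  expect_equal(pp$per_lesion$percentile, 1)
  expect_equal(pp$per_lesion$n_outscoring, 0)
  expect_equal(pp$stats$fraction_rank1, 1)

  # positive with exactly 50 strictly higher scorers among 100
  s2 <- seq(0.01, 1, length.out = 100)
  l2 <- rep(0, 100); l2[50] <- 1  # ascending rank 50
  pp2 <- per_patient_percentiles(s2, l2, rep("p", 100))
  expect_equal(pp2$per_lesion$percentile, 0.50)
  expect_equal(pp2$per_lesion$n_outscoring, 50)
  expect_equal(pp2$stats$fraction_lt_p95, 1)

  # all lesions tied: strict counting gives 0 outscoring, percentile 1
  pp3 <- per_patient_percentiles(rep(0.5, 10), c(1, rep(0, 9)), rep("p", 10))
  expect_equal(pp3$per_lesion$n_outscoring, 0)
  expect_equal(pp3$per_lesion$percentile, 1)
})

test_that("every metric is invariant to strictly increasing score transforms", {
  set.seed(9)
  for (i in 1:10) {
    n <- 300
    pid <- sample(sprintf("p%d", 1:6), n, replace = TRUE)
    l <- rbinom(n, 1, 0.1); l[1] <- 1; l[2] <- 0
    s <- round(runif(n), 2)
    tr <- function(x) exp(3 * x) + 7  # strictly increasing
    expect_equal(partial_auc_above_tpr(tr(s), l), partial_auc_above_tpr(s, l),
                 tolerance = 1e-10)
    expect_equal(auc(tr(s), l), auc(s, l), tolerance = 1e-12)
    expect_equal(as.numeric(nnt_at_sensitivity(tr(s), l, 0.8)),
                 as.numeric(nnt_at_sensitivity(s, l, 0.8)))
    expect_equal(sensitivity_top_k(tr(s), l, pid, 10),
                 sensitivity_top_k(s, l, pid, 10))
  }
})

test_that("pAUC is bounded by min(0.2, AUC) and NNT is at least 1", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.3))
    s <- sample(1:10, n, replace = TRUE) / 10
    pa <- partial_auc_above_tpr(s, l)
    expect_gte(pa, 0)
    expect_lte(pa, min(0.2, auc(s, l)) + 1e-12)
    expect_gte(as.numeric(nnt_at_sensitivity(s, l, 0.9)), 1)
  }
})

test_that("metric_report aggregates all statistics consistently", {
  set.seed(13)
  n <- 500
  pid <- sample(sprintf("p%d", 1:10), n, replace = TRUE)
  l <- rbinom(n, 1, 0.05); l[1] <- 1; l[2] <- 0
  s <- runif(n) + l  # informative
  mr <- metric_report(s, l, pid)
  expect_s3_class(mr, "triage_metric_report")
  expect_equal(mr$auc, auc(s, l))
  expect_equal(mr$pauc_above_tpr, partial_auc_above_tpr(s, l))
  expect_named(mr$nnt, c("nnt_80", "nnt_90"))
  expect_output(print(mr), "pAUC")
})
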