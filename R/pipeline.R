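# End-to-end ablation study: simulate -> measure -> features -> fit ->
# evaluate -> compare.

#' Run the feature-class ablation study on a cohort
#'
#' Orchestrates the full analysis: builds (or accepts) a cohort, optionally
#' renders and measures tiles, assembles the feature table, fits the logistic
#' baseline and every requested ablation variant of the boosted risk model
#' with patient-grouped cross-validation, evaluates all of them with the
#' triage metrics on out-of-fold scores, and compares the full variant with
#' its no-patient-context counterpart by DeLong's test.
#'
#' One structured log line is emitted per stage (seed, row and positive
#' counts -- the quantities that determine every downstream metric). The
#' report is fully reproducible given the seeds and contains no timestamps.
#'
#' @param x A [cohort_config()] or a `tbp_cohort` from [generate_cohort()].
#' @param variants Named list of [ablation_spec()]s (default: all ten).
#' @param cv_seed Seed for fold assignment and boosting members.
#' @param k Per-patient review budget for the top-k sensitivity (default 15).
#' @param targets Sensitivities at which NNT is reported (default 0.8, 0.9).
#' @param tile_measurements Optional precomputed [measure_cohort_tiles()]
#'   output; if absent and a variant uses tiles, tiles are rendered and
#'   measured on the fly (`render = TRUE`) with `noise` texture.
#' @param render Allow on-the-fly tile measurement (default TRUE).
#' @param noise Passed to [measure_cohort_tiles()].
#' @param model_args Extra arguments forwarded to [fit_risk_model()] (e.g.
#'   `nrounds`, `param_grid`) to scale the study up or down.
#' @param out_dir Optional directory; when given, writes `report.csv` and
#'   `report.json` there.
#' @return Object of class `ablation_report`: `table` (one row per model:
#'   baseline first, then each variant, with pAUC, AUC, NNT at each target,
#'   and top-k sensitivities), `delong` (full vs no-context comparison, when
#'   both variants are present), `scores` (per-lesion out-of-fold score
#'   matrix), and the seeds/counts needed to reproduce it.
#' @export
run_ablation_study <- function(x, variants = make_ablation_variants(),
                               cv_seed = 1, k = 15, targets = c(0.8, 0.9),
                               tile_measurements = NULL, render = TRUE,
                               noise = TRUE, model_args = list(),
                               out_dir = NULL) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  log_line <- function(name, ...) {
    message(sprintf("[%s] %s", name, paste(sprintf(...), collapse = "")))
  }

  cohort <- stage("simulate", {
    if (inherits(x, "cohort_config")) generate_cohort(x)
    else if (inherits(x, "tbp_cohort")) x
    else stopf("x must be a cohort_config or tbp_cohort")
  })
  rec <- cohort$records
  if (nrow(rec) == 0) stopf("stage 'simulate' failed: empty cohort")
  log_line("simulate", "seed=%d lesions=%d patients=%d positives=%d",
           cohort$config$seed, nrow(rec),
           length(unique(rec$patient_id)), sum(rec$target))

  needs_tiles <- any(vapply(variants, function(v) isTRUE(v$tiles),
                            logical(1)))
  if (needs_tiles && is.null(tile_measurements)) {
    if (!render) {
      stopf("stage 'measure' failed: tile variants requested but render=FALSE and no tile_measurements given")
    }
    tile_measurements <- stage("measure",
                               measure_cohort_tiles(cohort, noise = noise))
    log_line("measure", "tiles=%d no_lesion=%d",
             nrow(tile_measurements),
             sum(is.na(tile_measurements$img_area_mm2)))
  }

  features <- stage("features", prepare_features(rec, tile_measurements))
  labels <- rec$target
  pid <- rec$patient_id
  log_line("features", "columns=%d rows=%d", ncol(features), nrow(features))

  fold_of <- assign_patient_folds(pid, n_folds = 5, cv_seed = cv_seed)
  baseline_scores <- stage("baseline", {
    s <- rep(NA_real_, nrow(rec))
    for (f in sort(unique(fold_of))) {
      tr <- fold_of != f
      mdl <- fit_baseline(rec[tr, , drop = FALSE])
      s[!tr] <- predict(mdl, rec[!tr, , drop = FALSE])
    }
    s
  })
  log_line("baseline", "cv_seed=%d folds=%d", cv_seed,
           length(unique(fold_of)))

  score_mat <- matrix(NA_real_, nrow(rec), length(variants) + 1,
                      dimnames = list(rec$isic_id,
                                      c("baseline_glm", names(variants))))
  score_mat[, 1] <- baseline_scores
  rows <- list()
  eval_one <- function(scores, label) {
    mr <- metric_report(scores, labels, pid, k = k, targets = targets)
    row <- data.frame(model = label,
                      pauc_above_80tpr = mr$pauc_above_tpr,
                      auc = mr$auc, stringsAsFactors = FALSE)
    for (nm in names(mr$nnt)) row[[nm]] <- mr$nnt[[nm]]
    row$se_top_k_patient <- mr$se_top_k_patient
    row$se_top_k_macro <- mr$se_top_k_macro
    row
  }
  rows[["baseline_glm"]] <- eval_one(baseline_scores, "baseline_glm")

  for (vn in names(variants)) {
    mdl <- stage(paste0("fit:", vn), {
      do.call(fit_risk_model,
              c(list(features = features, labels = labels,
                     patient_ids = pid, spec = variants[[vn]],
                     cv_seed = cv_seed), model_args))
    })
    score_mat[, vn] <- mdl$oof_scores
    rows[[vn]] <- stage(paste0("evaluate:", vn),
                        eval_one(mdl$oof_scores, vn))
    log_line("fit", "variant=%s pauc=%.4f auc=%.4f", vn,
             rows[[vn]]$pauc_above_80tpr, rows[[vn]]$auc)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  delong <- NULL
  full_nm <- names(variants)[vapply(variants, function(v) {
    v$meta_basic && v$meta_wb360 && v$patient_context
  }, logical(1)) & vapply(variants, function(v) isTRUE(v$tiles), logical(1))]
  noctx_nm <- names(variants)[vapply(variants, function(v) {
    v$meta_basic && v$meta_wb360 && v$tiles && !v$patient_context
  }, logical(1))]
  if (length(full_nm) == 1 && length(noctx_nm) == 1) {
    delong <- stage("delong",
                    delong_test(score_mat[, full_nm], score_mat[, noctx_nm],
                                labels))
    log_line("delong", "full=%s vs noctx=%s p=%.4g", full_nm, noctx_nm,
             delong$p_value)
  }

  report <- structure(list(table = table, delong = delong,
                           scores = score_mat, cv_seed = cv_seed,
                           cohort_seed = cohort$config$seed,
                           n_lesions = nrow(rec),
                           n_patients = length(unique(pid)),
                           n_positive = sum(labels), k = k,
                           targets = targets),
                      class = "ablation_report")
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(table, file.path(out_dir, "report.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(table = table,
             delong = delong,
             cv_seed = cv_seed, cohort_seed = cohort$config$seed,
             n_lesions = nrow(rec), n_positive = sum(labels)),
        file.path(out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    })
  }
  report
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("Ablation study: %d lesions, %d patients, %d malignant (cohort seed %d, cv seed %d)\n",
              x$n_lesions, x$n_patients, x$n_positive, x$cohort_seed,
              x$cv_seed))
  print(x$table, digits = 4, row.names = FALSE)
  if (!is.null(x$delong)) {
    cat(sprintf("DeLong full vs no-context: AUC %.4f vs %.4f, p = %.4g\n",
                x$delong$auc_a, x$delong$auc_b, x$delong$p_value))
  }
  invisible(x)
}
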