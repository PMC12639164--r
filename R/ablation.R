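# Feature-class ablation design.

#' Define a feature-class combination for the risk model
#'
#' @param meta_basic Use basic demographics metadata (age, sex, anatomic
#'   site, hospital).
#' @param meta_wb360 Use vendor-style appearance measurements.
#' @param tiles Use image-derived measurements computed from tile pixels.
#' @param patient_context Use patient-contextual features.
#' @return Object of class `ablation_spec`.
#' @export
ablation_spec <- function(meta_basic = FALSE, meta_wb360 = FALSE,
                          tiles = FALSE, patient_context = FALSE) {
  flags <- c(meta_basic = isTRUE(meta_basic),
             meta_wb360 = isTRUE(meta_wb360),
             tiles = isTRUE(tiles),
             patient_context = isTRUE(patient_context))
  if (!any(flags)) stopf("at least one feature class must be enabled")
  structure(as.list(flags), class = "ablation_spec")
}

#' @export
format.ablation_spec <- function(x, ...) {
  parts <- c("basic", "wb360", "tiles", "ctx")[unlist(x)]
  paste(parts, collapse = "+")
}

#' @export
print.ablation_spec <- function(x, ...) {
  cat("<ablation_spec>", format(x), "\n")
  invisible(x)
}

#' The ten ablation variants
#'
#' Enumerates the ten feature-class combinations of the ablation design: the
#' five base combinations (all three lesion-level classes; tiles only;
#' tiles + basic metadata; appearance metadata only; appearance + basic
#' metadata), each with and without the patient-context class.
#'
#' @return Named list of 10 unique [ablation_spec()] objects, full model
#'   first.
#' @export
make_ablation_variants <- function() {
  v <- list(
    ablation_spec(TRUE,  TRUE,  TRUE,  TRUE),
    ablation_spec(TRUE,  TRUE,  TRUE,  FALSE),
    ablation_spec(TRUE,  TRUE,  FALSE, TRUE),
    ablation_spec(TRUE,  TRUE,  FALSE, FALSE),
    ablation_spec(TRUE,  FALSE, TRUE,  TRUE),
    ablation_spec(TRUE,  FALSE, TRUE,  FALSE),
    ablation_spec(FALSE, TRUE,  FALSE, TRUE),
    ablation_spec(FALSE, TRUE,  FALSE, FALSE),
    ablation_spec(FALSE, FALSE, TRUE,  TRUE),
    ablation_spec(FALSE, FALSE, TRUE,  FALSE)
  )
  names(v) <- vapply(v, format, character(1))
  v
}
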