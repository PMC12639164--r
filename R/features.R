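# Assembly of the model feature table from cohort records.

#' Build the model feature table with feature-class annotations
#'
#' Converts cohort records (plus, optionally, image-derived tile
#' measurements) into an all-numeric feature table whose columns are tagged
#' with their feature class:
#' \describe{
#'   \item{meta_basic}{age, sex, anatomic-site and hospital indicators.}
#'   \item{meta_wb360}{the `tbp_lv_*` measurement columns and the lighting
#'     modality indicator.}
#'   \item{tiles}{image-derived `img_*` measurement columns (pixel stand-in
#'     for a learned image representation), when `tile_measurements` is
#'     given.}
#'   \item{ctx_wb360 / ctx_tiles}{patient-contextual features derived from
#'     the appearance-metadata block and (when available) from the
#'     image-derived block; the model picks whichever matches its enabled
#'     measurement source, so a variant never sees context computed from a
#'     feature class it excludes.}
#' }
#'
#' @param records Cohort records data frame (see [generate_cohort()]).
#' @param tile_measurements Optional data frame from
#'   [measure_cohort_tiles()]: `isic_id` plus `img_*` columns.
#' @return All-numeric data frame with attribute `feature_classes` (named
#'   character vector mapping each column to its class) and attribute
#'   `patient_ids`.
#' @export
prepare_features <- function(records, tile_measurements = NULL) {
  n <- nrow(records)
  out <- list()
  cls <- character(0)
  add <- function(block, class_name) {
    out[[length(out) + 1]] <<- block
    cls <<- c(cls, stats::setNames(rep(class_name, ncol(block)),
                                   names(block)))
  }

  basic <- data.frame(age_approx = as.numeric(records$age_approx),
                      sex_male = as.numeric(records$sex == "male"))
  for (s in anatomic_sites()) {
    basic[[paste0("site_", gsub("[ /]", "_", s))]] <-
      as.numeric(records$anatom_site_general == s)
  }
  for (cen in sort(unique(records$attribution))) {
    basic[[paste0("center_", make.names(cen))]] <-
      as.numeric(records$attribution == cen)
  }
  add(basic, "meta_basic")

  lv_cols <- grep("^tbp_lv_", names(records), value = TRUE)
  if (length(lv_cols) == 0) stopf("records contain no tbp_lv_* columns")
  wb <- records[, lv_cols, drop = FALSE]
  wb$lighting_xp <- as.numeric(records$tbp_tile_type == "cross-polarized")
  add(wb, "meta_wb360")

  ctxw <- contextualize(records[, lv_cols, drop = FALSE],
                        records$patient_id)
  names(ctxw) <- paste0("w_", names(ctxw))
  add(ctxw, "ctx_wb360")

  if (!is.null(tile_measurements)) {
    m <- match(records$isic_id, tile_measurements$isic_id)
    if (anyNA(m)) stopf("tile_measurements missing some lesions")
    img_cols <- grep("^img_", names(tile_measurements), value = TRUE)
    img <- tile_measurements[m, img_cols, drop = FALSE]
    rownames(img) <- NULL
    add(img, "tiles")
    ctxt <- contextualize(img, records$patient_id)
    names(ctxt) <- paste0("t_", names(ctxt))
    add(ctxt, "ctx_tiles")
  }

  feat <- do.call(cbind, out)
  attr(feat, "feature_classes") <- cls
  attr(feat, "patient_ids") <- records$patient_id
  feat
}

# Columns of `features` permitted under an ablation spec. Context features
# follow the measurement source: appearance metadata when enabled, otherwise
# the image-derived block.
select_feature_columns <- function(features, spec) {
  cls <- attr(features, "feature_classes")
  if (is.null(cls)) stopf("features must come from prepare_features()")
  allowed <- character(0)
  if (spec$meta_basic) allowed <- c(allowed, "meta_basic")
  if (spec$meta_wb360) allowed <- c(allowed, "meta_wb360")
  if (spec$tiles) allowed <- c(allowed, "tiles")
  if (spec$patient_context) {
    if (spec$meta_wb360) {
      allowed <- c(allowed, "ctx_wb360")
    } else if (spec$tiles) {
      allowed <- c(allowed, "ctx_tiles")
    } else {
      allowed <- c(allowed, "ctx_wb360")
    }
  }
  miss <- setdiff(allowed, unique(cls))
  if (length(miss)) {
    stopf("feature table lacks class(es) %s required by spec '%s'",
          paste(miss, collapse = ", "), format(spec))
  }
  names(cls)[cls %in% allowed]
}
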