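# Reading and writing cohorts on disk.

#' Write a cohort to a directory
#'
#' Writes `metadata.csv` (the per-lesion records in a SLICE-3D-like schema),
#' a `traits.json` sidecar holding the true generative traits (for
#' measurement-recovery experiments), and optionally one PNG tile per lesion
#' under `tiles/`.
#'
#' @param cohort A `tbp_cohort`.
#' @param dir Output directory (created if needed).
#' @param render Also render tiles to `tiles/<isic_id>.png` (default FALSE;
#'   rendering every tile of a large cohort is slow and rarely needed since
#'   [measure_cohort_tiles()] can work in memory).
#' @param noise Passed to [render_tile()] when rendering.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, render = FALSE, noise = TRUE) {
  if (!inherits(cohort, "tbp_cohort")) stopf("cohort must be a tbp_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$records, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$traits, file.path(dir, "traits.json"),
                       digits = NA, dataframe = "columns")
  if (render) {
    tdir <- file.path(dir, "tiles")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$traits))) {
      tile <- render_tile(cohort$traits[i, ],
                          mm_per_px = cohort$config$mm_per_px, noise = noise)
      png::writePNG(tile$pixels,
                    file.path(tdir, paste0(cohort$traits$isic_id[i], ".png")))
    }
  }
  invisible(dir)
}

#' Read cohort metadata from CSV
#'
#' Reads a metadata table in the schema written by [write_cohort()] (or any
#' SLICE-3D-like CSV with `isic_id`, `patient_id`, `target`, demographics and
#' `tbp_lv_*` measurement columns).
#'
#' @param path Path to the CSV file.
#' @return Data frame of per-lesion records.
#' @export
read_cohort_metadata <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("isic_id", "patient_id", "target")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stopf("metadata CSV lacks required column(s): %s",
          paste(miss, collapse = ", "))
  }
  rec
}

#' Read a tile image from PNG
#'
#' @param path PNG file path.
#' @param mm_per_px Physical scale of the tile (default 15/128).
#' @return A [tile_image()].
#' @export
read_tile <- function(path, mm_per_px = 15 / 128) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  tile_image(px, mm_per_px)
}

#' Triage arithmetic for a cohort's headline counts
#'
#' Summarizes the screening burden implied by raw cohort counts: how many
#' lesions a reader scans per melanoma encountered, and the malignancy
#' prevalence as a percentage.
#'
#' @param n_lesions Total lesion count.
#' @param n_malignant Number of malignant lesions.
#' @param n_melanoma Number of melanomas.
#' @return List with `lesions_per_melanoma` and `malignancy_prevalence_pct`
#'   (both unrounded).
#' @export
triage_prevalence_summary <- function(n_lesions, n_malignant, n_melanoma) {
  if (n_lesions <= 0 || n_malignant < 0 || n_melanoma < 0) {
    stopf("counts must be nonnegative with n_lesions > 0")
  }
  list(lesions_per_melanoma = n_lesions / n_melanoma,
       malignancy_prevalence_pct = 100 * n_malignant / n_lesions)
}

#' Headline counts of the calibration evaluation cohort
#'
#' The evaluation-set totals the simulator defaults are calibrated to:
#' 370,704 lesions from 935 patients, 342 malignant (99 melanomas, 190 basal
#' cell carcinomas, 53 squamous cell carcinomas).
#'
#' @return Named list of counts.
#' @export
calibration_counts <- function() {
  list(n_lesions = 370704L, n_patients = 935L, n_malignant = 342L,
       n_melanoma = 99L, n_bcc = 190L, n_scc = 53L)
}
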