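# Synthetic multi-center 3D-TBP cohort generator.
#
# The generator emulates the statistical structure of a multi-institution
# total-body-photography lesion dataset: patients clustered by hospital,
# per-patient lesion counts spanning <100 to 400+ tiles, binary malignancy at
# ~0.1% prevalence with melanoma/BCC/SCC subclasses, lesion appearance traits
# (size, hue, contrast, border irregularity, asymmetry, internal color
# variance), and a per-center propensity for cross-polarized vs white-light
# capture. Vendor-style appearance measurements (tbp_lv_* columns) are
# derived analytically from the true traits with configurable noise, so
# metadata-only analyses need no image rendering.

#' Names of the per-lesion appearance measurements
#'
#' The measurement vector shared by the synthetic metadata writer and the
#' pixel-based measurement module. The first eleven entries returned by
#' [baseline_features()] form the multivariable logistic baseline's
#' morphology block.
#'
#' @return Character vector of measurement field names.
#' @export
measurement_fields <- function() {
  c("area_mm2", "perimeter_mm", "minor_axis_mm", "border_jaggedness",
    "shape_asymmetry", "asymmetry_angle_deg", "hue_inside_deg",
    "hue_outside_deg", "lightness_contrast", "redgreen_contrast",
    "blueyellow_contrast", "overall_color_contrast", "color_variance_inside",
    "color_asymmetry", "background_lightness_variance")
}

#' The eleven morphology features of the logistic baseline
#'
#' Lesion area, border jaggedness, the three per-channel CIELAB contrasts and
#' the overall color contrast against background skin, minimum (minor-axis)
#' lesion diameter, internal color variation, color asymmetry, background
#' lightness variance, and the asymmetry angle.
#'
#' @return Character vector of 11 measurement field names.
#' @export
baseline_features <- function() {
  c("area_mm2", "border_jaggedness", "lightness_contrast",
    "redgreen_contrast", "blueyellow_contrast", "overall_color_contrast",
    "minor_axis_mm", "color_variance_inside", "color_asymmetry",
    "background_lightness_variance", "asymmetry_angle_deg")
}

#' Anatomic site categories
#' @return The five site labels used throughout the package.
#' @export
anatomic_sites <- function() {
  c("head/neck", "anterior torso", "posterior torso",
    "upper extremity", "lower extremity")
}

default_center_weights <- function() {
  c("FNQH Cairns" = 0.189,
    "ACEMID MIA" = 0.036,
    "Monash University and Alfred Health" = 0.032,
    "University of Queensland" = 0.143,
    "Hospital Clinic de Barcelona" = 0.144,
    "Medical University of Vienna" = 0.013,
    "University Hospital of Basel" = 0.217,
    "University of Athens" = 0.012,
    "Memorial Sloan Kettering Cancer Center" = 0.214)
}

default_lighting_policy <- function(centers) {
  p <- rep(0.85, length(centers))
  names(p) <- centers
  if ("FNQH Cairns" %in% centers) p["FNQH Cairns"] <- 0.35
  p
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults are calibrated to the distributional profile of a large
#' multi-center 3D-TBP evaluation cohort: 935 patients spread over nine
#' hospitals, per-patient tile counts with strata weights 22.8% (<100),
#' 18.9% (100-199), 15.3% (200-299), 10.9% (300-399) and 32.1% (400+), and a
#' malignancy prevalence of 0.09% split into melanoma/BCC/SCC subclasses.
#'
#' @param n_patients Number of patients (>= 0).
#' @param center_weights Named probability vector over hospitals.
#' @param lesion_count_distribution Named probability vector over the five
#'   per-patient tile-count strata `<100`, `100-199`, `200-299`, `300-399`,
#'   `400+`.
#' @param malignancy_prevalence Fraction of lesions that are malignant
#'   (default 0.0009).
#' @param subclass_mix List with elements `malignant` and `benign`, each a
#'   named probability vector over diagnostic subclasses.
#' @param trait_effect_sizes Named vector of malignant-vs-benign shifts, in
#'   SD units of the underlying latent trait scales: `diameter`, `hue`
#'   (negative = malignant lesions redder), `contrast`,
#'   `border_irregularity`, `asymmetry`, `color_variance`.
#' @param lighting_policy Named per-center probability of cross-polarized
#'   capture; remaining captures use white light, which attenuates
#'   lesion/background contrast.
#' @param malignancy_rule `"trait_shift"` (malignancy drawn independently at
#'   `malignancy_prevalence`, appearance traits shifted by
#'   `trait_effect_sizes`) or `"relative_size"` (malignancy determined by a
#'   lesion's size relative to the patient's own lesions, a construction in
#'   which absolute appearance carries little signal and patient context
#'   carries most of it).
#' @param mm_per_px Tile scale; default 15/128 mm per pixel (128 px tiles).
#' @param measurement_noise_sd Relative SD of vendor-style measurement noise
#'   applied to the metadata measurement columns (default 0.05).
#' @param seed Master seed; every downstream draw derives from it.
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_patients = 935,
                          center_weights = default_center_weights(),
                          lesion_count_distribution = c(
                            "<100" = 0.228, "100-199" = 0.189,
                            "200-299" = 0.153, "300-399" = 0.109,
                            "400+" = 0.321),
                          malignancy_prevalence = 0.0009,
                          subclass_mix = list(
                            malignant = c(melanoma = 99, bcc = 190,
                                          scc = 53) / 342,
                            benign = c(nevus = 357, actinic_keratosis = 35,
                                       indeterminate = 57, other = 125,
                                       nos = 369788) / 370362),
                          trait_effect_sizes = c(
                            diameter = 1.0, hue = -0.8, contrast = 0.8,
                            border_irregularity = 0.8, asymmetry = 0.6,
                            color_variance = 0.8),
                          lighting_policy = NULL,
                          malignancy_rule = c("trait_shift", "relative_size"),
                          mm_per_px = 15 / 128,
                          measurement_noise_sd = 0.05,
                          seed = 1L) {
  malignancy_rule <- match.arg(malignancy_rule)
  check_probs <- function(p, what) {
    if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stopf("%s must be nonnegative and sum to 1", what)
    }
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 0) {
    stopf("n_patients must be a single nonnegative number")
  }
  check_probs(center_weights, "center_weights")
  check_probs(lesion_count_distribution, "lesion_count_distribution")
  strata <- c("<100", "100-199", "200-299", "300-399", "400+")
  if (!identical(names(lesion_count_distribution), strata)) {
    stopf("lesion_count_distribution must be named %s",
          paste(strata, collapse = ", "))
  }
  if (malignancy_prevalence <= 0 || malignancy_prevalence >= 1) {
    stopf("malignancy_prevalence must be in (0, 1)")
  }
  check_probs(subclass_mix$malignant, "subclass_mix$malignant")
  check_probs(subclass_mix$benign, "subclass_mix$benign")
  if (mm_per_px <= 0) stopf("mm_per_px must be positive")
  if (is.null(lighting_policy)) {
    lighting_policy <- default_lighting_policy(names(center_weights))
  }
  if (!all(names(center_weights) %in% names(lighting_policy))) {
    stopf("lighting_policy must cover every center")
  }
  if (any(lighting_policy < 0 | lighting_policy > 1)) {
    stopf("lighting_policy entries must be probabilities")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    center_weights = center_weights,
    lesion_count_distribution = lesion_count_distribution,
    malignancy_prevalence = malignancy_prevalence,
    subclass_mix = subclass_mix,
    trait_effect_sizes = trait_effect_sizes,
    lighting_policy = lighting_policy,
    malignancy_rule = malignancy_rule,
    mm_per_px = mm_per_px,
    measurement_noise_sd = measurement_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Draw one per-patient lesion count for each stratum label.
draw_lesion_counts <- function(strata) {
  n <- length(strata)
  counts <- integer(n)
  lo <- c("<100" = 3, "100-199" = 100, "200-299" = 200, "300-399" = 300)
  hi <- c("<100" = 99, "100-199" = 199, "200-299" = 299, "300-399" = 399)
  for (s in names(lo)) {
    idx <- strata == s
    if (any(idx)) {
      counts[idx] <- sample(seq(lo[[s]], hi[[s]]), sum(idx), replace = TRUE)
    }
  }
  idx <- strata == "400+"
  if (any(idx)) {
    # heavy upper tail so the cohort-wide mean (~400 lesions/patient) and
    # upper quartile (~490) resemble the calibration cohort
    counts[idx] <- pmin(400 + round(stats::rexp(sum(idx), rate = 1 / 473)),
                        3000L)
  }
  counts
}

#' Generate a synthetic multi-center lesion cohort
#'
#' Produces per-lesion records (metadata plus vendor-style measurement
#' columns) and the underlying true appearance traits. Deterministic given
#' `config$seed`; each lesion also carries a `render_seed` derived by hashing
#' the master seed with the lesion index, so tiles can be rendered for any
#' subset of lesions, in any order, with identical results.
#'
#' @param config A [cohort_config()].
#' @return A list of class `tbp_cohort` with data frames `records` (one row
#'   per lesion: identifiers, demographics, site, lighting, `target`,
#'   `diagnosis`, and `tbp_lv_*` measurement columns) and `traits` (true
#'   generative traits incl. lesion/background sRGB colors).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stopf("config must be created by cohort_config()")
  }
  empty <- function() {
    structure(list(records = data.frame(), traits = data.frame(),
                   config = config), class = "tbp_cohort")
  }
  if (config$n_patients == 0) return(empty())

  with_seed(config$seed, {
    np <- config$n_patients
    patients <- data.frame(
      patient_id = sprintf("SP_%06d", seq_len(np)),
      attribution = sample(names(config$center_weights), np, replace = TRUE,
                           prob = config$center_weights),
      age_approx = sample(seq(20, 90, by = 5), np, replace = TRUE),
      sex = sample(c("male", "female"), np, replace = TRUE),
      stringsAsFactors = FALSE
    )
    strata <- sample(names(config$lesion_count_distribution), np,
                     replace = TRUE, prob = config$lesion_count_distribution)
    patients$n_lesions <- draw_lesion_counts(strata)
    patients$bg_L <- stats::rnorm(np, 68, 3)
    patients$bg_a <- stats::rnorm(np, 11.5, 1.5)
    patients$bg_b <- stats::rnorm(np, 16, 2)
    # per-patient typical lesion size (log-scale); wide between-patient
    # spread is what gives patient context its value
    patients$meanlog_d <- stats::rnorm(np, log(2.8), 0.6)

    n <- sum(patients$n_lesions)
    pi_idx <- rep(seq_len(np), patients$n_lesions)
    rec <- data.frame(
      isic_id = sprintf("SYN_%07d", seq_len(n)),
      patient_id = patients$patient_id[pi_idx],
      attribution = patients$attribution[pi_idx],
      age_approx = patients$age_approx[pi_idx],
      sex = patients$sex[pi_idx],
      anatom_site_general = sample(anatomic_sites(), n, replace = TRUE,
                                   prob = c(0.08, 0.22, 0.30, 0.18, 0.22)),
      stringsAsFactors = FALSE
    )
    xp_prob <- config$lighting_policy[rec$attribution]
    rec$tbp_tile_type <- ifelse(stats::runif(n) < xp_prob,
                                "cross-polarized", "white")

    eff <- config$trait_effect_sizes
    within_z <- stats::rnorm(n)           # within-patient size deviation
    if (config$malignancy_rule == "relative_size") {
      latent <- within_z + stats::rnorm(n, 0, 0.5)
      thr <- stats::qnorm(1 - config$malignancy_prevalence,
                          sd = sqrt(1 + 0.25))
      rec$target <- as.integer(latent > thr)
      logd <- patients$meanlog_d[pi_idx] + 0.45 * within_z
      shift <- rep(0, n)                  # no appearance shift by class
    } else {
      rec$target <- stats::rbinom(n, 1, config$malignancy_prevalence)
      logd <- log(2.8) + 0.45 * (within_z + rec$target * eff[["diameter"]])
      shift <- rec$target
    }
    rec$diagnosis <- ifelse(
      rec$target == 1,
      sample(names(config$subclass_mix$malignant), n, replace = TRUE,
             prob = config$subclass_mix$malignant),
      sample(names(config$subclass_mix$benign), n, replace = TRUE,
             prob = config$subclass_mix$benign))

    d <- pmin(exp(logd), 13)
    hue <- pmin(pmax(stats::rnorm(n, 55, 12) + shift * eff[["hue"]] * 12,
                     5), 110)
    level <- function(effname) {
      stats::plogis(stats::rnorm(n, -0.5, 0.9) + shift * eff[[effname]] * 0.9)
    }
    irr <- level("border_irregularity")
    asym <- level("asymmetry")
    colorvar <- level("color_variance")
    contrast0 <- level("contrast")
    # white light attenuates lesion/background contrast
    contrast <- contrast0 * ifelse(rec$tbp_tile_type == "cross-polarized",
                                   1, 0.6)

    bg_L <- patients$bg_L[pi_idx] + stats::rnorm(n, 0, 0.5)
    bg_a <- patients$bg_a[pi_idx] + stats::rnorm(n, 0, 0.3)
    bg_b <- patients$bg_b[pi_idx] + stats::rnorm(n, 0, 0.3)
    les_L <- bg_L - (6 + 34 * contrast)
    chroma <- pmax(stats::rnorm(n, 24, 3), 8)
    les_a <- chroma * cos(hue * pi / 180)
    les_b <- chroma * sin(hue * pi / 180)
    les_rgb <- lab_to_srgb(cbind(les_L, les_a, les_b))
    bg_rgb <- lab_to_srgb(cbind(bg_L, bg_a, bg_b))

    traits <- data.frame(
      isic_id = rec$isic_id,
      patient_id = rec$patient_id,
      true_diameter_mm = d,
      true_hue_deg = hue,
      lesion_r = les_rgb[, 1], lesion_g = les_rgb[, 2],
      lesion_b = les_rgb[, 3],
      bg_r = bg_rgb[, 1], bg_g = bg_rgb[, 2], bg_b = bg_rgb[, 3],
      border_irregularity_level = irr,
      asymmetry_level = asym,
      internal_color_variance_level = colorvar,
      contrast_level = contrast,
      render_seed = vapply(seq_len(n), function(i) sub_seed(config$seed, i),
                           numeric(1)),
      stringsAsFactors = FALSE
    )

    # vendor-style measurement columns, analytic in the traits + noise
    nz <- function(x, rel = config$measurement_noise_sd) {
      x * (1 + stats::rnorm(n, 0, rel))
    }
    s_ax <- 0.35 * asym
    area <- pi * (d / 2)^2 * (1 - s_ax^2) * (1 + 0.2 * irr^2)
    jag <- 1 + 0.9 * irr^1.5
    lab_les <- cbind(les_L, les_a, les_b)
    lab_bg <- cbind(bg_L, bg_a, bg_b)
    dlab <- lab_les - lab_bg
    m <- data.frame(
      area_mm2 = nz(area),
      perimeter_mm = nz(jag * 2 * sqrt(pi * area)),
      minor_axis_mm = nz(d * (1 - s_ax)),
      border_jaggedness = pmax(nz(jag), 1),
      shape_asymmetry = pmin(pmax(
        0.05 + 0.25 * irr + 0.10 * s_ax + stats::rnorm(n, 0, 0.02), 0), 1),
      asymmetry_angle_deg = stats::runif(n, 0, 180),
      hue_inside_deg = hue + stats::rnorm(n, 0, 2),
      hue_outside_deg = atan2(bg_b, bg_a) * 180 / pi + stats::rnorm(n, 0, 2),
      lightness_contrast = nz(dlab[, 1]),
      redgreen_contrast = nz(dlab[, 2]),
      blueyellow_contrast = nz(dlab[, 3]),
      overall_color_contrast = nz(sqrt(rowSums(dlab^2))),
      color_variance_inside = nz(2 + 180 * colorvar^2),
      color_asymmetry = pmax(nz(1.5 * colorvar + 0.5 * irr), 0),
      background_lightness_variance = exp(stats::rnorm(n, log(0.5), 0.3))
    )
    names(m) <- paste0("tbp_lv_", names(m))
    rec <- cbind(rec, m)

    structure(list(records = rec, traits = traits, config = config),
              class = "tbp_cohort")
  })
}

#' @export
print.tbp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TBP cohort: %d lesions from %d patients (%d malignant)\n",
              nrow(x$records),
              length(unique(x$records$patient_id)),
              sum(x$records$target)))
  invisible(x)
}
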