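# Rendering of synthetic 15 x 15 mm lesion tiles.

#' Construct a tile image object
#'
#' @param pixels Numeric array `side x side x 3`, sRGB values in \[0, 1\].
#' @param mm_per_px Physical scale in mm per pixel (> 0).
#' @return Object of class `tile_image`.
#' @export
tile_image <- function(pixels, mm_per_px) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stopf("pixels must be a h x w x 3 array")
  }
  if (dim(pixels)[1] != dim(pixels)[2]) stopf("tiles must be square")
  if (dim(pixels)[1] < 16) stopf("tile side must be >= 16 px")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 || mm_per_px <= 0) {
    stopf("mm_per_px must be a single positive number")
  }
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stopf("pixel values must lie in [0, 1]")
  }
  structure(list(pixels = pixels, mm_per_px = mm_per_px),
            class = "tile_image")
}

#' Render a lesion tile from generative traits
#'
#' Draws a 15 x 15 mm skin patch with a single centered lesion. The lesion
#' boundary is the polar curve `r(theta) = R * (1 + irregularity * sum of
#' small random harmonics)`, anisotropically scaled along a random
#' orientation to the degree set by `asymmetry_level`, so the rendered shape
#' responds monotonically and independently to the border-irregularity and
#' asymmetry traits. Interior texture noise is proportional to
#' `internal_color_variance_level`. Fully deterministic given `seed`.
#'
#' @param traits One-row data frame or list with fields `true_diameter_mm`,
#'   `lesion_r/g/b`, `bg_r/g/b`, `border_irregularity_level`,
#'   `asymmetry_level`, `internal_color_variance_level` (as produced in the
#'   `traits` table of [generate_cohort()]).
#' @param mm_per_px Scale; default 15/128 (a 128 px tile).
#' @param seed Seed for the boundary harmonics and texture; defaults to the
#'   lesion's `render_seed` when present.
#' @param noise If `FALSE`, render noise-free: no background grain and no
#'   interior texture (used for measurement-recovery experiments).
#' @return A [tile_image()] with attribute `true_mask` (logical matrix of
#'   the exact rendered lesion support, for oracle checks).
#' @export
render_tile <- function(traits, mm_per_px = 15 / 128, seed = NULL,
                        noise = TRUE) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 || mm_per_px <= 0) {
    stopf("mm_per_px must be a single positive number")
  }
  tr <- as.list(traits)
  need <- c("true_diameter_mm", "lesion_r", "lesion_g", "lesion_b",
            "bg_r", "bg_g", "bg_b", "border_irregularity_level",
            "asymmetry_level", "internal_color_variance_level")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stopf("traits missing fields: %s",
                          paste(miss, collapse = ", "))
  if (tr$true_diameter_mm < 0) stopf("true_diameter_mm must be >= 0")
  if (is.null(seed)) seed <- if (!is.null(tr$render_seed)) tr$render_seed else 1

  side <- round(15 / mm_per_px)
  with_seed(seed, {
    ctr <- (side + 1) / 2
    xs <- (seq_len(side) - ctr) * mm_per_px
    X <- matrix(xs, side, side, byrow = TRUE)   # column offset, mm
    Y <- matrix(xs, side, side)                 # row offset, mm

    R <- tr$true_diameter_mm / 2
    irr <- tr$border_irregularity_level
    s_ax <- 0.35 * tr$asymmetry_level
    phi0 <- stats::runif(1, 0, pi)
    ks <- 2:6
    # amplitude magnitude is deterministic in the irregularity trait (only
    # signs, phases and a mild jitter are random) so that measured boundary
    # roughness responds monotonically to the trait
    amps <- irr * (0.40 / ks) * sample(c(-1, 1), length(ks), replace = TRUE) *
      stats::runif(length(ks), 0.85, 1.15)
    phases <- stats::runif(length(ks), 0, 2 * pi)

    if (R > 0) {
      # inverse of rotation + anisotropic scaling
      u <- (cos(phi0) * X + sin(phi0) * Y) / (1 + s_ax)
      v <- (-sin(phi0) * X + cos(phi0) * Y) / (1 - s_ax)
      r <- sqrt(u^2 + v^2)
      th <- atan2(v, u)
      rb <- matrix(R, side, side)
      for (i in seq_along(ks)) {
        rb <- rb + R * amps[i] * cos(ks[i] * th + phases[i])
      }
      rb <- pmax(rb, 0.15 * R)
      mask <- r <= rb
    } else {
      mask <- matrix(FALSE, side, side)
    }

    px <- array(0, c(side, side, 3))
    bg <- c(tr$bg_r, tr$bg_g, tr$bg_b)
    les <- c(tr$lesion_r, tr$lesion_g, tr$lesion_b)
    n_in <- sum(mask)
    tex_sd <- 0.10 * tr$internal_color_variance_level
    for (ch in 1:3) {
      plane <- matrix(bg[ch], side, side)
      if (noise) plane <- plane + stats::rnorm(side * side, 0, 0.008)
      if (n_in > 0) {
        val <- les[ch]
        if (noise && tex_sd > 0) {
          plane[mask] <- val + stats::rnorm(n_in, 0, tex_sd)
        } else {
          plane[mask] <- val
        }
      }
      px[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    out <- tile_image(px, mm_per_px)
    attr(out, "true_mask") <- mask
    # generating boundary parameters, exposed so analytic oracles can
    # recompute the blob's exact polygon area independently of any pixels
    attr(out, "boundary") <- list(R = R, s_ax = s_ax, phi0 = phi0,
                                  ks = ks, amps = amps, phases = phases)
    out
  })
}
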