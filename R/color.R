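# CIELAB conversions (D65 white point, sRGB gamma), via grDevices.

#' Convert sRGB to CIELAB
#'
#' @param rgb Matrix (n x 3) or length-3 vector of sRGB values in \[0, 1\]
#'   (gamma-encoded, D65).
#' @return Matrix (n x 3) of L*, a*, b*.
#' @export
srgb_to_lab <- function(rgb) {
  m <- if (is.null(dim(rgb))) matrix(rgb, ncol = 3) else as.matrix(rgb)
  out <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  colnames(out) <- c("L", "a", "b")
  out
}

#' Convert CIELAB to sRGB
#'
#' @param lab Matrix (n x 3) or length-3 vector of L*, a*, b* (D65).
#' @return Matrix (n x 3) of sRGB values clipped to \[0, 1\].
#' @export
lab_to_srgb <- function(lab) {
  m <- if (is.null(dim(lab))) matrix(lab, ncol = 3) else as.matrix(lab)
  out <- grDevices::convertColor(m, from = "Lab", to = "sRGB", clip = TRUE)
  colnames(out) <- c("r", "g", "b")
  out
}

# Hue angle (degrees in [0, 360)) of a mean chroma vector; NA when the color
# is achromatic (chroma below `min_chroma`), never coerced to 0.
lab_hue <- function(a, b, min_chroma = 1e-3) {
  if (sqrt(a^2 + b^2) < min_chroma) return(NA_real_)
  h <- atan2(b, a) * 180 / pi
  if (h < 0) h <- h + 360
  h
}
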