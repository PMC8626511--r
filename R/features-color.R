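# Colorimetric feature maps: RGB pass-through plus HSV, CIE XYZ and CIE
# L*a*b* transforms. Conventions: sRGB primaries with D65 white point; XYZ
# through the standard sRGB linearization (grDevices::convertColor); L*a*b*
# from that XYZ; HSV per the hexcone model with H scaled to [0, 1).

#' Compute the 12 colorimetric feature maps of an RGB image
#'
#' Returns the R, G, B channels rescaled to \[0, 1\], the HSV transform
#' (H in \[0, 1)), CIE XYZ (Y of white = 1) and CIE L*a*b* (L* in \[0, 100\])
#' of an 8-bit RGB image, as named per-pixel maps.
#'
#' @param image `H x W x 3` array of 8-bit RGB values in \[0, 255\] (values in
#'   \[0, 1\] are also accepted and used as-is).
#' @return Named list of 12 `H x W` numeric matrices:
#'   `R, G, B, H, S, V, X, Y, Z, L*, a*, b*`.
#' @examples
#' img <- array(255L, dim = c(2, 2, 3))
#' maps <- rgb_to_color_features(img)
#' maps[["L*"]][1, 1]  # 100: white point
#' @export
rgb_to_color_features <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("`image` must be an H x W x 3 RGB array")
  h <- dim(image)[1L]; w <- dim(image)[2L]
  mx <- suppressWarnings(max(image))
  rgb01 <- if (is.finite(mx) && mx > 1) image / 255 else image + 0
  flat <- matrix(rgb01, ncol = 3L)  # (H*W) x 3, column-major

  hsv <- t(grDevices::rgb2hsv(t(flat), maxColorValue = 1))
  xyz <- grDevices::convertColor(flat, from = "sRGB", to = "XYZ")
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")

  as_map <- function(v) matrix(v, nrow = h, ncol = w)
  out <- list(
    R = as_map(flat[, 1L]), G = as_map(flat[, 2L]), B = as_map(flat[, 3L]),
    H = as_map(hsv[, 1L]),  S = as_map(hsv[, 2L]),  V = as_map(hsv[, 3L]),
    X = as_map(xyz[, 1L]),  Y = as_map(xyz[, 2L]),  Z = as_map(xyz[, 3L])
  )
  out[["L*"]] <- as_map(lab[, 1L])
  out[["a*"]] <- as_map(lab[, 2L])
  out[["b*"]] <- as_map(lab[, 3L])
  out
}

#' Grayscale used by all textural features: CIE Y luminance in \[0, 1\]
#' @noRd
luminance_gray <- function(image) {
  rgb_to_color_features(image)[["Y"]]
}
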