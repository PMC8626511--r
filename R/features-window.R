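# Windowed features computed on the luminance map: local mean/variance over
# a circular neighborhood, the Gabor filter bank and the riu2 LBP bank.
# All border handling is boundary reflection (see pad_reflect).

#' Direct spatial filtering with a small kernel
#'
#' Shift-and-accumulate correlation with reflect padding. Direct summation
#' (rather than FFT products) keeps the response of a pixel a function of its
#' neighborhood only, so tiled computation is bit-identical to whole-image
#' computation.
#' @noRd
conv_spatial <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  p <- pad_reflect(m, max(kr, kc))
  pr <- max(kr, kc) - kr
  pc <- max(kr, kc) - kc
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (j in seq_len(ncol(kernel))) {
    for (i in seq_len(nrow(kernel))) {
      wij <- kernel[i, j]
      if (wij == 0) next
      out <- out + wij * p[pr + i:(i + h - 1L), pc + j:(j + w - 1L)]
    }
  }
  out
}

#' Binary disk kernel of a given radius (offsets with dx^2 + dy^2 <= r^2)
#' @noRd
disk_kernel <- function(radius) {
  d <- seq.int(-radius, radius)
  g <- outer(d^2, d^2, `+`) <= radius^2
  matrix(as.numeric(g), nrow = length(d))
}

#' Local mean and variance over a circular neighborhood
#'
#' Per-pixel mean and variance of the grayscale values inside a disk of the
#' given radius centered on the pixel, with reflect-padded borders. Variance
#' is `E[x^2] - E[x]^2` over the neighborhood (clamped at 0 against rounding).
#'
#' @param gray `H x W` numeric matrix.
#' @param radius_px integer disk radius in pixels (>= 1).
#' @return Named list of two `H x W` matrices, `Mean` and `Var`.
#' @export
local_mean_variance <- function(gray, radius_px) {
  stopifnot(is.matrix(gray), radius_px >= 1)
  if (radius_px > max(dim(gray)))
    stop("`radius_px` is larger than the image extent")
  k <- disk_kernel(radius_px)
  k <- k / sum(k)
  m1 <- conv_spatial(gray, k)
  m2 <- conv_spatial(gray * gray, k)
  list(Mean = m1, Var = pmax(m2 - m1 * m1, 0))
}

#' Analytic Gabor kernel
#'
#' Gaussian envelope times a complex sinusoid:
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * exp(i (2 pi x'/lambda + psi))`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`,
#' x along columns and y along rows (increasing downward). Support is
#' truncated at `+/- ceiling(3 sigma)` pixels.
#'
#' @param wavelength_px sinusoid wavelength lambda in pixels.
#' @param orientation_deg orientation theta in degrees.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @param aspect_ratio spatial aspect ratio gamma.
#' @param phase_deg phase offset psi in degrees.
#' @return List with `real` and `imaginary` kernel matrices.
#' @export
gabor_kernel <- function(wavelength_px, orientation_deg, sigma_px = 2,
                         aspect_ratio = 1.5, phase_deg = 0) {
  half <- ceiling(3 * sigma_px)
  d <- seq.int(-half, half)
  x <- matrix(d, nrow = length(d), ncol = length(d), byrow = TRUE)  # columns
  y <- matrix(d, nrow = length(d), ncol = length(d))                # rows
  th <- orientation_deg * pi / 180
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  env <- exp(-(xp^2 + aspect_ratio^2 * yp^2) / (2 * sigma_px^2))
  arg <- 2 * pi * xp / wavelength_px + phase_deg * pi / 180
  list(real = env * cos(arg), imaginary = env * sin(arg))
}

#' Gabor filter bank responses
#'
#' Real and imaginary filter responses for every configured wavelength and
#' orientation, named `G_<lambda>_<R|I>_<theta>` (e.g. `G_20_R_135`), ordered
#' by wavelength, then part (real before imaginary), then orientation.
#'
#' @param gray `H x W` numeric matrix.
#' @param config a [feature_bank_config()].
#' @return Named list of `H x W` matrices (one per wavelength/part/orientation).
#' @export
gabor_bank <- function(gray, config) {
  stopifnot(is.matrix(gray))
  out <- list()
  for (lam in config$gabor_wavelengths_px) {
    kr <- lapply(config$gabor_orientations_deg, function(th)
      gabor_kernel(lam, th, config$gabor_sigma_px, config$gabor_aspect_ratio,
                   config$gabor_phase_deg))
    for (part in c("R", "I")) {
      comp <- if (part == "R") "real" else "imaginary"
      for (i in seq_along(config$gabor_orientations_deg)) {
        nm <- sprintf("G_%s_%s_%s", format(lam), part,
                      format(config$gabor_orientations_deg[i]))
        out[[nm]] <- conv_spatial(gray, kr[[i]][[comp]])
      }
    }
  }
  out
}

#' Rotation-invariant uniform LBP maps
#'
#' One riu2-coded map per configured radius: P sampling points on a circle,
#' bilinear interpolation, sign convention `s(x) = 1` for `x >= 0`. Uniform
#' patterns (at most two 0/1 circular transitions) are coded by their number
#' of one-bits (0..P); non-uniform patterns get code P+1.
#'
#' @param gray `H x W` numeric matrix.
#' @param config a [feature_bank_config()].
#' @return Named list of `H x W` integer-valued matrices `LBP_<radius>`.
#' @export
lbp_bank <- function(gray, config) {
  stopifnot(is.matrix(gray), config$lbp_points >= 4)
  out <- list()
  for (r in config$lbp_radii_px)
    out[[sprintf("LBP_%s", format(r))]] <-
      lbp_riu2(gray, r, config$lbp_points)
  out
}

#' riu2 LBP at one radius
#' @noRd
lbp_riu2 <- function(gray, radius, points) {
  h <- nrow(gray); w <- ncol(gray)
  pad <- as.integer(ceiling(radius)) + 1L
  p <- pad_reflect(gray, pad)
  crop <- function(dy, dx)
    p[(pad + 1L + dy):(pad + h + dy), (pad + 1L + dx):(pad + w + dx)]
  bits <- vector("list", points)
  for (k in seq_len(points)) {
    a <- 2 * pi * (k - 1) / points
    dx <- radius * cos(a); dy <- radius * sin(a)
    # snap near-integer offsets so axis-aligned samples are exact
    if (abs(dx - round(dx)) < 1e-9) dx <- round(dx)
    if (abs(dy - round(dy)) < 1e-9) dy <- round(dy)
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0; fy <- dy - y0
    g <- (1 - fy) * (1 - fx) * crop(y0, x0) +
         (1 - fy) * fx       * crop(y0, x0 + 1) +
         fy       * (1 - fx) * crop(y0 + 1, x0) +
         fy       * fx       * crop(y0 + 1, x0 + 1)
    # tolerance keeps flat regions stable against interpolation round-off
    bits[[k]] <- (g - gray) >= -1e-10
  }
  ones <- Reduce(`+`, bits)
  trans <- matrix(0, h, w)
  for (k in seq_len(points)) {
    nxt <- if (k == points) 1L else k + 1L
    trans <- trans + abs(bits[[k]] - bits[[nxt]])
  }
  ifelse(trans <= 2, ones, points + 1)
}
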