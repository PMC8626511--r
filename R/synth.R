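# Seeded generator of synthetic DAB-stained histology images with exact
# four-class ground truth (0 background, 1 tissue, 2 neuron, 3 artifact).
# Staining is emulated with correlated dark-brown RGB (R ~ G > B) on a light
# textured tissue over a near-white background; artifacts are larger irregular
# dark blotches. The generator is the package's test-data source: its images
# carry the class geometry and color/texture contrasts of stained tissue, not
# the optics of a real scanner.

#' Synthetic sample configuration
#'
#' @param height,width image extent in pixels.
#' @param tissue_fraction expected fraction of the image covered by tissue.
#' @param neuron_density expected fraction of image pixels that are neuron.
#' @param neuron_radius_px length-2 range of neuron blob radii (pixels).
#' @param neuron_color mean RGB (0-255) of neurons (dark brown; the contrast
#'   against tissue is strongest in the blue channel, as brown chromogens
#'   absorb blue).
#' @param neuron_color_spread residual per-blob RGB jitter standard deviation.
#' @param neuron_texture_amplitude per-pixel intensity texture inside blobs
#'   (standard deviation, intensity units).
#' @param neuron_texture_wavelength_px `NULL` for unstructured speckle
#'   texture; a wavelength in pixels paints each blob with a sinusoidal
#'   grating of that period at a random per-blob orientation instead. A
#'   grating changes the spatial arrangement of intensities while keeping
#'   their per-pixel distribution close to the speckle case, which makes the
#'   neuron class visible to oriented texture features but not to pixelwise
#'   color.
#' @param stain_intensity_range per-blob multiplicative stain-intensity
#'   factor range (correlated across channels), emulating staining
#'   variability between objects and sections.
#' @param tissue_color base RGB of unstained tissue (light brown/gray).
#' @param tissue_texture_amplitude amplitude of the band-limited tissue
#'   texture (intensity units).
#' @param tissue_texture_wavelength_px `NULL` for the default smooth
#'   low-frequency tissue texture; a wavelength paints the tissue with a
#'   sinusoidal grating instead (random orientation and phase per image).
#'   Pairing tissue and neuron gratings of equal amplitude but different
#'   wavelengths yields classes with matched per-pixel intensity
#'   distributions that differ only in spatial arrangement.
#' @param background_color RGB of the slide background (near white).
#' @param artifact_count number of artifact blotches.
#' @param artifact_radius_px length-2 range of artifact radii (pixels).
#' @param artifact_color RGB of artifacts (very dark, non-specific staining).
#' @param artifact_texture_amplitude per-pixel texture inside artifacts;
#'   dense stain accumulations are more homogeneous than neuron nuclei.
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(height = 128L, width = 128L,
                         tissue_fraction = 0.75,
                         neuron_density = 0.08,
                         neuron_radius_px = c(2.5, 4.5),
                         neuron_color = c(120, 85, 50),
                         neuron_color_spread = 4,
                         neuron_texture_amplitude = 10,
                         neuron_texture_wavelength_px = NULL,
                         stain_intensity_range = c(0.8, 1.25),
                         tissue_color = c(205, 190, 175),
                         tissue_texture_amplitude = 6,
                         tissue_texture_wavelength_px = NULL,
                         background_color = c(245, 243, 240),
                         artifact_count = 2L,
                         artifact_radius_px = c(8, 14),
                         artifact_color = c(85, 58, 35),
                         artifact_texture_amplitude = 3,
                         noise_sigma = 3) {
  stopifnot(height >= 16L, width >= 16L,
            tissue_fraction >= 0, tissue_fraction <= 1,
            neuron_density >= 0, neuron_density <= 1,
            all(neuron_radius_px >= 1), all(artifact_radius_px >= 1))
  structure(as.list(environment()), class = "synth_config")
}

#' Generate one synthetic sample
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the same (config, seed) pair yields a
#'   byte-identical sample.
#' @return Object of class `synth_sample`: list with `image`
#'   (`H x W x 3` integer array, 0-255), `mask` (`H x W` integer matrix,
#'   values 0-3) and `metadata` (neuron/artifact object counts and per-class
#'   pixel counts).
#' @export
generate_sample <- function(config, seed = 1L) {
  cfg <- config
  h <- cfg$height; w <- cfg$width
  if (cfg$neuron_density > 0.6 * max(cfg$tissue_fraction, 1e-9))
    stop("neuron density infeasible for the configured tissue geometry")
  with_seed(seed, {
    # tissue region: thresholded low-frequency random field
    if (cfg$tissue_fraction >= 1) {
      tissue <- matrix(TRUE, h, w)
    } else if (cfg$tissue_fraction <= 0) {
      tissue <- matrix(FALSE, h, w)
    } else {
      field <- bilinear_upsample(matrix(stats::rnorm(36), 6L, 6L), h, w)
      tissue <- field > stats::quantile(field, 1 - cfg$tissue_fraction)
    }
    img <- array(0, dim = c(h, w, 3L))
    bg_var <- bilinear_upsample(matrix(stats::rnorm(16), 4L, 4L), h, w) * 2
    tex <- if (is.null(cfg$tissue_texture_wavelength_px)) {
      bilinear_upsample(matrix(stats::rnorm(1024), 32L, 32L), h, w) *
        cfg$tissue_texture_amplitude
    } else {
      tang <- stats::runif(1L, 0, pi)
      tphase <- stats::runif(1L, 0, 2 * pi)
      xg <- matrix(seq_len(w), h, w, byrow = TRUE)
      yg <- matrix(seq_len(h), h, w)
      sqrt(2) * cfg$tissue_texture_amplitude *
        sin(2 * pi * (xg * cos(tang) + yg * sin(tang)) /
              cfg$tissue_texture_wavelength_px + tphase)
    }
    for (c_i in 1:3) {
      plane <- matrix(cfg$background_color[c_i], h, w) + bg_var
      plane[tissue] <- cfg$tissue_color[c_i] + tex[tissue]
      img[, , c_i] <- plane
    }
    mask <- matrix(0L, h, w)
    mask[tissue] <- 1L

    paint_blob <- function(cy, cx, r, color, texture_amp, label,
                           restrict = tissue, grating_wavelength = NULL) {
      ecc <- stats::runif(1L, 0.75, 1)        # mild ellipticity
      ang <- stats::runif(1L, 0, pi)
      y_lo <- max(1, floor(cy - r - 1)); y_hi <- min(h, ceiling(cy + r + 1))
      x_lo <- max(1, floor(cx - r - 1)); x_hi <- min(w, ceiling(cx + r + 1))
      if (y_lo > y_hi || x_lo > x_hi) return(0L)  # blob entirely off-image
      ys <- y_lo:y_hi
      xs <- x_lo:x_hi
      dy <- matrix(ys - cy, length(ys), length(xs))
      dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
      u <- dx * cos(ang) + dy * sin(ang)
      v <- -dx * sin(ang) + dy * cos(ang)
      inside <- (u / r)^2 + (v / (r * ecc))^2 <= 1
      sel <- inside & restrict[ys, xs, drop = FALSE]
      if (!any(sel)) return(0L)
      base <- color * stats::runif(1L, cfg$stain_intensity_range[1L],
                                   cfg$stain_intensity_range[2L]) +
        stats::rnorm(3L, 0, cfg$neuron_color_spread)
      ptex <- if (is.null(grating_wavelength)) {
        stats::rnorm(sum(sel), 0, texture_amp)
      } else {
        gang <- stats::runif(1L, 0, pi)
        gphase <- stats::runif(1L, 0, 2 * pi)
        wave <- sqrt(2) * texture_amp *
          sin(2 * pi * (dx * cos(gang) + dy * sin(gang)) /
                grating_wavelength + gphase)
        wave[sel]
      }
      for (c_i in 1:3) {
        plane <- img[ys, xs, c_i]
        plane[sel] <- base[c_i] + ptex
        img[ys, xs, c_i] <<- plane
      }
      mk <- mask[ys, xs, drop = FALSE]
      mk[sel] <- label
      mask[ys, xs] <<- mk
      sum(sel)
    }

    n_artifacts <- 0L
    if (cfg$artifact_count > 0L && any(tissue)) {
      at <- which(tissue)
      for (k in seq_len(cfg$artifact_count)) {
        ctr <- at[sample.int(length(at), 1L)]
        cy <- (ctr - 1L) %% h + 1L; cx <- (ctr - 1L) %/% h + 1L
        r0 <- stats::runif(1L, cfg$artifact_radius_px[1L],
                           cfg$artifact_radius_px[2L])
        # irregular blotch: a few overlapping lobes
        for (lobe in 1:3)
          paint_blob(cy + stats::rnorm(1L, 0, r0 / 2),
                     cx + stats::rnorm(1L, 0, r0 / 2),
                     r0 * stats::runif(1L, 0.5, 1), cfg$artifact_color,
                     cfg$artifact_texture_amplitude, 3L)
        n_artifacts <- n_artifacts + 1L
      }
    }

    n_neurons <- 0L
    target <- round(cfg$neuron_density * h * w)
    if (target > 0L && any(tissue)) {
      at <- which(tissue)
      mean_area <- pi * mean(cfg$neuron_radius_px)^2
      max_tries <- 50L * max(1L, ceiling(target / mean_area))
      tries <- 0L
      while (sum(mask == 2L) < target && tries < max_tries) {
        tries <- tries + 1L
        ctr <- at[sample.int(length(at), 1L)]
        cy <- (ctr - 1L) %% h + 1L; cx <- (ctr - 1L) %/% h + 1L
        r <- stats::runif(1L, cfg$neuron_radius_px[1L],
                          cfg$neuron_radius_px[2L])
        if (paint_blob(cy, cx, r, cfg$neuron_color,
                       cfg$neuron_texture_amplitude, 2L,
                       grating_wavelength =
                         cfg$neuron_texture_wavelength_px) > 0L)
          n_neurons <- n_neurons + 1L
      }
      if (sum(mask == 2L) < 0.5 * target)
        stop("neuron density infeasible: could not place enough blobs")
    }

    noise <- array(stats::rnorm(h * w * 3L, 0, cfg$noise_sigma),
                   dim = c(h, w, 3L))
    img <- round(pmin(pmax(img + noise, 0), 255))
    storage.mode(img) <- "integer"
    counts <- vapply(0:3, function(k) sum(mask == k), integer(1L))
    names(counts) <- names(.class_levels)
    structure(list(image = img, mask = mask,
                   metadata = list(n_neurons = n_neurons,
                                   n_artifacts = n_artifacts,
                                   class_pixels = counts, seed = seed)),
              class = "synth_sample")
  })
}

#' Generate learning and test sample lists
#'
#' Every sample gets its own seed drawn without replacement from a stream
#' seeded by `seed`, so the two sets are disjoint and reproducible.
#'
#' @param config a [synth_config()].
#' @param n_learn,n_test number of samples per split.
#' @param seed integer master seed.
#' @return List with `learn` and `test` (lists of `synth_sample`).
#' @export
generate_dataset <- function(config, n_learn, n_test, seed = 1L) {
  stopifnot(n_learn >= 1L, n_test >= 1L)
  seeds <- with_seed(seed,
                     sample.int(2147483646L, n_learn + n_test))
  learn <- lapply(seeds[seq_len(n_learn)],
                  function(s) generate_sample(config, s))
  test <- lapply(seeds[n_learn + seq_len(n_test)],
                 function(s) generate_sample(config, s))
  list(learn = learn, test = test)
}

#' Write a synthetic sample as image PNG + mask PNG (+ manifest JSON)
#'
#' The mask PNG stores the raw labels 0-3 in an 8-bit gray channel.
#'
#' @param sample a `synth_sample`.
#' @param prefix path prefix; writes `<prefix>_image.png`,
#'   `<prefix>_mask.png` and `<prefix>_manifest.json`.
#' @export
write_sample <- function(sample, prefix) {
  png::writePNG(sample$image / 255, paste0(prefix, "_image.png"))
  png::writePNG(sample$mask / 255, paste0(prefix, "_mask.png"))
  jsonlite::write_json(sample$metadata, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a sample written by [write_sample()]
#' @param prefix path prefix used at write time.
#' @return A `synth_sample` (metadata from the manifest).
#' @export
read_sample <- function(prefix) {
  img <- png::readPNG(paste0(prefix, "_image.png"))
  img <- round(img * 255)
  storage.mode(img) <- "integer"
  mask <- round(png::readPNG(paste0(prefix, "_mask.png")) * 255)
  storage.mode(mask) <- "integer"
  meta <- jsonlite::read_json(paste0(prefix, "_manifest.json"),
                              simplifyVector = TRUE)
  structure(list(image = img, mask = mask, metadata = meta),
            class = "synth_sample")
}

#' Bilinear upsampling of a coarse matrix to h x w
#' @noRd
bilinear_upsample <- function(m, h, w) {
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L)
  ry <- seq(1, nrow(m), length.out = h)
  rx <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(ry), nrow(m) - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(m) - 1L); fx <- rx - x0
  fy_m <- matrix(fy, h, w); fx_m <- matrix(fx, h, w, byrow = TRUE)
  (1 - fy_m) * (1 - fx_m) * m[y0, x0] +
    (1 - fy_m) * fx_m * m[y0, x0 + 1L] +
    fy_m * (1 - fx_m) * m[y0 + 1L, x0] +
    fy_m * fx_m * m[y0 + 1L, x0 + 1L]
}
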