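# Feature-bank configuration, the ordered feature catalog and its naming
# scheme, and assembly of the full per-pixel feature stack.

.all_spaces <- c("RGB", "HSV", "XYZ", "LAB", "MEAN", "VAR",
                 "GABOR", "HARALICK", "LBP")
.color_members <- list(
  RGB = c("R", "G", "B"), HSV = c("H", "S", "V"),
  XYZ = c("X", "Y", "Z"), LAB = c("L*", "a*", "b*"))

#' Feature-bank configuration
#'
#' Parameters of the initial hand-crafted feature vector. The two staining
#' presets share the Gabor parameterization (aspect ratio 1.5, sigma 2 px,
#' phase 0, wavelengths 2.5/5/10/20 px, orientations 0/45/90/135) and differ
#' in the window radii: `"NeuN"` uses mean/variance radius 10 px and
#' LBP/Haralick radii 11, 40, 68, 134 px; `"anti-Phox2B"` uses radius 5 px
#' and 5, 10, 20, 40 px. Either preset yields a 114-feature catalog:
#' 12 colorimetric + 2 local statistics + 4 LBP + 64 Haralick + 32 Gabor.
#'
#' `spaces` restricts the bank to a subset of the nine feature spaces
#' (`RGB, HSV, XYZ, LAB, MEAN, VAR, GABOR, HARALICK, LBP`), and the radius /
#' wavelength vectors may be shortened, which scales the catalog down for
#' desk-size experiments.
#'
#' @param preset `"NeuN"`, `"anti-Phox2B"` or `"custom"`.
#' @param spaces character vector of included spaces.
#' @param mean_var_radius_px disk radius for local mean/variance.
#' @param lbp_radii_px,haralick_radii_px integer radii in pixels.
#' @param gabor_wavelengths_px,gabor_orientations_deg Gabor grids.
#' @param gabor_sigma_px,gabor_aspect_ratio,gabor_phase_deg Gabor constants.
#' @param glcm_levels number of gray levels for GLCM quantization.
#' @param lbp_points number of LBP sampling points P.
#' @return An object of class `feature_bank_config`.
#' @export
feature_bank_config <- function(preset = c("NeuN", "anti-Phox2B", "custom"),
                                spaces = .all_spaces,
                                mean_var_radius_px = NULL,
                                lbp_radii_px = NULL,
                                haralick_radii_px = NULL,
                                gabor_wavelengths_px = c(2.5, 5, 10, 20),
                                gabor_orientations_deg = c(0, 45, 90, 135),
                                gabor_sigma_px = 2,
                                gabor_aspect_ratio = 1.5,
                                gabor_phase_deg = 0,
                                glcm_levels = 16L,
                                lbp_points = 8L) {
  preset <- match.arg(preset)
  if (preset == "NeuN") {
    mean_var_radius_px <- mean_var_radius_px %||% 10L
    lbp_radii_px <- lbp_radii_px %||% c(11L, 40L, 68L, 134L)
    haralick_radii_px <- haralick_radii_px %||% c(11L, 40L, 68L, 134L)
  } else if (preset == "anti-Phox2B") {
    mean_var_radius_px <- mean_var_radius_px %||% 5L
    lbp_radii_px <- lbp_radii_px %||% c(5L, 10L, 20L, 40L)
    haralick_radii_px <- haralick_radii_px %||% c(5L, 10L, 20L, 40L)
  } else {
    mean_var_radius_px <- mean_var_radius_px %||% 5L
    lbp_radii_px <- lbp_radii_px %||% c(5L, 10L)
    haralick_radii_px <- haralick_radii_px %||% c(5L, 10L)
  }
  stopifnot(all(spaces %in% .all_spaces), mean_var_radius_px >= 1,
            all(lbp_radii_px >= 1), all(haralick_radii_px >= 1),
            glcm_levels >= 2, lbp_points >= 4)
  structure(list(
    preset = preset, spaces = spaces,
    mean_var_radius_px = mean_var_radius_px,
    lbp_radii_px = lbp_radii_px,
    haralick_radii_px = haralick_radii_px,
    gabor_wavelengths_px = gabor_wavelengths_px,
    gabor_orientations_deg = gabor_orientations_deg,
    gabor_sigma_px = gabor_sigma_px,
    gabor_aspect_ratio = gabor_aspect_ratio,
    gabor_phase_deg = gabor_phase_deg,
    glcm_levels = as.integer(glcm_levels),
    lbp_points = as.integer(lbp_points)
  ), class = "feature_bank_config")
}

#' Ordered feature catalog implied by a configuration
#'
#' The canonical ordering is: color spaces (RGB, HSV, XYZ, LAB), local mean,
#' local variance, LBP by radius, Haralick by statistic then radius then
#' direction, Gabor by wavelength then part (real, imaginary) then
#' orientation.
#'
#' @param config a [feature_bank_config()].
#' @return `data.frame` with columns `name`, `space`, `family` and the
#'   space-specific parameter columns (`radius_px`, `wavelength_px`,
#'   `orientation_deg`, `part`, `statistic`, `channel`), `NA` where not
#'   applicable.
#' @export
feature_catalog <- function(config) {
  rows <- list()
  add <- function(name, space, family, radius = NA, wavelength = NA,
                  orientation = NA, part = NA, statistic = NA, channel = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, space = space, family = family, radius_px = radius,
      wavelength_px = wavelength, orientation_deg = orientation,
      part = part, statistic = statistic, channel = channel,
      stringsAsFactors = FALSE)
  }
  for (sp in c("RGB", "HSV", "XYZ", "LAB")) {
    if (!sp %in% config$spaces) next
    for (ch in .color_members[[sp]]) add(ch, sp, sp, channel = ch)
  }
  if ("MEAN" %in% config$spaces)
    add("Mean", "MEAN", "Mean", radius = config$mean_var_radius_px)
  if ("VAR" %in% config$spaces)
    add("Var", "VAR", "Var", radius = config$mean_var_radius_px)
  if ("LBP" %in% config$spaces)
    for (r in config$lbp_radii_px)
      add(sprintf("LBP_%s", format(r)), "LBP", sprintf("LBP_%s", format(r)),
          radius = r)
  if ("HARALICK" %in% config$spaces)
    for (st in .haralick_stats)
      for (r in config$haralick_radii_px)
        for (d in names(.haralick_offsets))
          add(sprintf("H%s%s_%s", st, format(r), d), "HARALICK",
              sprintf("H%s%s", st, format(r)), radius = r,
              orientation = as.numeric(d), statistic = st)
  if ("GABOR" %in% config$spaces)
    for (lam in config$gabor_wavelengths_px)
      for (part in c("R", "I"))
        for (th in config$gabor_orientations_deg)
          add(sprintf("G_%s_%s_%s", format(lam), part, format(th)), "GABOR",
              sprintf("G_%s_%s", format(lam), part), wavelength = lam,
              orientation = th, part = part)
  do.call(rbind, rows)
}

#' Nomenclature string of a feature specification
#'
#' The naming scheme is bijective: Gabor features are `G_<lambda>_<R|I>_<angle>`
#' (`R` real part, `I` imaginary part), Haralick features are
#' `H<A|Corr|Con|V><radius>_<angle>`, LBP features `LBP_<radius>`, local
#' statistics `Mean` / `Var`, and colorimetric features their channel label.
#'
#' @param spec a list or one-row data.frame with a `space` field and the
#'   fields relevant to that space (see [feature_catalog()]).
#' @return The feature name string.
#' @seealso [parse_feature_name()]
#' @export
feature_name <- function(spec) {
  sp <- as.character(spec$space)
  if (sp %in% c("RGB", "HSV", "XYZ", "LAB")) return(as.character(spec$channel))
  if (sp == "MEAN") return("Mean")
  if (sp == "VAR") return("Var")
  if (sp == "LBP") return(sprintf("LBP_%s", format(spec$radius_px)))
  if (sp == "HARALICK")
    return(sprintf("H%s%s_%s", spec$statistic, format(spec$radius_px),
                   format(spec$orientation_deg)))
  if (sp == "GABOR")
    return(sprintf("G_%s_%s_%s", format(spec$wavelength_px), spec$part,
                   format(spec$orientation_deg)))
  stop("unknown feature space: ", sp)
}

#' Parse a nomenclature string back to a feature specification
#'
#' Inverse of [feature_name()].
#' @param name feature name string.
#' @return List with fields `name`, `space` and the space-specific fields.
#' @export
parse_feature_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  color <- unlist(.color_members)
  if (name %in% color) {
    sp <- names(which(vapply(.color_members, function(m) name %in% m,
                             logical(1L))))
    return(list(name = name, space = sp, channel = name))
  }
  if (name == "Mean") return(list(name = name, space = "MEAN"))
  if (name == "Var") return(list(name = name, space = "VAR"))
  m <- regmatches(name, regexec("^LBP_([0-9.]+)$", name))[[1L]]
  if (length(m))
    return(list(name = name, space = "LBP", radius_px = as.numeric(m[2L])))
  m <- regmatches(name, regexec("^H(A|Corr|Con|V)([0-9.]+)_(0|45|90|135)$",
                                name))[[1L]]
  if (length(m))
    return(list(name = name, space = "HARALICK", statistic = m[2L],
                radius_px = as.numeric(m[3L]),
                orientation_deg = as.numeric(m[4L])))
  m <- regmatches(name, regexec("^G_([0-9.]+)_(R|I)_(0|45|90|135)$",
                                name))[[1L]]
  if (length(m))
    return(list(name = name, space = "GABOR", wavelength_px = as.numeric(m[2L]),
                part = m[3L], orientation_deg = as.numeric(m[4L])))
  stop("cannot parse feature name: ", name)
}

#' Compute the full per-pixel feature stack of an RGB image
#'
#' Computes every feature of the configured catalog in canonical order. All
#' textural features are computed on the CIE Y luminance of the linearized
#' RGB image.
#'
#' @param image `H x W x 3` 8-bit RGB array.
#' @param config a [feature_bank_config()].
#' @param features optional character vector restricting computation to a
#'   subset of catalog features (catalog order is preserved).
#' @return Object of class `feature_stack`: list with `data` (`H x W x F`
#'   array, feature names on the third dimension) and `specs` (the
#'   corresponding rows of [feature_catalog()]).
#' @export
build_feature_stack <- function(image, config, features = NULL) {
  cat_df <- feature_catalog(config)
  if (!is.null(features)) {
    missing <- setdiff(features, cat_df$name)
    if (length(missing))
      stop("features not in catalog: ", paste(missing, collapse = ", "))
    cat_df <- cat_df[cat_df$name %in% features, , drop = FALSE]
  }
  need_space <- unique(cat_df$space)
  maps <- list()
  if (any(need_space %in% c("RGB", "HSV", "XYZ", "LAB")))
    maps <- rgb_to_color_features(image)
  gray <- luminance_gray(image)
  if (any(need_space %in% c("MEAN", "VAR"))) {
    mv <- local_mean_variance(gray, config$mean_var_radius_px)
    maps$Mean <- mv$Mean; maps$Var <- mv$Var
  }
  if ("LBP" %in% need_space) {
    sub <- config
    sub$lbp_radii_px <- unique(cat_df$radius_px[cat_df$space == "LBP"])
    maps <- c(maps, lbp_bank(gray, sub))
  }
  if ("HARALICK" %in% need_space) {
    sub <- config
    sub$haralick_radii_px <-
      unique(cat_df$radius_px[cat_df$space == "HARALICK"])
    maps <- c(maps, haralick_bank(gray, sub))
  }
  if ("GABOR" %in% need_space) {
    sub <- config
    sub$gabor_wavelengths_px <-
      unique(cat_df$wavelength_px[cat_df$space == "GABOR"])
    maps <- c(maps, gabor_bank(gray, sub))
  }
  h <- dim(image)[1L]; w <- dim(image)[2L]
  data <- array(NA_real_, dim = c(h, w, nrow(cat_df)),
                dimnames = list(NULL, NULL, cat_df$name))
  for (i in seq_len(nrow(cat_df))) data[, , i] <- maps[[cat_df$name[i]]]
  structure(list(data = data, specs = cat_df), class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("feature_stack: %d x %d pixels, %d features\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Write a feature stack as a multi-page 32-bit TIFF with a JSON sidecar
#'
#' Each feature plane is affinely rescaled to \[0, 1\] for TIFF storage; the
#' sidecar records the ordered feature names and the per-plane offset/scale
#' needed to undo the rescaling on read.
#'
#' @param stack a `feature_stack`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @export
write_feature_stack <- function(stack, path) {
  planes <- lapply(seq_len(dim(stack$data)[3L]), function(i) stack$data[, , i])
  lo <- vapply(planes, min, numeric(1L))
  hi <- vapply(planes, max, numeric(1L))
  scale <- ifelse(hi > lo, hi - lo, 1)
  norm <- Map(function(p, l, s) (p - l) / s, planes, lo, scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(features = stack$specs$name, offset = lo, scale = scale),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a feature stack written by [write_feature_stack()]
#' @param path TIFF path with `<path>.json` sidecar.
#' @param config the [feature_bank_config()] the stack was built with.
#' @return A `feature_stack`.
#' @export
read_feature_stack <- function(path, config) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  cat_df <- feature_catalog(config)
  cat_df <- cat_df[match(meta$features, cat_df$name), , drop = FALSE]
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  data <- array(NA_real_, dim = c(h, w, length(planes)),
                dimnames = list(NULL, NULL, meta$features))
  for (i in seq_along(planes))
    data[, , i] <- planes[[i]] * meta$scale[i] + meta$offset[i]
  structure(list(data = data, specs = cat_df), class = "feature_stack")
}
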