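# Orchestration of the full two-step selection pipeline and tiled application
# of a trained model with a reduced feature vector to large images.

#' Pipeline run configuration
#'
#' Bundles the feature bank, size limits, forest parameters and seeds of a
#' full selection run. `preset` resolves the staining presets of
#' [feature_bank_config()]; pass `bank` explicitly for a custom bank.
#'
#' @param preset `"NeuN"`, `"anti-Phox2B"` or `"custom"`.
#' @param bank a [feature_bank_config()] (required when `preset = "custom"`,
#'   defaults to the preset bank otherwise).
#' @param step1_max_size brute-force size limit of the family-selection step.
#' @param step2_max_size size limit of the feature-selection step.
#' @param n_trees forest size.
#' @param depth_grid,weight_grid optimization grids (see [optimize_wrf()]).
#' @param optimize run the depth/weight optimization (set `FALSE` to use
#'   `default_params`).
#' @param default_params a [wrf_params()] used when `optimize = FALSE`.
#' @param per_class_cap pixel subsampling cap per class per image.
#' @param class_of_interest scored class (default 2, neuron).
#' @param workers parallel workers for combination evaluation.
#' @param seed global seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(preset = c("custom", "NeuN", "anti-Phox2B"),
                       bank = NULL,
                       step1_max_size = 2L, step2_max_size = 4L,
                       n_trees = 100L,
                       depth_grid = c(2L, 4L, 6L, 8L, 10L, 15L, 20L),
                       weight_grid = c(1, 1.5, 2, 2.5, 3),
                       optimize = TRUE,
                       default_params = NULL,
                       per_class_cap = 4000L,
                       class_of_interest = 2L,
                       workers = 1L, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(bank)) {
    if (preset == "custom")
      stop("a custom run needs an explicit `bank` configuration")
    bank <- feature_bank_config(preset)
  }
  stopifnot(step1_max_size >= 1L, step2_max_size >= 1L)
  structure(list(preset = preset, bank = bank,
                 step1_max_size = as.integer(step1_max_size),
                 step2_max_size = as.integer(step2_max_size),
                 n_trees = as.integer(n_trees),
                 depth_grid = depth_grid, weight_grid = weight_grid,
                 optimize = optimize, default_params = default_params,
                 per_class_cap = per_class_cap,
                 class_of_interest = as.integer(class_of_interest),
                 workers = as.integer(workers), seed = as.integer(seed)),
            class = "run_config")
}

#' A small desk-scale feature bank
#'
#' 18 features (RGB, HSV, local mean/variance at radius 8, LBP at radii 4 and
#' 10, and the 5-px-wavelength Gabor octave), sized so that the two-step
#' pipeline runs in minutes on one CPU while still mixing colorimetric and
#' textural spaces. The window radii follow the scale rationale of the full
#' presets: they span the object size range up to about twice the largest
#' object of interest, so that windowed statistics can separate small stained
#' objects from larger stain accumulations.
#'
#' @return A [feature_bank_config()].
#' @export
reduced_bank_config <- function() {
  feature_bank_config(
    preset = "custom",
    spaces = c("RGB", "HSV", "MEAN", "VAR", "LBP", "GABOR"),
    mean_var_radius_px = 8L,
    lbp_radii_px = c(4L, 10L),
    gabor_wavelengths_px = 5)
}

#' Run the full two-step selection pipeline
#'
#' Executes, on learning and test sample lists: feature extraction, pixel
#' sampling, forest optimization, the step-1 brute force over all individual
#' features (size limit `step1_max_size`), family selection by fMPV, the
#' step-2 brute force over the retained features (size limit
#' `step2_max_size`), iterative aggregation under both validation conditions,
#' and reconciliation of the two selected vectors.
#'
#' @param learn,test lists of `synth_sample` objects (or lists with `image`
#'   and `mask` fields).
#' @param config a [run_config()].
#' @param outdir optional directory where all intermediate tables and reports
#'   are persisted (CSV/JSON).
#' @return Object of class `pipeline_run`: list with the trained-parameter
#'   optimization result, step-1 and step-2 `combination_table`s per
#'   condition, the `family_selection`, the two `aggregation_trace`s, the
#'   `selection_outcome`, and the full-bank and selected-vector F-scores.
#' @export
run_pipeline <- function(learn, test, config, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  bank <- config$bank
  cat_df <- feature_catalog(bank)

  stacks_learn <- stage("extract", lapply(learn, function(s)
    build_feature_stack(s$image, bank)))
  stacks_test <- stage("extract", lapply(test, function(s)
    build_feature_stack(s$image, bank)))

  set_a <- stage("sample", sample_pixels(stacks_learn,
                                         lapply(learn, `[[`, "mask"),
                                         config$per_class_cap,
                                         derive_seed(config$seed, "learn"),
                                         ids = paste0("learn_",
                                                      seq_along(learn))))
  set_b <- stage("sample", sample_pixels(stacks_test,
                                         lapply(test, `[[`, "mask"),
                                         config$per_class_cap,
                                         derive_seed(config$seed, "test"),
                                         ids = paste0("test_",
                                                      seq_along(test))))

  params <- if (config$optimize) {
    opt <- stage("optimize", optimize_wrf(
      set_a, set_b, config$depth_grid, config$weight_grid, config$n_trees,
      derive_seed(config$seed, "optimize"),
      class_of_interest = config$class_of_interest))
    opt$params
  } else {
    opt <- NULL
    config$default_params %||% wrf_params(config$n_trees,
                                          seed = config$seed)
  }

  full_eval <- stage("full-bank", two_fold(
    set_a, set_b, params, class_of_interest = config$class_of_interest))

  evaluator <- function(features, seed) {
    p <- params
    p$seed <- seed
    ev <- two_fold(set_a, set_b, p, features,
                   class_of_interest = config$class_of_interest)
    c(DV = ev$fscore_dv, CV = ev$fscore_cv)
  }

  step1_combos <- enumerate_combinations(cat_df$name, config$step1_max_size)
  step1_tables <- stage("step1", evaluate_all(
    step1_combos, evaluator, config$workers, derive_seed(config$seed, "s1")))

  fam_catalog <- build_family_catalog(bank)
  families <- stage("select-families", select_families(
    step1_tables$DV, step1_tables$CV, fam_catalog))
  if (!length(families$features))
    stop("[stage select-families] no family passed both selection rules")

  step2_combos <- enumerate_combinations(families$features,
                                         min(config$step2_max_size,
                                             length(families$features)))
  step2_tables <- stage("step2", evaluate_all(
    step2_combos, evaluator, config$workers, derive_seed(config$seed, "s2")))

  trace_dv <- stage("aggregate", aggregate_select(step2_tables$DV,
                                                  config$step2_max_size))
  trace_cv <- stage("aggregate", aggregate_select(step2_tables$CV,
                                                  config$step2_max_size))
  outcome <- stage("reconcile", reconcile(trace_dv, trace_cv,
                                          step2_tables$DV, step2_tables$CV))

  run <- structure(list(
    config = config, params = params, optimization = opt,
    fscore_full = c(DV = full_eval$fscore_dv, CV = full_eval$fscore_cv),
    step1_tables = step1_tables, families = families,
    step2_tables = step2_tables,
    trace_dv = trace_dv, trace_cv = trace_cv, outcome = outcome,
    fscore_selected = outcome$fscores,
    pixel_sets = list(learn = set_a, test = set_b)
  ), class = "pipeline_run")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_combination_table(step1_tables$DV, file.path(outdir, "step1_dv.csv"))
    write_combination_table(step1_tables$CV, file.path(outdir, "step1_cv.csv"))
    write_combination_table(step2_tables$DV, file.path(outdir, "step2_dv.csv"))
    write_combination_table(step2_tables$CV, file.path(outdir, "step2_cv.csv"))
    write_fmpv_report(families$report_dv, file.path(outdir, "fmpv_dv.json"))
    write_fmpv_report(families$report_cv, file.path(outdir, "fmpv_cv.json"))
    write_selection_report(trace_dv, trace_cv, outcome,
                           file.path(outdir, "selection.json"))
    jsonlite::write_json(list(
      selected_families = families$selected,
      retained_features = families$features,
      final_vector = outcome$final,
      fscore_full = as.list(run$fscore_full),
      fscore_selected = as.list(run$fscore_selected),
      params = list(n_trees = params$n_trees, max_depth = params$max_depth,
                    class_weights = as.list(params$class_weights))
    ), file.path(outdir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  cat("  retained families:", paste(x$families$selected, collapse = ", "), "\n")
  cat("  selected vector:  ", paste(x$outcome$final, collapse = " ; "), "\n")
  cat(sprintf("  F-score selected: DV %.4f / CV %.4f (full bank: DV %.4f / CV %.4f)\n",
              x$fscore_selected["DV"], x$fscore_selected["CV"],
              x$fscore_full["DV"], x$fscore_full["CV"]))
  invisible(x)
}

#' Spatial support halo of a feature set
#'
#' The number of pixels beyond a tile that must be read so that every
#' interior pixel's features equal the whole-image computation: the maximum
#' over active features of the window radius (mean/variance), `radius + 1`
#' (Haralick window plus unit offset), `ceiling(radius) + 1` (LBP bilinear
#' sampling) or the Gabor kernel half-width.
#'
#' @param config a [feature_bank_config()].
#' @param features feature names in use.
#' @return Integer halo in pixels.
#' @export
feature_halo <- function(config, features) {
  halo <- 0L
  for (f in features) {
    spec <- parse_feature_name(f)
    h <- switch(spec$space,
      RGB = , HSV = , XYZ = , LAB = 0L,
      MEAN = , VAR = as.integer(config$mean_var_radius_px),
      LBP = as.integer(ceiling(spec$radius_px)) + 1L,
      HARALICK = as.integer(spec$radius_px) + 1L,
      GABOR = as.integer(ceiling(3 * config$gabor_sigma_px)))
    halo <- max(halo, h)
  }
  halo
}

#' Segment a large image tile by tile
#'
#' Splits the image into a grid of `tile_size` tiles, extends each tile by
#' `overlap` pixels of real image data (reflection applies only at the true
#' image border, as in whole-image computation), computes the model's feature
#' subset on the extended tile and predicts the interior. With
#' `overlap >= feature_halo(...)` the stitched mask is bit-identical to
#' whole-image segmentation.
#'
#' @param image `H x W x 3` RGB array, or a path to a PNG/TIFF file.
#' @param model a `wrf_model` trained on features of `config`'s catalog.
#' @param config the [feature_bank_config()] used for extraction.
#' @param tile_size interior tile extent in pixels.
#' @param overlap halo width in pixels; must be at least
#'   [feature_halo()] of the model's features.
#' @return `H x W` integer label matrix.
#' @export
segment_large_image <- function(image, model, config, tile_size = 256L,
                                overlap = NULL) {
  if (is.character(image)) image <- read_rgb_image(image)
  halo <- feature_halo(config, model$features)
  overlap <- overlap %||% halo
  if (overlap < halo)
    stop(sprintf("overlap %d is smaller than the feature support halo %d",
                 overlap, halo))
  h <- dim(image)[1L]; w <- dim(image)[2L]
  out <- matrix(NA_integer_, h, w)
  for (r0 in seq(1L, h, by = tile_size)) {
    r1 <- min(r0 + tile_size - 1L, h)
    er0 <- max(1L, r0 - overlap); er1 <- min(h, r1 + overlap)
    for (c0 in seq(1L, w, by = tile_size)) {
      c1 <- min(c0 + tile_size - 1L, w)
      ec0 <- max(1L, c0 - overlap); ec1 <- min(w, c1 + overlap)
      crop <- image[er0:er1, ec0:ec1, , drop = FALSE]
      stack <- build_feature_stack(crop, config, features = model$features)
      lab <- predict(model, stack)
      out[r0:r1, c0:c1] <-
        lab[(r0 - er0 + 1L):(r1 - er0 + 1L), (c0 - ec0 + 1L):(c1 - ec0 + 1L)]
    }
  }
  out
}

#' Read an 8-bit RGB PNG or TIFF as an H x W x 3 integer array
#' @param path image path.
#' @return `H x W x 3` integer array with values 0-255.
#' @export
read_rgb_image <- function(path) {
  img <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("expected a 3-channel RGB image: ", path)
  img <- round(img * 255)
  storage.mode(img) <- "integer"
  img
}

#' Memory-reduction accounting for a selected feature vector
#'
#' Per-pixel feature storage is 4 bytes per feature (32-bit floats), so
#' reducing the vector from `n_initial` to `n_selected` features divides the
#' feature memory by `n_initial / n_selected` (e.g. 114 / 2 = 57).
#'
#' @param n_selected selected vector size.
#' @param n_initial initial vector size (default 114).
#' @return List with `factor`, `bytes_per_pixel_initial`,
#'   `bytes_per_pixel_selected` and `pct_of_initial` (selected size as a
#'   percentage of the initial size, rounded to 2 decimals).
#' @export
memory_reduction <- function(n_selected, n_initial = 114L) {
  stopifnot(n_selected >= 1L, n_initial >= n_selected)
  list(factor = n_initial / n_selected,
       bytes_per_pixel_initial = 4L * n_initial,
       bytes_per_pixel_selected = 4L * n_selected,
       pct_of_initial = round(100 * n_selected / n_initial, 2L))
}
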