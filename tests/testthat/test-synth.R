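test_that("generation is byte-identical under a fixed (config, seed) pair", {
  cfg <- synth_config(height = 48L, width = 48L)
  s1 <- generate_sample(cfg, 7L)
  s2 <- generate_sample(cfg, 7L)
  expect_identical(s1, s2)
  s3 <- generate_sample(cfg, 8L)
  expect_false(identical(s1$image, s3$image))
  # metadata is consistent with the mask
  expect_equal(unname(s1$metadata$class_pixels),
               vapply(0:3, function(k) sum(s1$mask == k), integer(1L)))
  expect_equal(dim(s1$image)[1:2], dim(s1$mask))
  expect_true(all(s1$image >= 0L & s1$image <= 255L))
})

test_that("degenerate densities produce the expected class sets", {
  cfg0 <- synth_config(height = 32L, width = 32L, neuron_density = 0,
                       artifact_count = 0L)
  s <- generate_sample(cfg0, 3L)
  expect_setequal(unique(as.vector(s$mask)), c(0L, 1L))
  # infeasible density for the tissue geometry errors out
  expect_error(generate_sample(synth_config(height = 32L, width = 32L,
                                            neuron_density = 0.7), 1L),
               "infeasible")
})

test_that("realized neuron pixel fraction tracks the configured density", {
  cfg <- synth_config(height = 64L, width = 64L, neuron_density = 0.08)
  dens <- vapply(1:20, function(sd)
    mean(generate_sample(cfg, sd)$mask == 2L), numeric(1L))
  expect_true(all(dens > 0.08 * 0.7 & dens < 0.08 * 1.3))
})

test_that("learning and test splits are seed-disjoint and class-balanced", {
  ds <- generate_dataset(synth_config(height = 64L, width = 64L),
                         10L, 10L, seed = 1L)
  expect_length(ds$learn, 10L)
  expect_length(ds$test, 10L)
  seeds <- vapply(c(ds$learn, ds$test), function(s) s$metadata$seed,
                  numeric(1L))
  expect_false(anyDuplicated(seeds) > 0)
  prop <- function(lst) {
    cc <- Reduce(`+`, lapply(lst, function(s) s$metadata$class_pixels))
    cc / sum(cc)
  }
  pl <- prop(ds$learn); pt <- prop(ds$test)
  expect_true(all(abs(pl - pt) / pmax(pl, 1e-9) < 0.10))
  # minimal dataset is valid
  ds1 <- generate_dataset(synth_config(height = 32L, width = 32L), 1L, 1L,
                          seed = 2L)
  expect_s3_class(ds1$learn[[1]], "synth_sample")
  # an uneven split (the 54/46 design) is honored exactly
  ds2 <- generate_dataset(synth_config(height = 32L, width = 32L), 54L, 46L,
                          seed = 3L)
  expect_length(ds2$learn, 54L)
  expect_length(ds2$test, 46L)
})

test_that("samples round-trip through PNG pairs and a manifest", {
  s <- generate_sample(synth_config(height = 32L, width = 32L), 5L)
  prefix <- file.path(withr::local_tempdir(), "sample01")
  write_sample(s, prefix)
  back <- read_sample(prefix)
  expect_identical(back$image, s$image)
  expect_identical(back$mask, s$mask)
  expect_equal(back$metadata$n_neurons, s$metadata$n_neurons)
})

test_that("a weighted forest on the full feature bank reaches the good
           segmentation bar on default synthetic data", {
  # this gates the downstream selection tests: with the full 114-feature
  # bank and the default forest parameters, neuron F-score must exceed 0.8
  ds <- generate_dataset(synth_config(), 4L, 4L, seed = 11L)
  bank <- feature_bank_config("anti-Phox2B")
  stacks_l <- lapply(ds$learn, function(s) build_feature_stack(s$image, bank))
  stacks_t <- lapply(ds$test, function(s) build_feature_stack(s$image, bank))
  sa <- sample_pixels(stacks_l, lapply(ds$learn, `[[`, "mask"), 1000L, 7L,
                      ids = paste0("a", 1:4))
  sb <- sample_pixels(stacks_t, lapply(ds$test, `[[`, "mask"), 1000L, 8L,
                      ids = paste0("b", 1:4))
  ev <- two_fold(sa, sb, wrf_params(seed = 33L))
  expect_gt(ev$fscore_dv, 0.8)
  expect_gt(ev$fscore_cv, 0.8)
})

test_that("degenerate configurations steer the fMPV ranking toward the
           expected feature spaces", {
  bank <- reduced_bank_config()
  fc <- build_family_catalog(bank)
  run_tables <- function(scfg, sd) {
    ds <- generate_dataset(scfg, 4L, 4L, seed = sd)
    stacks_l <- lapply(ds$learn, function(s) build_feature_stack(s$image, bank))
    stacks_t <- lapply(ds$test, function(s) build_feature_stack(s$image, bank))
    sa <- sample_pixels(stacks_l, lapply(ds$learn, `[[`, "mask"), 300L, 7L,
                        ids = paste0("a", 1:4))
    sb <- sample_pixels(stacks_t, lapply(ds$test, `[[`, "mask"), 300L, 8L,
                        ids = paste0("b", 1:4))
    p <- wrf_params(10L, 10L, c("2" = 2), 33L)
    ev <- function(features, seed) {
      pp <- p; pp$seed <- seed
      e <- two_fold(sa, sb, pp, features)
      c(DV = e$fscore_dv, CV = e$fscore_cv)
    }
    evaluate_all(enumerate_combinations(colnames(sa$features), 2L), ev,
                 seed = 9L)
  }
  top_spaces <- function(tabs, k = 3L) {
    rp <- fmpv_report(tabs$DV, fc)
    space_of(fc, names(sort(rp$feature))[seq_len(k)])
  }

  # color only: no texture anywhere, classes differ in color alone
  col_cfg <- synth_config(height = 48L, width = 48L,
                          tissue_texture_amplitude = 0,
                          neuron_texture_amplitude = 0,
                          artifact_count = 0L, noise_sigma = 1,
                          stain_intensity_range = c(1, 1))
  expect_true(all(top_spaces(run_tables(col_cfg, 5L)) %in%
                    c("RGB", "HSV", "XYZ", "LAB")))

  # texture only: identical colors and matched intensity distributions,
  # classes differ in grating wavelength alone
  tex_cfg <- synth_config(height = 48L, width = 48L,
                          neuron_color = c(205, 190, 175),
                          neuron_color_spread = 0,
                          stain_intensity_range = c(1, 1),
                          neuron_texture_amplitude = 6,
                          tissue_texture_amplitude = 6,
                          neuron_texture_wavelength_px = 5,
                          tissue_texture_wavelength_px = 2.5,
                          artifact_count = 0L, noise_sigma = 1)
  expect_true(all(top_spaces(run_tables(tex_cfg, 5L)) %in%
                    c("GABOR", "LBP", "MEAN", "VAR")))
})
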