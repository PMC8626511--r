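test_that("position vectors and medians follow their definitions", {
  tab <- make_table(list("R", "G", c("B", "R")), c(0.9, 0.7, 0.5))
  # R appears in the rows ranked 1 and 3
  expect_equal(position_vector(tab, "R"), c(1L, 3L))
  expect_equal(fmpv(tab, "R"), 2.0)            # even count: midpoint
  expect_equal(fmpv(tab, "B"), 3.0)            # single position [3]
  expect_error(position_vector(tab, "Q"), "absent")

  # a feature present in every combination spans all ranks
  tab2 <- make_table(list("a", c("a", "b"), c("a", "c")), c(0.3, 0.9, 0.6))
  expect_equal(position_vector(tab2, "a"), 1:3)
  expect_equal(fmpv(tab2, "a"), 2)

  # pooled scale: merged rank vectors with multiplicity
  tab3 <- make_table(list("x", c("x", "y"), "y", "z"),
                     c(0.9, 0.8, 0.5, 0.2))
  # x in ranks 1,2; y in ranks 2,3 -> pooled median of (1,2,2,3) = 2
  expect_equal(pooled_fmpv(tab3, c("x", "y")), 2)
  expect_error(pooled_fmpv(tab3, character(0)), "empty")
})

test_that("fMPV equals a naive full-table scan on random tables", {
  set.seed(99)
  feats <- paste0("f", 1:12)
  for (rep in 1:3) {
    combos <- enumerate_combinations(feats, 2)
    tab <- make_table(combos, runif(length(combos)))
    for (f in sample(feats, 5)) {
      expect_equal(position_vector(tab, f), oracle_positions(tab, f))
      expect_equal(fmpv(tab, f), stats::median(oracle_positions(tab, f)))
    }
  }
})

test_that("promoting a combination containing a feature never increases its
           fMPV", {
  set.seed(17)
  feats <- letters[1:8]
  combos <- enumerate_combinations(feats, 2)
  scores <- runif(length(combos))
  tab <- make_table(combos, scores)
  for (f in c("a", "d", "h")) {
    before <- fmpv(tab, f)
    # promote one combination containing f to the global best score
    hit <- which(vapply(strsplit(tab$features, ";"), function(s)
      f %in% s, logical(1L)))
    target_key <- tab$features[max(hit)]
    scores2 <- scores
    keys <- vapply(combos, function(x) paste(sort(x), collapse = ";"),
                   character(1L))
    scores2[keys == target_key] <- max(scores) + 1
    after <- fmpv(make_table(combos, scores2), f)
    expect_lte(after, before)
  }
})

test_that("family selection keeps families that dominate the top ranks in
           both conditions", {
  bank <- feature_bank_config("custom", spaces = c("RGB", "LBP"),
                              lbp_radii_px = c(2L, 3L))
  fc <- build_family_catalog(bank)   # features R,G,B,LBP_2,LBP_3
  combos <- enumerate_combinations(c("R", "G", "B", "LBP_2", "LBP_3"), 2)
  # RGB members fill the top of the table in both conditions
  score_rgb_top <- function(cmb) vapply(cmb, function(s)
    sum(s %in% c("R", "G", "B")) + 0.001 * length(s), numeric(1L))
  tab_dv <- make_table(combos, score_rgb_top(combos), "DV")
  tab_cv <- make_table(combos, score_rgb_top(combos) + 0.0001, "CV")
  sel <- select_families(tab_dv, tab_cv, fc)
  expect_true("RGB" %in% sel$selected)
  expect_false(any(c("LBP_2", "LBP_3") %in% sel$selected))
  expect_setequal(sel$features[sel$features %in% c("R", "G", "B")],
                  c("R", "G", "B"))

  # a family passing in DV only is excluded from the intersection
  score_lbp_top <- function(cmb) vapply(cmb, function(s)
    sum(s %in% c("LBP_2", "LBP_3")) + 0.001 * length(s), numeric(1L))
  sel2 <- select_families(tab_dv, make_table(combos, score_lbp_top(combos),
                                             "CV"), fc)
  expect_false("RGB" %in% sel2$selected)

  # all-equal scores: the selection is reproducible
  tab_eq <- make_table(combos, rep(0.5, length(combos)), "DV")
  s1 <- select_families(tab_eq, tab_eq, fc)
  s2 <- select_families(tab_eq, tab_eq, fc)
  expect_identical(s1$selected, s2$selected)
})

test_that("fmpv_report exposes both scales, both rules and both modes", {
  bank <- feature_bank_config("custom", spaces = c("RGB", "LBP"),
                              lbp_radii_px = c(2L, 3L))
  fc <- build_family_catalog(bank)
  combos <- enumerate_combinations(c("R", "G", "B", "LBP_2", "LBP_3"), 2)
  tab <- make_table(combos, vapply(combos, function(s)
    sum(s %in% c("R", "G", "B")), numeric(1L)))
  rep_p <- fmpv_report(tab, fc, mode = "pooled")
  expect_equal(sort(names(rep_p$family)),
               sort(c("RGB", "LBP_2", "LBP_3")))
  expect_true(all(rep_p$feature >= 1 & rep_p$feature <= nrow(tab)))
  expect_lt(rep_p$family["RGB"], rep_p$family["LBP_2"])
  rep_s <- fmpv_report(tab, fc, mode = "strict")
  expect_s3_class(rep_s, "fmpv_report")
  # strict mode can only be more conservative than pooled
  expect_true(all(rep_s$selection$selected <= rep_p$selection$selected |
                    !rep_s$selection$selected))

  # catalog/table mismatch is caught
  fc_big <- build_family_catalog(feature_bank_config("NeuN"))
  expect_error(fmpv_report(tab, fc_big), "mismatch")

  path <- withr::local_tempfile(fileext = ".json")
  write_fmpv_report(rep_p, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_feature_fmpv, rep_p$mean_feature)
})
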