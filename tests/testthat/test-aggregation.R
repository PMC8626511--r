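combo_key_test <- function(x) paste(sort(x), collapse = ";")

# a table where combinations containing more of S always outrank the rest
planted_table <- function(feats, S, max_size, condition = "DV") {
  combos <- enumerate_combinations(feats, max_size)
  scores <- vapply(combos, function(s) {
    k <- length(intersect(s, S))
    base <- k - 0.05 * abs(length(s) - length(S))
    if (setequal(s, S)) base + 1 else base
  }, numeric(1L))
  make_table(combos, scores, condition)
}

test_that("aggregation follows the surviving-combination filter", {
  feats <- letters[1:5]
  tab <- planted_table(feats, c("a", "b"), 3)
  tr <- aggregate_select(tab, 3L)
  expect_s3_class(tr, "aggregation_trace")
  # the filter invariant: V_i grows by one feature, L_i shrinks
  expect_equal(tr$size, seq_len(nrow(tr)))
  expect_true(all(diff(tr$n_surviving) <= 0))
  # subset-filter oracle: after V_2, survivors are exactly the supersets
  sets <- strsplit(tab$features, ";")
  v2 <- strsplit(tr$vector[2], ";")[[1L]]
  expect_equal(tr$n_surviving[2],
               sum(vapply(sets, function(s) all(v2 %in% s), logical(1L))))
  # the planted pair is recovered
  expect_setequal(choose_vector(tr), c("a", "b"))
})

test_that("max_size 1 reduces to the global minimum-fMPV feature", {
  tab <- planted_table(letters[1:4], "c", 2)
  tr <- aggregate_select(tab, 1L)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$criterion, "fmpv")
  med <- vapply(letters[1:4], function(f) fmpv(tab, f), numeric(1L))
  expect_equal(tr$feature, names(which.min(med)))
})

test_that("a feature whose combinations fill the top ranks is selected
           first", {
  combos <- list("a", "b", "c", c("a", "b"), c("a", "c"), c("b", "c"))
  # every a-containing combination outranks the rest
  scores <- c(0.9, 0.3, 0.2, 0.95, 0.85, 0.25)
  tr <- aggregate_select(make_table(combos, scores), 2L)
  expect_equal(tr$feature[1], "a")
})

test_that("the final-round iterate is chosen by F-score but is not itself
           selectable", {
  feats <- letters[1:5]
  tab <- planted_table(feats, c("a", "b"), 4)
  tr <- aggregate_select(tab, 4L)
  expect_equal(tr$criterion, c(rep("fmpv", nrow(tr) - 1L), "fscore"))
  # choose_vector ignores the F-criterion round even if its F-score is best
  tr2 <- tr
  tr2$fscore[nrow(tr2)] <- 1.5
  expect_equal(combo_key_test(choose_vector(tr2)),
               combo_key_test(c("a", "b")))
  # ties on F-score go to the smaller vector
  tr3 <- tr
  tr3$fscore[] <- 0.5
  tr3$fscore[1:2] <- 0.9
  expect_equal(choose_vector(tr3), strsplit(tr3$vector[1], ";")[[1L]])
  tr_na <- tr
  tr_na$fscore <- NA_real_
  expect_error(choose_vector(tr_na), "no iterate")
  expect_error(aggregate_select(tab[0, ], 2L), "empty")
})

test_that("choose_vector picks the best-F fMPV iterate (size-2 plateau
           pattern)", {
  tr <- structure(data.frame(
    iteration = 1:3, feature = c("x", "y", "z"),
    vector = c("x", "x;y", "x;y;z"), size = 1:3,
    n_surviving = c(9L, 4L, 1L),
    fscore = c(0.5, 0.86, 0.85),
    criterion = "fmpv", stringsAsFactors = FALSE),
    class = c("aggregation_trace", "data.frame"))
  expect_equal(choose_vector(tr), c("x", "y"))
})

test_that("reconcile returns identical vectors directly and breaks
           disagreements by mean F-score", {
  feats <- letters[1:4]
  tab_dv <- planted_table(feats, c("a", "b"), 3, "DV")
  tab_cv <- planted_table(feats, c("a", "b"), 3, "CV")
  tr_dv <- aggregate_select(tab_dv, 3L)
  tr_cv <- aggregate_select(tab_cv, 3L)
  out <- reconcile(tr_dv, tr_cv, tab_dv, tab_cv)
  expect_equal(out$rationale, "identical")
  expect_setequal(out$final, c("a", "b"))

  # disagreement: plant different pairs; the higher mean-F vector wins
  tab_cv2 <- planted_table(feats, c("a", "c"), 3, "CV")
  tr_cv2 <- aggregate_select(tab_cv2, 3L)
  out2 <- reconcile(tr_dv, tr_cv2, tab_dv, tab_cv2)
  expect_equal(out2$rationale, "best-F tiebreak")
  lookup <- function(tab, v) tab$fscore[match(combo_key_test(v),
                                              tab$features)]
  m_dv <- mean(c(lookup(tab_dv, out2$vector_dv),
                 lookup(tab_cv2, out2$vector_dv)))
  m_cv <- mean(c(lookup(tab_dv, out2$vector_cv),
                 lookup(tab_cv2, out2$vector_cv)))
  expect_equal(out2$final,
               if (m_dv >= m_cv) out2$vector_dv else out2$vector_cv)
})

test_that("traces and outcomes persist to JSON", {
  feats <- letters[1:4]
  tab <- planted_table(feats, c("a", "b"), 3)
  tr <- aggregate_select(tab, 3L)
  out <- reconcile(tr, tr, tab, tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(tr, tr, out, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(back$final, out$final)
  expect_equal(back$rationale, "identical")
})
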