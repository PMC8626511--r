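test_that("combination counts reproduce the binomial sums", {
  expect_equal(count_combinations(21, 4), 7546)
  expect_equal(count_combinations(1, 1), 1)
  expect_equal(count_combinations(114, 2), 114 + choose(114, 2))  # 6555
  expect_equal(count_combinations(114, 2), 6555)
  for (n in c(3, 7, 11)) expect_equal(count_combinations(n, n), 2^n - 1)
  # the full 114-feature space is astronomically large
  expect_gt(count_combinations(114, 114), 2e34)
  expect_error(count_combinations(10, 0), "max_size")
})

test_that("enumeration is exhaustive, duplicate-free and canonically ordered", {
  expect_equal(enumerate_combinations(c("b", "a"), 2),
               list("a", "b", c("a", "b")))
  cmb <- enumerate_combinations(paste0("f", sprintf("%02d", 1:19)), 4)
  expect_length(cmb, 5035L)
  # sizes ascending, lexicographic within size
  expect_true(!is.unsorted(lengths(cmb)))
  keys <- vapply(cmb, paste, character(1L), collapse = ";")
  expect_false(anyDuplicated(keys) > 0)
  # set equality with a direct combn enumeration on a smaller instance
  cmb10 <- enumerate_combinations(letters[1:10], 3)
  direct <- unlist(lapply(1:3, function(k)
    utils::combn(letters[1:10], k, simplify = FALSE)), recursive = FALSE)
  expect_setequal(vapply(cmb10, paste, character(1L), collapse = ";"),
                  vapply(direct, function(x)
                    paste(sort(x), collapse = ";"), character(1L)))
})

test_that("sort_table ranks by descending F-score with deterministic
           tie-breaks", {
  rows <- data.frame(features = c("a", "b", "c"), size = c(1L, 1L, 1L),
                     fscore = c(0.2, 0.9, 0.5))
  tab <- sort_table(rows)
  expect_equal(tab$features, c("b", "c", "a"))
  expect_equal(tab$rank, 1:3)
  # equal scores: the smaller combination wins
  rows2 <- data.frame(features = c("a;b", "c"), size = c(2L, 1L),
                      fscore = c(0.5, 0.5))
  expect_equal(sort_table(rows2)$features[1], "c")
  # equal scores and sizes: bytewise-lexicographic feature string
  rows3 <- data.frame(features = c("z", "m"), size = 1L, fscore = 0.5)
  expect_equal(sort_table(rows3)$features, c("m", "z"))
  expect_error(sort_table(data.frame(features = "a", size = 1L,
                                     fscore = NaN)), "finite")
})

test_that("table ranks equal a reference sort and are invariant to row
           permutation", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 40L
    rows <- data.frame(
      features = replicate(n, paste(sort(sample(letters[1:6],
                                                sample(1:3, 1))),
                                    collapse = ";")),
      fscore = round(runif(n), 2), stringsAsFactors = FALSE)
    rows$size <- lengths(strsplit(rows$features, ";"))
    tab <- sort_table(rows)
    expect_equal(tab$features, oracle_sort(rows)$features)
    shuffled <- rows[sample(n), , drop = FALSE]
    expect_equal(sort_table(shuffled)$features, tab$features)
  }
})

test_that("evaluation tables are independent of worker count and record
           failures without aborting", {
  cmb <- enumerate_combinations(letters[1:6], 3)
  ev <- toy_evaluator(c("a", "b"))
  t1 <- evaluate_all(cmb, ev, workers = 1L, seed = 5L)
  t4 <- evaluate_all(cmb, ev, workers = 4L, seed = 5L)
  expect_identical(t1, t4)
  expect_named(t1, c("DV", "CV"))
  expect_equal(nrow(t1$DV), length(cmb))
  expect_equal(attr(t1, "n_failed"), 0L)

  # toy scoring by overlap with {a, b}: those features occupy the top ranks
  top <- strsplit(t1$DV$features[1], ";")[[1L]]
  expect_setequal(intersect(top, c("a", "b")), c("a", "b"))
  fc_a <- fmpv(t1$DV, "a")
  fc_f <- fmpv(t1$DV, "f")
  expect_lt(fc_a, fc_f)

  # constant evaluator: ranks follow the deterministic tie-break order
  tc <- evaluate_all(cmb, function(features, seed) c(DV = 0.5), seed = 5L)
  expect_equal(tc$DV$features,
               sort_table(data.frame(features = tc$DV$features,
                                     size = tc$DV$size,
                                     fscore = 0.5))$features)

  # failing evaluator rows are recorded and excluded
  ev_fail <- function(features, seed) {
    if ("c" %in% features) stop("boom")
    c(DV = length(features))
  }
  tf <- evaluate_all(cmb, ev_fail, seed = 5L)
  expect_gt(attr(tf, "n_failed"), 0L)
  expect_false(any(grepl("c", tf$DV$features)))
})

test_that("combination tables round-trip through CSV", {
  cmb <- enumerate_combinations(letters[1:5], 2)
  tab <- evaluate_all(cmb, toy_evaluator("a"), seed = 1L)$DV
  path <- withr::local_tempfile(fileext = ".csv")
  write_combination_table(tab, path)
  back <- read_combination_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
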