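# Size-limited brute-force exploration of feature combinations and the
# sorted combination tables that the fMPV criterion is computed from.

#' Number of feature combinations up to a size limit
#'
#' `sum over k = 1..max_size of choose(n_features, k)`.
#'
#' @param n_features number of available features.
#' @param max_size maximal combination size.
#' @return The count (numeric; exact up to 2^53).
#' @examples
#' count_combinations(21, 4)  # 7546
#' @export
count_combinations <- function(n_features, max_size) {
  if (max_size < 1) stop("`max_size` must be >= 1")
  stopifnot(max_size <= n_features)
  sum(choose(n_features, seq_len(max_size)))
}

#' Enumerate all feature combinations up to a size limit
#'
#' Sizes ascending; lexicographic order within each size (features are sorted
#' bytewise first, so the order is locale-independent).
#'
#' @param features character vector of feature names.
#' @param max_size maximal combination size.
#' @return List of character vectors (each a sorted feature combination).
#' @export
enumerate_combinations <- function(features, max_size) {
  if (max_size < 1) stop("`max_size` must be >= 1")
  stopifnot(max_size <= length(features), !anyDuplicated(features))
  feats <- sort(features, method = "radix")
  out <- vector("list", count_combinations(length(feats), max_size))
  n <- 0L
  for (k in seq_len(max_size)) {
    cmb <- utils::combn(feats, k, simplify = FALSE)
    out[n + seq_along(cmb)] <- cmb
    n <- n + length(cmb)
  }
  out
}

#' Canonical string form of a combination
#' @noRd
combo_key <- function(features) {
  paste(sort(features, method = "radix"), collapse = ";")
}

#' Evaluate every combination and build sorted tables per condition
#'
#' Applies `evaluator` to each combination and assembles one sorted
#' combination table per validation condition. Results are independent of the
#' worker count: each evaluation derives its own seed from the global seed and
#' the combination, and the tables are sorted deterministically. A failing
#' evaluation is recorded (score `NA`, excluded from the tables) and the run
#' continues; `attr(result, "n_failed")` reports the failure count.
#'
#' @param combinations list of character vectors (see
#'   [enumerate_combinations()]).
#' @param evaluator `function(features, seed)` returning a named numeric
#'   vector `c(DV = ..., CV = ...)` (any subset of conditions is allowed).
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param seed global seed from which per-combination seeds are derived.
#' @return Named list of `combination_table` objects, one per condition.
#' @export
evaluate_all <- function(combinations, evaluator, workers = 1L, seed = 1L) {
  stopifnot(length(combinations) >= 1L)
  eval_one <- function(feats) {
    key <- combo_key(feats)
    res <- tryCatch(evaluator(feats, seed = derive_seed(seed, key)),
                    error = function(e) NULL)
    list(key = key, size = length(feats), scores = res)
  }
  rows <- if (workers > 1L)
    parallel::mclapply(combinations, eval_one, mc.cores = workers)
  else lapply(combinations, eval_one)
  failed <- vapply(rows, function(r) is.null(r$scores), logical(1L))
  conds <- unique(unlist(lapply(rows[!failed],
                                function(r) names(r$scores))))
  if (is.null(conds) || !length(conds))
    stop("all evaluations failed or evaluator returned unnamed scores")
  tables <- lapply(conds, function(cond) {
    df <- data.frame(
      features = vapply(rows[!failed], `[[`, character(1L), "key"),
      size = vapply(rows[!failed], `[[`, integer(1L), "size"),
      fscore = vapply(rows[!failed], function(r) unname(r$scores[cond]),
                      numeric(1L)),
      stringsAsFactors = FALSE)
    tab <- sort_table(df)
    tab$condition <- cond
    tab
  })
  names(tables) <- conds
  attr(tables, "n_failed") <- sum(failed)
  tables
}

#' Sort combination rows into a ranked combination table
#'
#' Descending F-score; ties broken by ascending combination size, then by
#' bytewise-lexicographic feature string, so ranks are deterministic.
#'
#' @param rows `data.frame` with columns `features` (";"-joined sorted names),
#'   `size` and `fscore`.
#' @return `combination_table`: the rows sorted, with a 1-based `rank` column.
#' @export
sort_table <- function(rows) {
  stopifnot(all(c("features", "size", "fscore") %in% names(rows)))
  if (anyNA(rows$fscore) || any(!is.finite(rows$fscore)))
    stop("non-finite F-score in combination rows")
  o <- order(-rows$fscore, rows$size, rows$features, method = "radix")
  out <- rows[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("combination_table", "data.frame")
  out
}

#' Feature membership lists of a combination table
#' @noRd
table_feature_sets <- function(table) {
  strsplit(table$features, ";", fixed = TRUE)
}

#' Write/read a combination table as CSV
#'
#' Columns: `rank`, `features` (";"-joined), `size`, `fscore`, `condition`.
#' @param table a `combination_table`.
#' @param path CSV path.
#' @export
write_combination_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_combination_table
#' @export
read_combination_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("combination_table", "data.frame")
  out
}
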