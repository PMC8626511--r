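# Step-2 iterative feature aggregation. Starting from the sorted combination
# table of the step-2 brute force (built over the step-1 retained features),
# each round selects the feature with the lowest fMPV among the surviving
# combinations, then keeps only the combinations containing all features
# selected so far. Positions reuse the global ranks of the initial table: the
# list is filtered, never re-sorted. At the final permitted round (the size
# limit), the criterion switches from fMPV to the best F-score among the
# surviving combinations of maximal size.

#' Iterative feature aggregation on a combination table
#'
#' @param table a `combination_table` (one validation condition).
#' @param max_size maximal vector size (default 4).
#' @return Object of class `aggregation_trace`: data.frame with one row per
#'   iteration: `iteration`, `feature` (the feature selected that round),
#'   `vector` (";"-joined accumulated vector), `size`, `n_surviving` (rows of
#'   the filtered list after selection), `fscore` (table F-score of the exact
#'   accumulated vector, `NA` if that combination was never evaluated), and
#'   `criterion` (`"fmpv"` or `"fscore"`).
#' @export
aggregate_select <- function(table, max_size = 4L) {
  if (!nrow(table)) stop("empty combination table")
  sets <- table_feature_sets(table)
  live <- rep(TRUE, nrow(table))
  selected <- character(0L)
  rows <- list()
  for (i in seq_len(max_size)) {
    cand_rows <- which(live)
    if (!length(cand_rows)) break
    if (i == max_size && max_size > 1L) {
      # final permitted round: best F-score among surviving combinations of
      # maximal size (each contains exactly one not-yet-selected feature)
      full <- cand_rows[lengths(sets[cand_rows]) == max_size]
      if (!length(full)) break
      best <- full[order(-table$fscore[full], table$features[full],
                         method = "radix")][1L]
      f_i <- setdiff(sets[[best]], selected)
      criterion <- "fscore"
    } else {
      cand_feats <- setdiff(
        unique(unlist(sets[cand_rows], use.names = FALSE)), selected)
      if (!length(cand_feats)) break
      long_feat <- unlist(sets[cand_rows], use.names = FALSE)
      long_rank <- rep.int(table$rank[cand_rows], lengths(sets[cand_rows]))
      med <- vapply(split(long_rank, long_feat), stats::median, numeric(1L))
      med <- med[names(med) %in% cand_feats]
      nm <- sort(names(med), method = "radix")  # lexicographic tie-break
      f_i <- nm[which.min(med[nm])]
      criterion <- "fmpv"
    }
    selected <- c(selected, f_i)
    live <- live & vapply(sets, function(s) all(selected %in% s), logical(1L))
    key <- combo_key(selected)
    at <- match(key, table$features)
    rows[[i]] <- data.frame(
      iteration = i, feature = f_i, vector = key, size = length(selected),
      n_surviving = sum(live),
      fscore = if (is.na(at)) NA_real_ else table$fscore[at],
      criterion = criterion, stringsAsFactors = FALSE)
    if (!any(live)) break
  }
  out <- do.call(rbind, rows)
  attr(out, "condition") <- table$condition[1L] %||% NA_character_
  class(out) <- c("aggregation_trace", "data.frame")
  out
}

#' Choose the final vector from an aggregation trace
#'
#' Among the fMPV-selected iterates whose exact vector appears in the
#' combination table, takes the one with the best F-score; ties go to the
#' smaller vector. The final-round iterate picked by the F-score criterion is
#' reported in the trace but is not itself selectable: it was not chosen for
#' its stability, only to probe the size limit.
#'
#' @param trace an `aggregation_trace`.
#' @return Character vector of feature names (sorted).
#' @export
choose_vector <- function(trace) {
  ok <- !is.na(trace$fscore) & trace$criterion == "fmpv"
  if (!any(ok)) ok <- !is.na(trace$fscore)  # degenerate one-round traces
  if (!any(ok)) stop("no iterate corresponds to an evaluated combination")
  t2 <- trace[ok, , drop = FALSE]
  best <- t2[order(-t2$fscore, t2$size), , drop = FALSE][1L, ]
  strsplit(best$vector, ";", fixed = TRUE)[[1L]]
}

#' Reconcile the vectors selected under the two validation conditions
#'
#' If the direct- and cross-validation vectors are identical as sets, that
#' vector is returned; otherwise the vector with the higher mean of its DV
#' and CV table F-scores is selected.
#'
#' @param trace_dv,trace_cv `aggregation_trace`s for the two conditions.
#' @param table_dv,table_cv the corresponding `combination_table`s, used to
#'   look up each candidate's F-score under both conditions.
#' @return Object of class `selection_outcome`: list with `vector_dv`,
#'   `vector_cv`, `final` (the selected vector), `fscores` (per condition,
#'   for the final vector), `mean_fscore`, and `rationale`
#'   (`"identical"` or `"best-F tiebreak"`).
#' @export
reconcile <- function(trace_dv, trace_cv, table_dv, table_cv) {
  v_dv <- choose_vector(trace_dv)
  v_cv <- choose_vector(trace_cv)
  lookup <- function(table, v) {
    at <- match(combo_key(v), table$features)
    if (is.na(at)) NA_real_ else table$fscore[at]
  }
  score <- function(v)
    mean(c(lookup(table_dv, v), lookup(table_cv, v)), na.rm = TRUE)
  if (setequal(v_dv, v_cv)) {
    final <- v_dv
    rationale <- "identical"
  } else {
    final <- if (score(v_dv) >= score(v_cv)) v_dv else v_cv
    rationale <- "best-F tiebreak"
  }
  structure(list(
    vector_dv = v_dv, vector_cv = v_cv, final = final,
    fscores = c(DV = lookup(table_dv, final), CV = lookup(table_cv, final)),
    mean_fscore = score(final), rationale = rationale
  ), class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("selected vector:", paste(x$final, collapse = " ; "), "\n")
  cat(sprintf("mean F-score %.4f (DV %.4f / CV %.4f), rationale: %s\n",
              x$mean_fscore, x$fscores["DV"], x$fscores["CV"], x$rationale))
  invisible(x)
}

#' Write aggregation traces and the outcome as JSON
#'
#' @param trace_dv,trace_cv `aggregation_trace`s.
#' @param outcome a `selection_outcome`.
#' @param path output JSON path.
#' @export
write_selection_report <- function(trace_dv, trace_cv, outcome, path) {
  jsonlite::write_json(list(
    trace = list(DV = as.data.frame(trace_dv), CV = as.data.frame(trace_cv)),
    vector_dv = outcome$vector_dv, vector_cv = outcome$vector_cv,
    final = outcome$final, fscores = as.list(outcome$fscores),
    mean_fscore = outcome$mean_fscore, rationale = outcome$rationale
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
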