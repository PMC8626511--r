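# The feature Median Position Value (fMPV): the median of the 1-based ranks,
# in the descending-F-score-sorted combination table, of all combinations
# containing a feature. Lower is better: a low fMPV means the feature
# concentrates in well-ranked combinations. The criterion pools naturally to
# family and space scale by merging the member features' rank vectors.

#' Ranks of all combinations containing a feature
#'
#' @param table a `combination_table`.
#' @param feature feature name.
#' @return Ascending integer vector of 1-based ranks.
#' @export
position_vector <- function(table, feature) {
  sets <- table_feature_sets(table)
  hit <- vapply(sets, function(s) feature %in% s, logical(1L))
  if (!any(hit)) stop("feature absent from every combination: ", feature)
  sort(table$rank[hit])
}

#' fMPV of a feature
#'
#' Median of the feature's position vector; for an even count, the mean of
#' the two central ranks.
#'
#' @inheritParams position_vector
#' @return The fMPV (numeric, in \[1, nrow(table)\]).
#' @export
fmpv <- function(table, feature) {
  stats::median(position_vector(table, feature))
}

#' Pooled fMPV of a feature set (family or space scale)
#'
#' Median of the concatenated position vectors of all features in the set
#' (ranks are kept with multiplicity: a combination containing two members
#' contributes its rank twice).
#'
#' @param table a `combination_table`.
#' @param feature_set character vector of feature names.
#' @return The pooled fMPV.
#' @export
pooled_fmpv <- function(table, feature_set) {
  if (!length(feature_set)) stop("empty feature set")
  pool <- unlist(lapply(feature_set, function(f) position_vector(table, f)),
                 use.names = FALSE)
  stats::median(pool)
}

#' fMPV of every feature in a table at once
#' @noRd
fmpv_all_features <- function(table) {
  sets <- table_feature_sets(table)
  long_feat <- unlist(sets, use.names = FALSE)
  long_rank <- rep.int(table$rank, lengths(sets))
  vapply(split(long_rank, long_feat), stats::median, numeric(1L))
}

#' Full fMPV report for one combination table
#'
#' Computes fMPV at the three scales (feature, family, space), the means used
#' by the family-selection rules, and the per-family pass/fail of the two
#' rules: P1, the family fMPV must be below the mean of all per-feature
#' fMPVs; P2, the fMPV of the family's space must be below the mean of all
#' space fMPVs.
#'
#' @param table a `combination_table` covering the catalog features.
#' @param catalog a [build_family_catalog()] result.
#' @param mode `"pooled"` scores a family by the pooled fMPV of its members;
#'   `"strict"` requires every member's own fMPV to pass P1.
#' @return List of class `fmpv_report` with elements `feature`, `family`,
#'   `space` (named fMPV vectors), `mean_feature`, `mean_space`, and a
#'   `selection` data.frame (family, p1, p2, selected).
#' @export
fmpv_report <- function(table, catalog, mode = c("pooled", "strict")) {
  mode <- match.arg(mode)
  feat_in_table <- unique(unlist(table_feature_sets(table), use.names = FALSE))
  missing <- setdiff(names(catalog$feature_family), feat_in_table)
  if (length(missing))
    stop("catalog/table mismatch; features never evaluated: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  feat_fmpv <- fmpv_all_features(table)
  feat_fmpv <- feat_fmpv[names(catalog$feature_family)]
  fam_fmpv <- vapply(catalog$families, function(m) pooled_fmpv(table, m),
                     numeric(1L))
  sp_fmpv <- vapply(catalog$spaces, function(m) pooled_fmpv(table, m),
                    numeric(1L))
  mean_feature <- mean(feat_fmpv)
  mean_space <- mean(sp_fmpv)
  p1 <- if (mode == "pooled") fam_fmpv < mean_feature
        else vapply(catalog$families,
                    function(m) all(feat_fmpv[m] < mean_feature), logical(1L))
  p2 <- sp_fmpv[catalog$family_space[names(catalog$families)]] < mean_space
  sel <- data.frame(
    family = names(catalog$families),
    family_fmpv = unname(fam_fmpv),
    p1 = unname(p1), p2 = unname(p2),
    selected = unname(p1 & p2),
    stringsAsFactors = FALSE)
  structure(list(feature = feat_fmpv, family = fam_fmpv, space = sp_fmpv,
                 mean_feature = mean_feature, mean_space = mean_space,
                 selection = sel, mode = mode,
                 condition = table$condition[1L] %||% NA_character_),
            class = "fmpv_report")
}

#' @export
print.fmpv_report <- function(x, ...) {
  cat(sprintf("fmpv_report (%s): mean feature fMPV %.2f, mean space fMPV %.2f\n",
              x$condition, x$mean_feature, x$mean_space))
  cat(sprintf("families passing both rules: %d / %d\n",
              sum(x$selection$selected), nrow(x$selection)))
  invisible(x)
}

#' Step-1 family selection from the two validation conditions
#'
#' Keeps, per condition, the families whose fMPV passes both rules (see
#' [fmpv_report()]), and returns the families common to direct and cross
#' validation, ordered by ascending family fMPV (averaged over conditions).
#'
#' @param table_dv,table_cv `combination_table`s for the two conditions,
#'   built over the full catalog.
#' @param catalog a [build_family_catalog()] result.
#' @param mode see [fmpv_report()].
#' @return List of class `family_selection`: `selected` (family names),
#'   `features` (their member features, catalog order), and the two
#'   `fmpv_report`s.
#' @export
select_families <- function(table_dv, table_cv, catalog,
                            mode = c("pooled", "strict")) {
  mode <- match.arg(mode)
  rep_dv <- fmpv_report(table_dv, catalog, mode)
  rep_cv <- fmpv_report(table_cv, catalog, mode)
  sel_dv <- rep_dv$selection$family[rep_dv$selection$selected]
  sel_cv <- rep_cv$selection$family[rep_cv$selection$selected]
  common <- intersect(sel_dv, sel_cv)
  avg <- (rep_dv$family[common] + rep_cv$family[common]) / 2
  common <- common[order(avg, method = "radix")]
  features <- unlist(catalog$families[names(catalog$families) %in% common],
                     use.names = FALSE)
  structure(list(selected = common, features = features,
                 report_dv = rep_dv, report_cv = rep_cv),
            class = "family_selection")
}

#' @export
print.family_selection <- function(x, ...) {
  cat(sprintf("family_selection: %d families, %d features\n",
              length(x$selected), length(x$features)))
  if (length(x$selected)) cat(paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Write an fMPV report as JSON
#' @param report an `fmpv_report`.
#' @param path output JSON path.
#' @export
write_fmpv_report <- function(report, path) {
  jsonlite::write_json(list(
    condition = report$condition, mode = report$mode,
    feature_fmpv = as.list(report$feature),
    family_fmpv = as.list(report$family),
    space_fmpv = as.list(report$space),
    mean_feature_fmpv = report$mean_feature,
    mean_space_fmpv = report$mean_space,
    selection = report$selection
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
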