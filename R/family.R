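# Feature families: the intermediate pool between feature spaces and
# individual features. A textural family groups the non-oriented variants of
# one descriptor at one spatial scale (the four orientations of a Gabor
# wavelength/part, or one Haralick statistic at one radius across the four
# directions); LBP, Mean and Variance are their own single-member families;
# each colorimetric family is its three-channel space.

#' Build the family catalog implied by a feature-bank configuration
#'
#' With a full preset this yields 34 families partitioning the 114 features:
#' 4 colorimetric families of cardinality 3, plus 30 textural families
#' (Mean, Var and 4 LBP of cardinality 1, 8 Gabor and 16 Haralick of
#' cardinality 4).
#'
#' @param config a [feature_bank_config()].
#' @return Object of class `family_catalog`: list with `families` (named list
#'   of member feature-name vectors), `family_space` (named space label per
#'   family), `feature_family` / `feature_space` (named lookups per feature)
#'   and `spaces` (named list of member features per space).
#' @export
build_family_catalog <- function(config) {
  cat_df <- feature_catalog(config)
  fam_names <- unique(cat_df$family)
  families <- lapply(fam_names, function(f) cat_df$name[cat_df$family == f])
  names(families) <- fam_names
  family_space <- vapply(fam_names, function(f)
    cat_df$space[cat_df$family == f][1L], character(1L))
  spaces <- split(cat_df$name, factor(cat_df$space, levels = unique(cat_df$space)))
  structure(list(
    families = families,
    family_space = family_space,
    feature_family = stats::setNames(cat_df$family, cat_df$name),
    feature_space = stats::setNames(cat_df$space, cat_df$name),
    spaces = spaces
  ), class = "family_catalog")
}

#' @export
print.family_catalog <- function(x, ...) {
  card <- lengths(x$families)
  cat(sprintf("family_catalog: %d features, %d families, %d spaces\n",
              sum(card), length(card), length(x$spaces)))
  invisible(x)
}

#' Family of a feature
#' @param catalog a [build_family_catalog()] result.
#' @param feature feature name string.
#' @return Family name string.
#' @export
family_of <- function(catalog, feature) {
  out <- catalog$feature_family[feature]
  if (anyNA(out)) stop("unknown feature: ",
                       paste(feature[is.na(out)], collapse = ", "))
  unname(out)
}

#' Space of a feature
#' @inheritParams family_of
#' @return Space label string.
#' @export
space_of <- function(catalog, feature) {
  out <- catalog$feature_space[feature]
  if (anyNA(out)) stop("unknown feature: ",
                       paste(feature[is.na(out)], collapse = ", "))
  unname(out)
}

#' Members of a family
#' @inheritParams family_of
#' @param family family name string.
#' @return Character vector of member feature names.
#' @export
family_members <- function(catalog, family) {
  if (!family %in% names(catalog$families)) stop("unknown family: ", family)
  catalog$families[[family]]
}

#' Export a family catalog as JSON (family -> member features)
#' @inheritParams family_of
#' @param path output JSON path.
#' @export
write_family_catalog <- function(catalog, path) {
  jsonlite::write_json(catalog$families, path, auto_unbox = FALSE)
  invisible(path)
}
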