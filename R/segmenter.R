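# Weighted random-forest pixel segmentation: pixel sampling, training and
# prediction, the class-of-interest F-score, two-fold swap validation and
# sequential depth/weight optimization. The forest itself is ranger; class
# weights strengthen the minority class of interest at split evaluation.

.class_levels <- c(background = 0L, tissue = 1L, neuron = 2L, artifact = 3L)

#' Stratified pixel sampling from labeled images
#'
#' Draws at most `per_class_cap` pixels per class from each image/mask pair,
#' reproducibly under `seed`, and assembles the feature rows into a pixel
#' dataset.
#'
#' @param stacks list of `feature_stack` objects (one per image).
#' @param masks list of `H x W` integer label matrices with values 0-3
#'   (background, tissue, neuron, artifact).
#' @param per_class_cap maximum pixels per class per image (`Inf` keeps all).
#' @param seed integer RNG seed.
#' @param ids per-image provenance identifiers (default `1..n`); give the
#'   learning and test sets disjoint ids so [two_fold()] can verify fold
#'   disjointness.
#' @return Object of class `pixel_dataset`: list with `features`
#'   (`N x F` matrix, feature names as columns), `labels` (integer vector)
#'   and `sample_id` (per-row provenance index).
#' @export
sample_pixels <- function(stacks, masks, per_class_cap = 4000L, seed = 1L,
                          ids = seq_along(stacks)) {
  stopifnot(length(stacks) == length(masks), length(stacks) >= 1L,
            length(ids) == length(stacks))
  if (per_class_cap <= 0) stop("`per_class_cap` must be positive")
  rows <- list()
  with_seed(seed, {
    for (i in seq_along(stacks)) {
      mk <- masks[[i]]
      dm <- dim(stacks[[i]]$data)
      stopifnot(nrow(mk) == dm[1L], ncol(mk) == dm[2L])
      flat <- matrix(stacks[[i]]$data, nrow = dm[1L] * dm[2L], ncol = dm[3L],
                     dimnames = list(NULL, dimnames(stacks[[i]]$data)[[3L]]))
      lab <- as.vector(mk)
      idx <- unlist(lapply(sort(unique(lab)), function(cl) {
        at <- which(lab == cl)
        if (length(at) > per_class_cap)
          at <- sort(sample(at, per_class_cap))
        at
      }), use.names = FALSE)
      rows[[i]] <- list(features = flat[idx, , drop = FALSE],
                        labels = lab[idx],
                        sample_id = rep(ids[i], length(idx)))
    }
  })
  structure(list(
    features = do.call(rbind, lapply(rows, `[[`, "features")),
    labels = unlist(lapply(rows, `[[`, "labels"), use.names = FALSE),
    sample_id = unlist(lapply(rows, `[[`, "sample_id"), use.names = FALSE)
  ), class = "pixel_dataset")
}

#' Weighted random-forest parameters
#'
#' Defaults follow the optimized operating point for the low-contrast
#' staining preset: 100 trees, maximal depth 10, neuron-class weight 2.0.
#'
#' @param n_trees number of trees.
#' @param max_depth maximal tree depth (0 = unlimited in ranger; use >= 1).
#' @param class_weights named numeric vector (names in
#'   `c("0","1","2","3")` or class labels); missing classes get weight 1.
#' @param seed integer seed threaded into training.
#' @return List of class `wrf_params`.
#' @export
wrf_params <- function(n_trees = 100L, max_depth = 10L,
                       class_weights = c("2" = 2.0), seed = 1L) {
  stopifnot(n_trees >= 1L, all(class_weights > 0))
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 class_weights = class_weights,
                 seed = as.integer(seed)), class = "wrf_params")
}

#' Train a weighted random forest on a pixel dataset
#'
#' @param dataset a [sample_pixels()] result (or compatible list).
#' @param params a [wrf_params()].
#' @param features optional character vector restricting the predictors to a
#'   feature subset.
#' @return Object of class `wrf_model` wrapping the fitted ranger forest.
#' @export
train_wrf <- function(dataset, params = wrf_params(), features = NULL) {
  x <- dataset$features
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing))
      stop("features absent from dataset: ", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  y <- factor(dataset$labels)
  if (nlevels(y) < 2L) stop("training data must contain at least 2 classes")
  cw <- rep(1, nlevels(y))
  names(cw) <- levels(y)
  hit <- intersect(names(params$class_weights), levels(y))
  cw[hit] <- params$class_weights[hit]
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = params$n_trees, max.depth = params$max_depth,
    class.weights = unname(cw), seed = params$seed, num.threads = 1L,
    verbose = FALSE)
  structure(list(fit = fit, features = colnames(x), params = params),
            class = "wrf_model")
}

#' Predict a label map (or label vector) with a trained model
#'
#' @param object a `wrf_model`.
#' @param newdata a `feature_stack`, a `pixel_dataset`, or an `N x F` matrix.
#' @param ... unused.
#' @return For a `feature_stack`, an `H x W` integer label matrix; otherwise
#'   an integer label vector.
#' @export
predict.wrf_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_stack")) {
    dm <- dim(newdata$data)
    flat <- matrix(newdata$data, nrow = dm[1L] * dm[2L], ncol = dm[3L],
                   dimnames = list(NULL, dimnames(newdata$data)[[3L]]))
    lab <- predict.wrf_model(object, flat)
    return(matrix(lab, dm[1L], dm[2L]))
  }
  x <- if (inherits(newdata, "pixel_dataset")) newdata$features else newdata
  x <- x[, object$features, drop = FALSE]
  # ranger breaks prediction ties from the RNG; pin it so prediction is a
  # pure function of (model, data)
  pred <- predict(object$fit, data = as.data.frame(x), num.threads = 1L,
                  seed = object$params$seed, verbose = FALSE)
  as.integer(as.character(pred$predictions))
}

#' F-score of the class of interest
#'
#' Harmonic mean of precision and recall for one class, pooled over all
#' pixels. Returns 0 when the class has no true positives (including when it
#' is absent from both prediction and truth).
#'
#' @param pred,truth equal-length integer label vectors (or matrices).
#' @param class_of_interest the class label scored (default 2, neuron).
#' @return F-score in \[0, 1\].
#' @export
f_score <- function(pred, truth, class_of_interest = 2L) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length")
  p <- as.vector(pred) == class_of_interest
  t <- as.vector(truth) == class_of_interest
  tp <- sum(p & t)
  if (tp == 0L) return(0)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  2 * tp / (2 * tp + fp + fn)
}

#' Two-fold swap validation
#'
#' Direct validation (DV) trains on set A and tests on set B; cross
#' validation (CV) swaps the two. The two pixel sets must come from disjoint
#' images.
#'
#' @param set_a,set_b `pixel_dataset` objects with disjoint `sample_id`s.
#' @param params a [wrf_params()].
#' @param features optional feature subset.
#' @param class_of_interest scored class (default 2, neuron).
#' @return Object of class `eval_result`: list with `fscore_dv`, `fscore_cv`,
#'   `confusion` (DV confusion table) and `params`.
#' @export
two_fold <- function(set_a, set_b, params = wrf_params(), features = NULL,
                     class_of_interest = 2L) {
  if (length(intersect(unique(set_a$sample_id), unique(set_b$sample_id))))
    stop("learning and test sets overlap (shared sample ids)")
  if (nrow(set_b$features) == 0L || nrow(set_a$features) == 0L)
    stop("empty fold")
  m_a <- train_wrf(set_a, params, features)
  pred_b <- predict(m_a, set_b)
  m_b <- train_wrf(set_b, params, features)
  pred_a <- predict(m_b, set_a)
  structure(list(
    fscore_dv = f_score(pred_b, set_b$labels, class_of_interest),
    fscore_cv = f_score(pred_a, set_a$labels, class_of_interest),
    confusion = table(pred = pred_b, truth = set_b$labels),
    params = params
  ), class = "eval_result")
}

#' Sequential sweep of tree depth, then class-of-interest weight
#'
#' Depth is optimized first at weight 1; the weight of the class of interest
#' is then swept at the chosen depth. Candidates are scored by the mean of
#' the DV and CV F-scores; ties go to the smaller candidate value. The
#' default grids are depth 2, 4, 6, 8, 10, 15, 20 and weight 1.0 to 3.0 in
#' steps of 0.5.
#'
#' @param set_a,set_b disjoint `pixel_dataset` folds.
#' @param depth_grid,weight_grid numeric candidate grids.
#' @param n_trees forest size used throughout.
#' @param seed training seed.
#' @param features optional feature subset.
#' @param class_of_interest scored (and weighted) class.
#' @return List with `best_depth`, `best_weight`, the resulting
#'   [wrf_params()], and the per-candidate score tables.
#' @export
optimize_wrf <- function(set_a, set_b,
                         depth_grid = c(2L, 4L, 6L, 8L, 10L, 15L, 20L),
                         weight_grid = c(1, 1.5, 2, 2.5, 3),
                         n_trees = 100L, seed = 1L, features = NULL,
                         class_of_interest = 2L) {
  if (!length(depth_grid) || !length(weight_grid))
    stop("candidate grids must be non-empty")
  sweep1 <- lapply(depth_grid, function(d) {
    ev <- two_fold(set_a, set_b,
                   wrf_params(n_trees, d, c(), seed), features,
                   class_of_interest)
    c(depth = d, dv = ev$fscore_dv, cv = ev$fscore_cv,
      score = (ev$fscore_dv + ev$fscore_cv) / 2)
  })
  depth_tab <- as.data.frame(do.call(rbind, sweep1))
  best_depth <- depth_tab$depth[order(-depth_tab$score, depth_tab$depth)][1L]
  sweep2 <- lapply(weight_grid, function(w) {
    cw <- stats::setNames(w, as.character(class_of_interest))
    ev <- two_fold(set_a, set_b, wrf_params(n_trees, best_depth, cw, seed),
                   features, class_of_interest)
    c(weight = w, dv = ev$fscore_dv, cv = ev$fscore_cv,
      score = (ev$fscore_dv + ev$fscore_cv) / 2)
  })
  weight_tab <- as.data.frame(do.call(rbind, sweep2))
  best_weight <-
    weight_tab$weight[order(-weight_tab$score, weight_tab$weight)][1L]
  list(best_depth = as.integer(best_depth), best_weight = best_weight,
       params = wrf_params(n_trees, best_depth,
                           stats::setNames(best_weight,
                                           as.character(class_of_interest)),
                           seed),
       depth_table = depth_tab, weight_table = weight_tab)
}

#' @rdname optimize_wrf
#' @export
optimize_depth <- function(set_a, set_b,
                           depth_grid = c(2L, 4L, 6L, 8L, 10L, 15L, 20L),
                           ...) {
  optimize_wrf(set_a, set_b, depth_grid = depth_grid, weight_grid = 1,
               ...)$best_depth
}

#' @rdname optimize_wrf
#' @export
optimize_weight <- function(set_a, set_b, depth,
                            weight_grid = c(1, 1.5, 2, 2.5, 3), ...) {
  optimize_wrf(set_a, set_b, depth_grid = depth, weight_grid = weight_grid,
               ...)$best_weight
}
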