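# Thin R interface over the compiled random forest. The classifier follows
# the common recipe (bootstrap-resampled fully grown CART trees, Gini
# impurity, sqrt(p) features per split, probability = mean of per-tree leaf
# class fractions) and is deterministic given its seed.

#' Fit a binary random forest (Gini criterion)
#'
#' @param x numeric feature matrix (n x p).
#' @param y 0/1 integer labels (1 = positive class, here "correct").
#' @param n_trees number of trees.
#' @param mtry features considered per split (default `floor(sqrt(p))`).
#' @param min_leaf minimum observations per leaf.
#' @param class_weights length-2 weights for classes 0 and 1.
#' @param seed integer seed (trees and bootstraps are derived from it).
#' @return object of class `cbci_forest`.
#' @export
rf_fit <- function(x, y, n_trees = 100L, mtry = NULL, min_leaf = 1L,
                   class_weights = c(1, 1), seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop_param("y must be 0/1")
  if (length(unique(y)) < 2) stop_param("both classes must be present")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  fit <- .rf_fit_cpp(x, y, as.integer(n_trees), as.integer(mtry),
                     as.integer(min_leaf), as.numeric(class_weights),
                     as.integer(seed))
  structure(c(fit, list(mtry = mtry, seed = seed)), class = "cbci_forest")
}

#' Predict class-1 probabilities from a fitted forest
#'
#' @param forest a `cbci_forest` from [rf_fit()].
#' @param x feature matrix with the same columns as in training.
#' @return probabilities in `[0, 1]` (mean of per-tree leaf fractions).
#' @export
rf_predict <- function(forest, x) {
  stopifnot(inherits(forest, "cbci_forest"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != forest$n_features)
    stop_param("feature count mismatch (%d vs %d)", ncol(x), forest$n_features)
  .rf_predict_cpp(forest, x)
}
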