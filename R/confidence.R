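# Per-trial decision-confidence estimation: CSP log-variance neural features,
# reconstructed RT and (optionally) reported confidence feed a cross-validated
# random forest that outputs the out-of-fold probability of the decision being
# correct. One estimator per participant; no information ever crosses the
# train/test fold boundary (CSP is refitted inside each training fold).

#' Feature schema
#'
#' Declares which inputs a confidence estimator uses. The four study schemas
#' are `"rt"`, `"rt+conf"`, `"nf+rt"` and `"nf+rt+conf"`.
#'
#' @param use_neural include CSP log-variance features.
#' @param use_rt include the reconstructed RT (seconds).
#' @param use_reported_confidence include the reported confidence (0--100).
#' @return object of class `feature_schema`.
#' @export
feature_schema <- function(use_neural = FALSE, use_rt = TRUE,
                           use_reported_confidence = FALSE) {
  if (!any(use_neural, use_rt, use_reported_confidence))
    stop_param("a feature schema must enable at least one input")
  structure(list(use_neural = use_neural, use_rt = use_rt,
                 use_reported_confidence = use_reported_confidence),
            class = "feature_schema")
}

#' Parse a schema name
#'
#' @param name one of `"rt"`, `"rt+conf"`, `"nf+rt"`, `"nf+rt+conf"`.
#' @return a [feature_schema()].
#' @export
schema_from_name <- function(name) {
  switch(name,
         "rt" = feature_schema(FALSE, TRUE, FALSE),
         "rt+conf" = feature_schema(FALSE, TRUE, TRUE),
         "nf+rt" = feature_schema(TRUE, TRUE, FALSE),
         "nf+rt+conf" = feature_schema(TRUE, TRUE, TRUE),
         stop_param("unknown schema '%s'", name))
}

schema_name <- function(schema) {
  paste0(if (schema$use_neural) "nf+" else "", "rt",
         if (schema$use_reported_confidence) "+conf" else "")
}

# Trace-normalized per-trial covariances, averaged per class.
class_covariance <- function(data3d) {
  n <- dim(data3d)[1]
  acc <- 0
  for (i in seq_len(n)) {
    x <- data3d[i, , , drop = TRUE]
    x <- x - rowMeans(x)
    ci <- tcrossprod(x) / (ncol(x) - 1)
    tr <- sum(diag(ci))
    if (tr > 0) acc <- acc + ci / tr
  }
  acc / n
}

# Ledoit-Wolf-style shrinkage intensity toward the scaled identity for an
# average of per-trial covariance estimates.
auto_shrinkage <- function(covs, cbar) {
  n <- length(covs)
  if (n < 2) return(0.1)
  num <- mean(vapply(covs, function(ci) sum((ci - cbar)^2), numeric(1))) / n
  mu <- mean(diag(cbar))
  den <- sum((cbar - diag(mu, nrow(cbar)))^2)
  if (den <= 0) return(0)
  max(0, min(1, num / den))
}

#' Fit a two-class common spatial patterns (CSP) model
#'
#' Solves the simultaneous diagonalization of the two class-average,
#' trace-normalized, shrinkage-regularized covariance matrices: generalized
#' eigenvectors of `(C_correct, C_correct + C_incorrect)`, ordered by
#' eigenvalue. The first and last components (largest variance ratio for each
#' class) are retained as features.
#'
#' @param epochs_correct,epochs_incorrect trials x channels x samples arrays
#'   (slices of an [epoch_set()]), at least two trials per class.
#' @param shrinkage shrinkage coefficient in `[0, 1]` toward the scaled
#'   identity, or `"auto"` for a Ledoit-Wolf-style estimate.
#' @return object of class `csp_model`: `projection` (channels x components,
#'   filters in columns, eigenvalue-ordered), `eigenvalues`,
#'   `kept_components` (first and last), `shrinkage`.
#' @export
fit_csp <- function(epochs_correct, epochs_incorrect, shrinkage = "auto") {
  if (dim(epochs_correct)[1] < 2 || dim(epochs_incorrect)[1] < 2)
    stop_param("CSP needs at least 2 trials per class")
  if (dim(epochs_correct)[2] != dim(epochs_incorrect)[2])
    stop_param("channel counts differ between classes")
  shrink_one <- function(data3d) {
    n <- dim(data3d)[1]
    covs <- lapply(seq_len(n), function(i) {
      x <- data3d[i, , , drop = TRUE]
      x <- x - rowMeans(x)
      ci <- tcrossprod(x) / (ncol(x) - 1)
      tr <- sum(diag(ci))
      if (tr > 0) ci / tr else ci
    })
    cbar <- Reduce(`+`, covs) / n
    g <- if (identical(shrinkage, "auto")) auto_shrinkage(covs, cbar)
         else shrinkage
    mu <- mean(diag(cbar))
    list(C = (1 - g) * cbar + g * diag(mu, nrow(cbar)), gamma = g)
  }
  s1 <- shrink_one(epochs_correct)
  s2 <- shrink_one(epochs_incorrect)
  C1 <- s1$C; C2 <- s2$C
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  pos <- ec$values > max(ec$values) * 1e-12
  P <- ec$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(ec$values[pos]), sum(pos))
  S <- t(P) %*% C1 %*% P
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- P %*% es$vectors # columns = spatial filters, eigenvalues descending
  structure(list(projection = W, eigenvalues = es$values,
                 kept_components = c(1L, ncol(W)),
                 class_order = c("correct", "incorrect"),
                 shrinkage = c(correct = s1$gamma, incorrect = s2$gamma)),
            class = "csp_model")
}

#' Extract a feature vector for one trial
#'
#' Concatenates, in fixed order: log-variance of the first and last CSP
#' components (if neural), reconstructed RT in seconds (if RT), reported
#' confidence 0--100 (if reported confidence).
#'
#' @param epoch channels x samples matrix, or `NULL` when not used.
#' @param rt reconstructed RT (s), or `NA`/`NULL`.
#' @param reported_confidence reported confidence (0--100), or `NA`/`NULL`.
#' @param csp a `csp_model` (required when `schema$use_neural`).
#' @param schema a [feature_schema()].
#' @return named numeric feature vector.
#' @export
extract_features <- function(epoch = NULL, rt = NULL,
                             reported_confidence = NULL, csp = NULL,
                             schema = feature_schema()) {
  out <- numeric(0)
  if (schema$use_neural) {
    if (is.null(epoch) || is.null(csp))
      stop_param("schema requires neural features but epoch/csp are missing")
    k <- csp$kept_components
    proj <- t(csp$projection[, k, drop = FALSE]) %*% epoch
    v <- apply(proj, 1, var)
    out <- c(out, csp_logvar1 = log(v[1]), csp_logvar2 = log(v[2]))
  }
  if (schema$use_rt) {
    if (is.null(rt) || is.na(rt)) stop_param("schema requires RT but it is missing")
    out <- c(out, rt = rt)
  }
  if (schema$use_reported_confidence) {
    if (is.null(reported_confidence) || is.na(reported_confidence))
      stop_param("schema requires reported confidence but it is missing")
    out <- c(out, reported_confidence = reported_confidence)
  }
  out
}

# Feature matrix for a set of trials under a schema (vectorized variant).
feature_matrix <- function(epochs3d, rts, confs, csp, schema) {
  n <- length(rts)
  cols <- list()
  if (schema$use_neural) {
    k <- csp$kept_components
    Wk <- csp$projection[, k, drop = FALSE]
    lv <- t(vapply(seq_len(n), function(i) {
      proj <- t(Wk) %*% epochs3d[i, , , drop = TRUE]
      log(apply(proj, 1, var))
    }, numeric(2)))
    cols$csp_logvar1 <- lv[, 1]; cols$csp_logvar2 <- lv[, 2]
  }
  if (schema$use_rt) cols$rt <- rts
  if (schema$use_reported_confidence) cols$reported_confidence <- confs
  do.call(cbind, cols)
}

# Stratified k-fold assignment (by label), seeded; retries if any training
# set would be single-class.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  for (attempt in 0:9) {
    fold <- integer(n)
    with_seed(derive_seed(seed, attempt), {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep(seq_len(k), length.out = length(idx))
      }
    })
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- labels[fold != f]
      length(unique(tr)) == 2 && min(table(tr)) >= 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop_param("could not build %d-fold stratified partition with two classes per training set", k)
}

#' Fit a cross-validated confidence estimator for one participant
#'
#' Eight-fold stratified cross-validation: in each fold a CSP projection is
#' fitted on the training trials only (when the schema uses neural features),
#' features are extracted, and a random forest (100 trees, Gini criterion) is
#' fitted on the training folds; each trial's confidence is the out-of-fold
#' predicted probability of the decision being correct.
#'
#' @param epochs an [epoch_set()] (conditioned, 32 Hz) for the participant,
#'   or `NULL` for behavioural-only schemas.
#' @param rts reconstructed RTs (s), aligned with trials.
#' @param reported_confidences reported confidences (0--100), aligned.
#' @param labels `"correct"`/`"incorrect"` per trial.
#' @param schema a [feature_schema()] or schema name.
#' @param seed integer seed fixing folds and forests.
#' @param n_folds number of cross-validation folds.
#' @param n_trees forest size.
#' @param class_weights `"balanced"` (inverse-frequency) or `"none"`.
#' @param shrinkage CSP covariance shrinkage (see [fit_csp()]).
#' @return object of class `confidence_estimator` with per-trial out-of-fold
#'   `confidences` in `[0, 1]`, `folds`, per-fold `csp` models and forests.
#' @export
fit_confidence <- function(epochs = NULL, rts, reported_confidences = NULL,
                           labels, schema = "nf+rt", seed = 1L,
                           n_folds = 8L, n_trees = 100L,
                           class_weights = c("balanced", "none"),
                           shrinkage = "auto") {
  if (is.character(schema)) schema <- schema_from_name(schema)
  class_weights <- match.arg(class_weights)
  n <- length(labels)
  if (n < n_folds) stop_param("need at least %d trials", n_folds)
  if (!all(labels %in% c("correct", "incorrect")))
    stop_param("labels must be 'correct'/'incorrect'")
  if (schema$use_neural && (is.null(epochs) || dim(epochs$data)[1] != n))
    stop_param("neural schema requires epochs aligned with labels")
  if (schema$use_rt && (length(rts) != n || anyNA(rts)))
    stop_param("RT schema requires complete RTs")
  if (schema$use_reported_confidence &&
      (is.null(reported_confidences) || anyNA(reported_confidences)))
    stop_param("schema requires complete reported confidences")

  y <- as.integer(labels == "correct")
  fold <- stratified_folds(labels, n_folds, seed)
  cw <- if (class_weights == "balanced") {
    tab <- table(factor(y, levels = 0:1))
    as.numeric(sum(tab) / (2 * pmax(tab, 1)))
  } else c(1, 1)

  confidences <- rep(NA_real_, n)
  csp_models <- vector("list", n_folds)
  forests <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    csp <- NULL
    if (schema$use_neural) {
      c_idx <- tr[labels[tr] == "correct"]
      i_idx <- tr[labels[tr] == "incorrect"]
      if (length(c_idx) < 2 || length(i_idx) < 2)
        stop_param("insufficient trials per class for CSP in fold %d", f)
      csp <- fit_csp(epochs$data[c_idx, , , drop = FALSE],
                     epochs$data[i_idx, , , drop = FALSE], shrinkage)
    }
    X <- feature_matrix(epochs$data, rts, reported_confidences, csp, schema)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    forest <- rf_fit(Xtr, y[tr], n_trees = n_trees,
                     class_weights = cw, seed = derive_seed(seed, f))
    confidences[te] <- rf_predict(forest, Xte)
    csp_models[[f]] <- csp
    forests[[f]] <- forest
  }
  structure(list(schema = schema, schema_name = schema_name(schema),
                 confidences = confidences, folds = fold,
                 csp_models = csp_models, forests = forests,
                 forest_params = list(n_trees = n_trees,
                                      split_criterion = "gini",
                                      class_weights = class_weights),
                 labels = labels, seed = seed),
            class = "confidence_estimator")
}

#' Class separation of confidences
#'
#' @param confidences numeric confidences (any scale).
#' @param labels `"correct"`/`"incorrect"` per trial.
#' @return list with `mean_correct`, `mean_incorrect`, `difference` (`NA`
#'   difference for single-class input).
#' @export
confidence_separation <- function(confidences, labels) {
  mc <- mean(confidences[labels == "correct"])
  mi <- mean(confidences[labels == "incorrect"])
  diff <- if (any(labels == "correct") && any(labels == "incorrect"))
    mc - mi else NA_real_
  list(mean_correct = mc, mean_incorrect = mi, difference = diff)
}
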