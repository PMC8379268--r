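# CSP and the cross-validated confidence estimator.

# Brute-force generalized eigendecomposition oracle for CSP on given
# covariance matrices: eig(C1, C1 + C2) via explicit solve().
csp_oracle <- function(C1, C2) {
  M <- solve(C1 + C2, C1)
  e <- eigen(M)
  list(values = Re(e$values), vectors = Re(e$vectors))
}

# Generate a trials x channels x samples array with per-channel SDs.
toy_epochs <- function(n_trials, sds, n_samp = 200) {
  out <- array(0, dim = c(n_trials, length(sds), n_samp))
  for (i in seq_len(n_trials))
    for (ch in seq_along(sds))
      out[i, ch, ] <- rnorm(n_samp, 0, sds[ch])
  out
}

test_that("CSP matches the closed-form eigen oracle on constructed data", {
  set.seed(4)
  # class A varies along axis 1, class B along axis 2
  a <- toy_epochs(40, c(3, 0.3))
  b <- toy_epochs(40, c(0.3, 3))
  m <- fit_csp(a, b, shrinkage = 0)
  w1 <- m$projection[, 1] / sqrt(sum(m$projection[, 1]^2))
  w2 <- m$projection[, 2] / sqrt(sum(m$projection[, 2]^2))
  expect_gt(abs(w1[1]), 0.99) # first filter ~ axis 1
  expect_gt(abs(w2[2]), 0.99) # last filter ~ axis 2
  expect_equal(m$kept_components, c(1L, 2L))

  # projection applied to training data: component variance ratio matches
  # the eigenvalue lambda/(1-lambda) relation of the composite problem
  C1 <- cbci:::class_covariance(a); C2 <- cbci:::class_covariance(b)
  orc <- csp_oracle(C1, C2)
  expect_equal(sort(m$eigenvalues), sort(orc$values), tolerance = 1e-8)
  # filters diagonalize both covariances simultaneously (up to scale)
  W <- m$projection
  d1 <- t(W) %*% C1 %*% W
  expect_lt(max(abs(d1[upper.tri(d1)])), 1e-8)
  expect_equal(diag(d1), m$eigenvalues, tolerance = 1e-8)

  # random 4-channel covariances: eigenvalues match the oracle exactly
  for (rep in 1:5) {
    x1 <- toy_epochs(30, runif(4, 0.5, 2))
    x2 <- toy_epochs(30, runif(4, 0.5, 2))
    mm <- fit_csp(x1, x2, shrinkage = 0)
    oo <- csp_oracle(cbci:::class_covariance(x1), cbci:::class_covariance(x2))
    expect_equal(sort(mm$eigenvalues), sort(oo$values), tolerance = 1e-8)
  }

  # identical class covariances: eigenvalues all ~ 0.5
  x <- toy_epochs(60, c(1, 1, 1))
  m0 <- fit_csp(x[1:30, , ], x[31:60, , ], shrinkage = 0.2)
  expect_equal(m0$eigenvalues, rep(0.5, 3), tolerance = 0.1)
  expect_error(fit_csp(x[1, , , drop = FALSE], x[1:5, , ]), "2 trials")
})

test_that("feature extraction follows the schema contract", {
  set.seed(5)
  ep <- matrix(rnorm(2 * 300), 2, 300)
  csp <- fit_csp(toy_epochs(20, c(2, 0.5)), toy_epochs(20, c(0.5, 2)),
                 shrinkage = 0)
  f <- extract_features(ep, rt = 0.63, reported_confidence = 70, csp = csp,
                        schema = feature_schema(TRUE, TRUE, TRUE))
  expect_named(f, c("csp_logvar1", "csp_logvar2", "rt", "reported_confidence"))
  # doubling the signal adds log(4) to each log-variance feature
  f2 <- extract_features(2 * ep, rt = 0.63, reported_confidence = 70,
                         csp = csp, schema = feature_schema(TRUE, TRUE, TRUE))
  expect_equal(f2[1:2] - f[1:2], c(csp_logvar1 = log(4), csp_logvar2 = log(4)),
               tolerance = 1e-10)
  # unit-variance components give log-variance 0
  csp_id <- csp
  csp_id$projection <- diag(2)
  ep_unit <- rbind(rnorm(5000), rnorm(5000))
  ep_unit <- ep_unit / apply(ep_unit, 1, sd)
  f0 <- extract_features(ep_unit, rt = 1, schema = feature_schema(TRUE, TRUE),
                         csp = csp_id)
  expect_equal(unname(f0[1:2]), c(0, 0), tolerance = 1e-10)
  # schema {rt}: length-1 vector; missing inputs error
  expect_length(extract_features(rt = 0.4, schema = feature_schema(use_rt = TRUE)), 1)
  expect_error(extract_features(rt = NA, schema = feature_schema(use_rt = TRUE)),
               "RT")
  expect_error(feature_schema(FALSE, FALSE, FALSE), "at least one")
})

test_that("cross-validated confidences are out-of-fold, bounded, deterministic", {
  set.seed(6)
  n <- 160
  labels <- rep(c("correct", "incorrect"), c(120, 40))[sample(n)]
  # separable RTs: incorrect much slower
  rts <- ifelse(labels == "correct", rnorm(n, 0.5, 0.05), rnorm(n, 1.5, 0.05))
  est <- fit_confidence(rts = rts, labels = labels, schema = "rt", seed = 3)
  expect_true(all(est$confidences >= 0 & est$confidences <= 1))
  expect_gt(mean(est$confidences[labels == "correct"]), 0.9)
  expect_lt(mean(est$confidences[labels == "incorrect"]), 0.1)
  # folds: stratified 8-fold, every trial held out exactly once
  expect_equal(sort(unique(est$folds)), 1:8)
  expect_true(all(table(est$folds, labels)[, "incorrect"] >= 4))
  # determinism
  est2 <- fit_confidence(rts = rts, labels = labels, schema = "rt", seed = 3)
  expect_identical(est$confidences, est2$confidences)
  expect_identical(est$folds, est2$folds)

  # shuffled labels (null): separation within the permutation band
  labs_null <- sample(labels)
  est0 <- fit_confidence(rts = rts, labels = labs_null, schema = "rt", seed = 3)
  sep0 <- confidence_separation(est0$confidences, labs_null)$difference
  perm <- replicate(200, {
    l <- sample(labs_null)
    confidence_separation(est0$confidences, l)$difference
  })
  expect_lt(abs(sep0), quantile(abs(perm), 0.99) + 0.05)
})

test_that("confidence_separation handles the edge cases", {
  expect_equal(confidence_separation(rep(0.7, 5),
                                     rep(c("correct", "incorrect"), c(3, 2)))$difference, 0)
  expect_equal(confidence_separation(c(1, 1, 0, 0),
                                     c("correct", "correct", "incorrect", "incorrect"))$difference, 1)
  expect_true(is.na(confidence_separation(c(0.5, 0.6),
                                          c("correct", "correct"))$difference))
})

test_that("neural schema uses per-fold CSP without leakage", {
  run <- small_run()
  est <- run$estimators$P01$`nf+rt`
  # one CSP per fold, each fitted on its own training folds
  expect_length(est$csp_models, 8)
  expect_true(all(!vapply(est$csp_models, is.null, logical(1))))
  # projections differ across folds (different training data)
  p1 <- est$csp_models[[1]]$projection
  p2 <- est$csp_models[[2]]$projection
  expect_false(isTRUE(all.equal(p1, p2)))
})
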