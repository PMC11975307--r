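# -- PCA ---------------------------------------------------------------

test_that("rank-1 structure puts all variance on PC1", {
  set.seed(1)
  x <- rnorm(40)
  lm <- make_labeled(cbind(a = x, b = 2 * x), rep(c("BLB", "PLP"), 20))
  res <- pca_integrate(lm)
  expect_equal(explained_variance(res)[1], 1, tolerance = 1e-12)

  lm2 <- make_labeled(cbind(a = x, b = -x), rep(c("BLB", "PLP"), 20))
  res2 <- pca_integrate(lm2)
  expect_equal(explained_variance(res2)[1], 1, tolerance = 1e-12)
  rot <- attr(res2, "model")$rotation
  expect_lt(rot[1, 1] * rot[2, 1], 0) # opposite-signed loadings
})

test_that("PCA reconstruction is exact and variance fractions are coherent", {
  set.seed(2)
  lm <- make_labeled(matrix(rnorm(200), 50, 4), rep(c("BLB", "PLP"), 25))
  res <- pca_integrate(lm)
  mdl <- attr(res, "model")
  recon <- mdl$pc_scores %*% t(mdl$rotation)
  recon <- sweep(recon, 2, mdl$center, "+")
  expect_equal(unname(recon), unname(score_values(lm)), tolerance = 1e-9)
  ev <- explained_variance(res)
  expect_equal(sum(ev), 1, tolerance = 1e-12)
  expect_true(all(diff(ev) <= 1e-12)) # non-increasing
})

test_that("PC1 sign follows the abnormal-low convention and errors are fatal", {
  st <- make_paperlike_study(seed = 4)
  lm <- assemble_labeled_matrix(harmonized_matrix(st), st$truth)
  res <- pca_integrate(lm)
  expect_lt(
    mean(res$integrated_score[lm$label == "PLP"]),
    mean(res$integrated_score[lm$label == "BLB"])
  )
  # two latent mechanisms -> two leading components dominate
  expect_gt(sum(explained_variance(res)[1:2]), 0.85)

  const <- make_labeled(cbind(a = rnorm(10), b = rep(1, 10)),
    rep(c("BLB", "PLP"), 5)
  )
  expect_error(pca_integrate(const), "constant")
  gap <- make_labeled(cbind(a = c(NA, rnorm(9)), b = rnorm(10)),
    rep(c("BLB", "PLP"), 5)
  )
  expect_error(pca_integrate(gap), "complete")
})

# -- K-means -----------------------------------------------------------

test_that("well-separated blobs split at the gap with centroids near means", {
  set.seed(3)
  x <- matrix(c(rnorm(15, 0, 0.3), rnorm(15, 10, 0.3)), ncol = 1)
  rownames(x) <- sprintf("v%d", 1:30)
  res <- kmeans_integrate(x, k = 2, seed = 1, n_restarts = 10)
  cl <- res$predicted_class
  expect_equal(length(unique(cl[1:15])), 1)
  expect_equal(length(unique(cl[16:30])), 1)
  expect_lt(max(abs(sort(attr(res, "model")$centers[, 1]) - c(0, 10))), 0.3)
  # lower-centroid cluster is the functionally abnormal one
  expect_equal(unique(cl[1:15]), "functionally_abnormal")
})

test_that("identical points cannot be clustered", {
  x <- matrix(1, 8, 2)
  expect_error(kmeans_integrate(x, k = 2, seed = 1), "degenerate")
})

test_that("k-means attains the exhaustive-search optimum for small n", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(2 * n), n, 2)
    rownames(x) <- sprintf("v%d", seq_len(n))
    res <- kmeans_integrate(x, k = 2, seed = i, n_restarts = 50)
    expect_equal(attr(res, "model")$tot_withinss, best_two_partition_wss(x),
      tolerance = 1e-8
    )
  }
})

# -- Naive Bayes -------------------------------------------------------

test_that("naive Bayes fit matches hand arithmetic", {
  lm <- make_labeled(
    matrix(c(0, 2, 8, 10), ncol = 1),
    c("BLB", "BLB", "PLP", "PLP")
  )
  model <- naive_bayes_fit(lm)
  expect_equal(model$priors, c(0.5, 0.5))
  expect_equal(unname(model$means[, 1]), c(1, 9))
  # sample-variance (n-1) convention: var({0,2}) = var({8,10}) = 2
  expect_equal(unname(model$vars[, 1]), c(2, 2))
})

test_that("training priors equal label proportions", {
  set.seed(5)
  lm <- make_labeled(
    matrix(rnorm(96 * 2), 96, 2),
    c(rep("BLB", 19), rep("PLP", 77))
  )
  model <- naive_bayes_fit(lm)
  expect_equal(model$priors, c(19 / 96, 77 / 96))
})

test_that("zero-variance features are floored with a warning", {
  lm <- make_labeled(
    cbind(a = c(1, 1, 5, 6), b = c(0, 1, 5, 6)),
    c("BLB", "BLB", "PLP", "PLP")
  )
  expect_warning(model <- naive_bayes_fit(lm), "floor")
  expect_equal(model$vars["BLB", "a"], 1e-6)
  expect_error(
    naive_bayes_fit(make_labeled(matrix(1:4, 4, 1), rep("PLP", 4))),
    "both classes"
  )
})

test_that("posteriors follow symmetry, priors, and the brute-force oracle", {
  lm <- make_labeled(
    matrix(c(0, 2, 8, 10), ncol = 1),
    c("BLB", "BLB", "PLP", "PLP")
  )
  model <- naive_bayes_fit(lm)
  mid <- matrix(5, 1, 1, dimnames = list("x", "assay1"))
  expect_equal(naive_bayes_predict(model, mid)$posterior, 0.5)
  expect_equal(naive_bayes_predict(model, mid)$predicted_class,
    "functionally_normal" # tie called conservatively
  )

  # uninformative likelihood returns the prior
  model2 <- model
  model2$priors <- c(0.8, 0.2)
  model2$means[] <- 0
  model2$vars[] <- 1
  expect_equal(
    naive_bayes_predict(model2, matrix(0.3, 1, 1,
      dimnames = list("x", "assay1")
    ))$posterior,
    0.2,
    tolerance = 1e-12
  )

  # 2-feature model vs independent density arithmetic
  set.seed(6)
  lm2 <- make_labeled(
    rbind(
      matrix(rnorm(20, 0, 1), 10, 2),
      matrix(rnorm(20, 3, 1.5), 10, 2)
    ),
    rep(c("BLB", "PLP"), each = 10)
  )
  m2 <- naive_bayes_fit(lm2)
  xnew <- matrix(c(1.2, 2.5), 1, 2, dimnames = list("q", m2$features))
  expect_equal(
    naive_bayes_predict(m2, xnew)$posterior,
    nb_posterior_oracle(as.numeric(xnew), m2$priors, m2$means, m2$vars),
    tolerance = 1e-9
  )
})

test_that("posteriors stay normalized under extreme log-likelihood offsets", {
  # scores hundreds of SDs from both class means drive every density to
  # underflow territory; log-space evaluation must keep posteriors proper
  lm <- make_labeled(
    matrix(c(0, 0.01, 1, 1.01, 0.1, 0.11, 0.9, 0.91), ncol = 2),
    c("BLB", "BLB", "PLP", "PLP")
  )
  suppressWarnings(model <- naive_bayes_fit(lm, variance_floor = 1e-6))
  far <- matrix(c(1e2, -1e2), 1, 2, dimnames = list("far", model$features))
  p <- naive_bayes_predict(model, far)$posterior
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  # log-likelihoods here are ~ -1e4 scale per class
  expect_equal(p + (1 - p), 1)
})

test_that("naive Bayes agrees with an established implementation", {
  skip_if_not_installed("e1071")
  st <- make_paperlike_study(seed = 8)
  lm <- assemble_labeled_matrix(harmonized_matrix(st), st$truth)
  sp <- split_train_test(lm, 0.6, seed = 1)
  model <- naive_bayes_fit(sp$train)
  mine <- naive_bayes_predict(model, sp$test)$posterior
  ref <- e1071::naiveBayes(
    score_values(sp$train), factor(sp$train$label, c("BLB", "PLP"))
  )
  theirs <- stats::predict(ref, score_values(sp$test),
    type = "raw", threshold = 0, eps = 0
  )[, "PLP"]
  expect_equal(mine, unname(theirs), tolerance = 1e-6)
})

# -- Random forest -----------------------------------------------------

test_that("forest votes are deterministic, bounded, and separate clean data", {
  set.seed(7)
  xtr <- matrix(c(rnorm(20, 0, 0.2), rnorm(20, 5, 0.2)), ncol = 1)
  lab <- rep(c("PLP", "BLB"), each = 20)
  train <- make_labeled(xtr, lab)
  xte <- matrix(c(-0.5, 0.2, 4.8, 5.5), ncol = 1)
  test <- make_labeled(xte, c("PLP", "PLP", "BLB", "BLB"))
  r1 <- forest_fit_predict(train, test, n_trees = 200, seed = 5)
  r2 <- forest_fit_predict(train, test, n_trees = 200, seed = 5)
  expect_identical(r1$posterior, r2$posterior)
  expect_true(all(r1$posterior >= 0 & r1$posterior <= 1))
  te <- r1[!r1$in_train, ]
  expect_equal(te$posterior[1:2], c(1, 1), tolerance = 0.02)
  expect_equal(te$posterior[3:4], c(0, 0), tolerance = 0.02)
  expect_error(forest_fit_predict(train, test, n_trees = 0, seed = 1), "n_trees")
})

test_that("permuted labels give held-out accuracy near the majority rate", {
  set.seed(8)
  n <- 120
  x <- matrix(rnorm(2 * n), n, 2)
  lab <- sample(rep(c("BLB", "PLP"), times = c(40, 80)))
  lm <- make_labeled(x, lab)
  sp <- split_train_test(lm, 0.6, seed = 2)
  res <- forest_fit_predict(sp$train, sp$test, n_trees = 300, seed = 2)
  te <- dplyr::inner_join(
    tidy(res)[!res$in_train, ],
    dplyr::select(tibble::as_tibble(lm), "variant", "label"),
    by = "variant"
  )
  acc <- mean((te$predicted_class == "functionally_abnormal") == (te$label == "PLP"))
  # majority rate 2/3; allow ~3 binomial SD on n = 48
  expect_lt(abs(acc - 2 / 3), 3 * sqrt(2 / 9 / nrow(te)) + 0.05)
})

test_that("training accuracy dominates held-out accuracy on average", {
  accs <- sapply(1:5, function(s) {
    st <- make_paperlike_study(seed = 100 + s)
    lm <- assemble_labeled_matrix(harmonized_matrix(st), st$truth)
    sp <- split_train_test(lm, 0.6, seed = s)
    res <- forest_fit_predict(sp$train, sp$test, n_trees = 200, seed = s)
    fit <- attr(res, "model")$fit
    resub <- stats::predict(fit, score_values(sp$train))
    tr_acc <- mean(as.character(resub) == sp$train$label)
    te <- dplyr::inner_join(
      tidy(res)[!res$in_train, ],
      dplyr::select(tibble::as_tibble(lm), "variant", "label"),
      by = "variant"
    )
    te_acc <- mean(
      (te$predicted_class == "functionally_abnormal") == (te$label == "PLP")
    )
    c(tr_acc, te_acc)
  })
  expect_gte(mean(accs[1, ]), mean(accs[2, ]))
})

# -- Cross-validation --------------------------------------------------

test_that("cross-validation predicts each variant exactly once, out of fold", {
  st <- make_paperlike_study(seed = 9)
  lm <- assemble_labeled_matrix(harmonized_matrix(st), st$truth)
  cv <- cross_validate("naive_bayes", lm, "kfold", k = 5, seed = 1)
  expect_equal(sort(cv$predictions$variant), sort(lm$variant))
  expect_equal(nrow(cv$folds), 5)
  expect_gt(cv$pooled$accuracy, 0.9)
})

test_that("leave-one-out yields singleton folds and respects the cap", {
  lm <- make_labeled(
    matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1),
    rep(c("PLP", "BLB"), each = 3)
  )
  cv <- cross_validate("naive_bayes", lm, "loo", seed = 1)
  expect_equal(nrow(cv$folds), 6)
  expect_true(all(cv$folds$n == 1))
  expect_equal(cv$pooled$accuracy, 1) # perfectly separated toy data
  expect_error(
    cross_validate("naive_bayes", lm, "loo", loo_cap = 4), "cap"
  )
})
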