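# Random-forest integration: an ensemble of decision trees fit on
# bootstrap resamples with random feature subsetting, via the randomForest
# package. The per-variant integrated score is the fraction of trees voting
# pathogenic; training rows are scored by their out-of-bag votes so the
# training half is not trivially memorized.

#' Fit a random forest on the training half and score all variants
#'
#' @param train,test `mave_labeled` halves from [split_train_test()].
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; results are deterministic given it.
#' @return A `mave_integration`: `posterior` is the fraction of trees
#'   voting PLP (out-of-bag for training rows), `integrated_score` is its
#'   complement so lower = more abnormal, and `predicted_class` is the
#'   majority vote with ties called `functionally_normal`.
#' @export
forest_fit_predict <- function(train, test, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(train, "mave_labeled"), inherits(test, "mave_labeled"))
  if (n_trees < 1) abort("n_trees must be >= 1")
  if (!identical(assay_ids(train), assay_ids(test))) {
    abort("train and test matrices must share the same assay columns")
  }
  ytr <- factor(train$label, levels = c("BLB", "PLP"))
  if (any(table(ytr) == 0)) abort("both classes must be present in training data")
  xtr <- score_values(train)
  xte <- score_values(test)
  if (anyNA(xtr) || anyNA(xte)) abort("random forest requires complete matrices")
  fit <- with_stream(seed, 37L, randomForest::randomForest(
    x = xtr, y = ytr, ntree = n_trees
  ))
  vote_tr <- fit$votes[, "PLP"] # out-of-bag vote fractions
  vote_te <- stats::predict(fit, xte, type = "vote", norm.votes = TRUE)[, "PLP"]
  tbl <- dplyr::bind_rows(
    tibble(variant = train$variant, posterior = as.numeric(vote_tr), in_train = TRUE),
    tibble(variant = test$variant, posterior = as.numeric(vote_te), in_train = FALSE)
  ) |>
    dplyr::mutate(
      method = "random_forest",
      integrated_score = 1 - .data$posterior,
      predicted_class = ifelse(.data$posterior > 0.5, class_abnormal, class_normal)
    ) |>
    dplyr::select(
      "variant", "method", "integrated_score", "predicted_class",
      "posterior", "in_train"
    )
  new_integration(tbl, "random_forest", seed = as.integer(seed), model = list(
    n_trees = n_trees, importance = fit$importance, oob_err = fit$err.rate,
    fit = fit
  ))
}
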