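# Stratified cross-validation for the supervised integrators: every
# labeled variant is predicted exactly once, out of fold, guarding against
# the overfitting a single train/test split can hide on small truth sets.

#' Cross-validate a supervised integration method
#'
#' @param method `"naive_bayes"` or `"random_forest"`.
#' @param lm A `mave_labeled` matrix.
#' @param scheme `"kfold"` (stratified) or `"loo"` (leave-one-out).
#' @param k Number of folds for `"kfold"` (default 5); must not exceed the
#'   smaller class count.
#' @param seed Integer seed for fold assignment (and the forest).
#' @param loo_cap Refuse leave-one-out above this many variants (default
#'   200) and direct the caller to k-fold instead.
#' @param ... Passed to the underlying fit (`variance_floor`, `n_trees`).
#' @return List with `folds` (tibble of per-fold metrics), `pooled`
#'   (metrics over all out-of-fold predictions) and `predictions`.
#' @export
cross_validate <- function(method = c("naive_bayes", "random_forest"),
                           lm, scheme = c("kfold", "loo"), k = 5L,
                           seed = 1L, loo_cap = 200L, ...) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  stopifnot(inherits(lm, "mave_labeled"))
  n <- nrow(lm)
  if (scheme == "loo") {
    if (n > loo_cap) {
      abort(paste0(
        "leave-one-out on ", n, " variants exceeds the cap (", loo_cap,
        "); use scheme = 'kfold'"
      ))
    }
    fold <- seq_len(n)
    k <- n
  } else {
    if (k > min(table(lm$label))) {
      abort("k must not exceed the smaller class count for stratified folds")
    }
    pri <- with_stream(seed, 41L, stats::runif(n))
    fold <- integer(n)
    for (cl in unique(lm$label)) {
      idx <- which(lm$label == cl)
      fold[idx[order(pri[idx])]] <- rep_len(seq_len(k), length(idx))
    }
  }
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- relabel_matrix(lm, which(fold != f))
    test_rows <- which(fold == f)
    test <- lm[test_rows, , drop = FALSE]
    for (a in c("assays", "provenance")) attr(test, a) <- attr(lm, a)
    class(test) <- class(lm)
    if (method == "naive_bayes") {
      model <- naive_bayes_fit(train, ...)
      p <- naive_bayes_predict(model, test)
    } else {
      ytr <- factor(train$label, levels = c("BLB", "PLP"))
      fit <- with_stream(seed, 37L + f, randomForest::randomForest(
        x = score_values(train), y = ytr, ...
      ))
      vote <- stats::predict(fit, score_values(test),
        type = "vote", norm.votes = TRUE
      )[, "PLP"]
      p <- tibble(
        variant = test$variant, posterior = as.numeric(vote),
        predicted_class = ifelse(vote > 0.5, class_abnormal, class_normal)
      )
    }
    p$fold <- f
    p$label <- test$label
    preds[[f]] <- p
  }
  preds <- dplyr::bind_rows(preds)
  fold_metrics <- preds |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(
        as_positive_call(.data$predicted_class) == (.data$label == "PLP")
      ),
      .groups = "drop"
    )
  pooled <- classification_metrics(
    confusion_matrix(preds$predicted_class, preds$label)
  )
  list(folds = fold_metrics, pooled = pooled, predictions = preds)
}
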