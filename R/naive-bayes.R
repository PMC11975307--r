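# Gaussian naive Bayes: each assay's score is modelled as an independent
# one-dimensional Gaussian within each truth class. The posterior
# probability of pathogenicity is computed in log space for numerical
# stability; class-conditional variances are floored to keep densities
# proper when a class shows no spread in one assay.

#' Fit a Gaussian naive Bayes classifier on a labeled training matrix
#'
#' Class priors are the training label proportions; per class and per assay
#' a Gaussian is fit by sample mean and sample variance (denominator
#' `n - 1`), floored at `variance_floor`.
#'
#' @param train A `mave_labeled` training matrix with both classes present
#'   and at least two members per class.
#' @param variance_floor Minimum class-conditional variance (default 1e-6
#'   on the rescaled score scale).
#' @return An `nb_model`: list with `classes`, `priors`, `means`, `vars`
#'   (class-by-assay matrices), `features`, `variance_floor`.
#' @export
naive_bayes_fit <- function(train, variance_floor = 1e-6) {
  stopifnot(inherits(train, "mave_labeled"))
  classes <- c("BLB", "PLP")
  counts <- table(factor(train$label, levels = classes))
  if (any(counts == 0)) abort("both classes must be present in training data")
  if (any(counts < 2)) abort("need >= 2 training members per class")
  x <- score_values(train)
  if (anyNA(x)) abort("naive Bayes training requires a complete matrix")
  means <- vars <- matrix(NA_real_, 2, ncol(x),
    dimnames = list(classes, colnames(x))
  )
  for (cl in classes) {
    xc <- x[train$label == cl, , drop = FALSE]
    means[cl, ] <- colMeans(xc)
    vars[cl, ] <- apply(xc, 2, stats::var)
  }
  floored <- vars < variance_floor
  if (any(floored)) {
    warn(paste0(
      "variance floor applied to ", sum(floored),
      " class/assay cell(s) with near-zero spread"
    ))
    vars[floored] <- variance_floor
  }
  structure(
    list(
      classes = classes,
      priors = as.numeric(counts) / sum(counts),
      means = means, vars = vars,
      features = colnames(x), variance_floor = variance_floor
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(
    "<nb_model> Gaussian naive Bayes:", length(x$features), "assays;",
    "priors BLB/PLP =", paste(signif(x$priors, 3), collapse = "/"), "\n"
  )
  invisible(x)
}

#' Posterior probability of pathogenicity under a naive Bayes model
#'
#' The posterior is proportional to prior times the product over assays of
#' the class-conditional Gaussian densities, normalized over the two
#' classes and evaluated in log space. A posterior exactly at 0.5 is
#' conservatively called `functionally_normal`.
#'
#' @param model An `nb_model`.
#' @param m A `mave_matrix`/`mave_labeled` (or numeric matrix) whose assay
#'   columns match the model's features.
#' @return Tibble with `variant`, `posterior` (P(pathogenic)) and
#'   `predicted_class`.
#' @export
naive_bayes_predict <- function(model, m) {
  stopifnot(inherits(model, "nb_model"))
  x <- if (inherits(m, "mave_matrix")) score_values(m) else as.matrix(m)
  if (!identical(colnames(x), model$features)) {
    if (!all(model$features %in% colnames(x))) {
      abort("feature mismatch: matrix columns do not match model features")
    }
    x <- x[, model$features, drop = FALSE]
  }
  if (anyNA(x)) abort("naive Bayes prediction requires a complete matrix")
  loglik <- vapply(seq_along(model$classes), function(ci) {
    ll <- log(model$priors[ci])
    for (j in seq_along(model$features)) {
      ll <- ll + stats::dnorm(
        x[, j], model$means[ci, j], sqrt(model$vars[ci, j]), log = TRUE
      )
    }
    ll
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) loglik <- matrix(loglik, nrow = 1)
  post <- unname(exp(loglik[, 2] - apply(loglik, 1, logsumexp)))
  tibble(
    variant = rownames(x) %||% as.character(seq_len(nrow(x))),
    posterior = post,
    predicted_class = ifelse(post > 0.5, class_abnormal, class_normal)
  )
}

#' Train/test naive Bayes integration over a labeled matrix
#'
#' Convenience wrapper: fits on the training half and predicts the full
#' variant list, recording which rows were used for training.
#'
#' @param train,test `mave_labeled` halves from [split_train_test()].
#' @param variance_floor Passed to [naive_bayes_fit()].
#' @return A `mave_integration` with `posterior` as P(pathogenic) and
#'   `integrated_score = posterior` of the benign class (so that the global
#'   lower-is-abnormal convention holds: `1 - posterior`).
#' @export
naive_bayes_integrate <- function(train, test, variance_floor = 1e-6) {
  model <- naive_bayes_fit(train, variance_floor = variance_floor)
  pred_tr <- naive_bayes_predict(model, train)
  pred_te <- naive_bayes_predict(model, test)
  tbl <- dplyr::bind_rows(
    dplyr::mutate(pred_tr, in_train = TRUE),
    dplyr::mutate(pred_te, in_train = FALSE)
  ) |>
    dplyr::mutate(
      method = "naive_bayes",
      integrated_score = 1 - .data$posterior
    ) |>
    dplyr::select(
      "variant", "method", "integrated_score", "predicted_class",
      "posterior", "in_train"
    )
  new_integration(tbl, "naive_bayes", model = list(nb = model))
}
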