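# broom-style accessors and ggplot2 views of the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted naive Bayes model
#'
#' @param x An `nb_model`.
#' @param ... Unused.
#' @return One row per class/assay with `mean`, `variance` and the class
#'   prior.
#' @method tidy nb_model
#' @export
tidy.nb_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$classes), function(ci) {
    tibble(
      class = x$classes[ci], assay = x$features,
      prior = x$priors[ci],
      mean = x$means[ci, ], variance = x$vars[ci, ]
    )
  })
}

#' @method glance nb_model
#' @export
glance.nb_model <- function(x, ...) {
  tibble(
    n_assays = length(x$features),
    prior_blb = x$priors[1], prior_plp = x$priors[2],
    variance_floor = x$variance_floor
  )
}

#' Tidy an integration result
#'
#' @param x A `mave_integration`.
#' @param ... Unused.
#' @return The per-variant tibble (`variant`, `method`,
#'   `integrated_score`, `predicted_class`, `posterior`, `in_train`).
#' @method tidy mave_integration
#' @export
tidy.mave_integration <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

unclass_keep <- function(x) {
  out <- x
  class(out) <- setdiff(class(x), c("mave_integration", "mave_labeled", "mave_matrix", "mave_calibration"))
  out
}

#' @method glance mave_integration
#' @export
glance.mave_integration <- function(x, ...) {
  mdl <- attr(x, "model")
  out <- tibble(method = attr(x, "method"), n_variants = nrow(x))
  if (attr(x, "method") == "pca") {
    out$pc1_variance_fraction <- mdl$explained_variance[1]
  }
  if (attr(x, "method") == "kmeans") {
    out$tot_withinss <- mdl$tot_withinss
  }
  out
}

#' Score distributions of one assay, split by molecular consequence
#'
#' The classic control view: synonymous variants should pile up at the
#' functionally normal end and nonsense variants at the abnormal end,
#' their separation showing the assay's dynamic range.
#'
#' @param object A `mave_scoreset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mave_scoreset
#' @export
autoplot.mave_scoreset <- function(object, ...) {
  d <- object$variants
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$consequence)) +
    ggplot2::geom_density(alpha = 0.5, color = NA) +
    ggplot2::labs(
      title = paste0(object$meta$assay_id, ": functional score distribution"),
      x = "score (lower = more abnormal after orientation)", y = "density"
    ) +
    ggplot2::theme_minimal()
}

#' Principal-component view of an integrated result
#'
#' For a PCA result, variants in PC1/PC2 space; for other methods, the
#' integrated-score distribution split by predicted class.
#'
#' @param object A `mave_integration`.
#' @param labels Optional named character vector (variant -> truth label)
#'   to color points by.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mave_integration
#' @export
autoplot.mave_integration <- function(object, labels = NULL, ...) {
  method <- attr(object, "method")
  if (method == "pca") {
    pc <- attr(object, "model")$pc_scores
    d <- tibble(variant = object$variant, PC1 = pc[, 1], PC2 = pc[, 2])
    d$label <- if (is.null(labels)) "variant" else unname(labels[d$variant])
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2, color = .data$label)) +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::labs(
          title = "Variants in principal-component space",
          x = paste0(
            "PC1 (", round(100 * attr(object, "model")$explained_variance[1]),
            "% of variance)"
          ),
          y = paste0(
            "PC2 (", round(100 * attr(object, "model")$explained_variance[2]),
            "% of variance)"
          )
        ) +
        ggplot2::theme_minimal()
    )
  }
  d <- as_tibble(unclass_keep(object))
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$integrated_score, fill = .data$predicted_class)
  ) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::labs(
      title = paste0("Integrated score (", method, ")"),
      x = "integrated score (lower = more abnormal)", y = "variants"
    ) +
    ggplot2::theme_minimal()
}

#' Evidence-strength overview across methods
#'
#' OddsPath (log scale) per method and side, with the evidence-strength
#' cut points drawn as reference lines.
#'
#' @param object A `mave_calibration` from [calibration_report()].
#' @param thresholds Cut points to draw (default [oddspath_thresholds]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mave_calibration
#' @export
autoplot.mave_calibration <- function(object, thresholds = oddspath_thresholds, ...) {
  d <- as_tibble(unclass_keep(object))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$method, y = .data$oddspath, fill = .data$is_single_assay
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = thresholds, linetype = "dashed", color = "grey40"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(
      title = "OddsPath evidence strength by method",
      y = "OddsPath (benign side inverted)", x = NULL,
      fill = "single assay"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
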