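# Integration methods: reduce the variant-by-assay matrix to one score or
# class per variant. All methods share the package-wide orientation
# convention that lower integrated score = more functionally abnormal, and
# every result is a `mave_integration` object carrying the per-variant
# tibble plus method-specific model summaries.

new_integration <- function(tbl, method, seed = NA_integer_, model = list()) {
  structure(
    tbl,
    class = c("mave_integration", class(tbl)),
    method = method, seed = seed, model = model
  )
}

#' @export
print.mave_integration <- function(x, ...) {
  cat("<mave_integration> method =", attr(x, "method"),
    "| n =", nrow(x), "\n")
  NextMethod()
}

#' Integrate assays by principal component analysis
#'
#' Reduces the centered (optionally scaled) variant-by-assay matrix to its
#' first principal component. The PC1 sign is anchored so that functionally
#' abnormal variants fall low: nonsense controls if present, else PLP truth
#' labels, else alignment with the per-variant mean score (which is already
#' oriented abnormal-low).
#'
#' @param m A `mave_matrix` or `mave_labeled` with no missing cells.
#' @param scale. Scale columns to unit variance before decomposition
#'   (default `FALSE`: assays are assumed already harmonized to a common
#'   scale).
#' @return A `mave_integration` with `integrated_score` = PC1; the model
#'   summary holds the rotation, column means, standard deviations, the
#'   explained-variance fractions, and the full PC coordinates.
#' @export
pca_integrate <- function(m, scale. = FALSE) {
  stopifnot(inherits(m, "mave_matrix"))
  x <- score_values(m)
  if (anyNA(x)) {
    abort("PCA requires a complete matrix; merge with policy = 'intersection' or drop masked rows")
  }
  if (ncol(x) < 2) abort("need at least 2 assays")
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    abort(paste0(
      "constant assay column(s): ",
      paste(colnames(x)[sds < .Machine$double.eps^0.5], collapse = ", ")
    ))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  pc <- fit$x
  flip <- pc1_sign_flip(m, pc[, 1])
  if (flip) {
    pc <- -pc
    fit$rotation <- -fit$rotation
  }
  tbl <- tibble(
    variant = m$variant, method = "pca",
    integrated_score = pc[, 1],
    predicted_class = NA_character_, posterior = NA_real_,
    in_train = NA
  )
  new_integration(tbl, "pca", model = list(
    rotation = fit$rotation, center = fit$center, scale = fit$scale,
    sdev = fit$sdev, explained_variance = ev, pc_scores = pc,
    sign_flipped = flip
  ))
}

pc1_sign_flip <- function(m, pc1) {
  anchor <- m$consequence == "nonsense"
  if (any(anchor)) return(mean(pc1[anchor]) > 0)
  if ("label" %in% names(m) && any(m$label == "PLP")) {
    return(mean(pc1[m$label == "PLP"]) > 0)
  }
  # fall back: align PC1 with the oriented per-variant mean score
  stats::cor(pc1, rowMeans(score_values(m))) < 0
}

#' Fraction of variance explained by each principal component
#' @param x A `mave_integration` produced by [pca_integrate()].
#' @return Numeric vector of explained-variance fractions (sums to 1).
#' @export
explained_variance <- function(x) {
  stopifnot(inherits(x, "mave_integration"), attr(x, "method") == "pca")
  attr(x, "model")$explained_variance
}

#' Cluster variants in principal-component space
#'
#' K-means clustering on the leading principal components (enough to cover
#' `var_explained` of the variance), minimizing within-cluster sum of
#' squares over random restarts. The cluster whose centroid lies lower on
#' the oriented PC1 is mapped to `functionally_abnormal` — a control-based
#' anchoring that keeps the method free of truth labels.
#'
#' @param pca A `mave_integration` from [pca_integrate()], or a numeric
#'   matrix of PC coordinates (column 1 treated as oriented PC1).
#' @param k Number of clusters (default 2: candidate normal and abnormal).
#' @param seed Integer seed.
#' @param n_restarts Random restarts for the k-means search (default 25).
#' @param var_explained Minimum cumulative variance fraction the retained
#'   components must cover (default 0.95); ignored for matrix input.
#' @return A `mave_integration` with `predicted_class` per variant (no
#'   integrated score: clustering yields a categorical output); the model
#'   summary holds centers, within-cluster sums of squares and the mapping.
#' @export
kmeans_integrate <- function(pca, k = 2L, seed = 1L, n_restarts = 25L,
                             var_explained = 0.95) {
  if (inherits(pca, "mave_integration")) {
    stopifnot(attr(pca, "method") == "pca")
    pc <- attr(pca, "model")$pc_scores
    ev <- attr(pca, "model")$explained_variance
    ncomp <- which(cumsum(ev) >= var_explained)[1]
    coords <- pc[, seq_len(max(ncomp, 1L)), drop = FALSE]
    variants <- pca$variant
  } else {
    coords <- as.matrix(pca)
    variants <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  }
  if (k < 2) abort("k must be >= 2")
  if (nrow(coords) < k) abort("fewer rows than clusters")
  if (nrow(unique(round(coords, 12))) < k) {
    abort("degenerate input: fewer distinct points than clusters")
  }
  fit <- with_stream(seed, 23L, stats::kmeans(
    coords, centers = k, nstart = n_restarts, iter.max = 100
  ))
  abnormal_cluster <- which.min(fit$centers[, 1])
  cls <- ifelse(fit$cluster == abnormal_cluster, class_abnormal, class_normal)
  tbl <- tibble(
    variant = variants, method = "kmeans",
    integrated_score = NA_real_,
    predicted_class = cls,
    posterior = NA_real_, in_train = NA
  )
  new_integration(tbl, "kmeans", seed = as.integer(seed), model = list(
    centers = fit$centers, cluster = fit$cluster,
    withinss = fit$withinss, tot_withinss = fit$tot.withinss,
    abnormal_cluster = abnormal_cluster, n_components = ncol(coords)
  ))
}
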