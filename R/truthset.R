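# Clinical truth sets: variants with benign-or-likely-benign (BLB) or
# pathogenic-or-likely-pathogenic (PLP) classifications. The BLB:PLP ratio
# sets the prior probability of pathogenicity used by OddsPath calibration;
# truth sets should be frozen snapshots predating the assays to avoid
# circularity, which is the user's responsibility.

label_vocabulary <- c(
  "blb" = "BLB", "b" = "BLB", "lb" = "BLB",
  "benign" = "BLB", "likely benign" = "BLB",
  "benign/likely benign" = "BLB", "benign or likely benign" = "BLB",
  "plp" = "PLP", "p" = "PLP", "lp" = "PLP",
  "pathogenic" = "PLP", "likely pathogenic" = "PLP",
  "pathogenic/likely pathogenic" = "PLP",
  "pathogenic or likely pathogenic" = "PLP"
)
uncertain_vocabulary <- c(
  "vus", "uncertain", "uncertain significance",
  "conflicting", "conflicting interpretations", "not provided"
)

#' Load a clinical truth set
#'
#' Reads a table with columns `variant` and `label`, maps the label
#' vocabulary onto BLB/PLP, excludes uncertain or conflicting entries, and
#' normalizes variant identifiers.
#'
#' @param table Data frame or CSV/TSV path with columns `variant`, `label`.
#' @param restrict_missense If `TRUE`, keep only missense variants.
#' @param source Free-text provenance (e.g. a ClinVar snapshot date).
#' @return A `mave_truthset` tibble (`variant`, `label`, `consequence`,
#'   `position`) with attributes `source` and `n_excluded`.
#' @export
load_truthset <- function(table, restrict_missense = FALSE, source = NA_character_) {
  tbl <- read_table_flex(table)
  names(tbl) <- tolower(names(tbl))
  if (!all(c("variant", "label") %in% names(tbl))) {
    abort("truth-set table must have 'variant' and 'label' columns")
  }
  key <- tolower(trimws(as.character(tbl$label)))
  mapped <- unname(label_vocabulary[key])
  unknown <- is.na(mapped) & !(key %in% uncertain_vocabulary)
  if (any(unknown)) {
    warn(paste0(
      "excluding ", sum(unknown), " row(s) with unrecognized labels: ",
      paste(unique(key[unknown]), collapse = ", ")
    ))
  }
  n_excluded <- sum(is.na(mapped))
  if (n_excluded > 0 && any(key %in% uncertain_vocabulary)) {
    inform(paste0(
      "excluded ", sum(key %in% uncertain_vocabulary),
      " uncertain/conflicting label(s)"
    ))
  }
  keep <- !is.na(mapped)
  parsed <- parse_variant(as.character(tbl$variant[keep]))
  out <- tibble(
    variant = parsed$variant, label = mapped[keep],
    consequence = parsed$consequence, position = parsed$position
  )
  conflicts <- out |>
    dplyr::distinct(.data$variant, .data$label) |>
    dplyr::count(.data$variant) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0(
      "conflicting BLB/PLP labels for: ",
      paste(conflicts$variant, collapse = ", ")
    ))
  }
  out <- dplyr::distinct(out)
  if (restrict_missense) out <- dplyr::filter(out, .data$consequence == "missense")
  structure(
    out,
    class = c("mave_truthset", class(out)),
    source = source, n_excluded = n_excluded,
    restrict_missense = restrict_missense
  )
}

#' Join truth labels onto a merged score matrix
#'
#' Restricts the matrix to variants that carry a truth label, and computes
#' the class counts and the prior probability of pathogenicity
#' `prior_p1 = n_plp / (n_blb + n_plp)` from the retained rows only.
#'
#' @param m A `mave_matrix`.
#' @param truth A `mave_truthset`.
#' @return A `mave_labeled` tibble: the matrix columns plus `label`, with
#'   attributes `n_blb`, `n_plp`, `prior_p1`, and the assay metadata.
#' @export
assemble_labeled_matrix <- function(m, truth) {
  stopifnot(inherits(m, "mave_matrix"), inherits(truth, "mave_truthset"))
  lm <- dplyr::inner_join(
    as_tibble(m),
    dplyr::select(as_tibble(truth), "variant", "label"),
    by = "variant"
  )
  if (nrow(lm) == 0) abort("no labeled variant is present in the score matrix")
  n_unscored <- nrow(truth) - nrow(lm)
  if (n_unscored / nrow(truth) > 0.10) {
    warn(paste0(
      n_unscored, " of ", nrow(truth),
      " labeled variants are not scored by all assays and were dropped"
    ))
  }
  n_blb <- sum(lm$label == "BLB")
  n_plp <- sum(lm$label == "PLP")
  if (n_blb == 0 || n_plp == 0) {
    abort("degenerate truth set: prior probability must be interior to (0, 1)")
  }
  structure(
    lm,
    class = c("mave_labeled", "mave_matrix", setdiff(class(lm), "mave_matrix")),
    assays = attr(m, "assays"),
    provenance = attr(m, "provenance"),
    n_blb = n_blb, n_plp = n_plp,
    prior_p1 = n_plp / (n_blb + n_plp)
  )
}

#' Prior probability of pathogenicity of a labeled matrix
#' @param lm A `mave_labeled`.
#' @return `n_plp / (n_blb + n_plp)`.
#' @export
prior_p1 <- function(lm) attr(lm, "prior_p1")

relabel_matrix <- function(m, rows) {
  out <- m[rows, , drop = FALSE]
  for (a in c("assays", "provenance")) attr(out, a) <- attr(m, a)
  class(out) <- class(m)
  n_blb <- sum(out$label == "BLB")
  n_plp <- sum(out$label == "PLP")
  attr(out, "n_blb") <- n_blb
  attr(out, "n_plp") <- n_plp
  attr(out, "prior_p1") <- n_plp / (n_blb + n_plp)
  out
}

#' Stratified train/test split of a labeled matrix
#'
#' Splits preserving the BLB:PLP proportions to within one variant per
#' class. Rows receive seed-determined random priorities and each class
#' contributes its quota of lowest-priority rows to the training half, so
#' the partition depends on the labels only through the per-class counts
#' (relabeling the classes reproduces the same row partition).
#'
#' @param lm A `mave_labeled`.
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly in (0, 1). Default 0.6.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with elements `train` and `test`, both `mave_labeled`.
#' @export
split_train_test <- function(lm, train_fraction = 0.6, seed = 1L) {
  stopifnot(inherits(lm, "mave_labeled"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must be strictly between 0 and 1")
  }
  counts <- table(lm$label)
  if (any(counts < 2)) {
    abort("each class needs at least 2 members to split")
  }
  pri <- with_stream(seed, 11L, stats::runif(nrow(lm)))
  in_train <- logical(nrow(lm))
  for (cl in names(counts)) {
    idx <- which(lm$label == cl)
    quota <- as.integer(round_half_away(train_fraction * length(idx)))
    quota <- max(1L, min(length(idx) - 1L, quota))
    take <- idx[order(pri[idx])][seq_len(quota)]
    in_train[take] <- TRUE
  }
  list(
    train = relabel_matrix(lm, which(in_train)),
    test = relabel_matrix(lm, which(!in_train))
  )
}
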