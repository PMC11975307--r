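# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A tiny scoreset with controls, built directly from a table.
toy_scoreset <- function(scores = c(0.2, 1.0, 0.0),
                         variants = c("p.Arg175His", "p.Ser215Ser", "p.Arg196Ter"),
                         assay_id = "toy", selection = "negative",
                         platform = "endogenous") {
  parse_scoreset(
    data.frame(variant = variants, score = scores),
    assay_meta(assay_id, "TP53", "NM_000546.6",
      platform = platform, phenotype = "LOF", selection = selection
    )
  )
}

# Scoreset with many controls for orientation/rescale tests.
control_scoreset <- function(syn, non, other = numeric(), assay_id = "ctl") {
  n_s <- length(syn); n_n <- length(non); n_o <- length(other)
  pos <- seq_len(n_s + n_n + n_o) + 100
  variants <- c(
    if (n_s > 0) paste0("p.Ser", pos[seq_len(n_s)], "Ser"),
    if (n_n > 0) paste0("p.Arg", pos[n_s + seq_len(n_n)], "Ter"),
    if (n_o > 0) paste0("p.Arg", pos[n_s + n_n + seq_len(n_o)], "His")
  )
  toy_scoreset(c(syn, non, other), variants, assay_id = assay_id)
}

# Labeled matrix built directly from a numeric matrix and labels.
make_labeled <- function(x, labels, assay_names = NULL) {
  if (is.null(assay_names)) {
    assay_names <- colnames(x) %||% paste0("assay", seq_len(ncol(x)))
  }
  colnames(x) <- assay_names
  tbl <- tibble::tibble(
    variant = sprintf("p.Arg%dHis", seq_len(nrow(x)) + 10),
    consequence = "missense",
    position = seq_len(nrow(x)) + 10
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(x))
  tbl$label <- labels
  structure(
    tbl,
    class = c("mave_labeled", "mave_matrix", class(tbl)),
    assays = tibble::tibble(
      assay_id = assay_names, gene = "G", transcript = "T",
      platform = "endogenous", phenotype = "LOF", selection = "negative"
    ),
    provenance = list(),
    n_blb = sum(labels == "BLB"), n_plp = sum(labels == "PLP"),
    prior_p1 = mean(labels == "PLP")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Harmonize a simulated study the way the pipeline does.
harmonized_matrix <- function(study, rescale = "anchor",
                              policy = "intersection") {
  sets <- lapply(study$scoresets, function(s) {
    s <- orient_scores(s)
    if (!is.null(rescale)) s <- rescale_scores(s, rescale)
    s
  })
  merge_scoresets(sets, policy)
}
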