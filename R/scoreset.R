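# A score set is one MAVE's per-variant functional scores plus the assay
# metadata needed to harmonize it with other assays: platform (cDNA vs
# endogenous), the molecular phenotype it senses (LOF, DN, abundance), and
# the selection direction of the screen.

#' Assay metadata for a score set
#'
#' @param assay_id Short unique name for the assay.
#' @param gene Gene symbol.
#' @param transcript Transcript identifier the variants are called against.
#' @param platform `"cDNA"` (exogenous construct, blind to splicing) or
#'   `"endogenous"` (edited at the native locus).
#' @param phenotype Molecular phenotype the assay senses: `"LOF"`, `"DN"`,
#'   `"abundance"` or `"other"`.
#' @param selection `"positive"` (functional variants enrich) or
#'   `"negative"` (functional variants deplete).
#' @param orientation Optional explicit orientation flag used when a set has
#'   no scored controls: `"abnormal_low"` or `"abnormal_high"`.
#' @return A list of class `mave_assay_meta`.
#' @export
assay_meta <- function(assay_id, gene, transcript,
                       platform = c("endogenous", "cDNA"),
                       phenotype = c("LOF", "DN", "abundance", "other"),
                       selection = c("negative", "positive"),
                       orientation = NULL) {
  platform <- match.arg(platform)
  phenotype <- match.arg(phenotype)
  selection <- match.arg(selection)
  if (!is.null(orientation)) {
    orientation <- match.arg(orientation, c("abnormal_low", "abnormal_high"))
  }
  structure(
    list(
      assay_id = assay_id, gene = gene, transcript = transcript,
      platform = platform, phenotype = phenotype, selection = selection,
      orientation = orientation
    ),
    class = "mave_assay_meta"
  )
}

new_scoreset <- function(variants, meta, provenance = character()) {
  structure(
    list(variants = variants, meta = meta, provenance = provenance),
    class = "mave_scoreset"
  )
}

#' Read and validate one MAVE score table
#'
#' Reads a delimited score table (or takes a data frame) with columns
#' `variant` and `score` (optional `se`), normalizes variant identifiers to
#' three-letter HGVS p. notation, derives molecular consequences, and
#' collapses duplicate variant rows to their mean score.
#'
#' @param table A data frame, or path to a CSV/TSV file with a header.
#' @param meta An [assay_meta()] record for the assay.
#' @return A `mave_scoreset`: list with `variants` (tibble `variant`,
#'   `score`, `se`, `consequence`, `position`), `meta`, and a `provenance`
#'   character vector recording transforms applied so far.
#' @examples
#' tbl <- data.frame(
#'   variant = c("p.Arg175His", "p.Ser215Ser", "p.Arg196Ter"),
#'   score = c(0.2, 1.0, 0.0)
#' )
#' ss <- parse_scoreset(tbl, assay_meta("demo", "TP53", "NM_000546.6"))
#' @export
parse_scoreset <- function(table, meta) {
  stopifnot(inherits(meta, "mave_assay_meta"))
  tbl <- read_table_flex(table)
  names(tbl) <- tolower(names(tbl))
  if (!"variant" %in% names(tbl)) {
    abort("score table must have a 'variant' column")
  }
  if (!"score" %in% names(tbl) || !is.numeric(tbl$score)) {
    abort("score table has no numeric 'score' column (fatal format error)")
  }
  if ("transcript" %in% names(tbl)) {
    tx <- unique(stats::na.omit(tbl$transcript))
    if (length(tx) > 0 && any(tx != meta$transcript)) {
      abort(paste0(
        "transcript mismatch: table says ", paste(tx, collapse = "/"),
        ", metadata says ", meta$transcript
      ))
    }
  }
  if (any(!is.finite(tbl$score))) {
    abort("all scores must be finite")
  }
  parsed <- purrr::imap(tbl$variant, function(v, i) {
    tryCatch(parse_variant_one(v), error = function(e) {
      abort(paste0("row ", i, ": ", conditionMessage(e)),
        class = "mavemeld_parse_error"
      )
    })
  })
  parsed <- dplyr::bind_rows(parsed)
  out <- tibble(
    variant = parsed$variant,
    score = tbl$score,
    se = if ("se" %in% names(tbl)) tbl$se else NA_real_,
    consequence = parsed$consequence,
    position = parsed$position
  )
  n_raw <- nrow(out)
  out <- out |>
    dplyr::group_by(.data$variant, .data$consequence, .data$position) |>
    dplyr::summarise(
      score = mean(.data$score), se = mean(.data$se), .groups = "drop"
    ) |>
    dplyr::select("variant", "score", "se", "consequence", "position") |>
    dplyr::arrange(.data$position, .data$variant)
  n_collapsed <- n_raw - nrow(out)
  if (n_collapsed > 0) {
    inform(paste0(
      meta$assay_id, ": collapsed ", n_collapsed,
      " duplicate variant row(s) to mean score"
    ))
  }
  new_scoreset(out, meta,
    provenance = paste0("parsed ", n_raw, " rows; ", n_collapsed, " collapsed")
  )
}

read_table_flex <- function(table) {
  if (is.data.frame(table)) return(as_tibble(table))
  stopifnot(is.character(table), length(table) == 1L)
  if (!file.exists(table)) abort(paste0("file not found: ", table))
  if (grepl("\\.tsv$|\\.txt$", table, ignore.case = TRUE)) {
    readr::read_tsv(table, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(table, show_col_types = FALSE, progress = FALSE)
  }
}

#' @export
print.mave_scoreset <- function(x, ...) {
  cat(
    "<mave_scoreset> ", x$meta$assay_id, ": ", nrow(x$variants),
    " variants (", x$meta$gene, "/", x$meta$transcript, ", ",
    x$meta$platform, ", ", x$meta$phenotype, ", ", x$meta$selection,
    " selection)\n",
    sep = ""
  )
  ctl <- scoreset_controls(x)
  cat(
    "  controls: ", length(ctl$synonymous), " synonymous, ",
    length(ctl$nonsense), " nonsense\n",
    sep = ""
  )
  if (length(x$provenance)) {
    cat("  provenance: ", paste(x$provenance, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' Control-variant subsets of a score set
#'
#' @param s A `mave_scoreset`.
#' @return List with character vectors `synonymous` and `nonsense`.
#' @export
scoreset_controls <- function(s) {
  stopifnot(inherits(s, "mave_scoreset"))
  list(
    synonymous = s$variants$variant[s$variants$consequence == "synonymous"],
    nonsense = s$variants$variant[s$variants$consequence == "nonsense"]
  )
}

control_medians <- function(s) {
  v <- s$variants
  list(
    synonymous = stats::median(v$score[v$consequence == "synonymous"]),
    nonsense = stats::median(v$score[v$consequence == "nonsense"])
  )
}

#' Orient a score set so that lower score means more functionally abnormal
#'
#' Uses synonymous (functionally normal) and nonsense (functionally
#' abnormal) control medians: if the nonsense median exceeds the synonymous
#' median, all scores are negated. After orientation every assay shares the
#' depletion-style convention lower = more abnormal. Idempotent.
#'
#' @param s A `mave_scoreset`. Needs scored controls of both kinds, or an
#'   explicit `orientation` flag in its metadata.
#' @return The oriented `mave_scoreset`, transform recorded in provenance.
#' @export
orient_scores <- function(s) {
  stopifnot(inherits(s, "mave_scoreset"))
  ctl <- scoreset_controls(s)
  if (length(ctl$synonymous) >= 1 && length(ctl$nonsense) >= 1) {
    med <- control_medians(s)
    if (isTRUE(all.equal(med$synonymous, med$nonsense))) {
      abort("orientation indeterminate: synonymous and nonsense control medians are equal")
    }
    flip <- med$nonsense > med$synonymous
  } else if (!is.null(s$meta$orientation)) {
    flip <- s$meta$orientation == "abnormal_high"
    # once flipped the convention holds; clear the flag so re-orienting is a no-op
  } else {
    abort("orientation indeterminate: no controls and no orientation flag")
  }
  if (flip) {
    s$variants$score <- -s$variants$score
    if (!is.null(s$meta$orientation)) s$meta$orientation <- "abnormal_low"
    s$provenance <- c(s$provenance, "oriented: scores negated (abnormal = low)")
  } else {
    s$provenance <- c(s$provenance, "oriented: unchanged (abnormal = low)")
  }
  s
}

#' Rescale a score set to a common scale
#'
#' @param s A `mave_scoreset`.
#' @param method `"anchor"` maps the synonymous control median to 1 and the
#'   nonsense control median to 0 linearly (requires controls); `"minmax"`
#'   maps the observed range to \[0, 1\]; `"zscore"` centers to mean 0 and
#'   scales to sample standard deviation 1.
#' @param log_transform If `TRUE`, natural-log transform scores first.
#'   Requires all scores positive unless `log_offset` is supplied.
#' @param log_offset Optional documented offset added before the log.
#' @return The rescaled `mave_scoreset`, transform recorded in provenance.
#' @export
rescale_scores <- function(s, method = c("anchor", "minmax", "zscore"),
                           log_transform = FALSE, log_offset = NULL) {
  stopifnot(inherits(s, "mave_scoreset"))
  method <- match.arg(method)
  x <- s$variants$score
  if (log_transform) {
    if (!is.null(log_offset)) x <- x + log_offset
    if (any(x <= 0)) {
      abort("log transform requires all scores > 0; supply an explicit log_offset")
    }
    x <- log(x)
    s$provenance <- c(s$provenance, paste0(
      "log transform (natural log",
      if (!is.null(log_offset)) paste0(", offset ", log_offset), ")"
    ))
    s$variants$score <- x
  }
  if (method == "anchor") {
    med <- control_medians(s)
    if (!is.finite(med$synonymous) || !is.finite(med$nonsense)) {
      abort("anchor rescaling requires synonymous and nonsense controls")
    }
    span <- med$synonymous - med$nonsense
    if (abs(span) < .Machine$double.eps^0.5) {
      abort("zero dynamic range: control medians are equal")
    }
    x <- (x - med$nonsense) / span
  } else if (method == "minmax") {
    rng <- range(x)
    if (diff(rng) < .Machine$double.eps^0.5) {
      abort("zero dynamic range: constant scores")
    }
    x <- (x - rng[1]) / diff(rng)
  } else {
    sdx <- stats::sd(x)
    if (!is.finite(sdx) || sdx < .Machine$double.eps^0.5) {
      abort("zero dynamic range: constant scores")
    }
    x <- (x - mean(x)) / sdx
  }
  s$variants$score <- x
  s$provenance <- c(s$provenance, paste0("rescaled: ", method))
  s
}

#' Merge score sets into a variant-by-assay matrix
#'
#' @param sets List of two or more `mave_scoreset` objects for the same gene
#'   and transcript.
#' @param policy `"intersection"` keeps only variants scored by every assay
#'   (no missing cells); `"union"` keeps variants scored by at least one
#'   assay, with `NA` marking absences.
#' @return A `mave_matrix`: tibble with `variant`, `consequence`, `position`
#'   and one numeric column per assay, carrying attributes `assays`
#'   (metadata tibble), `provenance` (per-assay transform record), and
#'   `merge_counts` (retained/dropped).
#' @export
merge_scoresets <- function(sets, policy = c("intersection", "union")) {
  policy <- match.arg(policy)
  stopifnot(is.list(sets), length(sets) >= 2)
  ok <- vapply(sets, inherits, logical(1), "mave_scoreset")
  if (!all(ok)) abort("all elements of 'sets' must be mave_scoreset objects")
  genes <- vapply(sets, function(s) s$meta$gene, character(1))
  txs <- vapply(sets, function(s) s$meta$transcript, character(1))
  if (length(unique(genes)) > 1 || length(unique(txs)) > 1) {
    abort("gene/transcript mismatch across score sets")
  }
  ids <- vapply(sets, function(s) s$meta$assay_id, character(1))
  if (anyDuplicated(ids)) abort("assay_id values must be unique")

  tables <- purrr::map2(sets, ids, function(s, id) {
    dplyr::select(s$variants, "variant", "consequence", "position", "score") |>
      dplyr::rename(!!id := "score")
  })
  join_type <- if (policy == "intersection") dplyr::inner_join else dplyr::full_join
  merged <- purrr::reduce(tables, join_type,
    by = c("variant", "consequence", "position")
  )
  merged <- dplyr::arrange(merged, .data$position, .data$variant)
  if (nrow(merged) == 0) {
    counts <- vapply(tables, nrow, integer(1))
    pairwise <- utils::combn(length(tables), 2, function(ix) {
      length(intersect(tables[[ix[1]]]$variant, tables[[ix[2]]]$variant))
    })
    abort(paste0(
      "empty intersection; per-assay variant counts: ",
      paste(ids, counts, sep = "=", collapse = ", "),
      "; pairwise overlaps: ", paste(pairwise, collapse = ", ")
    ))
  }
  n_union <- length(unique(unlist(lapply(tables, function(t) t$variant))))
  structure(
    merged,
    class = c("mave_matrix", class(merged)),
    assays = dplyr::bind_rows(lapply(sets, function(s) {
      tibble(
        assay_id = s$meta$assay_id, gene = s$meta$gene,
        transcript = s$meta$transcript, platform = s$meta$platform,
        phenotype = s$meta$phenotype, selection = s$meta$selection
      )
    })),
    provenance = stats::setNames(lapply(sets, function(s) s$provenance), ids),
    merge_counts = c(retained = nrow(merged), dropped = n_union - nrow(merged))
  )
}

#' Assay identifiers (column names) of a merged matrix
#' @param m A `mave_matrix`.
#' @return Character vector of assay ids in column order.
#' @export
assay_ids <- function(m) attr(m, "assays")$assay_id

#' Extract the numeric variant-by-assay matrix
#'
#' @param m A `mave_matrix` (or labeled matrix).
#' @return Numeric matrix, rownames = variant identifiers.
#' @export
score_values <- function(m) {
  out <- as.matrix(m[, assay_ids(m), drop = FALSE])
  rownames(out) <- m$variant
  out
}

#' Remove candidate splicing variants when any assay is cDNA-based
#'
#' cDNA-expression assays cannot sense splicing defects, so candidate
#' splice-region variants are uninterpretable in a merged matrix that
#' includes one; they are dropped. With only endogenous-locus assays the
#' matrix is returned unchanged.
#'
#' @param m A `mave_matrix`.
#' @return The filtered `mave_matrix`; attribute `n_splice_removed` records
#'   the number of rows removed.
#' @export
filter_splice_candidates <- function(m) {
  stopifnot(inherits(m, "mave_matrix"))
  if (!"platform" %in% names(attr(m, "assays"))) {
    abort("assay metadata lacks platform information")
  }
  if (!any(attr(m, "assays")$platform == "cDNA")) {
    attr(m, "n_splice_removed") <- 0L
    return(m)
  }
  drop <- m$consequence == "splice_candidate"
  if (any(drop)) {
    inform(paste0(
      "removed ", sum(drop),
      " splice-candidate variant(s): at least one assay is cDNA-based"
    ))
  }
  out <- m[!drop, , drop = FALSE]
  attrs <- attributes(m)
  for (a in c("assays", "provenance", "merge_counts")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(m)
  attr(out, "n_splice_removed") <- sum(drop)
  out
}

#' Write a score set back to its table format
#'
#' @param s A `mave_scoreset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scoreset <- function(s, path) {
  stopifnot(inherits(s, "mave_scoreset"))
  readr::write_csv(dplyr::select(s$variants, "variant", "score", "se"), path)
  invisible(path)
}

#' Write a merged matrix plus a JSON provenance sidecar
#'
#' @param m A `mave_matrix`.
#' @param path Output CSV path; provenance goes to `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  stopifnot(inherits(m, "mave_matrix"))
  readr::write_csv(as_tibble(m), path)
  sidecar <- list(
    assays = attr(m, "assays"),
    provenance = attr(m, "provenance"),
    merge_counts = as.list(attr(m, "merge_counts"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
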