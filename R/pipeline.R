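# End-to-end orchestration: harmonize -> integrate -> evaluate ->
# calibrate, each stage reading and writing plain CSV/JSON so that stages
# rerun in isolation on saved intermediates reproduce the end-to-end run
# bit for bit under the same seeds. All outputs are deterministic text
# (no timestamps), so identical configs yield identical checksums.

#' Build and validate a pipeline configuration
#'
#' @param config A list, or path to a YAML file, with entries:
#'   `scoresets` (list; each with `path` and the [assay_meta()] fields),
#'   `truthset` (`path`, optional `restrict_missense`, `source`),
#'   `outdir`, and optional `merge_policy` (`"intersection"`), `rescale`
#'   (`"anchor"`, `"minmax"`, `"zscore"`, or `"none"`), `methods`
#'   (default all four), `seed`, `train_fraction` (0.6), `n_trees` (500),
#'   `kmeans_k` (2), `kmeans_restarts` (25), `single_threshold` (0.5 on
#'   the anchor scale), `calibration_correction`
#'   (`"add_one_discordant"`).
#' @return A validated `mave_pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    merge_policy = "intersection", rescale = "anchor",
    methods = c("pca", "kmeans", "naive_bayes", "random_forest"),
    seed = 1L, train_fraction = 0.6, n_trees = 500L,
    kmeans_k = 2L, kmeans_restarts = 25L, single_threshold = 0.5,
    calibration_correction = "add_one_discordant"
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$scoresets) || length(config$scoresets) < 2) {
    abort("config needs at least two 'scoresets' entries")
  }
  if (is.null(config$truthset$path)) abort("config needs truthset$path")
  if (is.null(config$outdir)) abort("config needs an 'outdir'")
  for (s in config$scoresets) {
    if (is.null(s$path) || !file.exists(s$path)) {
      abort(paste0("score table not found: ", s$path %||% "<missing path>"))
    }
  }
  if (!file.exists(config$truthset$path)) {
    abort(paste0("truth-set table not found: ", config$truthset$path))
  }
  if (!(config$train_fraction > 0 && config$train_fraction < 1)) {
    abort("train_fraction must be in (0, 1)")
  }
  if (!config$merge_policy %in% c("intersection", "union")) {
    abort("merge_policy must be 'intersection' or 'union'")
  }
  structure(config, class = "mave_pipeline_config")
}

#' Harmonize stage: parse, orient, rescale, merge, filter
#'
#' @param cfg A [pipeline_config()].
#' @return The merged `mave_matrix`; also written to
#'   `outdir/merged_matrix.csv` with a JSON provenance sidecar.
#' @export
pipeline_harmonize <- function(cfg) {
  stopifnot(inherits(cfg, "mave_pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sets <- lapply(cfg$scoresets, function(s) {
    meta <- assay_meta(
      s$assay_id, s$gene, s$transcript,
      platform = s$platform %||% "endogenous",
      phenotype = s$phenotype %||% "other",
      selection = s$selection %||% "negative",
      orientation = s$orientation
    )
    ss <- parse_scoreset(s$path, meta)
    ss <- orient_scores(ss)
    if (cfg$rescale != "none") ss <- rescale_scores(ss, method = cfg$rescale)
    ss
  })
  m <- merge_scoresets(sets, policy = cfg$merge_policy)
  m <- filter_splice_candidates(m)
  write_score_matrix(m, file.path(cfg$outdir, "merged_matrix.csv"))
  m
}

#' Read back a merged matrix written by [write_score_matrix()]
#'
#' @param path CSV path (expects `<path>.provenance.json` beside it).
#' @return A `mave_matrix`.
#' @export
read_score_matrix <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".provenance.json"),
    simplifyVector = TRUE
  )
  structure(
    tbl,
    class = c("mave_matrix", class(tbl)),
    assays = as_tibble(side$assays),
    provenance = side$provenance,
    merge_counts = unlist(side$merge_counts)
  )
}

#' Integrate stage: run the requested methods and write per-method scores
#'
#' @param cfg A [pipeline_config()].
#' @param m Merged `mave_matrix` (from [pipeline_harmonize()] or
#'   [read_score_matrix()]).
#' @return List of `mave_integration` results plus the labeled matrix and
#'   split; per-method CSVs written to `outdir/scores_<method>.csv`.
#' @export
pipeline_integrate <- function(cfg, m) {
  stopifnot(inherits(cfg, "mave_pipeline_config"))
  truth <- load_truthset(
    cfg$truthset$path,
    restrict_missense = isTRUE(cfg$truthset$restrict_missense),
    source = cfg$truthset$source %||% NA_character_
  )
  lm <- assemble_labeled_matrix(m, truth)
  split <- NULL
  results <- list()
  if (any(c("pca", "kmeans") %in% cfg$methods)) {
    pca <- pca_integrate(lm)
    km <- kmeans_integrate(pca,
      k = cfg$kmeans_k, seed = cfg$seed, n_restarts = cfg$kmeans_restarts
    )
    if ("pca" %in% cfg$methods) {
      # threshold PC1 at the midpoint of the two cluster centers so the
      # statistical method stays truth-label-free
      thr <- mean(range(attr(km, "model")$centers[, 1]))
      pca$predicted_class <- classify_at_threshold(pca$integrated_score, thr)
      attr(pca, "model")$class_threshold <- thr
      results$pca <- pca
    }
    if ("kmeans" %in% cfg$methods) results$kmeans <- km
  }
  if (any(c("naive_bayes", "random_forest") %in% cfg$methods)) {
    split <- split_train_test(lm,
      train_fraction = cfg$train_fraction, seed = cfg$seed
    )
    if ("naive_bayes" %in% cfg$methods) {
      results$naive_bayes <- naive_bayes_integrate(split$train, split$test)
    }
    if ("random_forest" %in% cfg$methods) {
      results$random_forest <- forest_fit_predict(
        split$train, split$test,
        n_trees = cfg$n_trees, seed = cfg$seed
      )
    }
  }
  for (nm in names(results)) {
    readr::write_csv(
      as_tibble(results[[nm]]),
      file.path(cfg$outdir, paste0("scores_", nm, ".csv"))
    )
  }
  list(results = results, labeled = lm, split = split, truth = truth)
}

#' Evaluate stage: Table-style metrics for single assays and methods
#'
#' Single assays are thresholded at `cfg$single_threshold` on the
#' harmonized (anchor) scale. Supervised methods are reported twice: on
#' the held-out test set and on the whole truth set.
#'
#' @param cfg A [pipeline_config()].
#' @param integrations Output of [pipeline_integrate()].
#' @return Metrics tibble (one row per method/assay per evaluation
#'   scope), written to `outdir/metrics.csv`.
#' @export
pipeline_evaluate <- function(cfg, integrations) {
  lm <- integrations$labeled
  rows <- list()
  for (a in assay_ids(lm)) {
    pred <- classify_at_threshold(lm[[a]], cfg$single_threshold)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(method = a, is_single_assay = TRUE, evaluated_on = "all"),
      classification_metrics(confusion_matrix(pred, lm$label))
    )
  }
  for (nm in names(integrations$results)) {
    res <- as_tibble(integrations$results[[nm]])
    joined <- dplyr::inner_join(
      res, dplyr::select(as_tibble(lm), "variant", "label"),
      by = "variant"
    )
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(method = nm, is_single_assay = FALSE, evaluated_on = "all"),
      classification_metrics(
        confusion_matrix(joined$predicted_class, joined$label)
      )
    )
    if (any(!is.na(joined$in_train))) {
      test <- dplyr::filter(joined, !.data$in_train)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(method = nm, is_single_assay = FALSE, evaluated_on = "test"),
        classification_metrics(
          confusion_matrix(test$predicted_class, test$label)
        )
      )
    }
  }
  metrics <- dplyr::bind_rows(rows)
  readr::write_csv(metrics, file.path(cfg$outdir, "metrics.csv"))
  metrics
}

#' Calibrate stage: OddsPath evidence report
#'
#' Whole-truth-set rows feed the calibration; the report carries the best
#' single assay per side and, per integrated method, whether integration
#' improved the attainable evidence strength (if not, the best single
#' assay's score should be used instead).
#'
#' @param cfg A [pipeline_config()].
#' @param metrics Metrics tibble from [pipeline_evaluate()] (or read from
#'   `metrics.csv`).
#' @return A `mave_calibration` tibble, written to `outdir/evidence.csv`
#'   and `outdir/evidence.json`.
#' @export
pipeline_calibrate <- function(cfg, metrics) {
  use <- dplyr::filter(metrics, .data$evaluated_on == "all")
  report <- calibration_report(use, correction = cfg$calibration_correction)
  readr::write_csv(as_tibble(report), file.path(cfg$outdir, "evidence.csv"))
  best <- attr(report, "best_single")
  summary <- list(
    report = report,
    best_single = best,
    note = paste0(
      "Integrated scores are derived from a combination of assays (",
      paste(use$method[use$is_single_assay], collapse = ", "),
      "); do not double-count them with evidence from the constituent assays."
    )
  )
  jsonlite::write_json(summary, file.path(cfg$outdir, "evidence.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  report
}

#' Run the full pipeline
#'
#' Executes harmonize, integrate, evaluate and calibrate, writing the
#' merged matrix, per-method variant scores, a metrics table, the
#' evidence report and a deterministic run log into `outdir`.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @return Invisibly, a list with `matrix`, `integrations`, `metrics`,
#'   `evidence`, and `outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "mave_pipeline_config")) {
    config
  } else {
    pipeline_config(config)
  }
  m <- pipeline_harmonize(cfg)
  integrations <- pipeline_integrate(cfg, m)
  metrics <- pipeline_evaluate(cfg, integrations)
  evidence <- pipeline_calibrate(cfg, metrics)
  log_lines <- c(
    paste0("mavemeld ", as.character(utils::packageVersion("mavemeld"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed: ", cfg$seed),
    paste0("merge_policy: ", cfg$merge_policy, "; rescale: ", cfg$rescale),
    paste0("methods: ", paste(cfg$methods, collapse = ", ")),
    paste0(
      "variants merged: ", attr(m, "merge_counts")[["retained"]],
      " (dropped ", attr(m, "merge_counts")[["dropped"]], ")"
    ),
    paste0("splice candidates removed: ", attr(m, "n_splice_removed")),
    paste0(
      "labeled: ", attr(integrations$labeled, "n_blb"), " BLB + ",
      attr(integrations$labeled, "n_plp"), " PLP (prior P1 = ",
      signif(prior_p1(integrations$labeled), 6), ")"
    ),
    "integrated scores are combination-derived; see evidence.json note"
  )
  writeLines(log_lines, file.path(cfg$outdir, "run_log.txt"))
  invisible(list(
    matrix = m, integrations = integrations, metrics = metrics,
    evidence = evidence, outdir = cfg$outdir
  ))
}

#' Write a simulated study to the pipeline's input formats
#'
#' Emits one score CSV per assay, the truth-set CSV, the ground-truth
#' mechanism classes, and a ready-to-run pipeline YAML config.
#'
#' @param study A `sim_study` from [simulate_multimave()] or
#'   [make_paperlike_study()].
#' @param dir Output directory.
#' @return Path to the written YAML config, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  score_cfgs <- lapply(study$scoresets, function(s) {
    p <- file.path(dir, paste0("scores_", s$meta$assay_id, ".csv"))
    write_scoreset(s, p)
    list(
      path = p, assay_id = s$meta$assay_id, gene = s$meta$gene,
      transcript = s$meta$transcript, platform = s$meta$platform,
      phenotype = s$meta$phenotype, selection = s$meta$selection
    )
  })
  truth_path <- file.path(dir, "truthset.csv")
  readr::write_csv(
    dplyr::select(as_tibble(study$truth), "variant", "label"), truth_path
  )
  readr::write_csv(study$ground_truth, file.path(dir, "ground_truth.csv"))
  cfg <- list(
    scoresets = score_cfgs,
    truthset = list(
      path = truth_path, restrict_missense = TRUE,
      source = attr(study$truth, "source")
    ),
    outdir = file.path(dir, "results"),
    seed = study$config$seed
  )
  cfg_path <- file.path(dir, "pipeline.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
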