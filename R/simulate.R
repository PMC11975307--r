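# Synthetic multi-assay deep-mutational-scanning data. The generator works
# at the per-variant score level the downstream analysis consumes: each
# variant carries a latent mechanism class (benign-like, loss-of-function,
# dominant-negative, or hypomorphic), and each assay senses only the
# mechanism classes in its sensitivity map — an LOF-only screen reads a
# purely dominant-negative variant as benign-like, which is the scenario
# that motivates combining assays in the first place. Scores are Gaussian
# around class means on the oriented scale (abnormal low), with noise
# shared within a phenotype group to induce cross-assay correlation, and
# positive-selection assays are emitted sign-flipped so harmonization has
# real work to do.

#' Specification of one simulated assay
#'
#' @param assay_id Unique name.
#' @param phenotype `"LOF"` or `"DN"`; also the correlation group.
#' @param selection `"negative"` (emitted oriented) or `"positive"`
#'   (emitted sign-flipped, to be fixed by [orient_scores()]).
#' @param senses Character vector of mechanism classes (among
#'   `benign_like`, `lof`, `dn`, `hypomorph`) the assay separates from
#'   benign-like; unsensed classes score as benign-like.
#' @return List of class `sim_assay`.
#' @export
sim_assay <- function(assay_id, phenotype = c("LOF", "DN"),
                      selection = c("negative", "positive"),
                      senses = c("lof", "dn")) {
  phenotype <- match.arg(phenotype)
  selection <- match.arg(selection)
  bad <- setdiff(senses, c("benign_like", "lof", "dn", "hypomorph"))
  if (length(bad)) abort(paste0("unknown mechanism class: ", paste(bad, collapse = ", ")))
  structure(
    list(
      assay_id = assay_id, phenotype = phenotype,
      selection = selection, senses = senses
    ),
    class = "sim_assay"
  )
}

#' Configuration of a simulated multi-assay study
#'
#' @param n_variants Number of missense study variants (controls come on
#'   top, per `control_fractions`).
#' @param class_proportions Named proportions over `benign_like`, `lof`,
#'   `dn`, `hypomorph`; must sum to 1. Counts are apportioned
#'   deterministically (largest remainder), so configured proportions are
#'   met exactly up to integer rounding.
#' @param assays List of [sim_assay()] specs.
#' @param class_means,class_sds Named per-class score means and SDs on the
#'   oriented scale (abnormal low). Hypomorph means must lie strictly
#'   between the benign-like and lof means.
#' @param cross_assay_correlation Correlation of score noise between
#'   assays of the same phenotype group, in \[0, 1).
#' @param control_fractions Named fractions (`synonymous`, `nonsense`) of
#'   `n_variants` appended as controls. Synonymous controls score as
#'   benign-like; nonsense controls score from the lof distribution in
#'   every assay (full loss of function is visible to all platforms).
#' @param missing_rate Per-cell probability that an assay fails to score a
#'   variant, in \[0, 1).
#' @param heavy_tail_contamination Fraction of scores replaced by draws
#'   with 3x the class SD (default 0), for stress-testing robust
#'   statistics.
#' @param n_splice Number of extra coding-level splice-candidate variants
#'   (scored benign-like) appended, default 0.
#' @param seed Integer; one global seed governs all draws through
#'   documented substreams.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_variants = 200L,
                       class_proportions = c(
                         benign_like = 0.30, lof = 0.25, dn = 0.35,
                         hypomorph = 0.10
                       ),
                       assays = list(
                         sim_assay("lof_a", "LOF", "negative", c("lof", "dn", "hypomorph")),
                         sim_assay("lof_b", "LOF", "positive", c("lof", "dn", "hypomorph")),
                         sim_assay("dn_a", "DN", "negative", c("dn", "hypomorph")),
                         sim_assay("dn_b", "DN", "positive", c("dn", "hypomorph"))
                       ),
                       class_means = c(
                         benign_like = 1.0, lof = 0.0, dn = 0.0, hypomorph = 0.5
                       ),
                       class_sds = c(
                         benign_like = 0.15, lof = 0.35, dn = 0.35, hypomorph = 0.15
                       ),
                       cross_assay_correlation = 0.6,
                       control_fractions = c(synonymous = 0.12, nonsense = 0.12),
                       missing_rate = 0,
                       heavy_tail_contamination = 0,
                       n_splice = 0L,
                       seed = 1L) {
  need <- c("benign_like", "lof", "dn", "hypomorph")
  stopifnot(
    n_variants >= 4,
    setequal(names(class_proportions), need),
    setequal(names(class_means), need),
    setequal(names(class_sds), need)
  )
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class proportions must be non-negative and sum to 1")
  }
  if (any(class_sds <= 0)) abort("class SDs must be positive")
  lo <- min(class_means["benign_like"], class_means["lof"])
  hi <- max(class_means["benign_like"], class_means["lof"])
  if (!(class_means["hypomorph"] > lo && class_means["hypomorph"] < hi)) {
    abort("hypomorph mean must lie strictly between benign_like and lof means")
  }
  if (cross_assay_correlation < 0 || cross_assay_correlation >= 1) {
    abort("cross_assay_correlation must be in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)")
  }
  ids <- vapply(assays, function(a) a$assay_id, character(1))
  if (anyDuplicated(ids)) abort("assay ids must be unique")
  structure(
    list(
      n_variants = as.integer(n_variants),
      class_proportions = class_proportions[need],
      assays = assays,
      class_means = class_means[need], class_sds = class_sds[need],
      cross_assay_correlation = cross_assay_correlation,
      control_fractions = control_fractions,
      missing_rate = missing_rate,
      heavy_tail_contamination = heavy_tail_contamination,
      n_splice = as.integer(n_splice),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

sim_variant_ids <- function(counts, n_syn, n_non, n_splice) {
  aa <- aa_three[aa_three != "Ter"]
  n_mis <- sum(counts)
  pos <- seq_len(n_mis + n_syn + n_non) + 10L
  ref <- sample(aa, length(pos), replace = TRUE)
  alt <- vapply(ref[seq_len(n_mis)], function(r) sample(setdiff(aa, r), 1), character(1))
  mis <- paste0("p.", ref[seq_len(n_mis)], pos[seq_len(n_mis)], alt)
  syn_ix <- n_mis + seq_len(n_syn)
  syn <- paste0("p.", ref[syn_ix], pos[syn_ix], ref[syn_ix])
  non_ix <- n_mis + n_syn + seq_len(n_non)
  non <- paste0("p.", ref[non_ix], pos[non_ix], "Ter")
  spl <- if (n_splice > 0) {
    paste0(
      "c.", 3L * (max(pos) + seq_len(n_splice)), "+",
      sample(1:5, n_splice, replace = TRUE),
      sample(c("G", "T"), n_splice, replace = TRUE), ">",
      sample(c("A", "C"), n_splice, replace = TRUE)
    )
  } else {
    character()
  }
  list(missense = mis, synonymous = syn, nonsense = non, splice = spl)
}

#' Simulate a multi-assay MAVE study
#'
#' @param cfg A [sim_config()].
#' @return A `sim_study` list: `scoresets` (list of `mave_scoreset`, one
#'   per configured assay, every variant scored in every set before
#'   missingness), `truth` (a `mave_truthset`: BLB for benign-like, PLP
#'   for lof/dn; hypomorphs, controls and splice candidates are left
#'   unlabeled), `ground_truth` (tibble `variant`, `class`), and `config`.
#' @export
simulate_multimave <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- apportion(cfg$n_variants, cfg$class_proportions)
  n_syn <- as.integer(round_half_away(
    cfg$control_fractions[["synonymous"]] * cfg$n_variants
  ))
  n_non <- as.integer(round_half_away(
    cfg$control_fractions[["nonsense"]] * cfg$n_variants
  ))

  ids <- with_stream(cfg$seed, 1L, {
    sim_variant_ids(counts, n_syn, n_non, cfg$n_splice)
  })
  class_vec <- with_stream(cfg$seed, 2L, {
    sample(rep(names(counts), times = counts))
  })
  variants <- c(ids$missense, ids$synonymous, ids$nonsense, ids$splice)
  # effective scoring class per variant: controls anchor the two ends,
  # splice candidates read benign-like at the protein level
  eff_class <- c(
    class_vec,
    rep("benign_like", n_syn), rep("lof", n_non),
    rep("benign_like", cfg$n_splice)
  )
  n_all <- length(variants)

  rho <- cfg$cross_assay_correlation
  groups <- unique(vapply(cfg$assays, function(a) a$phenotype, character(1)))
  scores <- with_stream(cfg$seed, 3L, {
    zg <- matrix(stats::rnorm(n_all * length(groups)), n_all,
      dimnames = list(NULL, groups)
    )
    out <- matrix(NA_real_, n_all, length(cfg$assays))
    for (j in seq_along(cfg$assays)) {
      a <- cfg$assays[[j]]
      sensed <- eff_class %in% a$senses |
        variants %in% ids$nonsense # nonsense: full LOF, visible to all assays
      cl <- ifelse(sensed, eff_class, "benign_like")
      cl[variants %in% ids$nonsense] <- "lof"
      mu <- cfg$class_means[cl]
      sd <- cfg$class_sds[cl]
      if (cfg$heavy_tail_contamination > 0) {
        contam <- stats::runif(n_all) < cfg$heavy_tail_contamination
        sd[contam] <- sd[contam] * 3
      }
      eps <- stats::rnorm(n_all)
      x <- mu + sd * (sqrt(rho) * zg[, a$phenotype] + sqrt(1 - rho) * eps)
      if (a$selection == "positive") x <- -x
      out[, j] <- x
    }
    out
  })

  parsed <- parse_variant(variants)
  drop_mask <- if (cfg$missing_rate > 0) {
    with_stream(cfg$seed, 4L, {
      matrix(stats::runif(n_all * length(cfg$assays)) < cfg$missing_rate,
        n_all, length(cfg$assays)
      )
    })
  } else {
    matrix(FALSE, n_all, length(cfg$assays))
  }

  scoresets <- lapply(seq_along(cfg$assays), function(j) {
    a <- cfg$assays[[j]]
    keep <- !drop_mask[, j]
    new_scoreset(
      tibble(
        variant = parsed$variant[keep], score = scores[keep, j],
        se = NA_real_,
        consequence = parsed$consequence[keep],
        position = parsed$position[keep]
      ),
      assay_meta(a$assay_id, "SIMGENE", "SIMTX.1",
        platform = if (a$phenotype == "DN") "cDNA" else "endogenous",
        phenotype = a$phenotype, selection = a$selection
      ),
      provenance = paste0("simulated (seed ", cfg$seed, ")")
    )
  })

  labeled <- eff_class %in% c("benign_like", "lof", "dn") &
    parsed$consequence == "missense"
  truth <- tibble(
    variant = parsed$variant[labeled],
    label = ifelse(eff_class[labeled] == "benign_like", "BLB", "PLP"),
    consequence = parsed$consequence[labeled],
    position = parsed$position[labeled]
  )
  truth <- structure(
    truth,
    class = c("mave_truthset", class(truth)),
    source = paste0("simulated (seed ", cfg$seed, ")"),
    n_excluded = 0L, restrict_missense = TRUE
  )
  structure(
    list(
      scoresets = scoresets, truth = truth,
      ground_truth = tibble(variant = parsed$variant, class = eff_class),
      config = cfg
    ),
    class = "sim_study"
  )
}

#' Mask score-matrix cells at random
#'
#' Each cell is masked (set `NA`) independently with probability `rate`;
#' rows losing every assay are dropped with a warning.
#'
#' @param m A `mave_matrix`.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @return The masked `mave_matrix`; attribute `realized_missing_rate`
#'   records the achieved fraction.
#' @export
inject_missingness <- function(m, rate, seed = 1L) {
  stopifnot(inherits(m, "mave_matrix"))
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  ids <- assay_ids(m)
  x <- score_values(m)
  if (rate > 0) {
    mask <- with_stream(seed, 5L, {
      matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x))
    })
    x[mask] <- NA_real_
  }
  out <- m
  out[, ids] <- as.data.frame(x)
  all_gone <- rowSums(!is.na(x)) == 0
  if (any(all_gone)) {
    warn(paste0("dropping ", sum(all_gone), " fully masked row(s)"))
    keep <- which(!all_gone)
    attrs <- attributes(out)
    out <- out[keep, , drop = FALSE]
    for (a in c("assays", "provenance", "merge_counts")) {
      attr(out, a) <- attrs[[a]]
    }
    class(out) <- class(m)
  }
  attr(out, "realized_missing_rate") <- mean(is.na(score_values(out)))
  out
}

#' Preset study emulating the published four-assay TP53 integration setup
#'
#' 161 labeled missense variants (32 BLB, 129 PLP), four assays — two
#' loss-of-function screens sensing every pathogenic mechanism and two
#' dominant-negative reporters blind to pure-LOF variants — with mixed
#' selection signs, synonymous and nonsense controls, within-phenotype
#' score correlation 0.6 and no missingness. Noise levels are set so
#' single assays keep near-perfect PPV but imperfect NPV, the published
#' pattern that integration is meant to fix.
#'
#' @param seed Integer seed.
#' @return A `sim_study`; its truth set has exactly 32 BLB and 129 PLP.
#' @export
make_paperlike_study <- function(seed = 1L) {
  cfg <- sim_config(
    n_variants = 173L, # 161 labeled + 12 unlabeled hypomorphs
    class_proportions = c(
      benign_like = 32 / 173, lof = 8 / 173, dn = 121 / 173,
      hypomorph = 12 / 173
    ),
    assays = list(
      sim_assay("lof_nutlin", "LOF", "positive", c("lof", "dn", "hypomorph")),
      sim_assay("lof_etoposide", "LOF", "negative", c("lof", "dn", "hypomorph")),
      sim_assay("dn_reporter", "DN", "positive", c("dn", "hypomorph")),
      sim_assay("dn_null_nutlin", "DN", "negative", c("dn", "hypomorph"))
    ),
    class_means = c(benign_like = 1.0, lof = 0.0, dn = 0.0, hypomorph = 0.5),
    class_sds = c(benign_like = 0.15, lof = 0.35, dn = 0.35, hypomorph = 0.15),
    cross_assay_correlation = 0.6,
    control_fractions = c(synonymous = 0.12, nonsense = 0.12),
    missing_rate = 0,
    seed = seed
  )
  simulate_multimave(cfg)
}
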