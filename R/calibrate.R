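# OddsPath calibration: convert a classifier's concordance with the truth
# set into a likelihood ratio toward pathogenicity (or benignity) and map
# it onto ACMG/AMP PS3/BS3 evidence strengths. P1 is the prior proportion
# of pathogenic variants in the truth set; P2 is the posterior proportion
# among variants sharing a functional readout.

#' Evidence-strength thresholds (likelihood-ratio scale)
#'
#' Default cut points of the point-based Bayesian calibration framework:
#' very strong >= 350, strong >= 18.7, moderate >= 4.33, supporting
#' >= 2.08. Both evidence directions share this table: the benign side is
#' assessed on the inverse of its OddsPath.
#'
#' @export
oddspath_thresholds <- c(
  very_strong = 350, strong = 18.7, moderate = 4.33, supporting = 2.08
)

#' OddsPath: posterior odds of pathogenicity over prior odds
#'
#' @param p1 Prior probability of pathogenicity (truth-set PLP
#'   proportion), strictly in (0, 1).
#' @param p2 Posterior probability of pathogenicity among variants with
#'   the functional readout under consideration, strictly in (0, 1).
#' @return `[p2 (1 - p1)] / [(1 - p2) p1]`; values above 1 are evidence
#'   toward pathogenicity.
#' @export
oddspath <- function(p1, p2) {
  if (any(p1 <= 0 | p1 >= 1)) {
    abort("p1 must be strictly in (0, 1)")
  }
  if (any(p2 <= 0 | p2 >= 1)) {
    abort(paste0(
      "p2 at the boundary of [0, 1]: use oddspath_from_counts() with ",
      "correction = 'add_one_discordant' for perfectly concordant counts"
    ))
  }
  (p2 * (1 - p1)) / ((1 - p2) * p1)
}

#' OddsPath and evidence strength from a confusion matrix
#'
#' The pathogenic side uses `p2 = tp / (tp + fp)` (PLP proportion among
#' abnormal calls) and reports OddsPath directly; the benign side uses
#' `p2 = fn / (fn + tn)` (PLP proportion among normal calls) and reports
#' the inverse of the resulting OddsPath as strength toward benignity, so
#' both sides share one threshold table. When p2 lands on a boundary
#' (e.g. specificity 1 making the pathogenic-side p2 exactly 1),
#' `correction = "add_one_discordant"` adds one counter-example to the
#' relevant cell and flags it.
#'
#' @param c A confusion matrix (`tp`, `fn`, `fp`, `tn`), both truth
#'   classes represented.
#' @param side `"pathogenic"` or `"benign"`.
#' @param correction `"add_one_discordant"` (default) or `"none"`.
#' @param thresholds Named evidence cut points, see
#'   [oddspath_thresholds].
#' @return One-row tibble: `side`, `p1`, `p2`, `oddspath` (already
#'   inverted for the benign side), `code`, `correction_applied`.
#' @export
oddspath_from_counts <- function(c, side = c("pathogenic", "benign"),
                                 correction = c("add_one_discordant", "none"),
                                 thresholds = oddspath_thresholds) {
  side <- match.arg(side)
  correction <- match.arg(correction)
  tp <- c$tp; fn <- c$fn; fp <- c$fp; tn <- c$tn
  if (tp + fn < 1 || fp + tn < 1) abort("both truth classes must be represented")
  p1 <- (tp + fn) / (tp + fn + fp + tn)
  corrected <- FALSE
  if (side == "pathogenic") {
    n_called <- tp + fp
    if (n_called == 0) abort("no variants called functionally abnormal")
    p2 <- tp / n_called
    if (p2 %in% c(0, 1)) {
      if (correction == "none") {
        abort("boundary p2 on the pathogenic side; rerun with correction = 'add_one_discordant'")
      }
      if (p2 == 1) fp <- fp + 1L else tp <- tp + 1L
      p2 <- tp / (tp + fp)
      corrected <- TRUE
    }
    odds <- oddspath(p1, p2)
  } else {
    n_called <- fn + tn
    if (n_called == 0) abort("no variants called functionally normal")
    p2 <- fn / n_called
    if (p2 %in% c(0, 1)) {
      if (correction == "none") {
        abort("boundary p2 on the benign side; rerun with correction = 'add_one_discordant'")
      }
      if (p2 == 0) fn <- fn + 1L else tn <- tn + 1L
      p2 <- fn / (fn + tn)
      corrected <- TRUE
    }
    odds <- 1 / oddspath(p1, p2) # inverse OddsPath: strength toward benignity
  }
  tibble(
    side = side, p1 = p1, p2 = p2, oddspath = odds,
    code = evidence_strength(odds, side, thresholds),
    correction_applied = corrected
  )
}

#' Map an OddsPath value to an ACMG/AMP evidence-strength code
#'
#' @param odds Positive likelihood ratio; the benign side must already be
#'   inverted (see [oddspath_from_counts()]).
#' @param side `"pathogenic"` (PS3) or `"benign"` (BS3); affects only the
#'   reported direction, not the cut points.
#' @param thresholds Named cut points, see [oddspath_thresholds].
#' @return One of `"unmet"`, `"supporting"`, `"moderate"`, `"strong"`,
#'   `"very_strong"`.
#' @examples
#' evidence_strength(30.3) # "strong"
#' @export
evidence_strength <- function(odds, side = c("pathogenic", "benign"),
                              thresholds = oddspath_thresholds) {
  side <- match.arg(side)
  stopifnot(is.numeric(odds), length(odds) >= 1)
  if (any(odds <= 0)) abort("odds must be positive")
  thresholds <- sort(thresholds, decreasing = TRUE)
  vapply(odds, function(o) {
    hit <- names(thresholds)[o >= thresholds]
    if (length(hit) == 0) "unmet" else hit[1]
  }, character(1))
}

evidence_rank <- function(code) {
  match(code, c("unmet", "supporting", "moderate", "strong", "very_strong"))
}

#' Evidence-calibration report across methods
#'
#' One row per method per side: OddsPath, evidence code, and whether each
#' integrated method improves on the best-performing single assay on that
#' side (if none does, the recommendation is to fall back to the best
#' single assay's score).
#'
#' @param metrics A tibble with one row per method, columns `method`,
#'   `tp`, `fn`, `fp`, `tn`, and a logical `is_single_assay`.
#' @param correction,thresholds Passed to [oddspath_from_counts()].
#' @return A `mave_calibration` tibble: `method`, `is_single_assay`,
#'   `side`, `p1`, `p2`, `oddspath`, `code`, `correction_applied`,
#'   `integration_improved`; attribute `best_single` names the
#'   best-performing single assay per side.
#' @export
calibration_report <- function(metrics, correction = "add_one_discordant",
                               thresholds = oddspath_thresholds) {
  stopifnot(all(c("method", "tp", "fn", "fp", "tn") %in% names(metrics)))
  if (!"is_single_assay" %in% names(metrics)) metrics$is_single_assay <- FALSE
  rows <- purrr::map_dfr(seq_len(nrow(metrics)), function(i) {
    purrr::map_dfr(c("pathogenic", "benign"), function(sd) {
      dplyr::bind_cols(
        tibble(
          method = metrics$method[i],
          is_single_assay = metrics$is_single_assay[i]
        ),
        oddspath_from_counts(metrics[i, ], sd,
          correction = correction, thresholds = thresholds
        )
      )
    })
  })
  best_single <- rows |>
    dplyr::filter(.data$is_single_assay) |>
    dplyr::group_by(.data$side) |>
    dplyr::slice_max(.data$oddspath, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(best_single) > 0) {
    rows <- rows |>
      dplyr::left_join(
        dplyr::select(best_single,
          "side",
          best_single_method = "method", best_single_oddspath = "oddspath"
        ),
        by = "side"
      ) |>
      dplyr::mutate(
        integration_improved = !.data$is_single_assay &
          .data$oddspath > .data$best_single_oddspath
      )
  } else {
    rows$best_single_method <- NA_character_
    rows$best_single_oddspath <- NA_real_
    rows$integration_improved <- NA
  }
  structure(
    rows,
    class = c("mave_calibration", class(rows)),
    best_single = best_single
  )
}
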