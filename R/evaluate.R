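# Performance of a classification (or thresholded score) against the
# clinical truth set. The positive class is PLP / functionally abnormal
# throughout, matching the direction in which PS3 evidence is applied.

#' Confusion matrix with PLP / functionally abnormal as the positive class
#'
#' @param predicted Character vector of predicted classes
#'   (`functionally_abnormal`/`functionally_normal`, or `PLP`/`BLB`).
#' @param labels Character vector of truth labels (`PLP`/`BLB`).
#' @return A `mave_confusion` one-row tibble with integer `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(predicted, labels) {
  if (length(predicted) != length(labels)) {
    abort("predicted and labels must have equal length")
  }
  pred_pos <- as_positive_call(predicted)
  true_pos <- as_positive_call(labels)
  out <- tibble(
    tp = sum(pred_pos & true_pos),
    fn = sum(!pred_pos & true_pos),
    fp = sum(pred_pos & !true_pos),
    tn = sum(!pred_pos & !true_pos)
  )
  class(out) <- c("mave_confusion", class(out))
  out
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values, and accuracy. A zero-denominator PPV or NPV
#' is reported as `NA` with its `*_defined` flag set `FALSE`, never
#' silently as 0.
#'
#' @param c A `mave_confusion` (or list/one-row data frame with `tp`,
#'   `fn`, `fp`, `tn`).
#' @return A `mave_metrics` one-row tibble: `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy`, `ppv_defined`, `npv_defined`, the confusion
#'   counts and `n_evaluated`.
#' @export
classification_metrics <- function(c) {
  tp <- c$tp; fn <- c$fn; fp <- c$fp; tn <- c$tn
  stopifnot(all(c(tp, fn, fp, tn) >= 0))
  if (tp + fn < 1 || fp + tn < 1) {
    abort("both truth classes must be represented")
  }
  n <- tp + fn + fp + tn
  out <- tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / n,
    ppv_defined = tp + fp > 0,
    npv_defined = tn + fn > 0,
    tp = as.integer(tp), fn = as.integer(fn),
    fp = as.integer(fp), tn = as.integer(tn),
    n_evaluated = as.integer(n)
  )
  class(out) <- c("mave_metrics", class(out))
  out
}

#' Reconstruct integer confusion counts from printed sensitivity/specificity
#'
#' Given a published sensitivity and specificity and the truth-set class
#' sizes, back-computes the integer confusion matrix (rounding half away
#' from zero) and flags whether the rounded counts reproduce the inputs at
#' 3 decimal places. Useful for checking the internal consistency of
#' published metric tables.
#'
#' @param sensitivity,specificity Reals in \[0, 1\].
#' @param n_plp,n_blb Truth-set class sizes.
#' @return A `mave_confusion` tibble with an extra `consistent` flag.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_plp, n_blb) {
  stopifnot(
    sensitivity >= 0, sensitivity <= 1, specificity >= 0, specificity <= 1,
    n_plp >= 1, n_blb >= 1
  )
  tp <- as.integer(round_half_away(sensitivity * n_plp))
  tn <- as.integer(round_half_away(specificity * n_blb))
  out <- tibble(
    tp = tp, fn = as.integer(n_plp) - tp,
    fp = as.integer(n_blb) - tn, tn = tn
  )
  out$consistent <- round(tp / n_plp, 3) == round(sensitivity, 3) &&
    round(tn / n_blb, 3) == round(specificity, 3)
  class(out) <- c("mave_confusion", class(out))
  out
}

#' Dynamic range between two score groups
#'
#' Robust separation between (for example) functionally normal and
#' abnormal control distributions: the absolute difference of group
#' medians standardized by a pooled MAD-based scale, plus the raw overlap
#' coefficient of the two empirical distributions (shared-bin histogram
#' estimate of the integral of `min(f, g)`).
#'
#' @param scores Numeric vector.
#' @param group_a,group_b Index vectors (or logical masks) into `scores`;
#'   both must be non-empty.
#' @param robust If `FALSE`, use mean/pooled-SD instead of median/MAD.
#' @param n_bins Histogram bins for the overlap estimate (default 50).
#' @return Tibble with `standardized_difference`, `overlap`,
#'   `raw_difference`, and a `degenerate_scale` flag (when the pooled
#'   scale is zero the standardized difference is reported as the raw
#'   difference).
#' @export
dynamic_range <- function(scores, group_a, group_b, robust = TRUE,
                          n_bins = 50L) {
  a <- scores[group_a]
  b <- scores[group_b]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  if (robust) {
    loc_a <- stats::median(a); loc_b <- stats::median(b)
    pooled <- sqrt((stats::mad(a)^2 + stats::mad(b)^2) / 2)
  } else {
    loc_a <- mean(a); loc_b <- mean(b)
    pooled <- sqrt((stats::var(a) + stats::var(b)) / 2)
  }
  raw <- abs(loc_a - loc_b)
  degenerate <- !is.finite(pooled) || pooled < .Machine$double.eps^0.5
  std <- if (degenerate) raw else raw / pooled
  breaks <- seq(min(scores[c(group_a, group_b)]),
    max(scores[c(group_a, group_b)]),
    length.out = n_bins + 1L
  )
  if (diff(range(breaks)) < .Machine$double.eps^0.5) {
    overlap <- 1 # all mass in one point for both groups
  } else {
    ha <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
    hb <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
    overlap <- sum(pmin(ha, hb))
  }
  tibble(
    standardized_difference = std, overlap = overlap,
    raw_difference = raw, degenerate_scale = degenerate
  )
}

#' Scan every classification threshold of a continuous score
#'
#' Evaluates the midpoint between each pair of consecutive sorted unique
#' scores; variants strictly below the threshold are called functionally
#' abnormal (the package-wide lower = abnormal convention).
#'
#' @param scores Numeric vector with at least two distinct values.
#' @param labels Truth labels (`PLP`/`BLB`) aligned with `scores`.
#' @return Tibble: one row per threshold with the full metric set.
#' @export
threshold_scan <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  u <- sort(unique(scores))
  if (length(u) < 2) abort("constant scores: nothing to scan")
  mids <- (u[-1] + u[-length(u)]) / 2
  purrr::map_dfr(mids, function(thr) {
    pred <- ifelse(scores < thr, class_abnormal, class_normal)
    dplyr::bind_cols(
      tibble(threshold = thr),
      classification_metrics(confusion_matrix(pred, labels))
    )
  })
}

#' Classify a continuous integrated score at a fixed threshold
#'
#' @param scores Numeric vector (oriented lower = abnormal).
#' @param threshold Scores strictly below it are called abnormal.
#' @return Character vector of predicted classes.
#' @export
classify_at_threshold <- function(scores, threshold) {
  ifelse(scores < threshold, class_abnormal, class_normal)
}
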