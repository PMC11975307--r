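# Independent oracles: deliberately naive implementations used only to
# check the package's results on small inputs.

# Brute-force Gaussian naive Bayes posterior by direct density arithmetic.
nb_posterior_oracle <- function(x, priors, means, vars) {
  lik <- vapply(1:2, function(ci) {
    prod(stats::dnorm(x, means[ci, ], sqrt(vars[ci, ])))
  }, numeric(1))
  post <- priors * lik
  (post / sum(post))[2]
}

# Exhaustive best 2-partition within-cluster sum of squares (n <= 12).
best_two_partition_wss <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 12)
  wss_of <- function(idx) {
    sum(vapply(unique(idx), function(g) {
      xs <- x[idx == g, , drop = FALSE]
      sum(scale(xs, center = TRUE, scale = FALSE)^2)
    }, numeric(1)))
  }
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    idx <- as.integer(intToBits(code))[seq_len(n)] + 1L
    if (length(unique(idx)) < 2) next
    best <- min(best, wss_of(idx))
  }
  best
}

# Brute-force confusion tally with an explicit loop.
confusion_oracle <- function(pred_pos, true_pos) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(pred_pos)) {
    if (true_pos[i] && pred_pos[i]) tp <- tp + 1L
    if (true_pos[i] && !pred_pos[i]) fn <- fn + 1L
    if (!true_pos[i] && pred_pos[i]) fp <- fp + 1L
    if (!true_pos[i] && !pred_pos[i]) tn <- tn + 1L
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Direct OddsPath arithmetic.
oddspath_oracle <- function(p1, p2) (p2 * (1 - p1)) / ((1 - p2) * p1)
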