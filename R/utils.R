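#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom graphics hist
NULL

# Round half away from zero (base round() is round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# One global seed governs all draws; stages consume deterministic substreams
# derived from it so that a stage rerun in isolation reproduces the pipeline.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 21474836L) * 97L + as.integer(offset)
}

with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, offset))
  force(code)
}

# Largest-remainder apportionment of n among proportions p (named).
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(p))
}

class_abnormal <- "functionally_abnormal"
class_normal <- "functionally_normal"

# Map predicted vocabulary onto the positive (pathogenic) indicator
as_positive_call <- function(x) {
  x <- as.character(x)
  ok_pos <- c(class_abnormal, "PLP", "pathogenic")
  ok_neg <- c(class_normal, "BLB", "benign")
  bad <- setdiff(unique(x), c(ok_pos, ok_neg))
  if (length(bad) > 0) {
    abort(paste0("unrecognized class labels: ", paste(bad, collapse = ", ")))
  }
  x %in% ok_pos
}
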