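test_that("score tables parse with controls identified", {
  ss <- toy_scoreset()
  expect_s3_class(ss, "mave_scoreset")
  expect_equal(nrow(ss$variants), 3)
  ctl <- scoreset_controls(ss)
  expect_equal(ctl$synonymous, "p.Ser215Ser")
  expect_equal(ctl$nonsense, "p.Arg196Ter")
})

test_that("duplicate variant rows collapse to their mean score", {
  suppressMessages(
    ss <- toy_scoreset(
      scores = c(0.4, 0.6, 1.0),
      variants = c("p.Arg175His", "p.R175H", "p.Ser215Ser")
    )
  )
  expect_equal(nrow(ss$variants), 2)
  expect_equal(ss$variants$score[ss$variants$variant == "p.Arg175His"], 0.5)
})

test_that("format and record errors are fatal and name the offender", {
  meta <- assay_meta("a", "TP53", "NM_000546.6")
  expect_error(
    parse_scoreset(data.frame(variant = "p.R175H", score = "high"), meta),
    "numeric 'score'"
  )
  expect_error(
    parse_scoreset(
      data.frame(variant = c("p.R175H", "p.Xyz999Qq"), score = c(1, 2)), meta
    ),
    "row 2"
  )
  expect_error(
    parse_scoreset(
      data.frame(variant = "p.R175H", score = 1, transcript = "NM_OTHER.1"),
      meta
    ),
    "transcript mismatch"
  )
})

test_that("orientation flips sign only when nonsense controls score high", {
  already <- control_scoreset(syn = c(0.9, 1.0, 1.1), non = c(-0.1, 0.0, 0.1))
  expect_equal(orient_scores(already)$variants$score, already$variants$score)

  flipped <- control_scoreset(syn = c(-0.1, 0.0, 0.1), non = c(0.9, 1.0, 1.1))
  oriented <- orient_scores(flipped)
  expect_equal(oriented$variants$score, -flipped$variants$score)

  degenerate <- control_scoreset(syn = c(0.5, 0.5), non = c(0.5, 0.5))
  expect_error(orient_scores(degenerate), "indeterminate")
})

test_that("orientation is idempotent over randomly generated sets", {
  set.seed(42)
  for (i in 1:10) {
    ss <- control_scoreset(
      syn = rnorm(5, sample(c(-1, 1), 1)), non = rnorm(5, sample(c(-2, 2), 1)),
      other = rnorm(10)
    )
    once <- orient_scores(ss)
    twice <- orient_scores(once)
    expect_equal(twice$variants$score, once$variants$score)
  }
})

test_that("rescaling matches hand arithmetic for all three methods", {
  # anchor: syn median 2.0, nonsense median 0.5 -> raw 1.25 maps to 0.5
  ss <- control_scoreset(syn = c(2.0), non = c(0.5), other = 1.25)
  out <- rescale_scores(ss, "anchor")
  expect_equal(out$variants$score[out$variants$consequence == "missense"], 0.5)

  mm <- rescale_scores(control_scoreset(syn = 0, non = 5, other = 10), "minmax")
  expect_equal(sort(mm$variants$score), c(0, 0.5, 1))

  # zscore with the sample-sd convention
  zs <- rescale_scores(control_scoreset(syn = 1, non = 2, other = 3), "zscore")
  expect_equal(sort(zs$variants$score), c(-1, 0, 1))
})

test_that("anchor rescaling pins control medians to exactly 1 and 0", {
  set.seed(7)
  ss <- control_scoreset(
    syn = rnorm(9, 1.3, 0.2), non = rnorm(7, -0.4, 0.3), other = rnorm(20)
  )
  out <- rescale_scores(ss, "anchor")
  v <- out$variants
  expect_equal(median(v$score[v$consequence == "synonymous"]), 1, tolerance = 1e-9)
  expect_equal(median(v$score[v$consequence == "nonsense"]), 0, tolerance = 1e-9)
})

test_that("degenerate rescaling inputs are fatal", {
  expect_error(
    rescale_scores(control_scoreset(syn = 1, non = 1, other = 2), "anchor"),
    "dynamic range"
  )
  const <- control_scoreset(syn = 1, non = 1, other = 1)
  expect_error(rescale_scores(const, "minmax"), "constant")
  expect_error(rescale_scores(const, "zscore"), "constant")
  neg <- control_scoreset(syn = 1, non = -1, other = 0.5)
  expect_error(rescale_scores(neg, "minmax", log_transform = TRUE), "log_offset")
})

test_that("merging respects the intersection and union policies", {
  s1 <- toy_scoreset(
    scores = 1:3 / 3,
    variants = c("p.Ala10Val", "p.Ala11Val", "p.Ala12Val"), assay_id = "one"
  )
  s2 <- toy_scoreset(
    scores = 4:6 / 6,
    variants = c("p.Ala11Val", "p.Ala12Val", "p.Ala13Val"), assay_id = "two"
  )
  m_int <- merge_scoresets(list(s1, s2), "intersection")
  expect_equal(m_int$variant, c("p.Ala11Val", "p.Ala12Val"))
  expect_false(anyNA(score_values(m_int)))
  expect_equal(unname(attr(m_int, "merge_counts")), c(2L, 2L))

  m_uni <- merge_scoresets(list(s1, s2), "union")
  expect_equal(nrow(m_uni), 4)
  expect_equal(sum(is.na(score_values(m_uni))), 2)
  expect_true(all(m_int$variant %in% m_uni$variant))
})

test_that("incompatible or non-overlapping sets fail to merge", {
  s1 <- toy_scoreset(variants = c("p.Ala10Val", "p.Ser215Ser", "p.Arg196Ter"))
  s2 <- toy_scoreset(variants = c("p.Ala11Val", "p.Ser216Ser", "p.Arg197Ter"))
  s2$meta$assay_id <- "other"
  expect_error(merge_scoresets(list(s1, s2), "intersection"), "empty intersection")
  s3 <- s2
  s3$meta$gene <- "BRCA1"
  expect_error(merge_scoresets(list(s1, s3)), "mismatch")
})

test_that("splice candidates are removed only when a cDNA assay is present", {
  mk <- function(platform) {
    parse_scoreset(
      data.frame(
        variant = c("p.Ala10Val", "c.30+2G>A", "p.Ser215Ser", "p.Arg196Ter"),
        score = c(0.3, 0.5, 1, 0)
      ),
      assay_meta(paste0("a_", platform), "TP53", "NM_000546.6",
        platform = platform
      )
    )
  }
  endo <- merge_scoresets(list(mk("endogenous"), {
    s <- mk("endogenous"); s$meta$assay_id <- "b"; s
  }))
  expect_equal(nrow(filter_splice_candidates(endo)), nrow(endo))

  mixed <- merge_scoresets(list(mk("endogenous"), {
    s <- mk("cDNA"); s$meta$assay_id <- "c"; s
  }))
  suppressMessages(filtered <- filter_splice_candidates(mixed))
  expect_equal(attr(filtered, "n_splice_removed"), 1L)
  expect_false(any(filtered$consequence == "splice_candidate"))
})

test_that("a written score set re-parses identically", {
  set.seed(11)
  ss <- control_scoreset(syn = rnorm(4, 1), non = rnorm(4), other = rnorm(30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scoreset(ss, path)
  back <- parse_scoreset(path, ss$meta)
  expect_equal(back$variants$variant, ss$variants$variant)
  expect_equal(back$variants$score, ss$variants$score, tolerance = 1e-12)
})
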