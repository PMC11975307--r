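test_that("the generator is exactly reproducible under a fixed seed", {
  a <- make_paperlike_study(seed = 21)
  b <- make_paperlike_study(seed = 21)
  expect_identical(a$scoresets, b$scoresets)
  expect_identical(tibble::as_tibble(a$truth), tibble::as_tibble(b$truth))
  c <- make_paperlike_study(seed = 22)
  expect_false(identical(
    a$scoresets[[1]]$variants$score, c$scoresets[[1]]$variants$score
  ))
})

test_that("config validation enforces the documented constraints", {
  expect_error(
    sim_config(class_proportions = c(
      benign_like = 0.5, lof = 0.5, dn = 0.2, hypomorph = -0.2
    )),
    "sum to 1|proportions"
  )
  expect_error(
    sim_config(class_sds = c(benign_like = 0, lof = 1, dn = 1, hypomorph = 1)),
    "positive"
  )
  expect_error(
    sim_config(class_means = c(benign_like = 1, lof = 0, dn = 0, hypomorph = 2)),
    "hypomorph"
  )
  expect_error(sim_config(cross_assay_correlation = 1), "correlation")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("near-noiseless scores sit on class means and classify perfectly", {
  cfg <- sim_config(
    n_variants = 60,
    class_sds = c(benign_like = 1e-9, lof = 1e-9, dn = 1e-9, hypomorph = 1e-9),
    seed = 31
  )
  st <- simulate_multimave(cfg)
  s <- orient_scores(st$scoresets[[1]])
  joined <- dplyr::inner_join(
    s$variants, st$ground_truth, by = "variant"
  )
  sensed <- joined[joined$class %in% c("lof", "dn"), ]
  expect_equal(sensed$score, cfg$class_means[sensed$class],
    tolerance = 1e-5, ignore_attr = TRUE
  )
  # every stage recovers the labels exactly in the noiseless limit
  lm <- assemble_labeled_matrix(harmonized_matrix(st), st$truth)
  pred <- classify_at_threshold(lm[[assay_ids(lm)[1]]], 0.5)
  m <- classification_metrics(confusion_matrix(pred, lm$label))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
})

test_that("assays are blind to mechanism classes outside their sensitivity map", {
  cfg <- sim_config(
    n_variants = 10000,
    class_proportions = c(benign_like = 0.4, lof = 0.1, dn = 0.4, hypomorph = 0.1),
    assays = list(
      sim_assay("lof_only", "LOF", "negative", senses = c("lof")),
      sim_assay("dn_aware", "DN", "negative", senses = c("lof", "dn"))
    ),
    seed = 32
  )
  st <- simulate_multimave(cfg)
  gt <- st$ground_truth
  for (i in 1:2) {
    v <- st$scoresets[[i]]$variants
    j <- dplyr::inner_join(v, gt, by = "variant")
    dn <- j$score[j$class == "dn"]
    ben <- j$score[j$class == "benign_like"]
    t_stat <- (mean(dn) - mean(ben)) /
      sqrt(var(dn) / length(dn) + var(ben) / length(ben))
    if (st$scoresets[[i]]$meta$assay_id == "lof_only") {
      expect_lt(abs(t_stat), 3) # no separation for unsensed DN variants
    } else {
      expect_lt(t_stat, -20) # strong depletion signal for sensed DN variants
    }
  }
})

test_that("empirical moments and cross-assay correlation match the configuration", {
  cfg <- sim_config(n_variants = 10000, cross_assay_correlation = 0.6, seed = 33)
  st <- simulate_multimave(cfg)
  sets <- lapply(st$scoresets, orient_scores)
  gt <- st$ground_truth
  ben <- gt$variant[gt$class == "benign_like"]
  # class means converge at 1/sqrt(n)
  v1 <- sets[[1]]$variants
  x1 <- v1$score[v1$variant %in% ben]
  expect_lt(abs(mean(x1) - 1.0), 3 * 0.15 / sqrt(length(x1)) + 1e-9)
  # within-phenotype-group correlation (both LOF assays) on one class
  v2 <- sets[[2]]$variants
  x2 <- v2$score[v2$variant %in% ben]
  expect_lt(abs(cor(x1, x2) - 0.6), 0.05)
  # across phenotype groups the noise is independent (~3.5 SE bound)
  v3 <- sets[[3]]$variants
  x3 <- v3$score[v3$variant %in% ben]
  expect_lt(abs(cor(x1, x3)), 3.5 / sqrt(length(x1)))
})

test_that("missingness injection is binomial, seeded, and drops empty rows", {
  st <- make_paperlike_study(seed = 34)
  m <- harmonized_matrix(st)
  m161 <- m[m$variant %in% st$truth$variant, ]
  for (a in c("assays", "provenance")) attr(m161, a) <- attr(m, a)
  class(m161) <- class(m)

  expect_identical(
    score_values(inject_missingness(m161, 0, seed = 1)), score_values(m161)
  )
  out <- inject_missingness(m161, 0.2, seed = 2)
  n_missing <- sum(is.na(score_values(out)))
  sigma <- sqrt(644 * 0.2 * 0.8)
  expect_lt(abs(n_missing - 0.2 * 644), 3 * sigma)
  expect_identical(
    score_values(inject_missingness(m161, 0.2, seed = 2)), score_values(out)
  )
  small <- m161[1:10, ]
  for (a in c("assays", "provenance")) attr(small, a) <- attr(m, a)
  class(small) <- class(m)
  expect_warning(inject_missingness(small, 0.95, seed = 3), "masked row")
})

test_that("the paper-like preset reproduces the published truth-set shape", {
  st <- make_paperlike_study(seed = 35)
  expect_equal(sum(st$truth$label == "BLB"), 32)
  expect_equal(sum(st$truth$label == "PLP"), 129)
  expect_true(all(st$truth$consequence == "missense"))
  lm <- assemble_labeled_matrix(harmonized_matrix(st), st$truth)
  expect_equal(prior_p1(lm), 129 / 161)
  # hypomorphs are generated but deliberately unlabeled
  gt <- st$ground_truth
  hyp <- gt$variant[gt$class == "hypomorph"]
  expect_equal(length(hyp), 12)
  expect_length(intersect(hyp, st$truth$variant), 0)
})

test_that("splice candidates appear on request and are filterable", {
  cfg <- sim_config(n_variants = 40, n_splice = 5, seed = 36)
  st <- simulate_multimave(cfg)
  m <- harmonized_matrix(st)
  expect_equal(sum(m$consequence == "splice_candidate"), 5)
  suppressMessages(f <- filter_splice_candidates(m))
  expect_equal(attr(f, "n_splice_removed"), 5L) # DN assays are cDNA-based
})
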