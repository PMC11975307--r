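# mavemeld

Combine several multiplexed assays of variant effect (MAVEs) into one
functional score or class per variant, evaluate the result against a
clinical truth set, and translate classifier performance into ACMG/AMP
PS3/BS3 functional-evidence strengths via the OddsPath framework.

It is written for groups that have two or more deep mutational scanning /
saturation editing score sets for the same gene–disease dyad (for example
paired loss-of-function and dominant-negative screens of a tumor
suppressor) and want to know whether integrating them lets functional
evidence be applied at a stronger level than the best single assay — and,
if not, to fall back to that single assay.

## The method in brief

Each assay *j* contributes a per-variant enrichment score. After
harmonization (orientation so that lower = more functionally abnormal,
then anchor rescaling mapping the synonymous-control median to 1 and the
nonsense-control median to 0), the variant-by-assay matrix **X** is
reduced to a single call per variant by four methods:

- **PCA** — the projection on the first principal component of **X**;
- **K-means** (k = 2) on the leading principal components, the
  lower-PC1 cluster called functionally abnormal;
- **Gaussian naive Bayes** — with truth classes *c* ∈ {BLB, PLP},
  P(c | x) ∝ π_c ∏_j N(x_j; μ_cj, σ²_cj), fit on a stratified 60/40
  train/test split;
- **random forest** — 500 trees; the score is the fraction of trees
  voting pathogenic.

Calls are scored against a truth set of BLB (benign/likely benign) and
PLP (pathogenic/likely pathogenic) variants: sensitivity, specificity,
PPV, NPV, and dynamic range. Evidence strength comes from the likelihood
ratio

    OddsPath = [P2 (1 − P1)] / [(1 − P2) P1]

where P1 is the truth-set PLP proportion (the prior) and P2 the PLP
proportion among variants sharing the functional call (the posterior);
the benign side uses the PLP proportion among functionally-normal calls
and reports the inverse. Cut points 2.08 / 4.33 / 18.7 / 350 map the
ratio to supporting / moderate / strong / very strong. Perfectly
concordant counts are handled by an add-one-discordant correction
(flagged in every report).

A synthetic study generator (`make_paperlike_study()`,
`simulate_multimave()`) emulates the four-assay TP53-like setting — two
LOF-sensing and two DN-sensing assays with opposite selection signs,
bimodal scores anchored by synonymous and nonsense controls, an
unlabeled hypomorphic class, cross-assay correlation and configurable
missingness — so every stage is testable without external data.

## Worked example

```r
library(mavemeld)
library(dplyr)

study <- make_paperlike_study(seed = 42)        # 32 BLB + 129 PLP, 4 assays
sets  <- lapply(study$scoresets,
                \(s) rescale_scores(orient_scores(s), "anchor"))
mat   <- merge_scoresets(sets, policy = "intersection")
lm    <- assemble_labeled_matrix(mat, study$truth)
split <- split_train_test(lm, train_fraction = 0.6, seed = 42)
nb    <- naive_bayes_integrate(split$train, split$test)

joined  <- inner_join(tidy(nb),
                      select(tibble::as_tibble(lm), variant, label),
                      by = "variant")
metrics <- classification_metrics(
  confusion_matrix(joined$predicted_class, joined$label))
metrics[, c("sensitivity", "specificity", "ppv", "npv")]
#>   sensitivity specificity   ppv   npv
#> 1           1           1     1     1

calibration_report(
  bind_cols(tibble::tibble(method = "naive_bayes",
                           is_single_assay = FALSE), metrics))
#>   side          p1     p2 oddspath code   correction_applied
#> 1 pathogenic 0.801 0.992      32.0 strong TRUE
#> 2 benign     0.801 0.0303   129    strong TRUE
```

The integrated classifier recovers every truth-set label on this
simulated study; with the add-one correction its OddsPath is 32 toward
pathogenicity and 129 (inverse) toward benignity, both at the "strong"
evidence level — so PS3/BS3 could be applied at strong strength, versus
moderate for the best single assay on the same study.

`run_pipeline("config.yaml")` executes the whole workflow
(harmonize → integrate → evaluate → calibrate) from score tables and a
truth-set CSV on disk, writing per-method variant scores, a metrics
table, and the evidence report; `write_study()` emits a ready-to-run
config for any simulated study. A thin CLI with the same stages ships in
`inst/scripts/mavemeld`.

Truth-set CSVs need columns `variant` (HGVS p. or c. notation; one-letter
amino acids accepted) and `label` (any of BLB/LB/B/benign/likely benign
and the PLP equivalents; VUS and conflicting rows are excluded). Score
tables need `variant` and `score`, with assay metadata supplied per assay
in the config.

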