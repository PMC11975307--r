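---
title: "Integrating multiplexed assays of variant effect and calibrating PS3/BS3 evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating multiplexed assays of variant effect and calibrating PS3/BS3 evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavemeld)
```

## The problem

A single multiplexed assay of variant effect (MAVE) measures one
molecular phenotype. When a gene's pathogenic variants act through more
than one mechanism — loss of function in some variants, dominant-negative
interference in others — any single assay is partially blind: a pure
dominant-negative variant can look functionally normal in an LOF-only
screen. The practical consequence for clinical variant classification is
a classifier with high positive predictive value (what it calls abnormal
really is pathogenic) but mediocre negative predictive value (its
"normal" calls include pathogenic variants it cannot see). Combining
assays that sense complementary mechanisms should recover those missed
variants, raising NPV — and with it the evidence strength that the
ACMG/AMP PS3/BS3 criteria permit — without sacrificing PPV.

mavemeld implements that workflow end to end: harmonize the score sets,
integrate them into one score or class per variant, evaluate against a
clinical truth set, and convert concordance into OddsPath likelihood
ratios and evidence-strength codes.

## Harmonization

Variants are identified by protein-level HGVS strings (three-letter
amino-acid codes canonical; one-letter input is normalized, simple
coding-level `c.` notation is accepted and intronic offsets are flagged
as splice candidates). Consequences — missense, synonymous, nonsense,
splice candidate — are derived from the notation itself; anything
ambiguous is an error, never a guess. Duplicate rows for one variant
collapse to their mean, since the modelling consumes average enrichment
scores.

Three conventions make the assays commensurable:

* **Orientation.** Every assay is flipped, if necessary, so lower score =
  more functionally abnormal, decided by comparing the synonymous and
  nonsense control medians (or an explicit metadata flag when a set lacks
  controls). Equal control medians are a fatal "orientation
  indeterminate" error. The operation is idempotent.
* **Rescaling.** The default `anchor` method maps the synonymous median
  to 1 and the nonsense median to 0 linearly, putting every assay on a
  shared control-anchored scale; `minmax` and `zscore` (sample-SD
  convention) are available, and a natural-log pre-transform is applied
  only when scores are positive or the user supplies an explicit offset —
  never a silent one. Whether the original four-assay analysis rescaled
  its input columns is not stated in the source material, so rescaling is
  on by default and can be disabled in the pipeline config
  (`rescale: none`).
* **Merging.** The default policy is `intersection` — only variants
  scored by every assay, giving a complete matrix with no imputation —
  which is the right choice when the goal is evidence strength.
  `union` (with NA masks) is retained for the alternative goal of scoring
  as many variants as possible. If any merged assay is cDNA-based, splice
  candidates are removed: an expression construct cannot sense splicing
  defects.

## Integration methods

All four methods return a `mave_integration` with the same per-variant
columns, and all respect the lower-is-abnormal convention.

**PCA** centers (optionally scales) the matrix and takes the first
principal component. The PC1 sign is anchored so abnormal falls low:
nonsense controls if present in the matrix, else PLP truth labels, else
alignment with the per-variant mean score. For classification, PC1 is
thresholded at the midpoint of the two k-means centers, keeping the
statistical route truth-label-free.

**K-means** (default k = 2, 25 restarts, seeded) runs on the leading
principal components covering ≥ 95% of variance. The cluster whose
centroid sits lower on PC1 is called functionally abnormal — control
anchoring, deliberately not truth-label anchoring, so the unsupervised
method stays independent of ClinVar-style training data.

**Gaussian naive Bayes** is fit on the training half of a stratified
split: class priors are the label proportions; each class/assay cell gets
a Gaussian by sample mean and sample (n−1) variance, floored at 1e−6 on
the rescaled scale so a zero-spread cell cannot produce an improper
density. Posteriors are computed entirely in log space (log-sum-exp
normalization), so scores hundreds of SDs from both class means still
yield proper probabilities. A posterior of exactly 0.5 is conservatively
called functionally normal.

**Random forest** (500 trees by default, seeded) reports the fraction of
trees voting pathogenic; training rows are scored by their out-of-bag
votes so the training half is not trivially memorized. Ties again go to
functionally normal. The forest itself is the randomForest
implementation; the package's contribution is the harmonization,
evaluation and calibration around it.

Stratified k-fold and leave-one-out cross-validation are provided for the
supervised methods; LOO refuses sets larger than a cap (default 200) and
directs the caller to k-fold.

### Train/test splitting

The split is stratified, preserving each class's proportion to within one
variant (fraction 0.6 by default, matching the original analysis). Rows
receive seed-derived random priorities and each class contributes its
quota of lowest-priority rows to training; this makes the partition a
function of the per-class counts only, so relabeling the classes leaves
the row partition unchanged. Stratification exists to protect the small
benign class (32 of 161 in the motivating truth set).

## Evaluation

The positive class is PLP / functionally abnormal throughout, matching
the direction in which PS3 evidence is applied. `classification_metrics`
reports sensitivity, specificity, PPV, NPV and accuracy; a
zero-denominator predictive value is `NA` with a flag, never a silent 0.
`reconstruct_confusion` inverts printed sensitivity/specificity pairs
back to integer confusion matrices (rounding half away from zero — the
convention that reproduces the published four-assay metric table) for
consistency checking. `dynamic_range` reports a robust
median/MAD-standardized separation plus a histogram-overlap coefficient;
robust statistics are the default because MAVE score distributions are
typically bimodal and heavy-tailed, with a mean/SD variant behind a flag.
`threshold_scan` evaluates every midpoint between consecutive unique
scores.

Whether published supervised metrics refer to the held-out test set or
the whole truth set is often unclear, so the pipeline reports both scopes
side by side (`evaluated_on` = "test" / "all"); calibration uses the
whole-truth-set rows.

## OddsPath calibration

With prior P1 (truth-set PLP proportion) and posterior P2 (PLP proportion
among variants sharing the call), OddsPath = [P2(1−P1)]/[(1−P2)P1]. The
pathogenic side uses P2 = tp/(tp+fp); the benign side uses
P2 = fn/(fn+tn) and reports the inverse ratio, so both directions share
one threshold table: supporting ≥ 2.08, moderate ≥ 4.33, strong ≥ 18.7,
very strong ≥ 350. These cut points come from the point-based Bayesian
calibration framework the field uses for PS3/BS3 assignment; they are
configurable since they are adopted, not derived, here.

A perfectly concordant cell (e.g. specificity 1 making the
pathogenic-side P2 exactly 1) would give an infinite ratio; the default
`add_one_discordant` correction adds one counter-example to the relevant
cell and flags the row. At truth-set size 161 this caps a perfect
classifier at OddsPath 32 (pathogenic) and 129 (benign side) — both
"strong", which is the honest ceiling a 161-variant truth set supports.
The correction changes nothing away from the boundary.

`calibration_report` emits one row per method per side, carries the best
single assay alongside, and flags `integration_improved`; when no
integrated method beats the best single assay on a side, the
recommendation is to use that single assay's score for evidence
assignment. Reports explicitly note that integrated scores are
combination-derived, to guard against double-counting evidence from the
constituent assays. Per-variant log-likelihood-ratio evidence assignment
is out of scope by design; the package assigns one evidence strength per
method and side.

## The synthetic study generator

The generator works at the per-variant score level the analysis consumes
(it does not model reads or selection dynamics). Each variant carries a
latent mechanism class — benign-like, lof, dn, or hypomorph — and each
assay senses only the classes in its sensitivity map, scoring unsensed
variants from the benign-like distribution. Class-conditional scores are
Gaussian (matching the naive Bayes modelling assumption; a heavy-tail
contamination flag exists for stress-testing the robust statistics),
noise is shared within a phenotype group to induce cross-assay
correlation, and positive-selection assays are emitted sign-flipped so
harmonization is exercised. Synonymous controls draw from the benign-like
component; nonsense controls draw from the lof component in *every*
assay — full loss of function is visible on any platform, and without
that, control-based orientation of a DN-only assay would be impossible.

Class counts are apportioned deterministically (largest remainder) rather
than drawn multinomially, so configured compositions are met exactly; one
global seed drives documented substreams (ids, class shuffle, scores,
missingness) so stages rerun in isolation reproduce the pipeline.

`make_paperlike_study()` fixes the study conditions used throughout the
tests: 161 labeled missense variants (32 BLB; 129 PLP split 8 lof / 121
dn), 12 unlabeled hypomorphs (intermediate variants lack clinical truth,
so they are generated but never labeled), 21 synonymous and 21 nonsense
controls, four assays (two LOF screens sensing lof+dn+hypomorph, two DN
reporters sensing dn+hypomorph, mixed selection signs), class means
1.0/0.0/0.0/0.5 with SDs 0.15/0.35/0.35/0.15 on the oriented scale,
within-phenotype correlation 0.6 (a documented, tunable guess — no
quantitative inter-assay correlations are published for this setting),
and no missingness. The noise levels were chosen once so that single
assays show the motivating pattern — near-perfect PPV, NPV well below 1,
sensitivity near 0.9 — and are not revisited.

What passing tests on this generator do **not** show: real MAVE scores
have batch structure, position-correlated errors, variant-specific
measurement variance and truth sets with ascertainment bias, none of
which are simulated. The generator validates the machinery and the
qualitative integration claim (NPV rises, PPV holds, evidence strengthens
when assays are complementary), not any quantitative claim about real
TP53 data.

## Numerical and design choices

* Duplicate score rows collapse by mean; conflicting truth labels are
  fatal, uncertain ones excluded with a count — truth sets feed evidence
  calibration and must be clean.
* Coordinates are 1-based residue indices; no genomic liftover, VCF
  ingestion or transcript mapping (delegated upstream).
* Ties (posterior or vote fraction exactly 0.5) go to functionally
  normal: conservative toward not asserting abnormality.
* `reconstruct_confusion` rounds half away from zero; base R's
  round-half-even would change reconstructed cells.
* Anchor rescaling requires a non-zero control-median gap; constant
  columns are fatal for PCA and z-scoring; k-means refuses fewer distinct
  points than clusters.
* All stochastic steps (splits, k-means restarts, forests, simulation)
  take explicit integer seeds; pipeline outputs contain no timestamps, so
  identical configs give byte-identical outputs.
* Test and acceptance problem sizes — 161-variant studies, 50-seed
  averages, n = 10^4 moment checks — are the package's chosen balance of
  statistical resolution against runtime.

## Known limitations

Missing-data integration is limited to masking and row dropping: no
imputation, and PCA/naive Bayes/forest require a complete matrix (use the
intersection policy). Calibration assumes the truth set predates the
assays; circularity auditing is the user's responsibility. The
evidence-strength table is adopted from the cited calibration framework,
not re-derived, and the package stops at per-method PS3/BS3 strengths —
it does not combine them with other ACMG/AMP evidence into final variant
classifications.
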