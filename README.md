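# tbscreen

Slide-level diagnosis of cervical liquid-based thin-layer cytology smears
under the Bethesda System (TBS, 2014), for cytopathology labs and
computational-pathology engineers building or evaluating AI-assisted
screening pipelines.

A whole-slide screening system has two halves. Upstream, deep models find and
characterize individual targets: a detector proposes boxes with class
probabilities, a fine-grained classifier refines them over 24 morphological
annotation classes, a patch-context model screens squamous false positives,
and a nucleus segmenter measures the cells that matter most. Those models are
**not** in this package — they are pluggable front-ends. `tbscreen`
implements everything downstream of their per-target evidence records:

* **Taxonomy** — the 24 annotation classes (AGC_A … Debris), their TBS
  correspondences, the detection-time merge/exclusion rules (12 detection
  classes), and clinical groupings; shipped as a versioned CSV.
* **Evidence records** — validated per-target records (detection + refined +
  patch + nucleus evidence, probabilities via `sigmoid(z) = 1/(1+e^-z)`),
  ASAP XML annotation I/O, JSON-lines streams, 608-px ROI splitting and
  1216-px context crops, optional IoU deduplication.
* **Nucleus morphometry** — BT.601 grayscale, mean nucleus gray and area
  (0.0625 µm²/px at 0.25 µm/px) under a segmentation mask.
* **Slide features** — a named 121-feature vector per slide (counts,
  probability statistics, patch means, nucleus quantiles) with explicit
  missingness, plus split-count feature importance.
* **Decision engine** — stage 1: a k-fold boosted ensemble calls the slide
  positive for squamous lesions when *any* member fires (the union rule:
  ensemble sensitivity ≥ every member's, specificity ≤ every member's), with
  threshold tuning that drives training sensitivity to 1.0; stage 2: a
  boosted subtype model (ASCUS/LSIL/ASCH/HSIL/SCC, ties break less-severe);
  a logical decision tree for infectious/AGC/EMC findings
  (`count(class, p ≥ p₀) ≥ n` branch rules); and a single reported lesion by
  clinical-treatment priority.
* **Quality control (DPIQC)** — 6000-px tiling, variance-of-Laplacian focus,
  HSI colour histograms, Otsu cellularity ratio, and a boosted
  qualified/unqualified gate.
* **Synthetic generators** — seeded, manifest-reproducible slide corpora and
  smear-tile images with controllable class mix, probability separation,
  focus, stain and cellularity, so the whole pipeline is testable offline.
* **Metrics** — biopsy-cohort sensitivity, and group-level
  sensitivity/specificity under the clinical equivalence rule (subtype
  confusions within a group are not errors).

## Worked example

Train the engine on a 600-slide synthetic corpus and evaluate on 300
held-out slides:

```r
library(tbscreen)

train  <- make_corpus(600, seed = 42)
engine <- train_engine(train, k = 10, seed = 42)
test   <- make_corpus(300, seed = derive_seeds(42, 2)[2])
ev     <- evaluate_engine(engine, test)
```

This prints (exact numbers from this run; everything is seed-deterministic):

```
held-out detection sensitivity: 0.994
held-out specificity:           1.000
intraepithelial sensitivity:    1.000
squamous subtype accuracy:      0.983
```

`detection sensitivity` is the fraction of truth-positive slides reported as
any lesion; `specificity` the fraction of truth-NILM slides reported NILM;
`intraepithelial sensitivity` applies the clinical equivalence rule
(predicting any intraepithelial lesion for a squamous or glandular truth
counts as correct). Per-slide reports carry the full evidence trail:

```r
reports <- predict_tbs(engine, test$records[1:3])
vapply(reports, `[[`, "", "final_tbs")
#> "NILM" "NILM" "NILM"
```

Split-count importance of the first ensemble member shows the patch-model and
detector evidence dominating, as one would expect when false-positive
screening is the binding constraint:

```r
head(importance_from_splits(booster_split_counts(
  engine$stage1$members[[1]], engine$stage1$feature_names)), 3)
#>                       feature splits importance
#> 101 patch_True_LSIL_mean_prob     23  0.1513158
#> 12        det_ASC_H_mean_prob     22  0.1447368
#> 99  patch_True_HSIL_mean_prob     17  0.1118421
```

Biopsy-cohort sensitivity is exact arithmetic on printed counts:

```r
biopsy_sensitivity(n_biopsies = 980, n_positive = 837, n_missed = 44)
#> 0.9474313
```

A thin CLI over the same functions lives at `inst/cli/tbscreen.R`
(`simulate`, `qc`, `evaluate`, `report` subcommands).

## Documentation

The methods vignette (`vignettes/tbs-screening-pipeline.Rmd`) documents the
models, every tunable parameter with its default and rationale, the synthetic
study conditions and what they do and do not establish, and the numerical
conventions (tie-breaks, missingness, thresholds).
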