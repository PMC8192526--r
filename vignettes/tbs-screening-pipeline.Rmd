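---
title: "Slide-level TBS classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slide-level TBS classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbscreen)
```

## The problem

Cervical liquid-based cytology screening asks a reader to find a handful of
abnormal cells among tens of thousands on a whole-slide image, and to report a
single diagnosis under the Bethesda System (TBS, 2014): negative (NILM), one
of the squamous intraepithelial lesions (ASCUS, LSIL, ASCH, HSIL, SCC), a
glandular lesion (the AGC family), endometrial cells (EMC), or an infectious
finding (Trichomonas, Candida, HSV, Actinomyces, clue cells).

`tbscreen` implements the *slide-level* half of an AI-assisted screening
architecture. Upstream deep models — a detector, a fine-grained classifier, a
patch-context classifier and a nucleus segmenter — are deliberately out of
scope: they are pluggable front-ends whose outputs arrive as per-target
evidence records. Everything downstream of those records is implemented and
testable here: the annotation taxonomy, evidence fusion into a fixed slide
feature vector, the boosted two-stage diagnosis with its sensitivity-first
ensemble rule, the logical decision tree for non-squamous findings, the image
quality-control gate, and the screening metrics. A synthetic generator stands
in for the proprietary slide corpus so that every stage runs at desk scale.

## The annotation taxonomy

Targets are annotated in 24 morphological classes (`load_taxonomy()`), each
mapping to one or more TBS diagnoses — e.g. a single koilocyte (KC) indicates
LSIL, while superficial squamous epithelium (MC) is negative. At detection
time, morphologically similar classes are merged (AGC_A with AGC_B; KC with
ASC_L_F; the five high-N:C and carcinoma classes C6–C10) and six classes with
no diagnostic signal are excluded (GEC, MC, RC, Neutrophils, Mucus, Debris).
Enumerating those rules yields 12 detection classes; because the merge rules
admit more than one reading, the grouping lives in the shipped CSV
(`inst/extdata/taxonomy.csv`) rather than in code, and any alternative
grouping can be supplied as a file.

The rare glandular diagnoses (AGC_NOS, AGC_FN, AIS, ADC) collapse into one
merged AGC prediction class; clinical groups (negative / squamous /
glandular / infectious / EMC) drive both the priority rule and the
evaluation equivalences.

## Evidence records and geometry

A `TargetRecord` fuses, for one detected region: the detection class and
probability, the refined 24-class call and probability, an optional
patch-context label (True/False HSIL/LSIL — the patch model's false-positive
screen, defined only for squamous classes), and optional nucleus morphometry
(defined only for SC, ASC_L_S, ASC_H_S, the classes routed to segmentation).
Raw classifier scores map to probabilities through the logistic function
`sigmoid()`.

Geometry follows 0-based, half-open pixel conventions so tiling arithmetic is
exact. Oversized annotation regions are decomposed by `split_roi()` into an
equal-as-possible grid with sides at most 608 px; a human annotator would
split along morphology, which no deterministic rule can reproduce, so a grid
is used. `context_crop()` returns the 1216-px context window centred on a
target, shifting inward at slide borders rather than padding, because
shifting preserves true pixel statistics for downstream features; zero
padding is reserved for slides smaller than the window. Annotations round-trip
through the ASAP XML dialect (`read_asap_annotations()`,
`write_asap_annotations()`).

Nucleus statistics use ITU-R BT.601 luminance for grayscale conversion (the
paper-of-record convention in imaging libraries, fixed here for bit
reproducibility), the arithmetic mean of gray values under the mask (median
and integrated optical density were considered and not implemented), and
0.0625 µm² per pixel at the 0.25 µm/pixel scan resolution. Multi-component
masks are summarized jointly with the component count recorded.

## The 121-feature slide vector

`default_feature_schema()` composes 121 named features: per detection class,
count and max/mean probability (36); per retained refined class, counts above
0.5 and 0.9 plus max probability (54); top-5 mean probability per squamous
refined class (8); mean patch probability per patch label (4); 10/50/90%
quantiles of nucleus gray and area for the three segmented classes (18); and
the total target count (1). The schema is data, not code: any YAML schema of
the same grammar can replace it.

Two conventions matter downstream:

* **Missing ≠ zero.** Statistics over an empty set (e.g. max SCC probability
  on a slide with no SCC targets) are reported as 0 with an explicit missing
  flag, and `feature_matrix()` converts flagged values to `NA` so the boosted
  model can route missingness down its default branches. Counts are never
  missing.
* **Order invariance.** Aggregation sorts records internally by probability
  then coordinates, so feature vectors are invariant to record order and
  count features are additive across record batches (both property-tested).

Feature importance follows the split-count convention: the number of splits
on each feature across all trees, normalized to sum one
(`importance_from_splits()`, fed by `booster_split_counts()`).

## The two-stage decision and the any-positive rule

Stage 1 is a binary gradient-boosted classifier (positive vs negative for
squamous intraepithelial lesions) trained as a k-fold cross-validation
ensemble (default k = 10): each member trains on k−1 stratified folds with
early stopping on its held-out fold. At prediction time the slide is positive
when **one or more** members call it positive. This union rule can only raise
sensitivity and lower specificity relative to any single member — exactly the
trade a screening application wants — and that inequality is asserted as a
test invariant rather than any corpus-bound number.

`tune_sensitivity()` sets the screening operating point: each tuning-set
positive is assigned to the member that scores it highest, and that member's
threshold drops to the minimum score over its assigned positives (members
covering no positive never fire). Tuning-set ensemble sensitivity is 1.0 by
construction, thresholds stay as high as the cover allows, and lowering any
threshold can never reduce ensemble sensitivity.

Stage 2 is a multiclass boosted model over the five squamous subtypes,
applied only to stage-1 positives. Exact probability ties break toward the
**less severe** subtype: the paper of record is silent on ties, subtype
confusion does not change clinical management, and false escalation carries
communication cost.

Hyperparameters (depth 3, learning rate 0.2, at most 60 rounds, early
stopping patience 10, single-threaded for determinism) are conservative
defaults exposed through the training functions; nothing in the method
depends on them finely.

## The logical decision tree

Infectious lesions, merged AGC and EMC have distinctive morphology, so simple
count rules suffice: a branch fires when the slide has at least `min_count`
targets of its classes with refined probability at least `min_prob`
(`logic_tree_decide()`). The shipped defaults (probability 0.7 with count 3
for the five infectious branches; 0.7 with count 2 for the rarer EMC and
merged-AGC branches) were calibrated once against the shipped synthetic
corpus conditions and written into `default_logic_config()`; the original
system's thresholds are not public, and every value is overrideable via YAML.

`finalize_report()` resolves multiple findings to a single reported lesion by
clinical-treatment priority — SCC > HSIL > ASCH > AGC > LSIL > ASCUS > EMC >
HSV > TRI > ACTINO > CAN > CC > NILM. The source method states the principle
(report the lesion whose treatment is most urgent) but not the order; this
order follows treatment urgency of the TBS 2014 categories and is an explicit
design choice of this package.

## The quality-control gate

A digitized smear is tiled (nominally 6000 × 6000 px; edge tiles truncated
and flagged, never padded). Per tile:

* **Focus** — variance of the 4-neighbour 3×3 Laplacian response over the
  valid interior. The Laplacian stencil and the variance summary are fixed
  choices among the family of "Laplacian gradient" focus measures.
* **Colour** — 32-bin normalized histograms in HSI space, with the standard
  geometric conversion (I = (R+G+B)/3, S = 1 − min/I, geometric hue angle;
  hue 0 for achromatic pixels).
* **Cellularity** — Otsu's threshold over the 256-level histogram
  (between-class variance maximization, ties to the lowest threshold) with
  the **dark** class as foreground, because Papanicolaou-stained cells are
  dark on a bright-field background; a polarity flag covers other stains.
  Constant tiles return ratio 0 by convention. Note that on a pure-noise
  (cell-free but noisy) tile Otsu still bisects the noise — the gate relies
  on the joint feature set, not on the ratio alone.

Tile features are summarized per slide (quantiles and means of log-scaled
focus and of the cell ratio, tile-means of the histogram bins) and scored by
a boosted gate (`train_qc_gate()`, `qc_gate()`), thresholded at 0.5.

## What the synthetic generator emulates — and what it does not

`make_corpus()` draws labelled slides under fixed study conditions chosen
once as clinically plausible desk-scale defaults:

* lesion-bearing slides carry Poisson numbers of lesion targets with
  class-specific means (e.g. many organisms on infectious slides, mean 12;
  few equivocal cells on ASCUS slides, mean ~4.5 in total), with
  detection/refined probabilities Beta(8, 2) for confident lesions,
  Beta(5, 3) for ASCUS, Beta(6, 3) for ASCH;
* every slide carries background normal single cells with nucleus statistics,
  and detector false positives at Poisson rate 1.5 with Beta(2, 6)
  probabilities;
* nucleus gray falls and area rises with lesion grade (hyperchromasia,
  nuclear enlargement): SC 120/480 px, ASC_L_S 100/900 px, ASC_H_S 75/1400
  px (means of Normal draws);
* the class mix is imbalanced the way screening corpora are (44% NILM, rare
  AGC/EMC/HSV), so rare-class handling is exercised.

All randomness flows from one seed through per-slide derived seeds recorded
in the manifest, so corpora regenerate byte-identically, piecewise.

`simulate_tile()` renders stained-cell blobs on a bright background with
exactly one factor perturbed per quality preset (defocus blur, low
cellularity, washed-out stain). The default tile is 256 px — large enough for
stable focus/histogram/Otsu statistics while letting corpora of hundreds of
tiles generate in seconds; the QC arithmetic itself is size-agnostic and the
nominal 6000-px tiling is exercised directly by `tile_image()`.

What passing tests on this generator **does** show: the decision engine
recovers planted ground truth through the full record→features→ensemble→
report path; the union rule, tuning contract, determinism and metric
equivalences hold end to end. What it does **not** show: performance on real
smears. The generator draws independent targets with clean class-conditional
distributions; it has no spatial correlation, no staining batch effects, no
detector failure modes correlated across a slide, and no photorealistic
morphology. Corpus-bound performance figures from any real deployment are
therefore neither claimed nor reproducible here, and the package's own
evaluation bands (held-out sensitivity ≥ 0.95, specificity ≥ 0.80 on the
default conditions; quality-gate accuracy ≥ 0.95) characterize the synthetic
conditions only.

## Problem sizes and numerical conventions

The shipped evaluation trains on 600 synthetic slides and evaluates on 300
held-out slides (decision engine), and 400/200 tiles (quality gate) — sizes
chosen so the full suite runs in minutes on one CPU while keeping every class
represented in every cross-validation fold. Other conventions, gathered in
one place:

* probabilities validated to [0, 1] at record construction; refined classes
  to 1..24;
* quantiles are R type-7 throughout;
* `which.max` tie-breaks: first maximum — severity-ascending order makes this
  "least severe wins" in stage 2, and lowest-threshold in Otsu;
* biopsy-cohort sensitivity is computed as `(positives − missed)/positives`
  in exact double arithmetic (integer counts divide exactly within double
  precision);
* evaluation equivalences: subtype confusions within a clinical group are not
  errors, squamous/glandular confusion still counts as a detected
  intraepithelial lesion, and intraepithelial sensitivity is reported both
  with and without ASCUS truths (borderline calls concentrate there);
* multi-lesion slides are evaluated against the single priority-resolved
  label.

## A worked run

```{r example, eval = FALSE}
set.seed(NULL)  # all randomness below flows from explicit seeds
train <- make_corpus(600, seed = 42)
test  <- make_corpus(300, seed = derive_seeds(42, 2)[2])
engine <- train_engine(train, k = 10, seed = 42)
ev <- evaluate_engine(engine, test)
ev$detection$sensitivity; ev$group$specificity

reports <- predict_tbs(engine, test$records[1:3])
vapply(reports, `[[`, "", "final_tbs")
```

## Known limitations

* The 121-feature schema is a reconstruction of the evidence sources, not the
  original (non-public) feature list; importance rankings are therefore not
  comparable feature-by-feature with any published histogram.
* The logic-tree thresholds are calibrated to the synthetic conditions; real
  deployments must recalibrate on their own validation sets.
* Deduplication of overlapping detections is exposed (`dedup_records()`,
  IoU threshold) but disabled by default, since the upstream suppression
  policy is detector-specific.
* The QC gate sees single-factor degradations; real scans degrade jointly.
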