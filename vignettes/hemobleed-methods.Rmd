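---
title: "Detecting postoperative major bleeding in Chinese EMR text: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting postoperative major bleeding in Chinese EMR text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemobleed)
```

## The problem

Major bleeding after chest, abdominal or gynecological tumor resection is a
low-prevalence outcome (roughly 4–5% of stays) that is rarely recorded as a
structured diagnosis in Chinese hospital systems. The evidence is scattered
across free-text course notes ("腹腔引流出血性液体", "行剖腹探查止血术"),
hemoglobin laboratory series, and transfusion records. `hemobleed` turns one
hospitalization — a `patient_visit` bundling these sources — into a binary
classification: *major bleeding present / absent*, following the ISTH
definition: fatal or symptomatic bleeding in a critical area or organ, **or**
a hemoglobin fall of ≥ 2 g/dL, **or** transfusion of ≥ 2 units of
erythrocyte concentrate.

The rare-event setting drives every design choice below: with fewer than
one positive per twenty visits, a term-frequency representation scatters the
signal, and an unweighted classifier collapses to the majority class. The
package's answer is a compact engineered feature space (270 binary
indicators) plus a loss function that concentrates gradient on the rare
class.

## The feature space

Each visit maps to a 270-vector of presence/absence indicators, in a fixed,
versioned order (`inst/extdata/catalog_v1.tsv`):

* **cat1 (261)** — manually curated bleeding regexes over normalized text.
  Twenty of the 270 features are flagged `key`; nineteen of those are
  regexes (the twentieth is the structured rule below). Only these twenty
  are published with glosses; the remaining 242 cat1 entries in the shipped
  catalog are a *documented reconstruction*: decompositions of the key
  patterns (site × event grids such as 吻合口…渗血) plus standard bleeding
  lexicon (呕血, 黑便, 失血性休克, 氨甲环酸, …). The catalog is therefore
  faithful in structure and dimension, not a replica of the unpublished
  lexicon; it is user-replaceable via the TSV.
* **cat2 (8)** — tokens selected by corpus frequency after Chinese word
  segmentation, excluding anything already covered by a cat1 pattern.
  Frequency means *term* frequency (total occurrences), not document
  frequency — the counting convention is unstated upstream, and term
  frequency is adopted and flagged here. The default threshold (900) is
  tied to a ~33,654-record reference corpus; scale it as roughly 26.7 per
  1,000 notes elsewhere.
* **cat3 (1)** — the quantitative ISTH rule applied to the visit's labs,
  transfusions and critical-site text ("structured recognition").

Aggregation across a visit's notes is logical OR: the classification unit
is the stay, and OR is the minimal aggregation consistent with
presence/absence semantics. It also yields a useful invariant — appending
text can flip features only 0→1 — which the property suite checks on 1,000
random strings.

Text normalization (NFKC width folding, Latin case folding, whitespace
collapse) is idempotent and applied before all matching, so catalog patterns
are written with lowercase Latin (`ml`, `u`, `hb`). Segmentation is forward
maximum matching over a small clinical lexicon; it is deliberately pluggable
behind one contract — the concatenation of tokens must recover the input —
so a richer segmenter (e.g. a jieba port) can be swapped in without touching
feature selection.

## The ISTH rule and its numeric conventions

`adjudicate()` evaluates the three-way disjunction with these conventions,
each of which is open in the clinical definition and fixed here:

* **Baseline hemoglobin** = last measurement at or before surgery; if none
  exists, the first postoperative value. Drop = baseline − postoperative
  minimum. Comparisons are *inclusive* (a drop of exactly 2.0 g/dL is
  major) — the definition says "≥".
* **Units**: laboratories in China report g/L; the threshold is 2 g/dL =
  20 g/L. The generator emits g/L by default precisely to keep this
  conversion path exercised. Adjudication is invariant to the recorded
  unit (tested).
* **1 erythrocyte unit = 200 mL** (Chinese blood-banking convention),
  configurable via `isth_thresholds(ml_per_unit=)`. Volumes and units may
  be mixed: 1 U + 150 mL = 1.75 U.
* **Transfusion window**: surgery to end of stay; pre/intra-operative
  transfusions are excluded by default (`include_intraop = TRUE` reverses
  this), because the outcome is *postoperative* bleeding.
* **Missing data** make a criterion false rather than raising an error — a
  screening tool should degrade conservatively, not crash on sparse stays.
* **Fatal bleeding** is out of detection scope: the schema carries no death
  records; critical-site detection is delegated to flagged text patterns.

## Models

All three classifiers consume the same 270-vector; the catalog order is
frozen because the CNN convolves along it.

* **Logistic regression**: one weight per feature plus bias, logistic link.
* **1-D CNN**: 32 filters of width 3 (ReLU) over the feature axis, global
  max pooling, one dense sigmoid unit. With global max pooling over sparse
  binary input, filters whose pre-activations start non-positive never
  recover ("dead ReLU"), so the convolution bias is initialized at +0.1 —
  a numerical choice, not a modeling one.
* **KNN**: exact brute-force Euclidean neighbours, k = 5 (k is unreported
  upstream; 5 is the conventional odd default, exposed as a parameter).
  Distance ties resolve by stored-row order, keeping predictions
  deterministic; the test suite holds the implementation equal to an
  independent all-pairs oracle.

LR and CNN minimize mean **sigmoid focal cross-entropy** (α = 0.25, γ = 2,
the community defaults; the recipe names the loss but not its parameters)
with minibatch Adam (lr 1e-3, batch 32), a seeded stratified 20% validation
split, and early stopping on validation loss with patience 10. The analytic
gradient of the focal loss w.r.t. the logit,

$$\partial_z FL = y\,\alpha(1-p)^\gamma\,[\gamma p \log p - (1-p)]
  - (1-y)(1-\alpha)p^\gamma\,[\gamma(1-p)\log(1-p) - p],$$

is verified against finite differences in the tests. Decision threshold is
0.50 with ties classified positive: the tool screens for subsequent manual
review, so sensitivity wins tie-breaks.

Epochs, batch size and learning rate are unreported upstream; the defaults
above are stated in `model_config()` and exposed everywhere. Two trainings
with identical data and config produce identical loss trajectories (seeded
shuffling and initialization).

## The synthetic world

`generate_corpus()` emulates the corpus the pipeline was designed for:
visits at 4.31% prevalence, Poisson(21) course records (≈ 33,654/1,600),
age ~ Normal(62.86, 9.16²) truncated at 18, 48.5% female, hemoglobin in
g/L. Every positive visit realizes exactly one recorded mechanism — a
28–45 g/L postoperative fall, a 2–4 U red-cell transfusion, or a
critical-site narrative drawn from the template bank — and the ground truth
records which, so each stage can be tested against the mechanism that
should trigger it. Negative visits carry distractors at rate 0.3
(sub-threshold blood loss ~50–150 mL, negated bleeding 无出血, preoperative
anemia, 1-unit transfusions), mirroring the hard negatives that motivated
the upstream exclusion criteria. Slot values not fixed by any stated
statistic (baseline hemoglobin 110–150 g/L, drainage volumes, note timing)
were chosen once at clinically ordinary magnitudes and are not tuned.

Two deliberate limitations:

* The corpus is **separable by construction**: the cat3 feature *is* the
  rule that defines the label, and mechanism templates contain
  positive-only phrases. A green end-to-end test establishes that the
  plumbing — extraction, loss, optimization, thresholding — detects rare
  positives it should detect; it says nothing about performance on real
  prose, where the published experience is ~0.89/0.82
  sensitivity/specificity for LR.
* Linguistic realism stops at triggering/avoiding the catalog: template
  lengths, vocabulary breadth and note redundancy are not calibrated
  (no such statistics are published).

With measurement noise (default SD 2 g/L) an intended hemoglobin fall near
the 20 g/L threshold can cross it in either direction; that is a property of
the stated world. The exact generator/adjudicator agreement property is
therefore asserted on noise-free configurations (`hb_noise_sd = 0,
noise_rate = 0`), where it holds with sensitivity = specificity = 1.

## Reconstructing printed metric tables

Published evaluation tables print six metrics to 4 d.p. at known n and
prevalence. Because the metrics are deterministic images of a small integer
confusion matrix, the matrix is recoverable by exhaustive enumeration
(`reconstruct_cm()`): at n = 400 with 19 positives, the row (0.8275,
0.8947, 0.8241, 0.2024, 0.9937, 0.3301) is produced by exactly one matrix,
(tp 17, fn 2, fp 67, tn 314). One printed value (training-set KNN accuracy
0.9643) is the image of 1543/1600 = 0.964375, which half-up rounds to
0.9644; the nearest IEEE double to 0.964375 lies just below the tie, so
float printing yields 0.9643. Matching therefore accepts round-half-up *or*
truncation at the printed precision — under that rule all six published
rows invert uniquely.

## Degenerate inputs and tie-breaks, collected

* Metrics with zero denominators are `NA`, never 0 (no silent specificity
  inflation on single-class sets).
* ROC requires both classes; AUC is computed by trapezoid *and* rank-based
  concordance and must agree to 1e-12 (ties in scores are exercised
  explicitly).
* Probability exactly at threshold → positive. KNN distance ties → stored
  order. Empty hemoglobin series → criterion false. Empty text → zero
  feature vector.
* `split_corpus` splits at the visit level so no stay straddles
  train/test; the upstream description alternates between "notes" and
  "patients" as the allocation unit, and the visit-level reading is the one
  that prevents leakage.

## Known limitations

The 242 reconstructed cat1 patterns and the 8 shipped cat2 tokens stand in
for unpublished selections; ranking experiments against the original corpus
are impossible, which is why the acceptance suite checks structural
contracts (dimension 261/8/1, unique table inversion, rule exactness,
oracle equivalences, rare-event detection at desk scale) rather than
headline numbers. Quantity extraction covers Chinese numerals 一–十 and 两
only, and clause-local patterns can misread unusually interleaved prose;
the 50-snippet annotated fixture pins the supported constructions.
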