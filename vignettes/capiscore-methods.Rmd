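---
title: "CAPI-score: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAPI-score: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capiscore)
```

## The classification problem

Nailfold videocapillaroscopy (NVC) grades microvascular damage into five
disease patterns: normal, non-specific, and the scleroderma stages
SSc-early, SSc-active, SSc-late. The three SSc stages track progressive
microangiopathy — giant capillaries appear early, capillary loss
(falling density) and architectural distortion (abnormal, i.e. branching
or bushy, shapes) dominate late. CAPI-score encodes that clinical
progression as a deterministic decision tree over five exam-level
features, so that two analysts given the same measurement table always
obtain the same pattern, with a trace of the conditions that produced it.

The package starts at measurement tables (per-image counts from any
capillary-detection software); it deliberately does not touch pixels.

## From images to features

An exam is a set of images, each contributing a capillary count, the
millimetres of nailfold it covers, and counts of giant / abnormal /
tortuous capillaries and haemorrhages. Three quality rules exclude exams
before analysis, checked in a fixed order so each exclusion has one
deterministic reason: fewer than 8 images (`min_images`, configurable for
sensitivity analyses), missing calibration, and the degenerate
zero-capillary exam for which density and percentages are undefined.

Aggregation pools counts over the whole exam:

* density = Σ capillaries / Σ width — the *pooled* estimator weights each
  image by the width it actually covers. The alternative, the unweighted
  mean of per-image densities, is exposed as `method = "image_mean"` but
  is not the default: it over-weights narrow images, and pooling matches
  how per-exam totals are naturally reported (hundreds of capillaries
  over ~44 mm per exam).
* percentages use the exam-wide capillary denominator rather than
  averaging per-image percentages, which would be unstable for images
  with few capillaries.
* haemorrhage presence means pooled haemorrhage count ≥ 1 — the minimal
  reading of "presence of haemorrhages"; no count threshold is defined
  for it anywhere in the rules.

Counts, never percentages, are the canonical image-level representation;
this removes any ambiguity about denominators when pooling. A zero
haemorrhage count must be recorded explicitly, because the normal vs
non-specific rule depends on presence/absence and silent missingness
would flip classifications.

## The rules and their boundary semantics

```{r}
capi_thresholds()
```

The eleven cut-offs live in one configuration object; classification
output records the threshold set used (`thresholds_used.txt`, and the run
manifest), so sensitivity analyses never require code edits. Two
semantics are worth spelling out:

* Inequality directions are taken verbatim from the published rule
  statements: ≤ 6 caps/mm, > 10% abnormal and giant detection (> 0) for
  the SSc gate; ≥ 5 caps/mm for the staging split; ≥ 10% / ≥ 5% for the
  early→active override; ≥ 33% / ≤ 7% for the late→active override and
  ≤ 7% / ≥ 15% for the final late override; ≥ 20% / ≥ 2% for the
  non-specific gate. Feature values are compared exactly as computed, with
  no rounding — rounding would move boundary cases, and the test-suite
  probes every boundary at ±1e-9.
* Rule 3 is evaluated late-default → active-override → late-final-override,
  with the final override absolute ("regardless of these conditions").
  Both override clauses can fire simultaneously (e.g. giants 5%,
  abnormals 5%: abnormals ≤ 7 argues active, giants ≤ 7 argues late);
  the stated precedence resolves every such conflict in favour of
  SSc-late. This is the only ordering consistent with the rule's wording,
  and it is pinned by dedicated precedence tests.

The non-SSc branch reaches the normal/non-specific rule only via the SSc
gate, whose negation already guarantees density > 6 caps/mm; the rule's
"when density is > 6" is therefore treated as an assertion, not a third
branch.

## Gold standard from rater verdicts

Each exam carries verdicts from exactly three blinded raters (the design
is fixed at three; n-rater generalisations would change the consensus
semantics). Consensus is a ≥ 2/3 majority; 3/3 is full consensus.
`ungradable` votes participate as ordinary labels — a two-vote ungradable
majority is an ungradable consensus — and ungradable or non-consensual
exams are excluded from the gold-standard cohort. A (pattern, pattern,
ungradable) triple with two agreeing patterns is a pattern consensus: the
majority rule is applied literally, with no special abstention handling.

## Evaluation protocol

Accuracy is assessed per algorithm step: the SSc/non-SSc gate on all
paired exams, staging restricted to exams whose *gold* label is SSc, the
normal/non-specific split restricted to gold non-SSc exams, and the
overall five-class comparison. Restricting by gold label means an exam
the algorithm routed to the wrong side of the gate is excluded from the
restricted step (it is already penalised in the gate and overall steps)
rather than counted as a staging error; reports carry both `n` (pairs
compared, equal to the confusion-matrix total) and `n_gold_restricted`
(the gold-side restriction before that exclusion) so either accounting
is available. Confusion matrices are fixed as rows = true,
columns = predicted. Precision or recall for a class absent from the
predictions or the truth is reported as `NA` and excluded from any
averaging — substituting 0 would distort summaries for unrepresented
classes, which matters for the rare SSc-late pattern.

## What the simulator emulates — and what it does not

The generator reproduces the *structure* of a multi-centre NVC cohort:
a five-pattern mix defaulting to 231:326:162:122:40 over 881 exams,
24.8 (s.d. 9.9) images per exam truncated at 8, and per-image widths of
1.76 (s.d. 0.3) mm so expected exam width is ≈ 43.7 mm. Per exam, a
latent density is drawn from the pattern's truncated normal; per-image
capillary counts are Poisson with mean latent density × width (a standard
count law — only per-exam means and dispersions are specified anywhere,
so the count distribution is a modelling choice); morphology counts are
binomial with the profile's per-capillary probabilities; haemorrhages are
Poisson per image. Raters report the true pattern with probability
1 − `rater_error_rate` and otherwise a uniformly chosen *adjacent*
pattern along the severity chain normal – non-specific – early – active –
late, reflecting the qualitative observation that expert disagreement
concentrates between neighbouring patterns. The default error rate of
0.2 was fixed once as a realistic expert-panel disagreement level; a
single adjacent-error parameter cannot jointly match any particular pair
of observed consensus and full-consensus rates, and no attempt is made to
tune it to one.

Two presets ship with the package. `"separable"` places each pattern's
distributions well inside its rule region (e.g. SSc-active at density
5.5 caps/mm with 20% giants, which classifies active on *both* sides of
the staging split, making the preset robust to density noise); it is the
correctness preset — the classifier recovers the generating pattern in
≥ 99% of exams, so any closed-loop failure indicates a pipeline defect,
not preset overlap. `"overlapping"` pulls means toward the cut-offs to
produce non-trivial confusion matrices for exercising the evaluation
machinery. Both are synthetic by construction: the real feature
distributions per pattern are not publicly available, and the presets are
derived from the rule geometry, not fitted to data. Consequently,
passing closed-loop tests demonstrates that the pipeline is faithful to
the stated rules — it says nothing about how well the rules themselves
generalise to clinical exams, whose feature distributions overlap in ways
no preset reproduces (and whose published headline accuracies — 0.88 for
the SSc gate, 0.82 for staging, 0.73 for the normal/non-specific split —
were measured on an undeposited clinical cohort this package does not
attempt to replicate).

## Numerical and degenerate-input choices

* Truncated normals are sampled by rejection; `sd = 0` degenerates to the
  mean, and widths are floored at 0.05 mm to keep every per-image width
  strictly positive.
* The pooled-density identity `density = total_capillaries /
  total_width_mm` is verified on feature-table read at 1e-9 relative
  tolerance (disabled for image-mean tables, where it does not hold).
* Empty inputs are well-defined: header-only tables read as empty
  collections, an empty prediction set writes a header-only file, an
  evaluation step with no exams reports n = 0 with `NA` metrics.
* Cohort generation is vectorised across all images of all exams and is
  byte-reproducible from the configuration seed.

## Problem sizes in the test-suite

The suite checks the rule engine against an independently written nested
conditional transcription on a ~114,000-point grid refining every
threshold boundary at ±1e-9; consensus against a tally oracle on all 216
ordered verdict triples under all 6 permutations; metric identities
against loop-based counting on 1,000 random paired cohorts; and the
closed loop on a 10,000-exam separable cohort with noise-free raters,
where every evaluation step must reach accuracy ≥ 0.99. These sizes were
chosen to cover every decision boundary exhaustively while keeping the
full suite comfortably under a minute of compute.

## Known limitations

* The classifier is exam-level only; it does not grade single images.
* The tree is deterministic by design — no probabilistic output, no
  learned components, and no confidence intervals on the evaluation
  metrics.
* The simulator's independence assumptions (morphology counts independent
  given the pattern, raters independent given the truth) are simplistic;
  real rater errors and capillary morphologies are correlated.
* Thresholds are taken as given; the package supports sensitivity
  analyses around them but contains no re-fitting machinery.
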