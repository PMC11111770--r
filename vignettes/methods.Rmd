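---
title: "Methods: detection-to-grade aggregation for cervical cytology screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection-to-grade aggregation for cervical cytology screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

# Overview

`cytoscreen` models two-stage AI cytology screening. Stage one — a
patch-level abnormal-cell detector — is treated as a contract: any
process that emits `(grade, confidence, box, epithelium score)` records
per patch satisfies it, including the package's own simulated detector.
Stage two, implemented in full here, aggregates those records into a
slide-level feature vector and classifies the slide into one of the
five TBS 2014 categories (NILM, ASC-US, LSIL, HSIL+, AGC). Around this
core sit the stain-colour augmentation used when training patch
detectors, thumbnail quality control, and the diagnostic-accuracy
machinery used to evaluate screening arms.

# Grade vocabulary and risk strata

Patch-level classes are the six annotated abnormal-cell categories
(ASC-US, LSIL, ASC-H, HSIL, SCC, AGC). At the slide level ASC-H, HSIL
and SCC collapse into HSIL+ — they share morphology and clinical
management — giving five slide grades. Screening decisions are made on
nested "grade-or-worse" binarizations: ASC-US+ ⊃ LSIL+ ⊃ HSIL+, all
containing only squamous grades. AGC, the glandular umbrella category,
belongs to none of them and counts as abnormal only in the
all-abnormal stratum; this follows the usual subgroup-analysis
convention in which glandular lesions are reported separately.

One deliberate ordering choice: for deterministic reporting sorts and
argmax tie-breaks we place AGC between LSIL and HSIL+ in "severity".
This ordering never enters stratum membership; it only ensures that an
exact probability tie resolves toward the more severe call, the
sensitivity-favouring direction a screening program wants.

# Tiling and detection aggregation

Slides are decomposed by a sliding window: origins on a stride lattice,
with the final origin per axis clamped to `dim − patch` so the last
patch abuts the edge and coverage is complete. Defaults are a 1024 px
patch with a 768 px stride (25% overlap) at 40×; the source workflow
does not publish its geometry, and overlap is what prevents a cell on
a patch boundary from being unrepresentable. Coordinates are 0-based,
half-open, x = column, y = row, origin top-left — one convention,
stated once.

Overlap means one cell can be detected in two patches. After
translating boxes to slide coordinates, duplicates are suppressed
within each grade by greedy non-maximum suppression at IoU > 0.5
(standard NMS threshold; nothing is published about cross-patch
handling), keeping the higher confidence. No confidence floor is
applied before aggregation: the feature bins below are designed to
carry low-confidence mass, and a cutoff would silently discard it.

# The slide feature vector and classifier

Per patch class the detection confidences are summarized by their
maximum, mean and standard deviation, plus the proportion falling in
each confidence bin. Choices:

- **Bins**: B = 10 equal-width bins on [0, 1], left-closed, the last
  bin closed on both sides so a confidence of exactly 1 is counted.
  The bin count is unpublished; 10 is the natural default for
  proportions of a [0, 1] score.
- **SD**: population form, so a singleton class yields 0 rather than
  an undefined value; empty classes contribute zeros throughout.
- **Counts**: per-class detection counts are included by default with
  a switch (`include_counts = FALSE`) for the
  confidence-statistics-only variant. Bin proportions discard
  abundance, and slide grading plausibly needs to distinguish two
  suspicious cells from two hundred; the switch preserves the
  narrower reading.
- An optional glandular fraction (share of detections with epithelium
  score < 0.5) summarizes the squamous/glandular subnetwork output.

The classifier is a random forest: 500 CART trees grown on bootstrap
samples, Gini impurity splits over √p randomly drawn features per
split, minimum child size 1, depth capped at 25. The environment this
package targets ships no tree-ensemble R package, so the forest is
implemented in compiled code in-package (`src/forest.cpp`), seeded
through R's RNG for cross-platform reproducibility (training seed
default 20140101). Class probabilities are across-tree averages of
leaf class distributions; out-of-bag accuracy is reported from the
bootstrap; feature importance is mean decrease in Gini impurity.
Hyperparameters are unpublished upstream; these are the conventional
defaults of the classical random-forest literature.

The abnormality score is 1 − P(NILM); the score for any risk stratum
is the sum of member-grade probabilities, which makes the nesting
inequality score(HSIL+) ≤ score(LSIL+) ≤ score(ASC-US+) structural
rather than empirical.

# Stain augmentation

Colour augmentation operates in stain-density absorbance (SDA) space,
`sda = −ln((I + ε)/I₀)` with background intensity I₀ = 255 and ε = 1
to avoid log(0) — the standard optical-density convention under which
stains mix linearly (Beer–Lambert). The stain matrix is estimated by
the Macenko procedure: threshold tissue pixels at SDA norm β = 0.15,
project onto the top-two SVD plane, take the α = 1st/99th percentile
extreme angles as the two stain directions, complete with the
normalized cross product, and order haematoxylin first as the vector
with the greater blue-channel absorbance (haematoxylin absorbs
red-orange weakly and blue strongly). β and α are unpublished
upstream; these are the values in common use for this estimator.

Fitting the augmentation distribution is per-image: each training
image contributes its mean H and E concentration, and μ, σ (sample SD
across images) and min/max bounds are taken across images. The
perturbation draws one of {H, E, both, neither} uniformly (no weights
are published), draws each selected component's shift uniformly in
[−2σ, 2σ], applies it as a global additive shift to the per-image
component mean — not per-pixel noise — clamps the shifted mean to the
fitted bounds, and reconstructs RGB. Degenerate inputs are explicit:
fewer than two pixels above β yields an identity-like fallback matrix
with a warning; an effectively one-dimensional pixel cloud (angular
spread of the percentile angles under 5°) flags the second vector
unstable.

Numerical consequences worth knowing: reconstruction clamps RGB to
[0, 255], so re-measured component means can sit ~10⁻⁵ off the fitted
bounds; the SDA↔RGB round trip is exact in doubles and within 1/255
after 8-bit quantization.

# Quality control

Thumbnails are standardized to a 1000 px short edge (bilinear,
aspect-preserving, idempotent). The upstream QC network is trained on
private data, so the package ships a deterministic heuristic baseline
behind the same two-branch contract (binary summary + per-issue
severities): blur severity `exp(−r/0.1)` where r is the
high-frequency energy ratio of the grayscale image (monotone under
Gaussian blurring); incomplete-scan severity the blank-pixel
(gray ≥ 250) fraction; low-cellularity severity one minus the
tissue-pixel (gray < 220) fraction. Default thresholds 0.5 / 0.3 /
0.5 are tunable; none are published. The heuristics are scale-free
statistics, so tests run them on small rasters. A known artefact:
bilinearly *upscaling* a small synthetic texture smooths away its
contrast and inflates blur severity — real thumbnails are downscaled
from gigapixel scans, where this does not arise.

# Diagnostic evaluation

Confusion tables binarize predictions and truth by stratum membership.
Proportion metrics carry exact Clopper–Pearson 95% intervals — the
asymmetric near-boundary intervals typical of screening tables (e.g. a
sensitivity of 1.000 on 29 positives has interval 0.881–1.000) are
exactly this construction — and a metric with a zero denominator is
reported `NA`, never 0. AUC uses the rank (Mann–Whitney) formulation
with midrank tie handling; its CI is a stratified percentile bootstrap
(2000 replicates, seeded) since no interval method is named upstream.
Arm comparisons use the two-sided Pearson χ² without continuity
correction on the 2×2 table. "All grades" analyses binarize
abnormal-vs-NILM on the abnormality score, the only construction under
which a single AUC is defined. Reader (discrete) calls are scored as
0/1, giving the one-point ROC its trapezoidal AUC. No multiple-testing
adjustment is applied. The prevalence-weighted identities
(accuracy = π·sens + (1−π)·spec, and the analogous NPV/PPV forms) link
sensitivity/specificity to population metrics at a given prevalence
and are used as printed-arithmetic cross-checks.

# The synthetic world

The generators state, explicitly, the world the tests certify:

- **Cohorts**: slide grades drawn from a prevalence vector defaulting
  to the reference training composition rounded to three decimals
  (NILM 0.724, ASC-US 0.078, LSIL 0.107, HSIL+ 0.077, AGC 0.014);
  per-class true-cell counts Poisson with grade-conditioned rates
  whose dominant class differs ≥ 4× between adjacent grades; observed
  classes drawn through a confusion matrix (0.85 diagonal by
  default); confidences Beta(8, 2) for true detections and Beta(2, 8)
  for false positives; 0.5 false positives per slide on any tissue.
  These make cohorts learnable but not trivially separable once
  confusion noise rises.
- **Stain images**: RGB = I₀·exp(−M·c) from known unit stain vectors,
  with pixel concentrations drawn as a three-way mixture — 25%
  H-dominant (nuclei), 25% E-dominant (stroma/cytoplasm), 50% mixed,
  Gamma(shape 2) magnitudes. The pure-stain regions are deliberate:
  they are what anchors the percentile-angle estimator in real H&E,
  and a generator without them measures estimator bias rather than
  correctness.
- **Reader arms**: the unassisted reader is a per-stratum
  sensitivity/specificity draw. The assisted rule is an explicit
  model, not an inference from any study: AI-flagged slides are
  called positive with a confirmation probability (default 1);
  AI-missed positives are caught independently with a catch
  probability (default: the reader's sensitivity); AI-negative
  negatives are not flagged. With confirmation 1 the assisted arm is
  a union rule, so its sensitivity provably dominates the AI's — the
  qualitative ordering reported for assisted reading.

A green test on this world establishes that aggregation, feature
computation, classification and evaluation are implemented correctly
and recover the planted structure. It does **not** establish clinical
performance: no rendered cell morphology, no scanner or staining-batch
variation beyond the stated model, no reader behaviour beyond the
stated rule, and no access to the private cohorts or trained detector
behind the published tables.

# Known limitations

- TIFF I/O is unsupported (no TIFF reader in the dependency
  footprint); PNG and in-memory arrays are the image interfaces.
- The QC heuristics are baselines; they share a tissue-intensity
  definition between the incomplete-scan and cellularity severities
  and will correlate on real data.
- The minimum-cellularity adequacy rule of TBS (5000 squamous cells)
  is recorded as metadata only; enforcing it requires running a real
  detector over the full slide.
- Probability calibration of the forest is out of scope; scores are
  ensemble vote averages.
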