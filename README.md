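# cytoscreen

Slide-level cervical cytology grading from patch-level abnormal-cell
detections, with the supporting machinery a screening study needs:
stain-colour augmentation, slide quality control, risk-stratified
diagnostic evaluation, and seeded synthetic data generators.

## The problem

Cervical cancer screening by liquid-based cytology asks a reader to scan
a slide containing tens of thousands of cells and assign a Bethesda
System (TBS 2014) grade: **NILM** (negative), **ASC-US**, **LSIL**,
**HSIL+** (grouping ASC-H, HSIL and SCC) or **AGC**. AI-assisted
screening systems approach this in two stages: a detector proposes
abnormal cells with class labels and confidence scores on sliding-window
patches, and a slide-level classifier turns the detection profile of the
whole slide into a grade.

`cytoscreen` implements the second stage and everything around it as a
reusable, detector-agnostic library. A trained detector's output can be
ingested from CSV/JSON; a statistically parameterized simulated detector
is included so every downstream stage is testable at desk scale.

## The core method

For each slide, the detections of each patch class
*g ∈ {ASC-US, LSIL, ASC-H, HSIL, SCC, AGC}* with confidences
*c₁ … c₍n₎* are summarized as

- max(cᵢ), mean(cᵢ), population SD(cᵢ),
- the proportion of detections in each of *B* = 10 equal-width
  confidence bins on [0, 1],
- (optionally) the raw detection count,

giving a fixed-length feature vector (84 features at defaults). A
random-forest classifier (500 CART trees, Gini splits, √p features per
split, implemented in compiled code in-package) maps the feature vector
to the five slide grades; the abnormality score is 1 − P(NILM) and
nested risk-stratum scores (ASC-US+, LSIL+, HSIL+) are sums of
member-grade probabilities.

Supporting modules:

- **Tiling** — sliding-window patch grids with edge clamping and
  complete coverage; cross-patch duplicate suppression by per-class
  IoU-based non-maximum suppression.
- **Stain augmentation** — Beer–Lambert stain-density absorbance (SDA)
  transform, Macenko stain-matrix estimation (SVD + percentile extreme
  angles), per-image H/E component distribution fitting (μ, σ, bounds),
  and bounded uniform [−2σ, 2σ] perturbation of the H and/or E
  components with exact reconstruction.
- **Quality control** — thumbnail standardization to a 1000-px short
  edge and a deterministic heuristic quality report (blur,
  incomplete-scan, low-cellularity severities) behind a pluggable
  contract.
- **Evaluation** — risk-stratified confusion tables, sensitivity /
  specificity / accuracy / PPV / NPV with exact Clopper–Pearson 95%
  CIs, rank-based ROC AUC with stratified-bootstrap CIs, two-sided
  Pearson χ² arm comparisons, and prevalence-weighted metric
  identities.
- **Synthetic data** — grade-conditioned cohort generation (Poisson
  cell counts, class confusion, Beta confidences, false positives),
  two-stain Beer–Lambert images with known ground truth, and simulated
  unassisted/AI-assisted reader arms.

## Worked example

```r
library(cytoscreen)

co <- generate_cohort(cohort_config(1000, seed = 17))   # synthetic cohort
X  <- extract_feature_matrix(co$sets)
set.seed(17)
test_idx <- sort(sample.int(1000, 200))                  # 4:1 split
model <- train_slide_classifier(X[-test_idx, ], co$truth[-test_idx])
model
#> <slide_classifier> 500 trees, mtry 9, 84 features
#>   OOB accuracy: 0.998

pred <- predict_slide_grade(model, X[test_idx, ])
rep <- diagnostic_metrics(
  confusion_for_stratum(pred$grade, co$truth[test_idx], "ASC-US+"))
rep
#> <diagnostic_report> stratum ASC-US+, n = 200
#>   sensitivity 1.000 (0.927-1.000)
#>   specificity 0.993 (0.964-1.000)
#>   accuracy    0.995 (0.972-1.000)
#>   ppv         0.980 (0.894-0.999)
#>   npv         1.000 (0.976-1.000)

head(feature_importances(model, 5))
#>           feature importance
#> 1  ASCUS_max_conf   32.88264
#> 2     ASCUS_count   25.56837
#> 3      LSIL_count   23.40368
#> 4 ASCUS_mean_conf   21.75117
#> 5  LSIL_mean_conf   21.35066
```

The report reads as in a screening study: of the 200 held-out synthetic
slides, every slide at grade ASC-US or worse was flagged (sensitivity
1.000 with its exact 95% CI), one negative slide was over-called
(specificity 0.993), and the feature ranking shows the classifier
leaning on the confidence statistics and counts of the low-grade
squamous classes that dominate this cohort's abnormal slides. These
numbers describe the synthetic world of the default generator, not any
clinical cohort.

A full pipeline run (simulate → features → train → predict → evaluate,
with artifacts and a provenance log) is one call:

```r
run_pipeline(pipeline_config(list(out_dir = "demo-run", seed = 17)))
```

or, from the shell, `inst/cli/cytoscreen run --seed 17 --out demo-run`
(subcommands: `simulate`, `qc`, `augment`, `features`, `train`,
`predict`, `evaluate`, `run`).

## What a green test establishes

Synthetic cohorts are drawn from an explicit statistical model of a
detector (see the methods vignette, `vignettes/methods.Rmd`); passing
tests establish that the aggregation, classification and evaluation
machinery is correct and well-calibrated on that stated world. They do
not establish clinical performance: real cohorts and a trained detector
are private to the original screening studies.
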