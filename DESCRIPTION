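Package: cytoscreen
Title: Slide-Level Cervical Cytology Grading from Patch Detections
Version: 0.1.0
Authors@R:
    person("cytoscreen", "maintainers", email = "maintainers@cytoscreen.dev",
           role = c("aut", "cre"))
Description: Tools for whole-slide cervical cytology screening built around a
    two-stage design: patch-level abnormal-cell detections (from a pluggable
    or simulated detector) are aggregated into slide-level confidence
    statistics and classified into Bethesda System (TBS 2014) grades with a
    random-forest classifier. Includes sliding-window tiling, Macenko stain
    deconvolution with bounded H&E colour augmentation, thumbnail quality
    control heuristics, risk-stratified diagnostic accuracy evaluation
    (sensitivity, specificity, predictive values with exact confidence
    intervals, ROC/AUC, chi-squared arm comparisons), and seeded synthetic
    data generators for cohorts, stained images, and reader arms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
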