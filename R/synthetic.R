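#' Simulated patch-detector profile
#'
#' Statistical stand-in for a trained patch-level cell detector. Per
#' true slide grade it specifies mean abnormal-cell counts per patch
#' class (Poisson rates), a class-confusion matrix applied to each true
#' cell, Beta parameters for true-class and false-positive confidence
#' scores, and a per-slide false-positive rate on any tissue.
#'
#' Defaults give grade-conditioned rates whose dominant class differs
#' by at least 4x between adjacent grades: learnable but not trivially
#' separable once confusion noise is applied.
#'
#' @param rates 5 x 6 matrix (rows [slide_grades()], columns
#'   [patch_grades()]) of mean cells per slide.
#' @param confusion 6 x 6 row-stochastic confusion matrix over patch
#'   grades (true class in rows, observed in columns).
#' @param conf_true,conf_fp Beta (shape1, shape2) parameters for
#'   true-detection and false-positive confidences.
#' @param fp_rate Mean false positives per slide (Poisson).
#' @param box_half_px Half edge length of generated boxes.
#' @return A `detector_profile` object.
#' @export
detector_profile <- function(rates = NULL, confusion = NULL,
                             conf_true = c(8, 2), conf_fp = c(2, 8),
                             fp_rate = 0.5, box_half_px = 25) {
  if (is.null(rates)) {
    rates <- rbind(
      "NILM"   = c(0,    0,    0,   0,  0, 0),
      "ASC-US" = c(12,   1,    0,   0,  0, 0),
      "LSIL"   = c(4,    16,   0.5, 0,  0, 0),
      "HSIL+"  = c(1,    2,    8,   12, 1, 0),
      "AGC"    = c(0.5,  0.5,  0,   0,  0, 10)
    )
    colnames(rates) <- patch_grades()
  }
  if (is.null(confusion)) {
    confusion <- matrix(0.15 / 5, 6, 6,
                        dimnames = list(patch_grades(), patch_grades()))
    diag(confusion) <- 0.85
  }
  stopifnot(all(rates >= 0), all(confusion >= 0),
            max(abs(rowSums(confusion) - 1)) < 1e-8,
            all(conf_true > 0), all(conf_fp > 0), fp_rate >= 0)
  structure(list(rates = rates, confusion = confusion,
                 conf_true = conf_true, conf_fp = conf_fp,
                 fp_rate = fp_rate, box_half_px = box_half_px),
            class = "detector_profile")
}

#' Add confusion noise to a detector profile
#'
#' Mixes the profile's confusion matrix toward the uniform matrix:
#' `(1 - w) * C + w * U`. Used by the noise-monotonicity checks.
#'
#' @param profile A `detector_profile`.
#' @param w Mixing weight in `[0, 1]`.
#' @return A `detector_profile` with the blended confusion matrix.
#' @export
with_confusion_noise <- function(profile, w) {
  stopifnot(inherits(profile, "detector_profile"), w >= 0, w <= 1)
  U <- matrix(1 / 6, 6, 6, dimnames = dimnames(profile$confusion))
  profile$confusion <- (1 - w) * profile$confusion + w * U
  profile
}

#' Simulated detector on a latent slide description
#'
#' The simulated counterpart of running the patch detector over every
#' sliding window of a slide: consumes latent truth (the slide's true
#' cell inventory) instead of pixels. Each true cell is observed with a
#' class drawn from the confusion row of its true grade and a
#' confidence from the true-class Beta; false positives are added at
#' the profile's Poisson rate with the false-positive Beta. Glandular
#' (AGC) detections get low epithelium scores, squamous ones high.
#' Uses R's RNG; seed with [set.seed()] for determinism.
#'
#' @param latent List with `slide` (a `slide_record`) and `cells`, a
#'   data frame with column `grade` plus `cx`, `cy` centres.
#' @param profile A `detector_profile`.
#' @return A `slide_detection_set`.
#' @export
detect_simulated <- function(latent, profile) {
  if (!is.list(latent) || !inherits(latent$slide, "slide_record") ||
      !is.data.frame(latent$cells)) {
    stop("malformed latent patch descriptor: need $slide and $cells")
  }
  sl <- latent$slide
  cells <- latent$cells
  n_fp <- rpois(1, profile$fp_rate)
  n <- nrow(cells) + n_fp
  if (n == 0) return(slide_detection_set(sl))
  grade <- character(n)
  confidence <- numeric(n)
  cx <- numeric(n)
  cy <- numeric(n)
  if (nrow(cells)) {
    idx <- seq_len(nrow(cells))
    obs <- vapply(cells$grade, function(g) {
      sample(patch_grades(), 1, prob = profile$confusion[g, ])
    }, character(1))
    grade[idx] <- obs
    confidence[idx] <- rbeta(nrow(cells), profile$conf_true[1],
                             profile$conf_true[2])
    cx[idx] <- cells$cx
    cy[idx] <- cells$cy
  }
  if (n_fp > 0) {
    idx <- nrow(cells) + seq_len(n_fp)
    grade[idx] <- sample(patch_grades(), n_fp, replace = TRUE)
    confidence[idx] <- rbeta(n_fp, profile$conf_fp[1], profile$conf_fp[2])
    h <- profile$box_half_px
    cx[idx] <- runif(n_fp, h, sl$width_px - h)
    cy[idx] <- runif(n_fp, h, sl$height_px - h)
  }
  h <- profile$box_half_px
  epi <- ifelse(grade == "AGC", rbeta(n, 2, 8), rbeta(n, 8, 2))
  d <- data.frame(
    grade = grade, confidence = confidence,
    x0 = pmax(0, cx - h), y0 = pmax(0, cy - h),
    x1 = pmin(sl$width_px, cx + h), y1 = pmin(sl$height_px, cy + h),
    epithelium_score = epi
  )
  slide_detection_set(sl, d)
}

#' Reference training-cohort composition
#'
#' The per-category abnormal counts of the reference retrospective
#' training cohort (n = 9316): 730 ASC-US, 995 LSIL, 279 ASC-H,
#' 401 HSIL, 35 SCC and 131 AGC, the remainder NILM. Used as the
#' default prevalence fixture for synthetic cohorts.
#'
#' @return List with `counts` (named integer vector over the six patch
#'   categories) and `n_total`.
#' @export
reference_training_composition <- function() {
  list(counts = c("ASC-US" = 730L, "LSIL" = 995L, "ASC-H" = 279L,
                  "HSIL" = 401L, "SCC" = 35L, "AGC" = 131L),
       n_total = 9316L)
}

#' Default slide-grade prevalences
#'
#' Slide-grade prevalence vector mirroring the reference training
#' composition to three decimals (NILM 0.724, ASC-US 0.078, LSIL 0.107,
#' HSIL+ 0.077, AGC 0.014); sums to 1.
#'
#' @return Named numeric vector over [slide_grades()].
#' @export
training_prevalences <- function() {
  c("NILM" = 0.724, "ASC-US" = 0.078, "LSIL" = 0.107,
    "HSIL+" = 0.077, "AGC" = 0.014)
}

#' Cohort generator configuration
#'
#' @param n_slides Number of slides (>= 1).
#' @param prevalences Probability vector over [slide_grades()]; must sum
#'   to 1 (default [training_prevalences()]).
#' @param profile A `detector_profile`.
#' @param seed Integer RNG seed.
#' @param slide_width_px,slide_height_px Synthetic slide raster size.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_slides, prevalences = training_prevalences(),
                          profile = detector_profile(), seed = 1L,
                          slide_width_px = 5000L, slide_height_px = 5000L) {
  stopifnot(n_slides >= 1, inherits(profile, "detector_profile"))
  if (length(prevalences) != 5 ||
      !setequal(names(prevalences), slide_grades())) {
    stop("prevalences must be named over the five slide grades")
  }
  if (abs(sum(prevalences) - 1) > 1e-6 || any(prevalences < 0)) {
    stop("prevalences must be nonnegative and sum to 1")
  }
  structure(list(n_slides = as.integer(n_slides),
                 prevalences = prevalences[slide_grades()],
                 profile = profile, seed = as.integer(seed),
                 slide_width_px = as.integer(slide_width_px),
                 slide_height_px = as.integer(slide_height_px)),
            class = "cohort_config")
}

#' Generate a synthetic slide cohort
#'
#' For each slide: draws the true grade from the configured
#' prevalences, draws per-class true-cell counts from the
#' grade-conditioned Poisson rates, places cells uniformly, and runs
#' the simulated detector (confusion, Beta confidences, false
#' positives). Fully determined by `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return List with `sets` (list of `slide_detection_set`) and `truth`
#'   (character vector of true slide grades).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  p <- cfg$profile
  h <- p$box_half_px
  truth <- sample(slide_grades(), cfg$n_slides, replace = TRUE,
                  prob = cfg$prevalences)
  sets <- lapply(seq_len(cfg$n_slides), function(i) {
    sl <- slide_record(sprintf("synth-%05d", i),
                       cfg$slide_width_px, cfg$slide_height_px,
                       true_grade = truth[i])
    counts <- rpois(6, p$rates[truth[i], ])
    n_cells <- sum(counts)
    cells <- data.frame(
      grade = rep(patch_grades(), counts),
      cx = runif(n_cells, h, sl$width_px - h),
      cy = runif(n_cells, h, sl$height_px - h)
    )
    detect_simulated(list(slide = sl, cells = cells), p)
  })
  list(sets = sets, truth = truth)
}

#' Generate a synthetic two-stain Beer-Lambert image
#'
#' Oracle for the stain machinery: builds an RGB raster as
#' `background * exp(-(M %*% c))` per pixel from known unit-norm stain
#' vectors and random nonnegative concentration fields, quantized to
#' 8-bit. Ground-truth concentrations are returned alongside.
#'
#' @param stain_matrix 3 x 2 or 3 x 3 matrix whose first two columns are
#'   the H and E absorbance vectors (unit norm).
#' @param width,height Raster size in pixels.
#' @param mean_conc Length-2 mean H and E concentrations. Pixels are a
#'   three-way mixture mimicking stained tissue: H-dominant regions
#'   (nuclei, E = 0), E-dominant regions (stroma/cytoplasm, H = 0) and
#'   mixed regions, with Gamma(shape 2) concentration magnitudes. The
#'   pure-stain regions are what anchors the percentile-angle
#'   estimator, as in real H&E.
#' @param pure_fraction Fraction of pixels that are pure-H and pure-E
#'   respectively (default 0.25 each).
#' @param background Transmitted background intensity (default 255).
#' @param seed Optional integer seed.
#' @return List with `image` (`h x w x 3` array in `[0, 255]`) and
#'   `concentrations` (`n x 2` matrix, rows in raster order).
#' @export
generate_stain_image <- function(stain_matrix, width = 64, height = 64,
                                 mean_conc = c(0.8, 0.6), background = 255,
                                 pure_fraction = 0.25, seed = NULL) {
  M <- stain_matrix[, 1:2, drop = FALSE]
  nrm <- sqrt(colSums(M^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("stain vectors must be unit norm")
  if (!is.null(seed)) set.seed(seed)
  n <- width * height
  kind <- sample(1:3, n, replace = TRUE,
                 prob = c(pure_fraction, pure_fraction,
                          max(0, 1 - 2 * pure_fraction)))
  C <- cbind(H = rgamma(n, shape = 2, scale = mean_conc[1] / 2),
             E = rgamma(n, shape = 2, scale = mean_conc[2] / 2))
  C[kind == 1, "E"] <- 0 # H-dominant (nuclear) pixels
  C[kind == 2, "H"] <- 0 # E-dominant (stromal) pixels
  sda <- C %*% t(M)
  rgb <- background * exp(-sda)
  img <- array(round(pmin(pmax(rgb, 0), 255)), c(height, width, 3))
  list(image = img, concentrations = C)
}

#' Reader behaviour profile for simulated arms
#'
#' Describes a cytopathologist reading slides with stratum-level
#' sensitivity/specificity, and their behaviour when assisted by an AI
#' screen: AI-flagged slides are called positive with `confirm_prob`;
#' AI-missed truly-positive slides are caught independently with
#' `catch_prob` (defaults to the reader's own sensitivity); AI-negative
#' negative slides are not flagged. With `confirm_prob = 1` and
#' `catch_prob = 0` the assisted calls equal the AI calls exactly.
#'
#' @param sens,spec Reader sensitivity and specificity in `[0, 1]`.
#' @param confirm_prob Probability of calling an AI-positive slide
#'   positive on review (default 1).
#' @param catch_prob Probability of independently catching an
#'   AI-negative, truly-positive slide (default `sens`).
#' @return A `reader_profile`.
#' @export
reader_profile <- function(sens, spec, confirm_prob = 1, catch_prob = sens) {
  stopifnot(all(c(sens, spec, confirm_prob, catch_prob) >= 0),
            all(c(sens, spec, confirm_prob, catch_prob) <= 1))
  structure(list(sens = sens, spec = spec, confirm_prob = confirm_prob,
                 catch_prob = catch_prob),
            class = "reader_profile")
}

#' Simulate unassisted and AI-assisted reader calls
#'
#' Binarizes truth and AI predictions by the chosen risk stratum, then
#' draws: the unassisted reader's call from their sensitivity (positive
#' slides) or false-positive rate (negative slides); and the assisted
#' call per the [reader_profile()] rule. With `confirm_prob = 1` the
#' assisted arm is a union rule, so its sensitivity can never fall
#' below the AI's.
#'
#' @param truth Character vector of true slide grades.
#' @param ai_predictions Character vector of AI slide grades (same
#'   length).
#' @param rp A `reader_profile`.
#' @param stratum Risk stratum for the binary call (default
#'   `"ALL_ABNORMAL"`).
#' @param seed Optional integer seed.
#' @return List of logical vectors: `reader`, `assisted`, plus `ai` and
#'   `truth` binarized for convenience.
#' @export
simulate_reader_arms <- function(truth, ai_predictions, rp,
                                 stratum = "ALL_ABNORMAL", seed = NULL) {
  stopifnot(inherits(rp, "reader_profile"))
  if (length(truth) != length(ai_predictions)) {
    stop("truth and ai_predictions must have equal length")
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- stratum_membership(truth, stratum)
  ai <- stratum_membership(ai_predictions, stratum)
  n <- length(pos)
  reader <- ifelse(pos, rbinom(n, 1, rp$sens), rbinom(n, 1, 1 - rp$spec)) == 1
  assisted <- logical(n)
  assisted[ai] <- rbinom(sum(ai), 1, rp$confirm_prob) == 1
  assisted[!ai & pos] <- rbinom(sum(!ai & pos), 1, rp$catch_prob) == 1
  list(reader = reader, assisted = assisted, ai = ai, truth = pos)
}
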