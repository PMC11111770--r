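#' @useDynLib cytoscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate predict qbeta pchisq quantile rbeta rbinom
#'   rpois runif sd setNames rgamma
#' @importFrom utils head read.csv write.csv packageVersion
NULL

#' Patch-level cytology grades
#'
#' The six abnormal-cell categories annotated at the patch level under
#' TBS 2014: ASC-US, LSIL, ASC-H, HSIL, SCC and AGC, in canonical order
#' of increasing squamous severity with the glandular AGC category last.
#'
#' @return Character vector of the six patch grade labels.
#' @export
patch_grades <- function() {
  c("ASC-US", "LSIL", "ASC-H", "HSIL", "SCC", "AGC")
}

#' Slide-level cytology grades
#'
#' The five whole-slide categories: NILM, ASC-US, LSIL, HSIL+ (grouping
#' ASC-H/HSIL/SCC) and AGC.
#'
#' @return Character vector of the five slide grade labels.
#' @export
slide_grades <- function() {
  c("NILM", "ASC-US", "LSIL", "HSIL+", "AGC")
}

#' Severity ordering of slide grades for reporting
#'
#' Used only for deterministic sorts and argmax tie-breaking (more severe
#' wins). AGC is placed after LSIL and before HSIL+; this ordering never
#' enters risk-stratum membership.
#'
#' @return Character vector of slide grades from least to most severe.
#' @export
slide_grade_severity <- function() {
  c("NILM", "ASC-US", "LSIL", "AGC", "HSIL+")
}

.assert_patch_grade <- function(g) {
  bad <- !(g %in% patch_grades())
  if (any(bad)) {
    stop("unknown patch grade label(s): ", paste(unique(g[bad]), collapse = ", "))
  }
  invisible(g)
}

.assert_slide_grade <- function(g) {
  bad <- !(g %in% slide_grades())
  if (any(bad)) {
    stop("unknown slide grade label(s): ", paste(unique(g[bad]), collapse = ", "))
  }
  invisible(g)
}

#' Map a patch grade to its slide-level category
#'
#' ASC-H, HSIL and SCC collapse into the slide category HSIL+; ASC-US,
#' LSIL and AGC map to themselves. Vectorized and total over the six
#' patch grades.
#'
#' @param g Character vector of patch grade labels.
#' @return Character vector of slide grade labels, same length as `g`.
#' @examples
#' patch_to_slide_category(c("ASC-H", "AGC", "ASC-US"))
#' @export
patch_to_slide_category <- function(g) {
  .assert_patch_grade(g)
  map <- c("ASC-US" = "ASC-US", "LSIL" = "LSIL", "ASC-H" = "HSIL+",
           "HSIL" = "HSIL+", "SCC" = "HSIL+", "AGC" = "AGC")
  unname(map[g])
}

#' Risk strata over cytology grades
#'
#' Nested "grade-or-worse" binarizations used for screening decisions.
#' ASC-US+, LSIL+ and HSIL+ contain only squamous grades (AGC excluded);
#' ALL_ABNORMAL is every non-NILM grade including AGC.
#'
#' @return Character vector of the stratum names.
#' @export
risk_strata <- function() {
  c("ASC-US+", "LSIL+", "HSIL+", "ALL_ABNORMAL")
}

#' Patch-grade member set of a risk stratum
#'
#' @param s Stratum name, one of [risk_strata()].
#' @return Character vector of patch grade labels in the stratum.
#' @export
stratum_members <- function(s) {
  s <- match.arg(s, risk_strata())
  switch(s,
    "ASC-US+"      = c("ASC-US", "LSIL", "ASC-H", "HSIL", "SCC"),
    "LSIL+"        = c("LSIL", "ASC-H", "HSIL", "SCC"),
    "HSIL+"        = c("ASC-H", "HSIL", "SCC"),
    "ALL_ABNORMAL" = patch_grades()
  )
}

#' Test slide grades for risk-stratum membership
#'
#' A slide grade belongs to a stratum iff its patch-level constituents
#' fall in the stratum's member set: the slide category HSIL+ stands for
#' \{ASC-H, HSIL, SCC\}, all of which lie in ASC-US+, LSIL+ and HSIL+;
#' AGC belongs only to ALL_ABNORMAL; NILM belongs to no stratum.
#'
#' @param g Character vector of slide grade labels.
#' @param s Stratum name, one of [risk_strata()].
#' @return Logical vector, same length as `g`.
#' @examples
#' stratum_membership(c("HSIL+", "AGC", "NILM"), "ASC-US+")
#' @export
stratum_membership <- function(g, s) {
  .assert_slide_grade(g)
  members <- stratum_members(s)
  # slide grade -> patch constituents
  constituents <- list(
    "NILM"   = character(0),
    "ASC-US" = "ASC-US",
    "LSIL"   = "LSIL",
    "HSIL+"  = c("ASC-H", "HSIL", "SCC"),
    "AGC"    = "AGC"
  )
  vapply(g, function(gi) {
    cc <- constituents[[gi]]
    length(cc) > 0 && all(cc %in% members)
  }, logical(1), USE.NAMES = FALSE)
}

#' Slide metadata record
#'
#' @param slide_id Character identifier.
#' @param width_px,height_px Slide raster dimensions in pixels (>= 1).
#' @param pixel_size_um Specimen-level pixel pitch in micrometres per
#'   pixel; must lie in (0.1, 1.0). Default 0.2529 (a 40x scanner).
#' @param true_grade Optional known slide grade, or `NA`.
#' @return An object of class `slide_record`.
#' @export
slide_record <- function(slide_id, width_px, height_px,
                         pixel_size_um = 0.2529, true_grade = NA_character_) {
  stopifnot(length(slide_id) == 1, width_px >= 1, height_px >= 1)
  if (!(pixel_size_um > 0.1 && pixel_size_um < 1.0)) {
    stop("pixel_size_um must lie in (0.1, 1.0) um/px")
  }
  if (!is.na(true_grade)) .assert_slide_grade(true_grade)
  structure(
    list(slide_id = as.character(slide_id),
         width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um,
         true_grade = true_grade),
    class = "slide_record"
  )
}

#' @export
print.slide_record <- function(x, ...) {
  cat(sprintf("<slide_record> %s  %dx%d px @ %.4f um/px  grade: %s\n",
              x$slide_id, x$width_px, x$height_px, x$pixel_size_um,
              ifelse(is.na(x$true_grade), "unknown", x$true_grade)))
  invisible(x)
}
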