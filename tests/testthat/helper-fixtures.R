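# Shared fixtures: canonical H&E absorbance vectors, angle metric, and
# small hand-built detection sets.

he_stain_vectors <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  cbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)))
}

angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

toy_slide <- function(id = "s1", w = 4000, h = 4000, grade = NA_character_) {
  slide_record(id, w, h, true_grade = grade)
}

toy_detections <- function(grades, confs, x0 = NULL) {
  n <- length(grades)
  if (is.null(x0)) x0 <- seq(0, by = 100, length.out = n)
  data.frame(grade = grades, confidence = confs,
             x0 = x0, y0 = 10, x1 = x0 + 50, y1 = 60,
             epithelium_score = 0.9)
}

toy_detection_set <- function(grades, confs, ...) {
  slide_detection_set(toy_slide(...), toy_detections(grades, confs))
}
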