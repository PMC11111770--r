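.empty_detections <- function() {
  data.frame(grade = character(0), confidence = numeric(0),
             x0 = numeric(0), y0 = numeric(0),
             x1 = numeric(0), y1 = numeric(0),
             epithelium_score = numeric(0))
}

.validate_detections <- function(d, require_positive_area = TRUE) {
  need <- c("grade", "confidence", "x0", "y0", "x1", "y1")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("detections missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"epithelium_score" %in% names(d)) d$epithelium_score <- 1
  .assert_patch_grade(d$grade)
  if (any(d$confidence < 0 | d$confidence > 1)) {
    stop("detection confidences must lie in [0, 1]")
  }
  if (any(d$epithelium_score < 0 | d$epithelium_score > 1)) {
    stop("epithelium_score must lie in [0, 1]")
  }
  if (require_positive_area && nrow(d) &&
      any(d$x1 <= d$x0 | d$y1 <= d$y0)) {
    stop("detection boxes must have positive area")
  }
  d
}

#' Detections of one whole slide
#'
#' Container pairing a [slide_record()] with its slide-coordinate
#' detection table (one row per detected abnormal cell: `grade`,
#' `confidence`, box `x0,y0,x1,y1`, `epithelium_score`).
#'
#' @param slide A `slide_record`.
#' @param detections Data frame of detections in slide coordinates.
#' @return A `slide_detection_set`.
#' @export
slide_detection_set <- function(slide, detections = .empty_detections()) {
  stopifnot(inherits(slide, "slide_record"))
  detections <- .validate_detections(detections)
  if (nrow(detections) &&
      any(detections$x0 < 0 | detections$y0 < 0 |
          detections$x1 > slide$width_px | detections$y1 > slide$height_px)) {
    stop("detection boxes must lie within slide bounds")
  }
  structure(list(slide = slide, detections = detections),
            class = "slide_detection_set")
}

#' @export
print.slide_detection_set <- function(x, ...) {
  tab <- table(factor(x$detections$grade, levels = patch_grades()))
  cat(sprintf("<slide_detection_set> %s: %d detections (%s)\n",
              x$slide$slide_id, nrow(x$detections),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Intersection-over-union of axis-aligned boxes
#'
#' @param a Numeric `c(x0, y0, x1, y1)`.
#' @param b Either one box or a matrix of boxes (4 columns).
#' @return IoU value(s) in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  if (!is.matrix(b)) b <- matrix(b, ncol = 4)
  ix <- pmax(0, pmin(a[3], b[, 3]) - pmax(a[1], b[, 1]))
  iy <- pmax(0, pmin(a[4], b[, 4]) - pmax(a[2], b[, 2]))
  inter <- ix * iy
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  denom <- area_a + area_b - inter
  out <- ifelse(denom > 0, inter / denom, 0)
  out
}

.nms_keep <- function(boxes, confidence, iou_threshold) {
  n <- nrow(boxes)
  if (n <= 1) return(rep(TRUE, n))
  ord <- order(-confidence, boxes[, 2], boxes[, 1])
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (!length(cand)) break
    sup <- box_iou(as.numeric(boxes[i, ]), boxes[cand, , drop = FALSE]) >
      iou_threshold
    alive[cand[sup]] <- FALSE
  }
  keep
}

#' Aggregate per-patch detections to slide level
#'
#' Translates patch-local boxes to slide coordinates using each row's
#' patch origin, then suppresses duplicates that arise from overlapping
#' patches: within each grade, of any pair of boxes with IoU above
#' `dedup_iou` only the higher-confidence one is kept (greedy
#' non-maximum suppression). Boxes are clipped to the slide bounds.
#'
#' @param slide A `slide_record`.
#' @param patch_detections Data frame with detection columns plus
#'   `origin_x`, `origin_y` patch offsets. An empty or `NULL` table
#'   yields an empty set.
#' @param dedup_iou IoU threshold above which same-grade boxes are
#'   considered duplicates (default 0.5).
#' @return A `slide_detection_set`; never more detections than input.
#' @export
aggregate_detections <- function(slide, patch_detections, dedup_iou = 0.5) {
  if (is.null(patch_detections) || nrow(patch_detections) == 0) {
    return(slide_detection_set(slide))
  }
  d <- .validate_detections(patch_detections)
  if (!all(c("origin_x", "origin_y") %in% names(patch_detections))) {
    stop("patch_detections must carry origin_x / origin_y columns")
  }
  d$x0 <- pmax(0, d$x0 + patch_detections$origin_x)
  d$x1 <- pmin(slide$width_px, d$x1 + patch_detections$origin_x)
  d$y0 <- pmax(0, d$y0 + patch_detections$origin_y)
  d$y1 <- pmin(slide$height_px, d$y1 + patch_detections$origin_y)
  d <- d[d$x1 > d$x0 & d$y1 > d$y0, , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (g in unique(d$grade)) {
    idx <- which(d$grade == g)
    keep[idx] <- .nms_keep(as.matrix(d[idx, c("x0", "y0", "x1", "y1")]),
                           d$confidence[idx], dedup_iou)
  }
  d <- d[keep, c("grade", "confidence", "x0", "y0", "x1", "y1",
                 "epithelium_score")]
  rownames(d) <- NULL
  slide_detection_set(slide, d)
}

#' Top-k detections per patch class
#'
#' For reviewer display: within each of the six patch grades, up to `k`
#' detections sorted by confidence descending; ties broken by box
#' origin (y, then x) ascending.
#'
#' @param ds A `slide_detection_set`.
#' @param k Maximum detections per class (default 20).
#' @return Named list over [patch_grades()] of detection data frames.
#' @export
top_k_per_class <- function(ds, k = 20) {
  stopifnot(inherits(ds, "slide_detection_set"), k >= 1)
  d <- ds$detections
  out <- lapply(patch_grades(), function(g) {
    di <- d[d$grade == g, , drop = FALSE]
    di <- di[order(-di$confidence, di$y0, di$x0), , drop = FALSE]
    di <- head(di, k)
    rownames(di) <- NULL
    di
  })
  names(out) <- patch_grades()
  out
}

#' Read and write detection tables
#'
#' CSV columns: `slide_id, grade, confidence, x0, y0, x1, y1,
#' epithelium_score` — the plug-in contract for ingesting a real
#' detector's output. JSON mirrors the same records.
#'
#' @param sets List of `slide_detection_set` objects (or one).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_detections` returns `path` invisibly.
#' @export
write_detections <- function(sets, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(sets, "slide_detection_set")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$detections) == 0) return(NULL)
    cbind(slide_id = s$slide$slide_id, s$detections)
  }))
  if (is.null(df)) {
    df <- cbind(slide_id = character(0), .empty_detections())
  }
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA)
  }
  invisible(path)
}

#' @param slides Named list or data.frame of slide metadata used to
#'   rebuild `slide_record`s: either a list of `slide_record`s keyed by
#'   slide_id, or a data.frame with columns slide_id, width_px,
#'   height_px (and optionally pixel_size_um, true_grade).
#' @rdname write_detections
#' @export
read_detections <- function(path, slides, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.data.frame(slides)) {
    slides <- setNames(lapply(seq_len(nrow(slides)), function(i) {
      r <- slides[i, ]
      slide_record(r$slide_id, r$width_px, r$height_px,
                   if ("pixel_size_um" %in% names(r)) r$pixel_size_um else 0.2529,
                   if ("true_grade" %in% names(r)) r$true_grade else NA_character_)
    }), slides$slide_id)
  }
  lapply(slides, function(sl) {
    d <- df[df$slide_id == sl$slide_id,
            c("grade", "confidence", "x0", "y0", "x1", "y1",
              "epithelium_score"), drop = FALSE]
    rownames(d) <- NULL
    slide_detection_set(sl, d)
  })
}
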