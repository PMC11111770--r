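.bin_label <- function(i) sprintf("bin_%02d", i)

#' Feature names of the slide-level feature vector
#'
#' @param n_bins Number of equal-width confidence bins (default 10).
#' @param include_counts Include per-class detection counts.
#' @param include_glandular Include the glandular fraction feature.
#' @return Character vector of column names, e.g. `"HSIL_max_conf"`,
#'   `"LSIL_bin_07"`.
#' @export
slide_feature_names <- function(n_bins = 10, include_counts = TRUE,
                                include_glandular = FALSE) {
  cls <- gsub("-", "", patch_grades()) # "ASC-US" -> "ASCUS" for headers
  base <- unlist(lapply(cls, function(g) {
    c(paste0(g, "_max_conf"), paste0(g, "_mean_conf"),
      paste0(g, "_std_conf"), paste0(g, "_", .bin_label(seq_len(n_bins))))
  }))
  if (include_counts) base <- c(base, paste0(cls, "_count"))
  if (include_glandular) base <- c(base, "glandular_fraction")
  base
}

#' Slide-level statistical features from detections
#'
#' The slide classifier's input: per patch class, the maximum, mean and
#' (population) standard deviation of the detection confidences, plus
#' the proportion of that class's detections falling in each confidence
#' bin. Classes with no detections contribute zeros. Optionally the raw
#' per-class counts and the glandular fraction (share of detections
#' with epithelium score below 0.5) are appended.
#'
#' @param ds A `slide_detection_set`.
#' @param bins Strictly increasing bin edges spanning `[0, 1]`
#'   (default 10 equal-width bins). Bins are left-closed; the last is
#'   closed on both sides.
#' @param include_counts Append per-class counts (default TRUE; switch
#'   off for the confidence-statistics-only variant).
#' @param include_glandular Append glandular fraction (default FALSE).
#' @return Named numeric feature vector of fixed length
#'   `6 * (3 + B) (+ 6) (+ 1)`.
#' @export
extract_features <- function(ds, bins = seq(0, 1, length.out = 11),
                             include_counts = TRUE,
                             include_glandular = FALSE) {
  stopifnot(inherits(ds, "slide_detection_set"))
  if (length(bins) < 2 || any(diff(bins) <= 0) ||
      abs(bins[1]) > 1e-9 || abs(bins[length(bins)] - 1) > 1e-9) {
    stop("bins must be strictly increasing edges spanning [0, 1]")
  }
  n_bins <- length(bins) - 1
  d <- ds$detections
  vals <- unlist(lapply(patch_grades(), function(g) {
    conf <- d$confidence[d$grade == g]
    n <- length(conf)
    if (n == 0) return(numeric(3 + n_bins))
    # population SD; singleton -> 0
    stdev <- sqrt(mean((conf - mean(conf))^2))
    # right = FALSE: left-closed bins; include.lowest puts conf == 1
    # into the last (right-closed) bin
    h <- hist(conf, breaks = bins, plot = FALSE, right = FALSE,
              include.lowest = TRUE)
    c(max(conf), mean(conf), stdev, h$counts / n)
  }))
  if (include_counts) {
    vals <- c(vals, vapply(patch_grades(),
                           function(g) sum(d$grade == g), numeric(1)))
  }
  if (include_glandular) {
    gf <- if (nrow(d) == 0) 0 else mean(d$epithelium_score < 0.5)
    vals <- c(vals, gf)
  }
  setNames(vals, slide_feature_names(n_bins, include_counts,
                                     include_glandular))
}

#' Feature matrix for a cohort of slides
#'
#' @param sets List of `slide_detection_set` objects.
#' @inheritParams extract_features
#' @return Numeric matrix, one row per slide, named columns; row names
#'   are slide ids.
#' @export
extract_feature_matrix <- function(sets, bins = seq(0, 1, length.out = 11),
                                   include_counts = TRUE,
                                   include_glandular = FALSE) {
  X <- t(vapply(sets, extract_features,
                numeric(length(slide_feature_names(length(bins) - 1,
                                                   include_counts,
                                                   include_glandular))),
                bins = bins, include_counts = include_counts,
                include_glandular = include_glandular))
  rownames(X) <- vapply(sets, function(s) s$slide$slide_id, character(1))
  X
}

#' Write a feature matrix as CSV with stable headers
#'
#' @param X Feature matrix from [extract_feature_matrix()].
#' @param path Output path.
#' @param truth Optional character vector of true grades appended as a
#'   `true_grade` column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, truth = NULL) {
  df <- data.frame(slide_id = rownames(X), X, check.names = FALSE)
  if (!is.null(truth)) df$true_grade <- truth
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
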