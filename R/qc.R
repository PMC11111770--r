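.to_gray <- function(image) {
  if (length(dim(image)) == 3) {
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  } else {
    image
  }
}

.resize_bilinear <- function(channel, new_h, new_w) {
  h <- nrow(channel)
  w <- ncol(channel)
  ys <- pmin(pmax((seq_len(new_h) - 0.5) * h / new_h - 0.5, 0), h - 1)
  xs <- pmin(pmax((seq_len(new_w) - 0.5) * w / new_w - 0.5, 0), w - 1)
  y0 <- floor(ys); y1 <- pmin(y0 + 1, h - 1); fy <- ys - y0
  x0 <- floor(xs); x1 <- pmin(x0 + 1, w - 1); fx <- xs - x0
  a <- channel[y0 + 1, x0 + 1, drop = FALSE]
  b <- channel[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- channel[y1 + 1, x0 + 1, drop = FALSE]
  d <- channel[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, new_h, new_w)
  wx <- matrix(fx, new_h, new_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    c_ * wy * (1 - wx) + d * wy * wx
}

#' Standardize a WSI thumbnail
#'
#' Rescales so the short edge is exactly `short_edge` pixels (default
#' 1000), preserving aspect ratio with the long edge rounded to the
#' nearest integer; bilinear interpolation, upscaling permitted.
#' Idempotent: an already-standardized thumbnail is returned unchanged.
#'
#' @param image RGB array `h x w x 3` (values in `[0, 255]`).
#' @param short_edge Target short-edge length in pixels.
#' @return Resized RGB array.
#' @export
standardize_thumbnail <- function(image, short_edge = 1000) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2 || d[1] < 1 || d[2] < 1) {
    stop("empty image")
  }
  h <- d[1]; w <- d[2]
  if (min(h, w) == short_edge) return(image)
  scale <- short_edge / min(h, w)
  new_h <- if (h <= w) short_edge else as.integer(round(h * scale))
  new_w <- if (w < h) short_edge else as.integer(round(w * scale))
  out <- array(0, c(new_h, new_w, 3))
  for (ch in 1:3) out[, , ch] <- .resize_bilinear(image[, , ch], new_h, new_w)
  out
}

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution with edge replication (kernel rows
#' renormalized at the borders). Utility used by the blur-severity
#' checks and available for preprocessing.
#'
#' @param image RGB array or single-channel matrix.
#' @param sigma Gaussian standard deviation in pixels (0 returns the
#'   input).
#' @return Blurred image of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  kernel_matrix <- function(n) {
    idx <- seq_len(n)
    K <- exp(-(outer(idx, idx, "-")^2) / (2 * sigma^2))
    K[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
    K / rowSums(K)
  }
  blur_channel <- function(ch) {
    A <- kernel_matrix(nrow(ch))
    B <- kernel_matrix(ncol(ch))
    A %*% ch %*% t(B)
  }
  if (length(dim(image)) == 3) {
    out <- image
    for (ch in 1:3) out[, , ch] <- blur_channel(image[, , ch])
    out
  } else {
    blur_channel(image)
  }
}

.box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + pad[dy + 1:h, dx + 1:w]
  }
  acc / 9
}

#' Assess slide scanning quality from a thumbnail
#'
#' Deterministic heuristic baseline for the slide-quality contract
#' (binary summary plus multi-label issue severities); a learned model
#' can replace it behind the same report shape. Severities in `[0, 1]`:
#' \describe{
#'   \item{blur}{`exp(-r / 0.1)` where `r` is the high-frequency energy
#'     ratio `var(gray - box3(gray)) / var(gray)` — a normalized
#'     local-contrast statistic that decreases monotonically under
#'     Gaussian blurring.}
#'   \item{incomplete_scan}{fraction of blank (near-white, gray >= 250)
#'     pixels.}
#'   \item{low_cellularity}{one minus the tissue-pixel fraction
#'     (gray < 220).}
#' }
#' The slide is acceptable iff every severity is at or below its
#' threshold.
#'
#' @param thumbnail Standardized RGB thumbnail array.
#' @param thresholds Named numeric vector of per-issue thresholds
#'   (defaults: blur 0.5, incomplete_scan 0.3, low_cellularity 0.5).
#' @return A `quality_report`: list with `acceptable`, `issues`,
#'   `thresholds`.
#' @export
assess_quality <- function(thumbnail,
                           thresholds = c(blur = 0.5, incomplete_scan = 0.3,
                                          low_cellularity = 0.5)) {
  gray <- .to_gray(thumbnail)
  v <- stats::var(as.vector(gray))
  blur <- if (v <= 0) 1 else {
    r <- stats::var(as.vector(gray - .box3(gray))) / v
    exp(-r / 0.1)
  }
  incomplete <- mean(gray >= 250)
  low_cell <- 1 - mean(gray < 220)
  issues <- c(blur = blur, incomplete_scan = incomplete,
              low_cellularity = low_cell)
  structure(list(acceptable = all(issues <= thresholds[names(issues)]),
                 issues = issues, thresholds = thresholds),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> acceptable: %s\n", x$acceptable))
  for (nm in names(x$issues)) {
    cat(sprintf("  %-16s %.3f (threshold %.2f)\n", nm, x$issues[[nm]],
                x$thresholds[[nm]]))
  }
  invisible(x)
}

#' Serialize a quality report as JSON
#'
#' @param report A `quality_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  jsonlite::write_json(list(acceptable = report$acceptable,
                            issues = as.list(report$issues),
                            thresholds = as.list(report$thresholds)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic cytology thumbnail
#'
#' Tissue-covered thumbnail with pink-violet smear texture on a white
#' background: an elliptical tissue region scaled to the requested
#' coverage with per-pixel Gaussian texture noise. A positive control
#' for the QC heuristics; it does not emulate real cell morphology.
#'
#' @param width,height Raster size (default 200 x 200 — QC statistics
#'   are scale free, so tests use small rasters).
#' @param coverage Fraction of the raster the tissue ellipse spans
#'   (1 = full coverage).
#' @param noise_sd SD of the texture noise in intensity units.
#' @param seed Optional integer seed.
#' @return RGB array `height x width x 3` in `[0, 255]`.
#' @export
generate_thumbnail <- function(width = 200, height = 200, coverage = 1,
                               noise_sd = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- array(255, c(height, width, 3))
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  # ellipse through the corners at coverage = 1 (covers everything)
  mask <- ((yy - cy) / height)^2 + ((xx - cx) / width)^2 <= coverage^2 / 2
  base <- c(185, 130, 170)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- base[ch] + stats::rnorm(sum(mask), 0, noise_sd)
    img[, , ch] <- pmin(pmax(plane, 0), 255)
  }
  img
}
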