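#' Convert an RGB raster to stain-density absorbance (SDA) space
#'
#' Applies the Beer-Lambert optical-density transform per channel:
#' `sda = -ln((I + eps) / background_intensity)`. In SDA space stains
#' mix linearly, which is what the Macenko deconvolution and the colour
#' perturbation operate on.
#'
#' @param image Numeric array `h x w x 3` with values in `[0, 255]`.
#' @param background_intensity Transmitted intensity of blank glass
#'   (default 255). Must be positive.
#' @param eps Small offset avoiding `log(0)` on saturated dark pixels
#'   (default 1).
#' @return Numeric array of the same shape holding SDA values.
#' @export
rgb_to_sda <- function(image, background_intensity = 255, eps = 1) {
  if (background_intensity <= 0) stop("background_intensity must be > 0")
  -log((image + eps) / background_intensity)
}

#' Reconstruct an RGB raster from SDA space
#'
#' Exact inverse of [rgb_to_sda()] (before 8-bit quantization); output
#' is clamped to `[0, 255]`.
#'
#' @param sda Numeric array of SDA values.
#' @inheritParams rgb_to_sda
#' @return Numeric array with values in `[0, 255]`.
#' @export
sda_to_rgb <- function(sda, background_intensity = 255, eps = 1) {
  if (background_intensity <= 0) stop("background_intensity must be > 0")
  out <- background_intensity * exp(-sda) - eps
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

.sda_pixel_matrix <- function(sda) {
  if (length(dim(sda)) == 3) {
    matrix(sda, ncol = 3)
  } else {
    stopifnot(ncol(sda) == 3)
    sda
  }
}

.unit_nonneg <- function(v) {
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

#' Estimate the stain component matrix by the Macenko method
#'
#' Tissue pixels (SDA Euclidean norm above `beta`) are projected onto
#' the plane of their two leading singular vectors; the extreme
#' directions at the `alpha` / `100 - alpha` angle percentiles give the
#' two dominant stain absorbance vectors. The third column is the
#' normalized cross product (residual channel). Columns are unit-norm,
#' nonnegative, ordered haematoxylin first (greater blue-channel
#' absorbance).
#'
#' @param sda SDA raster (`h x w x 3` array) or an `n x 3` pixel matrix.
#' @param beta SDA magnitude threshold selecting tissue pixels
#'   (default 0.15).
#' @param alpha Robust percentile for the extreme angles (default 1,
#'   i.e. 1st/99th percentiles).
#' @return A 3 x 3 matrix with columns H, E, residual. If fewer than two
#'   pixels pass the threshold, an identity-like fallback is returned
#'   with a warning and attribute `degenerate = TRUE`. If the thresholded
#'   pixels are essentially one-dimensional (single stain), the second
#'   column carries attribute `unstable_second = TRUE`.
#' @export
estimate_stain_matrix_macenko <- function(sda, beta = 0.15, alpha = 1) {
  X <- .sda_pixel_matrix(sda)
  keep <- sqrt(rowSums(X^2)) > beta
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2) {
    warning("fewer than 2 pixels above the SDA threshold; ",
            "returning identity-like fallback stain matrix")
    m <- diag(3)
    attr(m, "degenerate") <- TRUE
    return(m)
  }
  sv <- svd(X, nu = 0, nv = 2)
  V <- sv$v # 3 x 2 basis of the dominant plane
  # orient basis vectors consistently
  for (j in 1:2) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  P <- X %*% V
  phi <- atan2(P[, 2], P[, 1])
  q <- quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  v1 <- .unit_nonneg(V %*% c(cos(q[1]), sin(q[1])))
  v2 <- .unit_nonneg(V %*% c(cos(q[2]), sin(q[2])))
  # one-stain images: the robust angular spread collapses (quantization
  # jitter only), leaving the second vector meaningless
  unstable <- sv$d[2] < 1e-6 * sv$d[1] || (q[2] - q[1]) < 5 * pi / 180
  resid <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
  resid <- .unit_nonneg(abs(resid))
  # haematoxylin absorbs more in the blue channel
  m <- if (v1[3] >= v2[3]) cbind(v1, v2, resid) else cbind(v2, v1, resid)
  dimnames(m) <- list(c("R", "G", "B"), c("H", "E", "residual"))
  if (unstable) attr(m, "unstable_second") <- TRUE
  m
}

#' Per-pixel stain concentrations by colour deconvolution
#'
#' Solves `sda = M %*% c` for each pixel given the 3 x 3 stain matrix.
#'
#' @param sda SDA raster or `n x 3` pixel matrix.
#' @param stain_matrix 3 x 3 stain component matrix (columns H, E,
#'   residual).
#' @return `n x 3` matrix of concentrations, columns H, E, residual.
#' @export
stain_concentrations <- function(sda, stain_matrix) {
  X <- .sda_pixel_matrix(sda)
  C <- t(solve(stain_matrix, t(X)))
  colnames(C) <- c("H", "E", "residual")
  C
}

#' Fit the H/E component distribution over a training set
#'
#' Estimates a pooled stain matrix from all images (Macenko on the
#' concatenated tissue pixels), computes each image's mean H and E
#' concentration, and summarizes across images: mean, standard
#' deviation (sample SD), and min/max bounds per component.
#'
#' @param images List of RGB arrays (`h x w x 3`, values in
#'   `[0, 255]`); at least two required so the SD is defined.
#' @param stain_matrix Optional fixed 3 x 3 stain matrix; estimated from
#'   the pooled pixels when `NULL`.
#' @param background_intensity,eps Passed to [rgb_to_sda()].
#' @param beta,alpha Passed to [estimate_stain_matrix_macenko()].
#' @return A `stain_model` object.
#' @export
fit_stain_distribution <- function(images, stain_matrix = NULL,
                                   background_intensity = 255, eps = 1,
                                   beta = 0.15, alpha = 1) {
  if (!is.list(images) || length(images) < 2) {
    stop("need at least 2 images to fit component standard deviations")
  }
  sdas <- lapply(images, rgb_to_sda,
                 background_intensity = background_intensity, eps = eps)
  if (is.null(stain_matrix)) {
    pooled <- do.call(rbind, lapply(sdas, .sda_pixel_matrix))
    stain_matrix <- estimate_stain_matrix_macenko(pooled, beta = beta,
                                                  alpha = alpha)
  }
  per_image <- t(vapply(sdas, function(s) {
    C <- stain_concentrations(s, stain_matrix)
    c(H = mean(C[, "H"]), E = mean(C[, "E"]))
  }, numeric(2)))
  structure(
    list(stain_matrix = stain_matrix,
         mu_H = mean(per_image[, "H"]), mu_E = mean(per_image[, "E"]),
         sigma_H = sd(per_image[, "H"]), sigma_E = sd(per_image[, "E"]),
         lower_H = min(per_image[, "H"]), upper_H = max(per_image[, "H"]),
         lower_E = min(per_image[, "E"]), upper_E = max(per_image[, "E"]),
         background_intensity = background_intensity, eps = eps,
         n_images = length(images)),
    class = "stain_model"
  )
}

#' @export
print.stain_model <- function(x, ...) {
  cat(sprintf(paste0("<stain_model> fitted on %d images\n",
                     "  H: mu=%.4f sd=%.4f bounds=[%.4f, %.4f]\n",
                     "  E: mu=%.4f sd=%.4f bounds=[%.4f, %.4f]\n"),
              x$n_images, x$mu_H, x$sigma_H, x$lower_H, x$upper_H,
              x$mu_E, x$sigma_E, x$lower_E, x$upper_E))
  invisible(x)
}

#' Draw a random stain perturbation
#'
#' Selects uniformly one of \{H only, E only, both, neither\} and draws
#' the selected components' shifts uniformly in `[-2 sigma, 2 sigma]`;
#' unselected shifts are zero. Uses R's RNG (seed with [set.seed()]).
#'
#' @param model A fitted `stain_model`.
#' @return List with `target`, `delta_H`, `delta_E`.
#' @export
draw_perturbation <- function(model) {
  stopifnot(inherits(model, "stain_model"))
  target <- sample(c("H", "E", "both", "neither"), 1)
  delta_H <- if (target %in% c("H", "both"))
    runif(1, -2 * model$sigma_H, 2 * model$sigma_H) else 0
  delta_E <- if (target %in% c("E", "both"))
    runif(1, -2 * model$sigma_E, 2 * model$sigma_E) else 0
  list(target = target, delta_H = delta_H, delta_E = delta_E)
}

#' Perturb the stain components of an image
#'
#' Decomposes the image with the model's stain matrix, shifts the H
#' and/or E concentration fields by a global additive delta (a shift to
#' the image's mean component magnitude, not per-pixel noise), clamps
#' the shifted per-image mean to the fitted `[lower, upper]` bounds,
#' and reconstructs RGB from the perturbed SDA.
#'
#' @param image RGB array `h x w x 3` in `[0, 255]`.
#' @param model A fitted `stain_model`.
#' @param draw Optional perturbation from [draw_perturbation()]; drawn
#'   internally when `NULL`.
#' @return RGB array of the same shape, values in `[0, 255]`, with
#'   attribute `draw` recording the realized perturbation.
#' @export
perturb_stains <- function(image, model, draw = NULL) {
  if (!inherits(model, "stain_model")) {
    stop("`model` must be a fitted stain_model (see fit_stain_distribution)")
  }
  if (is.null(draw)) draw <- draw_perturbation(model)
  dims <- dim(image)
  sda <- rgb_to_sda(image, model$background_intensity, model$eps)
  C <- stain_concentrations(sda, model$stain_matrix)
  shift_component <- function(x, delta, lower, upper) {
    m <- mean(x)
    target <- min(max(m + delta, lower), upper)
    x + (target - m)
  }
  C[, "H"] <- shift_component(C[, "H"], draw$delta_H, model$lower_H, model$upper_H)
  C[, "E"] <- shift_component(C[, "E"], draw$delta_E, model$lower_E, model$upper_E)
  sda_new <- C %*% t(model$stain_matrix)
  out <- sda_to_rgb(array(sda_new, dims), model$background_intensity, model$eps)
  attr(out, "draw") <- draw
  out
}

#' Read / write 8-bit RGB PNG rasters
#'
#' Thin wrappers over the `png` package mapping between files and the
#' `[0, 255]` arrays used throughout. TIFF is not supported in this
#' build.
#'
#' @param path File path.
#' @return `read_png_image` returns an `h x w x 3` array in `[0, 255]`.
#' @export
read_png_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @param image Array `h x w x 3` in `[0, 255]`.
#' @rdname read_png_image
#' @export
write_png_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Serialize / restore a stain model as JSON
#'
#' @param model A `stain_model`.
#' @param path JSON file path.
#' @return `write_stain_model` returns `path` invisibly;
#'   `read_stain_model` returns the `stain_model`.
#' @export
write_stain_model <- function(model, path) {
  stopifnot(inherits(model, "stain_model"))
  x <- unclass(model)
  x$stain_matrix <- as.vector(x$stain_matrix)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$stain_matrix <- matrix(x$stain_matrix, 3, 3,
                           dimnames = list(c("R", "G", "B"),
                                           c("H", "E", "residual")))
  structure(x, class = "stain_model")
}
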