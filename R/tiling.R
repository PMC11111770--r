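#' Sliding-window tile grid over a slide raster
#'
#' Decomposes a `width_px` x `height_px` image into `patch_size_px`
#' square patches laid out on a stride-`stride_px` lattice. Along each
#' axis the origins are 0, s, 2s, ...; the final origin is clamped to
#' `max(0, dim - patch)` so the last patch abuts the image edge and
#' every pixel is covered. Coordinates are 0-based, half-open,
#' x = column / y = row, origin top-left.
#'
#' @param width_px,height_px Image dimensions in pixels (>= 1).
#' @param patch_size_px Patch edge length (default 1024).
#' @param stride_px Stride between patch origins; must satisfy
#'   `1 <= stride_px <= patch_size_px` (default 768, 25\% overlap).
#' @return A `tile_grid` object: list with `patch_size_px`, `stride_px`
#'   and `origins`, a data.frame of (x, y) offsets sorted row-major.
#' @examples
#' tile_slide(2500, 1500, 1024, 768)$origins
#' @export
tile_slide <- function(width_px, height_px, patch_size_px = 1024L,
                       stride_px = 768L) {
  stopifnot(width_px >= 1, height_px >= 1, patch_size_px >= 1)
  if (stride_px < 1 || stride_px > patch_size_px) {
    stop("stride_px must satisfy 1 <= stride_px <= patch_size_px ",
         "(stride > patch leaves uncovered gaps)")
  }
  axis_origins <- function(dim) {
    last <- max(0L, as.integer(dim) - as.integer(patch_size_px))
    o <- seq.int(0L, by = as.integer(stride_px),
                 length.out = max(1L, ceiling(last / stride_px) + 1L))
    o[o > last] <- last
    unique(o)
  }
  xs <- axis_origins(width_px)
  ys <- axis_origins(height_px)
  origins <- data.frame(
    x = rep(xs, times = length(ys)),
    y = rep(ys, each = length(xs))
  )
  structure(
    list(patch_size_px = as.integer(patch_size_px),
         stride_px = as.integer(stride_px),
         origins = origins),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %d px, stride %d px\n",
              nrow(x$origins), x$patch_size_px, x$stride_px))
  invisible(x)
}

#' Translate a patch-local box to slide coordinates
#'
#' @param box Numeric vector `c(x0, y0, x1, y1)` in patch-local pixels,
#'   or a matrix with those four columns.
#' @param origin Numeric `c(x, y)` patch origin in slide coordinates.
#' @return Box (or matrix of boxes) translated by `origin`; dimensions
#'   preserved.
#' @export
to_slide_coords <- function(box, origin) {
  stopifnot(length(origin) == 2)
  if (is.matrix(box)) {
    stopifnot(ncol(box) == 4)
    sweep(box, 2, c(origin[1], origin[2], origin[1], origin[2]), "+")
  } else {
    stopifnot(length(box) == 4)
    box + c(origin[1], origin[2], origin[1], origin[2])
  }
}

#' Write a tile manifest as CSV
#'
#' @param grid A `tile_grid`.
#' @param slide_id Slide identifier recorded per row.
#' @param path Output CSV path.
#' @return Invisibly, the manifest data.frame (slide_id, x, y, patch_size).
#' @export
write_tile_manifest <- function(grid, slide_id, path) {
  stopifnot(inherits(grid, "tile_grid"))
  df <- data.frame(slide_id = slide_id,
                   x = grid$origins$x, y = grid$origins$y,
                   patch_size = grid$patch_size_px)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
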