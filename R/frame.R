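#' Calibrated multi-channel image frame
#'
#' An `image_frame` bundles named 2D intensity rasters sharing one geometry
#' with the physical pixel size, the unit of analysis for the whole pipeline.
#' Intensities are arbitrary detector units; all physical quantities derived
#' downstream (areas, axis lengths, densities) use `pixel_size`.
#'
#' @param channels named list of numeric matrices (row, col), all the same
#'   dimension, non-negative intensities.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param id optional frame identifier carried into output tables.
#' @return an object of class `image_frame`: a list with elements
#'   `channels`, `pixel_size`, `id`.
#' @examples
#' fr <- image_frame(list(mito = matrix(0, 8, 8)), pixel_size = 0.02)
#' frame_dim(fr)
#' @export
image_frame <- function(channels, pixel_size, id = "frame") {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("'channels' must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1)))) {
    stop("every channel must be a numeric matrix")
  }
  d0 <- dims[[1]]
  if (any(vapply(dims, function(d) !identical(d, d0), logical(1)))) {
    stop("all channels must share the same dimensions")
  }
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    stop("channel intensities must be non-negative")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number (μm/pixel)")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 id = as.character(id)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf("<image_frame '%s'> %d x %d px @ %.4g μm/px\n",
              x$id, d[1], d[2], x$pixel_size))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Frame dimensions in pixels
#' @param frame an `image_frame`.
#' @return integer vector (rows, cols).
#' @export
frame_dim <- function(frame) dim(frame$channels[[1]])

#' Extract one channel raster from a frame
#' @param frame an `image_frame`.
#' @param name channel name.
#' @return numeric matrix of intensities.
#' @export
get_channel <- function(frame, name) {
  if (!name %in% names(frame$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(frame$channels), collapse = ", ")))
  }
  frame$channels[[name]]
}

#' Binary mask with physical calibration
#'
#' @param raster logical matrix (or numeric, coerced by `!= 0`).
#' @param pixel_size micrometres per pixel.
#' @return object of class `binary_mask` with elements `raster` and
#'   `pixel_size`.
#' @export
binary_mask <- function(raster, pixel_size) {
  if (!is.matrix(raster)) stop("'raster' must be a matrix")
  if (!is.logical(raster)) raster <- raster != 0
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number")
  }
  structure(list(raster = raster, pixel_size = pixel_size),
            class = "binary_mask")
}

#' Mask area in square micrometres
#'
#' Exactly the true-pixel count times `pixel_size^2`; no smoothing or
#' boundary correction.
#' @param mask a `binary_mask`.
#' @return area in μm².
#' @export
mask_area_um2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$raster) * mask$pixel_size^2
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d fg px, %.4g μm²\n",
              nrow(x$raster), ncol(x$raster), sum(x$raster),
              mask_area_um2(x)))
  invisible(x)
}

# linear index <-> (row, col) helpers shared across modules
idx_to_rc <- function(idx, nr) {
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

rc_to_idx <- function(row, col, nr) {
  (col - 1L) * nr + row
}
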