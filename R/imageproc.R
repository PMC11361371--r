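#' Unsharp-mask sharpening of a channel
#'
#' Subtracts a weighted Gaussian-smoothed copy of the image and rescales,
#' `(I - w * G_r(I)) / (1 - w)`, clipping negatives to zero. With a very
#' large radius this flattens diffuse background while amplifying punctate
#' structure by about `1/(1 - w)`. Defaults follow the common Fiji recipe
#' for mitochondrial-network preprocessing (radius 100 px, weight 0.7).
#'
#' @param x numeric matrix of intensities.
#' @param radius Gaussian sigma in pixels; 0 returns `x` unchanged.
#' @param weight mask weight in `[0, 1)`.
#' @return numeric matrix, same dimension as `x`, non-negative.
#' @export
unsharp_mask <- function(x, radius = 100, weight = 0.7) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight >= 1) {
    stop("'weight' must be in [0, 1): weight >= 1 makes the rescaling blow up")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("'radius' must be a non-negative sigma in pixels")
  }
  if (radius == 0 || weight == 0) {
    if (weight == 0) return(pmax(x, 0))
    return(pmax(x, 0))
  }
  bl <- gaussian_smooth(x, sigma = radius)
  out <- (x - weight * bl) / (1 - weight)
  pmax(out, 0)
}

# Gaussian smoothing with replicated borders; kernel support is capped so the
# filter never exceeds the image (large radii behave like local background
# estimation rather than erroring).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  full <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L
  as.matrix(EBImage::gblur(x, sigma = sigma, radius = min(full, cap),
                           boundary = "replicate"))
}

#' Threshold a channel into a binary mask
#'
#' Foreground is `x >= threshold`; connected components smaller than
#' `min_size` pixels (8-connectivity) are removed. The threshold is either
#' found by Otsu's method on a 256-bin histogram or supplied absolutely.
#' The threshold actually applied is recorded on the result so every run is
#' reproducible from its log.
#'
#' @param x numeric matrix of intensities.
#' @param pixel_size micrometres per pixel for the resulting mask.
#' @param method `"otsu"` (default) or `"absolute"`.
#' @param threshold intensity cutoff, required for `method = "absolute"`.
#' @param min_size minimum component size in pixels (default 4, rejecting
#'   single-pixel shot noise at super-resolution sampling).
#' @return a [binary_mask()] with attributes `threshold`, `method`,
#'   `min_size`, `n_small_removed`.
#' @export
segment_mask <- function(x, pixel_size, method = c("otsu", "absolute"),
                         threshold = NULL, min_size = 4L) {
  stopifnot(is.matrix(x), is.numeric(x))
  method <- match.arg(method)
  if (method == "absolute") {
    if (is.null(threshold)) stop("method = 'absolute' requires 'threshold'")
    thr <- threshold
  } else {
    mx <- max(x)
    mn <- min(x)
    if (mx == 0) {
      # empty image: empty mask, by contract not an error
      m <- binary_mask(matrix(FALSE, nrow(x), ncol(x)), pixel_size)
      attr(m, "threshold") <- NA_real_
      attr(m, "method") <- method
      attr(m, "min_size") <- as.integer(min_size)
      attr(m, "n_small_removed") <- 0L
      return(m)
    }
    if (mx == mn) {
      stop("Otsu thresholding is undefined on a constant (degenerate) histogram")
    }
    thr <- as.numeric(EBImage::otsu(EBImage::Image(x / mx),
                                    range = c(0, 1), levels = 256L)) * mx
  }
  raster <- x >= thr
  removed <- 0L
  if (min_size > 1L && any(raster)) {
    lab <- label_components8(raster)
    if (attr(lab, "n") > 0L) {
      sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
      small <- which(sizes < min_size)
      if (length(small)) {
        raster[lab %in% small] <- FALSE
        removed <- length(small)
      }
    }
  }
  m <- binary_mask(raster, pixel_size)
  attr(m, "threshold") <- thr
  attr(m, "method") <- method
  attr(m, "min_size") <- as.integer(min_size)
  attr(m, "n_small_removed") <- removed
  m
}

# 8-connected component labelling: 4-connected pass (EBImage::bwlabel), then
# union-find over diagonally adjacent label pairs. Final labels are numbered
# 1..K in order of the smallest constituent 4-connected label, which follows
# column-major scan order and is fully deterministic.
label_components8 <- function(raster) {
  stopifnot(is.matrix(raster))
  if (!is.logical(raster)) raster <- raster != 0
  lab <- EBImage::bwlabel(raster)
  lab <- matrix(as.integer(round(as.numeric(lab))), nrow(raster), ncol(raster))
  k <- max(lab)
  if (k == 0L) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1L && nc > 1L) {
    p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
    p2 <- cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
    pairs <- rbind(p1, p2)
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(k)
      find_root <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (j in seq_len(nrow(pairs))) {
        ra <- find_root(pairs[j, 1]); rb <- find_root(pairs[j, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(k), find_root, integer(1))
      remap <- match(roots, sort(unique(roots)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      k <- max(remap)
    }
  }
  attr(lab, "n") <- k
  lab
}

#' Set of segmented foci (regions of interest)
#'
#' Internal container behind [label_foci()]: each focus is a vector of
#' linear pixel indices into the frame raster (column-major), all foci
#' pairwise disjoint.
#'
#' @param pixels list of integer vectors of linear pixel indices.
#' @param dim frame dimension (rows, cols).
#' @param pixel_size micrometres per pixel.
#' @param channel channel name the foci were segmented from.
#' @return object of class `foci_set`.
#' @export
foci_set <- function(pixels, dim, pixel_size, channel = "unknown") {
  stopifnot(is.list(pixels), length(dim) == 2L, pixel_size > 0)
  structure(list(pixels = pixels, dim = as.integer(dim),
                 pixel_size = pixel_size, channel = as.character(channel),
                 ids = seq_along(pixels)),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> %d foci from channel '%s' (%d x %d px @ %.4g μm/px)\n",
              length(x$pixels), x$channel, x$dim[1], x$dim[2], x$pixel_size))
  invisible(x)
}

#' @export
length.foci_set <- function(x) length(x$pixels)

subset_foci <- function(foci, keep) {
  out <- foci
  out$pixels <- foci$pixels[keep]
  out$ids <- foci$ids[keep]
  out
}

#' Label connected foci in a binary mask
#'
#' One region of interest per 8-connected component: two pixels touching
#' only at a corner belong to the same focus. The pixel sets are disjoint
#' and their union is the mask.
#'
#' @param mask a [binary_mask()].
#' @param channel channel name recorded on the result.
#' @return a [foci_set()].
#' @export
label_foci <- function(mask, channel = "unknown") {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components8(mask$raster)
  n <- attr(lab, "n")
  if (n == 0L) {
    return(foci_set(list(), dim(mask$raster), mask$pixel_size, channel))
  }
  fg <- which(lab > 0L)
  pix <- split(fg, lab[fg])
  names(pix) <- NULL
  foci_set(pix, dim(mask$raster), mask$pixel_size, channel)
}

#' Filter foci by containment in a mask
#'
#' Retains a focus according to the containment rule: `"centroid"` (default)
#' keeps a focus whose centroid pixel lies inside the mask, `"majority"`
#' requires more than half of its pixels inside, `"any"` requires at least
#' one pixel inside. Intended to drop foci outside the mitochondrial
#' network mask before downstream measurement.
#'
#' @param foci a [foci_set()].
#' @param mask a [binary_mask()] on the same frame geometry.
#' @param rule `"centroid"`, `"majority"` or `"any"`.
#' @return the retained [foci_set()], with attributes `rule`, `n_before`,
#'   `n_after`.
#' @export
filter_by_mask <- function(foci, mask, rule = c("centroid", "majority", "any")) {
  stopifnot(inherits(foci, "foci_set"), inherits(mask, "binary_mask"))
  rule <- match.arg(rule)
  if (!identical(as.integer(dim(mask$raster)), foci$dim)) {
    stop("foci and mask must share frame geometry")
  }
  nr <- foci$dim[1]
  keep <- vapply(foci$pixels, function(idx) {
    inside <- mask$raster[idx]
    switch(rule,
           any = any(inside),
           majority = mean(inside) > 0.5,
           centroid = {
             rc <- idx_to_rc(idx, nr)
             r <- pmin(pmax(as.integer(round(mean(rc[, 1]))), 1L), nr)
             cc <- pmin(pmax(as.integer(round(mean(rc[, 2]))), 1L), foci$dim[2])
             mask$raster[r, cc]
           })
  }, logical(1))
  out <- subset_foci(foci, keep)
  attr(out, "rule") <- rule
  attr(out, "n_before") <- length(foci)
  attr(out, "n_after") <- length(out)
  out
}

#' Partition a frame into cell regions seeded at nuclei
#'
#' Nuclei are segmented (or taken as given), and each cell body pixel is
#' assigned to its geodesically nearest nucleus by seeded region growing
#' over the cell-body mask (Voronoi-style propagation). Each resulting cell
#' contains exactly one nucleus; where two nuclei share one cell-body blob
#' the blob is split along the watershed of distance to the nuclei. A
#' nucleus whose cell never grows beyond the nucleus itself is flagged.
#'
#' @param nuclei numeric matrix (nuclear stain, segmented by Otsu) or a
#'   [binary_mask()] of nuclei.
#' @param body numeric matrix (whole-cell stain, segmented by Otsu), a
#'   [binary_mask()], or a logical matrix marking candidate cell-body
#'   pixels. Nuclei are always included in the body.
#' @param pixel_size micrometres per pixel; required when `nuclei` is a
#'   plain matrix.
#' @param nucleus_min_size minimum nucleus size in pixels.
#' @param body_threshold optional absolute threshold for the body channel
#'   (otherwise Otsu).
#' @return object of class `cell_set`: integer label matrices `nuclei` and
#'   `cells` (same labels; nucleus k lies inside cell k), `pixel_size`, and
#'   a per-cell `table` with areas in μm² and a `phase` column initialised
#'   to `"unassigned"`.
#' @export
build_cell_regions <- function(nuclei, body, pixel_size = NULL,
                               nucleus_min_size = 20L, body_threshold = NULL) {
  if (inherits(nuclei, "binary_mask")) {
    px <- nuclei$pixel_size
    nuc_raster <- nuclei$raster
  } else {
    stopifnot(is.matrix(nuclei))
    if (is.null(pixel_size)) stop("'pixel_size' required with raw nuclei raster")
    px <- pixel_size
    nuc_raster <- segment_mask(nuclei, px, min_size = nucleus_min_size)$raster
  }
  nuc_lab <- label_components8(nuc_raster)
  k <- attr(nuc_lab, "n")
  if (k == 0L) {
    return(empty_cell_set(dim(nuc_raster), px))
  }
  if (inherits(body, "binary_mask")) {
    body_raster <- body$raster
  } else if (is.logical(body)) {
    body_raster <- body
  } else {
    stopifnot(is.matrix(body))
    body_raster <- if (is.null(body_threshold)) {
      segment_mask(body, px, min_size = nucleus_min_size)$raster
    } else {
      segment_mask(body, px, method = "absolute", threshold = body_threshold,
                   min_size = nucleus_min_size)$raster
    }
  }
  body_raster <- body_raster | nuc_raster
  cells <- EBImage::propagate(matrix(0, nrow(nuc_raster), ncol(nuc_raster)),
                              seeds = nuc_lab, mask = body_raster)
  cells <- matrix(as.integer(round(as.numeric(cells))),
                  nrow(nuc_raster), ncol(nuc_raster))
  tab <- data.frame(cell_id = seq_len(k))
  tab$nucleus_area_um2 <- tabulate(nuc_lab[nuc_lab > 0L], nbins = k) * px^2
  cell_px <- tabulate(cells[cells > 0L], nbins = k)
  tab$cell_area_um2 <- cell_px * px^2
  tab$cytoplasm_area_um2 <- tab$cell_area_um2 - tab$nucleus_area_um2
  tab$phase <- "unassigned"
  tab$flagged <- tab$cytoplasm_area_um2 <= 0
  structure(list(nuclei = nuc_lab, cells = cells, pixel_size = px,
                 table = tab),
            class = "cell_set")
}

empty_cell_set <- function(d, px) {
  z <- matrix(0L, d[1], d[2])
  structure(list(nuclei = z, cells = z, pixel_size = px,
                 table = data.frame(cell_id = integer(),
                                    nucleus_area_um2 = numeric(),
                                    cell_area_um2 = numeric(),
                                    cytoplasm_area_um2 = numeric(),
                                    phase = character(),
                                    flagged = logical())),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells (%d x %d px @ %.4g μm/px)\n",
              nrow(x$table), nrow(x$cells), ncol(x$cells), x$pixel_size))
  invisible(x)
}

#' Number of cells in a cell_set
#' @param cells a `cell_set`.
#' @return integer count.
#' @export
n_cells <- function(cells) nrow(cells$table)
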