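#' Per-focus shape descriptors in physical units
#'
#' For each focus: area (pixel count times `pixel_size^2`), centroid, and
#' the axes of the ellipse sharing the pixel set's second central moments.
#' With eigenvalues `l1 >= l2` of the (population) covariance of pixel
#' centres, the axis lengths are `4 * sqrt(l)` pixels — the convention used
#' by standard region-properties tools — and eccentricity is
#' `sqrt(1 - l2/l1)`, 0 for a circle. A single-pixel focus is degenerate:
#' both axes are set to one pixel and eccentricity to 0; a collinear pixel
#' set gets a one-pixel minor axis. Degenerate fits are flagged.
#'
#' @param foci a [foci_set()].
#' @return data.frame with one row per focus: `focus_id`, `channel`,
#'   `n_pixels`, `area_um2`, `centroid_row`, `centroid_col`,
#'   `major_axis_um`, `minor_axis_um`, `eccentricity`, `degenerate`.
#' @export
shape_descriptors <- function(foci) {
  stopifnot(inherits(foci, "foci_set"))
  px <- foci$pixel_size
  nr <- foci$dim[1]
  n <- length(foci)
  out <- data.frame(focus_id = foci$ids,
                    channel = rep(foci$channel, n),
                    n_pixels = integer(n), area_um2 = numeric(n),
                    centroid_row = numeric(n), centroid_col = numeric(n),
                    major_axis_um = numeric(n), minor_axis_um = numeric(n),
                    eccentricity = numeric(n), degenerate = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    idx <- foci$pixels[[i]]
    if (length(idx) == 0L) stop("focus with empty pixel set")
    rc <- idx_to_rc(idx, nr)
    m <- length(idx)
    out$n_pixels[i] <- m
    out$area_um2[i] <- m * px^2
    mr <- mean(rc[, 1]); mc <- mean(rc[, 2])
    out$centroid_row[i] <- mr
    out$centroid_col[i] <- mc
    if (m == 1L) {
      out$major_axis_um[i] <- px
      out$minor_axis_um[i] <- px
      out$eccentricity[i] <- 0
      out$degenerate[i] <- TRUE
      next
    }
    # population second central moments of pixel centres
    crr <- mean((rc[, 1] - mr)^2)
    ccc <- mean((rc[, 2] - mc)^2)
    crc <- mean((rc[, 1] - mr) * (rc[, 2] - mc))
    tr <- crr + ccc
    disc <- sqrt(max((crr - ccc)^2 / 4 + crc^2, 0))
    l1 <- tr / 2 + disc
    l2 <- max(tr / 2 - disc, 0)
    major <- 4 * sqrt(l1) * px
    if (l2 <= .Machine$double.eps * tr) {
      # collinear pixels: moment ellipse collapses; fall back to pixel width
      out$major_axis_um[i] <- max(major, px)
      out$minor_axis_um[i] <- px
      out$eccentricity[i] <- sqrt(max(1 - (px / max(major, px))^2, 0))
      out$degenerate[i] <- TRUE
    } else {
      minor <- 4 * sqrt(l2) * px
      out$major_axis_um[i] <- major
      out$minor_axis_um[i] <- minor
      out$eccentricity[i] <- sqrt(max(1 - l2 / l1, 0))
      out$degenerate[i] <- FALSE
    }
  }
  out
}

#' Pixel-exact overlap of each query focus with a reference channel
#'
#' For every query focus, the intersection with the union of all reference
#' foci is counted pixel by pixel; the overlap percentage uses the query
#' focus's own area as denominator (asymmetric by design: "what fraction of
#' this granule is covered by the reference structure"). A query focus
#' straddling two reference foci accumulates both.
#'
#' @param query a [foci_set()] to be classified.
#' @param reference a [foci_set()] on the same frame geometry; may be empty
#'   (all overlaps are then 0).
#' @param complete_tol tolerance in percentage points below 100 that still
#'   counts as complete overlap (default 1: a strict 100% cutoff is fragile
#'   to single rasterization pixels).
#' @return data.frame of overlap records: `focus_id`, `query_channel`,
#'   `reference_channel`, `n_pixels`, `area_um2`, `overlap_area_um2`,
#'   `overlap_pct`, `category` (factor: none < partial < complete).
#' @export
compute_overlap <- function(query, reference, complete_tol = 1) {
  stopifnot(inherits(query, "foci_set"), inherits(reference, "foci_set"))
  if (!identical(query$dim, reference$dim)) {
    stop("query and reference foci must share frame geometry")
  }
  px <- query$pixel_size
  refmask <- logical(prod(query$dim))
  if (length(reference)) refmask[unlist(reference$pixels)] <- TRUE
  n <- length(query)
  sz <- vapply(query$pixels, length, integer(1))
  ov <- vapply(query$pixels, function(idx) sum(refmask[idx]), integer(1))
  pct <- if (n) 100 * ov / sz else numeric(0)
  data.frame(focus_id = query$ids,
             query_channel = rep(query$channel, n),
             reference_channel = rep(reference$channel, n),
             n_pixels = sz,
             area_um2 = sz * px^2,
             overlap_area_um2 = ov * px^2,
             overlap_pct = pct,
             category = categorize_overlap(pct, complete_tol),
             stringsAsFactors = FALSE)
}

#' Three-way overlap categorisation
#'
#' `none` for exactly zero overlap, `complete` for an overlap percentage at
#' or above `100 - complete_tol`, `partial` for anything strictly between.
#' Any nonzero intersection, however small, counts as partial.
#'
#' @param overlap_pct numeric vector of overlap percentages in `[0, 100]`.
#' @param complete_tol completeness tolerance in percentage points
#'   (default 1).
#' @return factor with levels `none`, `partial`, `complete`.
#' @export
categorize_overlap <- function(overlap_pct, complete_tol = 1) {
  stopifnot(all(overlap_pct >= 0 & overlap_pct <= 100))
  out <- ifelse(overlap_pct <= 0, "none",
                ifelse(overlap_pct >= 100 - complete_tol, "complete",
                       "partial"))
  factor(out, levels = c("none", "partial", "complete"))
}

#' Summarise overlap categories as percentages of foci counted
#'
#' @param records data.frame from [compute_overlap()].
#' @return one-row data.frame: `reference_channel`, `n_foci`, `pct_none`,
#'   `pct_partial`, `pct_complete` (summing to 100).
#' @export
summarize_overlap <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("overlap percentages are undefined for an empty record set")
  }
  cat_f <- factor(records$category, levels = c("none", "partial", "complete"))
  counts <- table(cat_f)
  n <- nrow(records)
  data.frame(reference_channel = records$reference_channel[1],
             n_foci = n,
             pct_none = 100 * as.numeric(counts["none"]) / n,
             pct_partial = 100 * as.numeric(counts["partial"]) / n,
             pct_complete = 100 * as.numeric(counts["complete"]) / n,
             stringsAsFactors = FALSE)
}

#' Focus areas stratified by overlap status
#'
#' Splits foci into a zero-overlap group and an any-overlap (partial or
#' complete) group and reports the area distribution of each, for asking
#' whether overlapping granules are systematically larger.
#'
#' @param records data.frame from [compute_overlap()].
#' @param shapes data.frame from [shape_descriptors()] for the same query
#'   foci (matched on `focus_id`).
#' @return data.frame with one row per group: `overlap_class`
#'   (`no_overlap` / `any_overlap`), `n`, `mean_area_um2`, `sd_area_um2`
#'   (NA for n < 2), and a list column `areas_um2`.
#' @export
size_stratified_overlap <- function(records, shapes) {
  stopifnot(is.data.frame(records), is.data.frame(shapes))
  m <- match(records$focus_id, shapes$focus_id)
  if (anyNA(m)) stop("records and shapes must be keyed consistently")
  areas <- shapes$area_um2[m]
  cls <- ifelse(records$overlap_pct > 0, "any_overlap", "no_overlap")
  out <- data.frame(overlap_class = c("no_overlap", "any_overlap"),
                    stringsAsFactors = FALSE)
  grp <- lapply(out$overlap_class, function(g) areas[cls == g])
  out$n <- vapply(grp, length, integer(1))
  out$mean_area_um2 <- vapply(grp, function(a)
    if (length(a)) mean(a) else NA_real_, numeric(1))
  out$sd_area_um2 <- vapply(grp, function(a)
    if (length(a) > 1) stats::sd(a) else NA_real_, numeric(1))
  out$areas_um2 <- I(grp)
  out
}
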