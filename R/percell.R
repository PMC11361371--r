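#' Foci density per square micrometre of mitochondria
#'
#' @param foci a [foci_set()] (already containment-filtered as desired).
#' @param mito a [binary_mask()] of the mitochondrial network.
#' @return foci per μm² of mitochondrial area.
#' @export
foci_density <- function(foci, mito) {
  stopifnot(inherits(foci, "foci_set"), inherits(mito, "binary_mask"))
  area <- mask_area_um2(mito)
  if (area <= 0) stop("foci density is undefined on an empty mitochondrial mask")
  length(foci) / area
}

cell_logical <- function(cells, cell_id, compartment = c("cell", "nucleus",
                                                         "cytoplasm")) {
  compartment <- match.arg(compartment)
  switch(compartment,
         cell = cells$cells == cell_id,
         nucleus = cells$nuclei == cell_id,
         cytoplasm = cells$cells == cell_id & cells$nuclei != cell_id)
}

#' Mean channel intensity over a cell's mitochondrial network
#'
#' Arithmetic mean of the channel over the pixels of `mito` intersected
#' with the cell's region. Background outside the mask never contributes.
#'
#' @param channel numeric matrix.
#' @param mito a [binary_mask()].
#' @param cells a `cell_set` from [build_cell_regions()].
#' @param cell_id which cell.
#' @return mean intensity, or `NA` (with a warning) when the cell's
#'   mitochondrial submask is empty.
#' @export
mean_mito_intensity <- function(channel, mito, cells, cell_id) {
  stopifnot(is.matrix(channel), inherits(mito, "binary_mask"),
            inherits(cells, "cell_set"))
  sub <- mito$raster & cell_logical(cells, cell_id, "cell")
  if (!any(sub)) {
    warning(sprintf("cell %s has an empty mitochondrial submask", cell_id))
    return(NA_real_)
  }
  mean(channel[sub])
}

#' Integrated channel intensity over a cell
#'
#' Sum of pixel intensities over the cell's cytoplasm (whole-cell region
#' minus nucleus by default; set `include_nucleus = TRUE` for the whole
#' cell). Additive over disjoint partitions of the region.
#'
#' @param channel numeric matrix.
#' @param cells a `cell_set`.
#' @param cell_id which cell.
#' @param include_nucleus include nuclear pixels in the sum.
#' @return summed intensity (intensity · pixels).
#' @export
integrated_intensity <- function(channel, cells, cell_id,
                                 include_nucleus = FALSE) {
  stopifnot(is.matrix(channel), inherits(cells, "cell_set"))
  reg <- cell_logical(cells, cell_id,
                      if (include_nucleus) "cell" else "cytoplasm")
  sum(channel[reg])
}

#' Cell-cycle phase thresholds
#'
#' Positivity cutoffs for the EdU and cyclin-A markers and a minimum
#' nuclear DAPI level. Defaults of `NULL` mean "derive by Otsu from the
#' per-cell marker distribution" in [classify_phases()].
#'
#' @param edu_pos intensity above which a nucleus is EdU-positive.
#' @param cyclinA_pos intensity above which a cell is cyclin-A-positive.
#' @param dapi_min minimum mean nuclear DAPI for a usable nucleus.
#' @return object of class `phase_thresholds`.
#' @export
phase_thresholds <- function(edu_pos, cyclinA_pos, dapi_min = 0) {
  stopifnot(edu_pos >= 0, cyclinA_pos >= 0, dapi_min >= 0)
  structure(list(edu_pos = edu_pos, cyclinA_pos = cyclinA_pos,
                 dapi_min = dapi_min),
            class = "phase_thresholds")
}

# Exhaustive 1D Otsu on a numeric vector: threshold (midpoint between
# consecutive order statistics) maximising between-class variance.
otsu_cutoff <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || x[1] == x[n]) return(NA_real_)
  best <- -Inf; cut <- NA_real_
  csum <- cumsum(x); tot <- csum[n]
  for (k in seq_len(n - 1L)) {
    if (x[k] == x[k + 1L]) next
    w1 <- k / n
    m1 <- csum[k] / k
    m2 <- (tot - csum[k]) / (n - k)
    v <- w1 * (1 - w1) * (m1 - m2)^2
    if (v > best) {
      best <- v
      cut <- (x[k] + x[k + 1L]) / 2
    }
  }
  cut
}

#' Classify cell-cycle phase of one cell from marker intensities
#'
#' Marker-to-phase mapping: EdU marks active DNA replication (S), cyclin-A
#' accumulates in S and G2, DAPI marks any nucleus. Decision precedence is
#' S then G2 then G1: an EdU-positive cell is S regardless of cyclin-A
#' (cyclin-A is expected positive in S too); an EdU-negative,
#' cyclin-A-positive cell is G2; an EdU-negative, cyclin-A-negative cell
#' with detectable nuclear DAPI is G1; otherwise unassigned.
#'
#' EdU and DAPI are measured as mean nuclear intensity; cyclin-A over the
#' whole cell by default (`cyclinA_compartment = "cell"`) or restricted to
#' the nucleus.
#'
#' @param cells a `cell_set`.
#' @param cell_id which cell.
#' @param dapi,edu,cyclinA numeric channel matrices.
#' @param thresholds a [phase_thresholds()].
#' @param cyclinA_compartment `"cell"` or `"nucleus"`.
#' @return one of `"G1"`, `"S"`, `"G2"`, `"unassigned"`.
#' @export
classify_phase <- function(cells, cell_id, dapi, edu, cyclinA, thresholds,
                           cyclinA_compartment = c("cell", "nucleus")) {
  stopifnot(inherits(cells, "cell_set"), inherits(thresholds, "phase_thresholds"))
  cyclinA_compartment <- match.arg(cyclinA_compartment)
  nuc <- cell_logical(cells, cell_id, "nucleus")
  if (!any(nuc)) return("unassigned")
  edu_mean <- mean(edu[nuc])
  cyc_reg <- cell_logical(cells, cell_id, cyclinA_compartment)
  cyc_mean <- mean(cyclinA[cyc_reg])
  dapi_mean <- mean(dapi[nuc])
  if (edu_mean >= thresholds$edu_pos) return("S")
  if (cyc_mean >= thresholds$cyclinA_pos) return("G2")
  if (dapi_mean >= thresholds$dapi_min) return("G1")
  "unassigned"
}

#' Classify phases for all cells, deriving thresholds if needed
#'
#' When `thresholds` is `NULL` the EdU and cyclin-A cutoffs are derived by
#' 1D Otsu on the per-cell marker means (the algorithmic stand-in for
#' visual gating) and the DAPI floor is 0.
#'
#' @inheritParams classify_phase
#' @param thresholds a [phase_thresholds()] or `NULL`.
#' @return the `cell_set` with its table's `phase` column filled; the
#'   thresholds used are attached as attribute `thresholds`.
#' @export
classify_phases <- function(cells, dapi, edu, cyclinA, thresholds = NULL,
                            cyclinA_compartment = c("cell", "nucleus")) {
  cyclinA_compartment <- match.arg(cyclinA_compartment)
  ids <- cells$table$cell_id
  if (is.null(thresholds)) {
    edu_means <- vapply(ids, function(i) {
      nuc <- cell_logical(cells, i, "nucleus")
      if (any(nuc)) mean(edu[nuc]) else NA_real_
    }, numeric(1))
    cyc_means <- vapply(ids, function(i) {
      reg <- cell_logical(cells, i, cyclinA_compartment)
      if (any(reg)) mean(cyclinA[reg]) else NA_real_
    }, numeric(1))
    thresholds <- phase_thresholds(
      edu_pos = otsu_cutoff(edu_means),
      cyclinA_pos = otsu_cutoff(cyc_means),
      dapi_min = 0)
  }
  cells$table$phase <- vapply(ids, function(i)
    classify_phase(cells, i, dapi, edu, cyclinA, thresholds,
                   cyclinA_compartment), character(1))
  attr(cells, "thresholds") <- thresholds
  cells
}

#' Assign foci to cells by centroid
#'
#' A focus belongs to the cell whose region contains its centroid pixel;
#' foci outside all cells get cell id 0 (dropped from per-cell counts and
#' reported in the QC log).
#'
#' @param foci a [foci_set()].
#' @param cells a `cell_set`.
#' @return integer vector of cell ids, one per focus.
#' @export
assign_foci_to_cells <- function(foci, cells) {
  stopifnot(inherits(foci, "foci_set"), inherits(cells, "cell_set"))
  nr <- foci$dim[1]
  vapply(foci$pixels, function(idx) {
    rc <- idx_to_rc(idx, nr)
    r <- pmin(pmax(as.integer(round(mean(rc[, 1]))), 1L), nr)
    cc <- pmin(pmax(as.integer(round(mean(rc[, 2]))), 1L), foci$dim[2])
    cells$cells[r, cc]
  }, integer(1))
}

#' Per-cell quantification table
#'
#' Combines per-cell foci densities (per μm² of that cell's mitochondrial
#' network), mean mitochondrial intensity and integrated cytoplasmic
#' intensity of each measured channel, areas, and the phase call.
#'
#' @param cells a `cell_set` (phases filled via [classify_phases()] if
#'   wanted beforehand).
#' @param mito a [binary_mask()] of the mitochondrial network.
#' @param foci_by_channel named list of [foci_set()] objects to count per
#'   cell (may be empty).
#' @param intensity_channels named list of numeric matrices to measure per
#'   cell (may be empty).
#' @return data.frame, one row per cell: ids, phase, areas
#'   (`cytoplasm_area_um2`, `mito_area_um2`), per-channel
#'   `n_foci_<ch>` and `density_<ch>_per_um2`, per-channel
#'   `mean_mito_<ch>` and `integrated_<ch>`. Attribute `n_foci_unassigned`
#'   counts foci whose centroid fell outside every cell.
#' @export
cell_metrics <- function(cells, mito, foci_by_channel = list(),
                         intensity_channels = list()) {
  stopifnot(inherits(cells, "cell_set"), inherits(mito, "binary_mask"))
  ids <- cells$table$cell_id
  px <- cells$pixel_size
  out <- data.frame(cell_id = ids,
                    phase = cells$table$phase,
                    cytoplasm_area_um2 = cells$table$cytoplasm_area_um2,
                    stringsAsFactors = FALSE)
  out$mito_area_um2 <- vapply(ids, function(i)
    sum(mito$raster & cells$cells == i) * px^2, numeric(1))
  unassigned <- 0L
  for (ch in names(foci_by_channel)) {
    fk <- foci_by_channel[[ch]]
    owner <- assign_foci_to_cells(fk, cells)
    unassigned <- unassigned + sum(owner == 0L)
    counts <- vapply(ids, function(i) sum(owner == i), integer(1))
    out[[paste0("n_foci_", ch)]] <- counts
    out[[paste0("density_", ch, "_per_um2")]] <-
      ifelse(out$mito_area_um2 > 0, counts / out$mito_area_um2, NA_real_)
  }
  for (ch in names(intensity_channels)) {
    m <- intensity_channels[[ch]]
    out[[paste0("mean_mito_", ch)]] <- vapply(ids, function(i) {
      sub <- mito$raster & cells$cells == i
      if (any(sub)) mean(m[sub]) else NA_real_
    }, numeric(1))
    out[[paste0("integrated_", ch)]] <- vapply(ids, function(i)
      integrated_intensity(m, cells, i), numeric(1))
  }
  attr(out, "n_foci_unassigned") <- unassigned
  out
}

#' Group summaries (n, mean, sample SD) of per-cell metrics
#'
#' Descriptive summaries per group for every numeric metric column; sample
#' SD uses the n−1 denominator and is reported missing for groups of one.
#'
#' @param metrics data.frame from [cell_metrics()] (or any per-cell table).
#' @param group_by character vector of grouping column names present in
#'   `metrics` (e.g. `"phase"`, `"condition"`).
#' @return long data.frame: grouping columns, `metric`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(metrics, group_by = "phase") {
  stopifnot(is.data.frame(metrics), all(group_by %in% names(metrics)))
  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                      c(group_by, "cell_id"))
  key <- interaction(metrics[group_by], drop = TRUE, lex.order = TRUE)
  rows <- list()
  for (g in levels(key)) {
    sub <- metrics[key == g, , drop = FALSE]
    for (mcol in num_cols) {
      v <- sub[[mcol]]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- cbind(
        sub[1, group_by, drop = FALSE],
        data.frame(metric = mcol, n = n, mean = mean(v),
                   sd = if (n > 1L) stats::sd(v) else NA_real_,
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(rows)) {
    out <- metrics[0, group_by, drop = FALSE]
    out$metric <- character(); out$n <- integer()
    out$mean <- numeric(); out$sd <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
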