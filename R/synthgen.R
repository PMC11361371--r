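#' Parameters for the synthetic frame generator
#'
#' Defines the study conditions emulated by [generate_frame()]: a tubular
#' mitochondrial network, punctate foci channels with controlled mean area
#' and planted overlap composition against a reference channel, and
#' DAPI/EdU/cyclin-A marker channels with separable positive/negative
#' per-cell populations. Defaults describe the super-resolution foci
#' regime: 0.02 μm/px sampling, granule mean areas of 0.019 μm² (query,
#' mt-dsRNA-like) and 0.017 μm² (reference, BrU-like), and the measured
#' overlap composition of roughly 3% complete, 65% partial, 32% none.
#'
#' @param frame_shape frame size in pixels, (rows, cols).
#' @param pixel_size μm per pixel.
#' @param n_cells number of cells; 0 gives an acellular foci-only frame
#'   (marker channels are rendered empty).
#' @param network_density target fraction of the frame covered by
#'   mitochondrial tubes.
#' @param tube_width tube diameter in μm (must be at least 2 px).
#' @param foci named list, one entry per foci channel, each a list with
#'   `n_foci`, `mean_area` (μm²), `area_cv`, `intensity`.
#' @param query_channel,reference_channel names within `foci`; planted
#'   overlap categories are for query foci against the reference channel.
#' @param overlap_composition fractions `c(complete=, partial=, none=)`
#'   summing to 1; per-category counts use largest-remainder rounding.
#' @param partial_overlap_range (lo, hi) target intersection fraction for
#'   partially overlapping foci, strictly inside (0, 1).
#' @param phase_mix fractions `c(G1=, S=, G2=)` summing to 1.
#' @param marker_levels list with `edu = c(pos=, neg=)`,
#'   `cyclinA = c(pos=, neg=)`, `dapi` (scalar level) and `sd`
#'   (cell-to-cell SD of marker levels; variation is truncated at 2.5 SD,
#'   as for gated antibody-stain populations with no extreme outliers).
#' @param noise `c(gaussian_sd=, poisson_scale=)`: Gaussian read noise SD
#'   and Poisson shot-noise scaling (0 disables either). Defaults give a
#'   peak SNR near 10 at the default foci intensity.
#' @param psf_sigma Gaussian PSF sigma in μm applied before noise.
#' @param mito_intensity plateau intensity of the network channel.
#' @param dapi_level nuclear stain plateau.
#' @param nucleus_radius,cell_radius cell geometry in μm.
#' @param complete_margin maximum fraction of its host reference focus a
#'   completely-overlapping query focus may occupy (area ratio); smaller
#'   leaves a wider containment margin.
#' @param seed integer seed; all generator randomness derives from it.
#' @return validated list of class `generator_params`.
#' @export
generator_params <- function(frame_shape = c(512L, 512L),
                             pixel_size = 0.02,
                             n_cells = 0L,
                             network_density = 0.15,
                             tube_width = 0.30,
                             foci = list(
                               dsRNA = list(n_foci = 100L, mean_area = 0.019,
                                            area_cv = 0.3, intensity = 150),
                               BrU = list(n_foci = 100L, mean_area = 0.017,
                                          area_cv = 0.3, intensity = 150)),
                             query_channel = "dsRNA",
                             reference_channel = "BrU",
                             overlap_composition = c(complete = 0.03,
                                                     partial = 0.65,
                                                     none = 0.32),
                             partial_overlap_range = c(0.15, 0.85),
                             phase_mix = c(G1 = 0.5, S = 0.3, G2 = 0.2),
                             marker_levels = list(edu = c(pos = 120, neg = 20),
                                                  cyclinA = c(pos = 120,
                                                              neg = 20),
                                                  dapi = 100, sd = 10),
                             noise = c(gaussian_sd = 10, poisson_scale = 1),
                             psf_sigma = 0.03,
                             mito_intensity = 120,
                             dapi_level = 100,
                             nucleus_radius = 3,
                             cell_radius = 7.5,
                             complete_margin = 0.5,
                             seed = 1L) {
  p <- list(frame_shape = as.integer(frame_shape), pixel_size = pixel_size,
            n_cells = as.integer(n_cells),
            network_density = network_density, tube_width = tube_width,
            foci = foci, query_channel = query_channel,
            reference_channel = reference_channel,
            overlap_composition = overlap_composition,
            partial_overlap_range = partial_overlap_range,
            phase_mix = phase_mix, marker_levels = marker_levels,
            noise = noise, psf_sigma = psf_sigma,
            mito_intensity = mito_intensity, dapi_level = dapi_level,
            nucleus_radius = nucleus_radius, cell_radius = cell_radius,
            complete_margin = complete_margin, seed = as.integer(seed))
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  if (length(p$frame_shape) != 2L || any(p$frame_shape < 16L)) {
    stop("'frame_shape' must be two pixel counts >= 16")
  }
  if (p$pixel_size <= 0) stop("'pixel_size' must be positive")
  comp <- p$overlap_composition
  if (!all(c("complete", "partial", "none") %in% names(comp)) ||
      abs(sum(comp) - 1) > 1e-9 || any(comp < 0)) {
    stop("'overlap_composition' must have complete/partial/none summing to 1")
  }
  mix <- p$phase_mix
  if (!all(c("G1", "S", "G2") %in% names(mix)) ||
      abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
    stop("'phase_mix' must have G1/S/G2 fractions summing to 1")
  }
  rng <- p$partial_overlap_range
  if (length(rng) != 2L || rng[1] <= 0 || rng[2] >= 1 || rng[1] >= rng[2]) {
    stop("'partial_overlap_range' must be strictly inside (0, 1)")
  }
  for (ch in names(p$foci)) {
    sp <- p$foci[[ch]]
    if (sp$n_foci < 0 || sp$mean_area <= 0 || sp$area_cv < 0 ||
        sp$intensity <= 0) {
      stop(sprintf("invalid foci spec for channel '%s'", ch))
    }
  }
  if (!p$query_channel %in% names(p$foci) ||
      !p$reference_channel %in% names(p$foci)) {
    stop("query and reference channels must appear in 'foci'")
  }
  if (p$complete_margin <= 0 || p$complete_margin >= 1) {
    stop("'complete_margin' must be in (0, 1)")
  }
  if (p$network_density < 0 || p$network_density > 0.9) {
    stop("'network_density' must be in [0, 0.9]")
  }
  invisible(p)
}

#' Preset parameters for the per-cell (confocal-like) regime
#'
#' Coarser sampling (0.1 μm/px), wider tubes, several whole cells per
#' frame, and larger diffraction-limited foci, for testing per-cell
#' density, intensity and phase-calling machinery.
#'
#' @param n_cells number of cells.
#' @param frame_shape frame size in pixels.
#' @param n_foci foci per channel.
#' @param ... further overrides passed to [generator_params()].
#' @return a `generator_params` object.
#' @export
cell_frame_params <- function(n_cells = 12L, frame_shape = c(1024L, 1024L),
                              n_foci = 60L, ...) {
  defaults <- list(
    frame_shape = frame_shape, pixel_size = 0.1, n_cells = n_cells,
    network_density = 0.12, tube_width = 0.8,
    foci = list(
      dsRNA = list(n_foci = n_foci, mean_area = 0.15, area_cv = 0.25,
                   intensity = 150),
      BrU = list(n_foci = n_foci, mean_area = 0.13, area_cv = 0.25,
                 intensity = 150)),
    psf_sigma = 0.1)
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_params, args)
}

#' Largest-remainder apportionment of counts
#'
#' Deterministically rounds `fracs * n` to integers summing to `n`: floor
#' everything, then give the leftover units to the largest fractional
#' remainders (ties broken by position).
#'
#' @param fracs non-negative fractions (need not be named).
#' @param n total count.
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(fracs, n) {
  stopifnot(all(fracs >= 0), n >= 0)
  raw <- fracs / sum(fracs) * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  out <- as.integer(base)
  if (left > 0L) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    out[give] <- out[give] + 1L
  }
  names(out) <- names(fracs)
  out
}

placement_error <- function(what) {
  stop(errorCondition(
    paste0("infeasible placement: ", what,
           " (network too sparse or frame too crowded; ",
           "lower n_foci/n_cells or raise network_density)"),
    class = c("granulemap_placement_error", "error", "condition")))
}

# reflect continuous coordinates into [1, n]
reflect_coord <- function(v, n) {
  if (n == 1L) return(rep(1, length(v)))
  period <- 2 * (n - 1)
  w <- (v - 1) %% period
  1 + pmin(w, period - w)
}

#' Render a tubular mitochondrial-network mask
#'
#' Union of persistent random-walk tubes dilated to the requested width,
#' grown until the covered fraction reaches `network_density` (walk length
#' is scaled so the final coverage overshoots by well under 20%). Fixed
#' seed gives an identical mask.
#'
#' @param params a [generator_params()].
#' @return a [binary_mask()].
#' @export
render_network <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  withr::with_seed(params$seed, .render_network(params))
}

.render_network <- function(params) {
  d <- params$frame_shape
  px <- params$pixel_size
  dens <- params$network_density
  if (dens == 0) return(binary_mask(matrix(FALSE, d[1], d[2]), px))
  w_px <- params$tube_width / px
  if (w_px < 1) stop("tube_width below one pixel: unresolvable structure")
  if (w_px < 2) stop("tube_width must be at least 2 pixels at this pixel size")
  brush_size <- max(3L, 2L * (as.integer(w_px) %/% 2L) + 1L)
  brush <- EBImage::makeBrush(brush_size, "disc")
  npx <- prod(d)
  skel <- matrix(FALSE, d[1], d[2])
  # per-walk coverage increment ~8% of target so the stopping rule cannot
  # overshoot the +/-20% coverage contract
  len <- max(30L, as.integer(round(0.08 * dens * npx / brush_size)))
  dil <- skel
  for (walk in seq_len(500L)) {
    r0 <- stats::runif(1, 1, d[1])
    c0 <- stats::runif(1, 1, d[2])
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(len - 1L, 0, 0.25)))
    rr <- reflect_coord(r0 + cumsum(sin(theta)), d[1])
    cc <- reflect_coord(c0 + cumsum(cos(theta)), d[2])
    skel[cbind(as.integer(round(rr)), as.integer(round(cc)))] <- TRUE
    dil <- as.matrix(EBImage::dilate(skel + 0, brush)) > 0
    if (mean(dil) >= dens) break
  }
  binary_mask(dil, px)
}

# Exactly n_px pixels closest to a (possibly fractional) centre: a rasterized
# disk with pixel-exact area. Returns linear indices, or NULL if the frame
# border clips the disk.
disk_exact <- function(cr, cc, n_px, d) {
  r_bb <- ceiling(sqrt(n_px / pi)) + 3L
  rows <- max(1L, floor(cr) - r_bb):min(d[1], ceiling(cr) + r_bb)
  cols <- max(1L, floor(cc) - r_bb):min(d[2], ceiling(cc) + r_bb)
  if (length(rows) * length(cols) < n_px) return(NULL)
  d2 <- outer((rows - cr)^2, (cols - cc)^2, "+")
  ord <- order(d2)[seq_len(n_px)]
  nr_bb <- length(rows)
  ri <- rows[((ord - 1L) %% nr_bb) + 1L]
  ci <- cols[((ord - 1L) %/% nr_bb) + 1L]
  # reject if the chosen set was clipped by the frame border (it would no
  # longer be disk-like): the furthest chosen pixel must sit inside the box
  if (max(sqrt(d2[ord])) > min(r_bb - 1L, Inf)) return(NULL)
  rc_to_idx(ri, ci, d[1])
}

# truncated normal (+/- lim SD), vectorised
rtrunc_norm <- function(n, mean, sd, lim = 2.5) {
  if (sd <= 0) return(rep(mean, n))
  mean + sd * stats::qnorm(stats::runif(n, stats::pnorm(-lim),
                                        stats::pnorm(lim)))
}

sample_areas_px <- function(n, mean_area, cv, px, min_px = 5L) {
  if (n == 0L) return(integer(0))
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mean_area) - sdlog^2 / 2
    a <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    a <- rep(mean_area, n)
  }
  pmax(as.integer(round(a / px^2)), min_px)
}

#' Generate a synthetic multi-channel frame with ground truth
#'
#' Renders, in order: the tubular network; cells (nuclei and cell bodies,
#' phases apportioned by largest remainder); reference foci (pixel-exact
#' disk areas placed inside the network with enforced separation); query
#' foci per overlap category — `complete` foci carved as exact pixel
#' subsets of a dedicated larger reference focus, `partial` foci shifted
#' off a reference focus until the pixel-exact intersection fraction falls
#' in `partial_overlap_range`, `none` foci kept clear of a safety margin
#' around every reference focus; then marker channels, PSF blur, and
#' Poisson+Gaussian noise (final intensities are rounded to integer
#' detector units). Truth tables record the planted pixel sets, categories
#' and phases before blur and noise.
#'
#' @param params a [generator_params()].
#' @return list with elements `frame` (an [image_frame()] with channels
#'   `mito`, the foci channels, `DAPI`, `EdU`, `cyclinA`) and `truth`
#'   (class `ground_truth`: `foci` table, `cells` table, `network` mask,
#'   `nuclei_lab`/`cell_lab` matrices, `params`).
#' @export
generate_frame <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  withr::with_seed(params$seed, .generate_frame(params))
}

.generate_frame <- function(p) {
  d <- p$frame_shape
  px <- p$pixel_size
  npx <- prod(d)
  nr <- d[1]
  net <- .render_network(p)

  # ---- cells -------------------------------------------------------------
  nuc_lab <- matrix(0L, d[1], d[2])
  cell_lab <- matrix(0L, d[1], d[2])
  cells_tab <- data.frame(cell_id = integer(), phase = character(),
                          center_row = numeric(), center_col = numeric(),
                          edu_level = numeric(), cyclinA_level = numeric(),
                          stringsAsFactors = FALSE)
  if (p$n_cells > 0L) {
    cr_px <- p$cell_radius / px
    nu_px <- p$nucleus_radius / px
    if (2 * cr_px + 4 > min(d)) placement_error("cells larger than the frame")
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(centers) < p$n_cells) {
      attempts <- attempts + 1L
      if (attempts > 2000L * p$n_cells) placement_error("cell placement")
      cand <- c(stats::runif(1, cr_px + 2, d[1] - cr_px - 1),
                stats::runif(1, cr_px + 2, d[2] - cr_px - 1))
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - cand[1])^2 +
                   (centers[, 2] - cand[2])^2) >= 2.1 * cr_px)) {
        centers <- rbind(centers, cand)
      }
    }
    phase_counts <- largest_remainder(p$phase_mix, p$n_cells)
    phases <- sample(rep(names(phase_counts), phase_counts))
    ml <- p$marker_levels
    edu_levels <- rtrunc_norm(p$n_cells,
                              ifelse(phases == "S", ml$edu["pos"],
                                     ml$edu["neg"]), ml$sd)
    cyc_levels <- rtrunc_norm(p$n_cells,
                              ifelse(phases %in% c("S", "G2"),
                                     ml$cyclinA["pos"], ml$cyclinA["neg"]),
                              ml$sd)
    edu_levels <- pmax(edu_levels, 0)
    cyc_levels <- pmax(cyc_levels, 0)
    for (i in seq_len(p$n_cells)) {
      cd <- disk_exact(centers[i, 1], centers[i, 2],
                       as.integer(round(pi * cr_px^2)), d)
      nd <- disk_exact(centers[i, 1], centers[i, 2],
                       as.integer(round(pi * nu_px^2)), d)
      if (is.null(cd) || is.null(nd)) placement_error("cell rendering")
      cell_lab[cd] <- i
      nuc_lab[nd] <- i
    }
    cells_tab <- data.frame(cell_id = seq_len(p$n_cells), phase = phases,
                            center_row = centers[, 1],
                            center_col = centers[, 2],
                            edu_level = edu_levels,
                            cyclinA_level = cyc_levels,
                            stringsAsFactors = FALSE)
    net$raster <- net$raster & cell_lab > 0L
  }

  # ---- foci placement ----------------------------------------------------
  sep_px <- max(4L, as.integer(ceiling(2.5 * p$psf_sigma / px)))
  gap_px <- sep_px
  dist_net <- if (any(net$raster)) {
    as.matrix(EBImage::distmap(net$raster))
  } else {
    matrix(0, d[1], d[2])
  }
  qch <- p$query_channel
  rch <- p$reference_channel
  qspec <- p$foci[[qch]]
  rspec <- p$foci[[rch]]
  counts <- largest_remainder(
    p$overlap_composition[c("complete", "partial", "none")], qspec$n_foci)
  q_areas <- list(
    complete = sample_areas_px(counts["complete"], qspec$mean_area,
                               qspec$area_cv, px),
    partial = sample_areas_px(counts["partial"], qspec$mean_area,
                              qspec$area_cv, px),
    none = sample_areas_px(counts["none"], qspec$mean_area, qspec$area_cv, px))
  r_areas <- sample_areas_px(rspec$n_foci, rspec$mean_area, rspec$area_cv, px)
  n_host <- counts["complete"]
  if (n_host > rspec$n_foci) {
    placement_error("more complete-overlap foci than reference foci")
  }
  if (n_host > 0L) {
    # hosts must leave a containment margin around their carved query focus
    need <- as.integer(ceiling(q_areas$complete / p$complete_margin))
    r_areas[seq_len(n_host)] <- pmax(r_areas[seq_len(n_host)], need)
  }

  occ_test <- function(occ, cr, cc, n_px) {
    t_px <- as.integer(ceiling(pi * (sqrt(n_px / pi) + sep_px)^2))
    t_idx <- disk_exact(cr, cc, t_px, d)
    is.null(t_idx) || any(occ[t_idx])
  }

  place_free <- function(n_px, occ, forbid = NULL, inside = net$raster) {
    r_eq <- sqrt(n_px / pi)
    elig <- which(dist_net > r_eq + 0.5 & inside)
    if (!length(elig)) return(NULL)
    for (a in seq_len(200L)) {
      ctr <- elig[sample.int(length(elig), 1L)]
      rc <- idx_to_rc(ctr, nr)
      if (occ_test(occ, rc[1], rc[2], n_px)) next
      idx <- disk_exact(rc[1], rc[2], n_px, d)
      if (is.null(idx) || !all(net$raster[idx])) next
      if (!is.null(forbid) && any(forbid[idx])) next
      return(idx)
    }
    NULL
  }

  occ_ref <- logical(npx)
  ref_pixels <- vector("list", rspec$n_foci)
  for (i in seq_len(rspec$n_foci)) {
    idx <- place_free(r_areas[i], occ_ref)
    if (is.null(idx)) placement_error("reference foci")
    ref_pixels[[i]] <- idx
    occ_ref[idx] <- TRUE
  }
  refunion <- occ_ref

  ref_forbid <- logical(npx)
  if (any(refunion)) {
    rm_mat <- matrix(as.numeric(refunion), d[1], d[2])
    ref_forbid <- as.vector(as.matrix(
      EBImage::dilate(rm_mat, EBImage::makeBrush(2L * gap_px + 1L, "disc"))) > 0)
  }

  occ_q <- logical(npx)
  q_rows <- list()
  add_q <- function(idx, category, frac) {
    q_rows[[length(q_rows) + 1L]] <<- list(idx = idx, category = category,
                                           frac = frac)
    occ_q[idx] <<- TRUE
  }

  # complete: exact pixel subset of the host reference focus
  for (i in seq_len(counts["complete"])) {
    host <- ref_pixels[[i]]
    n_q <- min(q_areas$complete[i],
               as.integer(floor(length(host) * p$complete_margin)))
    rc <- idx_to_rc(host, nr)
    hr <- mean(rc[, 1]); hc <- mean(rc[, 2])
    d2 <- (rc[, 1] - hr)^2 + (rc[, 2] - hc)^2
    if (occ_test(occ_q, hr, hc, n_q)) placement_error("complete-overlap foci")
    add_q(host[order(d2)[seq_len(n_q)]], "complete", 1)
  }

  # partial: slide a disk off a reference focus until the pixel-exact
  # intersection fraction lands in the requested range
  lo <- p$partial_overlap_range[1]
  hi <- p$partial_overlap_range[2]
  for (i in seq_len(counts["partial"])) {
    n_q <- q_areas$partial[i]
    r_q <- sqrt(n_q / pi)
    done <- FALSE
    for (a in seq_len(200L)) {
      j <- sample.int(rspec$n_foci, 1L)
      ref_idx <- ref_pixels[[j]]
      rc <- idx_to_rc(ref_idx, nr)
      ctr <- c(mean(rc[, 1]), mean(rc[, 2]))
      r_ref <- sqrt(length(ref_idx) / pi)
      theta <- stats::runif(1, 0, 2 * pi)
      u <- stats::runif(1, lo, hi)
      dl <- 0; dh <- r_q + r_ref + 2
      idx <- NULL; frac <- NA_real_
      for (it in seq_len(40L)) {
        dm <- (dl + dh) / 2
        cand <- disk_exact(ctr[1] + dm * sin(theta),
                           ctr[2] + dm * cos(theta), n_q, d)
        if (is.null(cand)) { dh <- dm; next }
        f <- sum(refunion[cand]) / n_q
        if (f >= lo && f <= hi &&
            (is.na(frac) || abs(f - u) < abs(frac - u))) {
          idx <- cand; frac <- f
        }
        if (abs(f - u) <= 0.02) break
        if (f > u) dl <- dm else dh <- dm
      }
      if (is.null(idx)) next
      if (frac <= 0 || frac >= 0.95) next
      if (!all(net$raster[idx])) next
      rcq <- idx_to_rc(idx, nr)
      if (occ_test(occ_q, mean(rcq[, 1]), mean(rcq[, 2]), n_q)) next
      add_q(idx, "partial", frac)
      done <- TRUE
      break
    }
    if (!done) placement_error("partial-overlap foci")
  }

  # none: clear of the dilated reference union
  for (i in seq_len(counts["none"])) {
    idx <- place_free(q_areas$none[i], occ_q, forbid = ref_forbid)
    if (is.null(idx)) placement_error("non-overlapping foci")
    add_q(idx, "none", 0)
  }

  # extra foci channels (neither query nor reference): planted freely
  extra_channels <- setdiff(names(p$foci), c(qch, rch))
  extra_pixels <- list()
  for (ch in extra_channels) {
    sp <- p$foci[[ch]]
    occ_e <- logical(npx)
    e_areas <- sample_areas_px(sp$n_foci, sp$mean_area, sp$area_cv, px)
    pixl <- vector("list", sp$n_foci)
    for (i in seq_len(sp$n_foci)) {
      idx <- place_free(e_areas[i], occ_e)
      if (is.null(idx)) placement_error(sprintf("foci in channel '%s'", ch))
      pixl[[i]] <- idx
      occ_e[idx] <- TRUE
    }
    extra_pixels[[ch]] <- pixl
  }

  # ---- truth tables ------------------------------------------------------
  owner_of <- function(idx) {
    if (p$n_cells == 0L) return(0L)
    rc <- idx_to_rc(idx, nr)
    cell_lab[as.integer(round(mean(rc[, 1]))), as.integer(round(mean(rc[, 2])))]
  }
  truth_rows <- list()
  for (i in seq_along(ref_pixels)) {
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      channel = rch, focus_id = i, category = NA_character_,
      overlap_frac = NA_real_,
      area_um2 = length(ref_pixels[[i]]) * px^2,
      cell_id = owner_of(ref_pixels[[i]]), stringsAsFactors = FALSE)
  }
  for (i in seq_along(q_rows)) {
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      channel = qch, focus_id = i, category = q_rows[[i]]$category,
      overlap_frac = q_rows[[i]]$frac,
      area_um2 = length(q_rows[[i]]$idx) * px^2,
      cell_id = owner_of(q_rows[[i]]$idx), stringsAsFactors = FALSE)
  }
  for (ch in extra_channels) {
    for (i in seq_along(extra_pixels[[ch]])) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        channel = ch, focus_id = i, category = NA_character_,
        overlap_frac = NA_real_,
        area_um2 = length(extra_pixels[[ch]][[i]]) * px^2,
        cell_id = owner_of(extra_pixels[[ch]][[i]]), stringsAsFactors = FALSE)
    }
  }
  foci_tab <- if (length(truth_rows)) {
    do.call(rbind, truth_rows)
  } else {
    data.frame(channel = character(), focus_id = integer(),
               category = character(), overlap_frac = numeric(),
               area_um2 = numeric(), cell_id = integer(),
               stringsAsFactors = FALSE)
  }
  foci_tab$pixels <- I(c(ref_pixels, lapply(q_rows, `[[`, "idx"),
                         unlist(lapply(extra_channels, function(ch)
                           extra_pixels[[ch]]), recursive = FALSE)))

  # ---- render channels ---------------------------------------------------
  blank <- function() matrix(0, d[1], d[2])
  ch_list <- list(mito = matrix(as.numeric(net$raster) * p$mito_intensity,
                                d[1], d[2]))
  qm <- blank(); qm[unlist(lapply(q_rows, `[[`, "idx"))] <- qspec$intensity
  rm_ <- blank(); rm_[unlist(ref_pixels)] <- rspec$intensity
  ch_list[[qch]] <- qm
  ch_list[[rch]] <- rm_
  for (ch in extra_channels) {
    em <- blank(); em[unlist(extra_pixels[[ch]])] <- p$foci[[ch]]$intensity
    ch_list[[ch]] <- em
  }
  dapi <- blank(); edu <- blank(); cyc <- blank()
  if (p$n_cells > 0L) {
    for (i in seq_len(p$n_cells)) {
      nucpix <- which(nuc_lab == i)
      cellpix <- which(cell_lab == i)
      dapi[nucpix] <- p$dapi_level
      edu[nucpix] <- cells_tab$edu_level[i]
      cyc[cellpix] <- cells_tab$cyclinA_level[i]
    }
  }
  ch_list$DAPI <- dapi
  ch_list$EdU <- edu
  ch_list$cyclinA <- cyc

  psf_px <- p$psf_sigma / px
  if (psf_px > 0) {
    # FFT-backed smoothing can leave tiny negative ripples; clamp them
    ch_list <- lapply(ch_list, function(m) pmax(gaussian_smooth(m, psf_px), 0))
  }
  gs <- p$noise[["gaussian_sd"]]
  ps <- p$noise[["poisson_scale"]]
  if (ps > 0 || gs > 0) {
    ch_list <- lapply(ch_list, function(m) {
      v <- pmax(as.numeric(m), 0)
      if (ps > 0) v <- stats::rpois(length(v), v * ps) / ps
      if (gs > 0) v <- v + stats::rnorm(length(v), 0, gs)
      matrix(round(pmax(v, 0)), d[1], d[2])
    })
  }

  frame <- image_frame(ch_list, px, id = sprintf("sim-seed%d", p$seed))
  truth <- structure(list(foci = foci_tab, cells = cells_tab,
                          network = net, nuclei_lab = nuc_lab,
                          cell_lab = cell_lab, params = p),
                     class = "ground_truth")
  list(frame = frame, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted foci, %d cells, network %.4g μm²\n",
              nrow(x$foci), nrow(x$cells), mask_area_um2(x$network)))
  invisible(x)
}

#' Cell regions taken directly from generator ground truth
#'
#' Builds a `cell_set` from the planted nucleus/cell label rasters,
#' bypassing segmentation — for analysing marker channels against the
#' exact planted geometry.
#'
#' @param truth a `ground_truth` from [generate_frame()].
#' @return a `cell_set`.
#' @export
truth_cell_set <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  px <- truth$network$pixel_size
  k <- nrow(truth$cells)
  tab <- data.frame(cell_id = truth$cells$cell_id)
  tab$nucleus_area_um2 <- tabulate(truth$nuclei_lab[truth$nuclei_lab > 0L],
                                   nbins = k) * px^2
  cell_px <- tabulate(truth$cell_lab[truth$cell_lab > 0L], nbins = k)
  tab$cell_area_um2 <- cell_px * px^2
  tab$cytoplasm_area_um2 <- tab$cell_area_um2 - tab$nucleus_area_um2
  tab$phase <- "unassigned"
  tab$flagged <- tab$cytoplasm_area_um2 <= 0
  structure(list(nuclei = truth$nuclei_lab, cells = truth$cell_lab,
                 pixel_size = px, table = tab),
            class = "cell_set")
}

#' Foci sets taken directly from generator ground truth
#'
#' @param truth a `ground_truth`.
#' @param channel which planted channel.
#' @return a [foci_set()] with the planted pixel sets.
#' @export
truth_foci_set <- function(truth, channel) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- truth$foci$channel == channel
  foci_set(truth$foci$pixels[rows], dim(truth$network$raster),
           truth$network$pixel_size, channel)
}
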