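# Fixture builders and independent brute-force oracles used across tests.

# linear indices of a rasterized disk (pixel centres within radius)
disk_indices <- function(cr, cc, radius, nr, nc) {
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  keep <- (rc$row - cr)^2 + (rc$col - cc)^2 <= radius^2
  (rc$col[keep] - 1L) * nr + rc$row[keep]
}

# linear indices of a rasterized axis-aligned ellipse with semi-axes (a, b)
ellipse_indices <- function(cr, cc, a, b, nr, nc) {
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  keep <- ((rc$row - cr) / b)^2 + ((rc$col - cc) / a)^2 <= 1
  (rc$col[keep] - 1L) * nr + rc$row[keep]
}

mask_from_indices <- function(idx, nr, nc, pixel_size = 0.02) {
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  binary_mask(m, pixel_size)
}

# brute-force second-moment descriptors of a pixel index set
oracle_moments <- function(idx, nr, pixel_size) {
  row <- ((idx - 1) %% nr) + 1
  col <- ((idx - 1) %/% nr) + 1
  n <- length(idx)
  crr <- mean((row - mean(row))^2)
  ccc <- mean((col - mean(col))^2)
  crc <- mean((row - mean(row)) * (col - mean(col)))
  ev <- eigen(matrix(c(crr, crc, crc, ccc), 2, 2), symmetric = TRUE)$values
  list(area = n * pixel_size^2,
       major = 4 * sqrt(ev[1]) * pixel_size,
       minor = 4 * sqrt(max(ev[2], 0)) * pixel_size,
       ecc = sqrt(max(1 - ev[2] / ev[1], 0)))
}

# exhaustive Otsu: threshold over a 256-level histogram maximising
# between-class variance (scans every bin boundary)
oracle_otsu <- function(x) {
  mx <- max(x)
  lv <- seq(0, mx, length.out = 257)[-1]
  best <- -Inf
  thr <- NA_real_
  for (t in lv) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; thr <- t }
  }
  thr
}

# brute-force pixel intersection count of a query focus with reference foci
oracle_intersection <- function(q_idx, ref_idx_list) {
  length(intersect(q_idx, unique(unlist(ref_idx_list))))
}

# foci_set from a list of index vectors
foci_from_indices <- function(idx_list, nr, nc, pixel_size = 0.02,
                              channel = "test") {
  foci_set(idx_list, c(nr, nc), pixel_size, channel)
}

# half-plant-intensity segmentation of a generated frame (the noise-robust
# threshold used when analysing frames whose planting intensities are known)
segment_sim <- function(sim) {
  fr <- sim$frame
  px <- fr$pixel_size
  p <- sim$truth$params
  mito <- segment_mask(get_channel(fr, "mito"), px, method = "absolute",
                       threshold = p$mito_intensity / 2)
  qch <- p$query_channel
  rch <- p$reference_channel
  qf <- filter_by_mask(
    label_foci(segment_mask(get_channel(fr, qch), px, method = "absolute",
                            threshold = p$foci[[qch]]$intensity / 2), qch),
    mito)
  rf <- label_foci(segment_mask(get_channel(fr, rch), px, method = "absolute",
                                threshold = p$foci[[rch]]$intensity / 2), rch)
  list(mito = mito, query = qf, reference = rf)
}

# map each recovered focus to the planted focus sharing most pixels
match_planted <- function(foci, truth, channel) {
  rows <- which(truth$foci$channel == channel)
  nrp <- nrow(truth$network$raster)
  owner <- integer(prod(dim(truth$network$raster)))
  for (k in seq_along(rows)) owner[truth$foci$pixels[[rows[k]]]] <- k
  vapply(foci$pixels, function(idx) {
    o <- owner[idx]
    o <- o[o > 0L]
    if (!length(o)) return(NA_integer_)
    rows[as.integer(names(sort(table(o), decreasing = TRUE))[1])]
  }, integer(1))
}
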