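test_that("unsharp mask preserves constants, is identity at weight 0, rejects weight >= 1", {
  const <- matrix(7, 40, 40)
  expect_equal(unsharp_mask(const, radius = 5, weight = 0.7), const)
  img <- matrix(runif(400, 0, 50), 20, 20)
  expect_equal(unsharp_mask(img, radius = 5, weight = 0), img)
  expect_error(unsharp_mask(img, radius = 5, weight = 1), "weight")
  expect_error(unsharp_mask(img, radius = 5, weight = 1.3), "weight")
})

test_that("unsharp mask amplifies an isolated peak by about 1/(1-weight)", {
  n <- 101L
  v <- 1000
  img <- matrix(0, n, n)
  img[51, 51] <- v
  w <- 0.7
  sigma <- 10
  out <- unsharp_mask(img, radius = sigma, weight = w)
  # oracle: centre of the normalized truncated Gaussian kernel
  half <- ceiling(3 * sigma)
  g1 <- dnorm(-half:half, sd = sigma)
  k <- outer(g1, g1)
  k <- k / sum(k)
  expected <- (v - w * v * k[half + 1, half + 1]) / (1 - w)
  expect_equal(out[51, 51], expected, tolerance = 0.01)
  expect_equal(out[51, 51], v / (1 - w), tolerance = 0.01)
})

test_that("Otsu segmentation separates two delta populations exactly", {
  set.seed(42)
  x <- matrix(10, 30, 30)
  bright <- sample(900, 90)
  x[bright] <- 200
  m <- segment_mask(x, pixel_size = 0.02, min_size = 1)
  expect_identical(sort(which(m$raster)), sort(bright))
  thr <- oracle_otsu(as.numeric(x))
  expect_true(attr(m, "threshold") > 10 && attr(m, "threshold") <= 200)
  expect_identical(m$raster, matrix(x >= thr, 30, 30))
})

test_that("segmentation handles degenerate and empty inputs per contract", {
  z <- matrix(0, 10, 10)
  m <- segment_mask(z, pixel_size = 0.02)
  expect_equal(sum(m$raster), 0)
  expect_error(segment_mask(matrix(5, 10, 10), pixel_size = 0.02),
               "degenerate")
  x <- matrix(c(1, 9), 10, 10)
  empty <- segment_mask(x, 0.02, method = "absolute", threshold = 10)
  expect_equal(sum(empty$raster), 0)
})

test_that("min_size removes small components and thresholding is monotone", {
  x <- matrix(0, 20, 20)
  x[2:3, 2:3] <- 100          # 4 px
  x[10:11, 10:12] <- 100      # 6 px
  m <- segment_mask(x, 0.02, method = "absolute", threshold = 50, min_size = 5)
  expect_equal(sum(m$raster), 6)
  expect_true(all(which(m$raster) %in% which(x == 100)))
  set.seed(7)
  img <- matrix(runif(400, 0, 100), 20, 20)
  prev <- NULL
  for (thr in c(20, 40, 60, 80)) {
    cur <- segment_mask(img, 0.02, method = "absolute", threshold = thr,
                        min_size = 1)$raster
    if (!is.null(prev)) expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("mask area is exactly pixel count times pixel_size squared", {
  set.seed(3)
  for (i in 1:5) {
    r <- matrix(runif(256) > 0.6, 16, 16)
    px <- runif(1, 0.01, 0.2)
    expect_identical(mask_area_um2(binary_mask(r, px)), sum(r) * px^2)
  }
})

test_that("foci labelling uses 8-connectivity and partitions the mask", {
  idx1 <- disk_indices(10, 10, 4, 40, 40)
  idx2 <- disk_indices(30, 30, 4, 40, 40)
  m <- mask_from_indices(c(idx1, idx2), 40, 40)
  f <- label_foci(m)
  expect_length(f, 2L)
  expect_setequal(unlist(f$pixels), which(m$raster))
  expect_equal(sum(duplicated(unlist(f$pixels))), 0)

  diag <- matrix(FALSE, 6, 6)
  diag[2, 2] <- TRUE
  diag[3, 3] <- TRUE
  expect_length(label_foci(binary_mask(diag, 0.02)), 1L)

  expect_length(label_foci(binary_mask(matrix(FALSE, 5, 5), 0.02)), 0L)
})

test_that("containment filter implements centroid, majority and any rules", {
  nr <- 30L; nc <- 30L
  mito <- matrix(FALSE, nr, nc)
  mito[, 1:15] <- TRUE
  mk <- binary_mask(mito, 0.02)
  inside <- disk_indices(8, 8, 3, nr, nc)
  outside <- disk_indices(22, 24, 3, nr, nc)
  # focus with 40% of pixels inside (cols <= 15) but centroid column 15.4,
  # whose centroid pixel is inside the mask
  cols <- c(14, 14, 15, 15, 16, 16, 16, 16, 16, 16)
  rows <- 10:19
  straddler <- as.integer((cols - 1L) * nr + rows)
  stopifnot(mean(mito[straddler]) == 0.4, round(mean(cols)) == 15)
  foci <- foci_from_indices(list(inside, outside, straddler), nr, nc)
  for (rule in c("centroid", "majority", "any")) {
    kept <- filter_by_mask(foci, mk, rule = rule)
    expect_true(1L %in% kept$ids)    # fully inside survives every rule
    expect_false(2L %in% kept$ids)   # fully outside never survives
  }
  expect_true(3L %in% filter_by_mask(foci, mk, "centroid")$ids)
  expect_false(3L %in% filter_by_mask(foci, mk, "majority")$ids)
  expect_true(3L %in% filter_by_mask(foci, mk, "any")$ids)
})

test_that("containment rules nest: any >= majority and any >= centroid", {
  set.seed(11)
  nr <- 48L; nc <- 48L
  for (i in 1:10) {
    mito <- matrix(runif(nr * nc) > 0.5, nr, nc)
    mk <- binary_mask(mito, 0.02)
    idx_list <- lapply(1:12, function(j) {
      disk_indices(sample(5:44, 1), sample(5:44, 1), sample(2:4, 1), nr, nc)
    })
    foci <- foci_from_indices(idx_list, nr, nc)
    k_any <- filter_by_mask(foci, mk, "any")$ids
    k_maj <- filter_by_mask(foci, mk, "majority")$ids
    k_cen <- filter_by_mask(foci, mk, "centroid")$ids
    expect_true(all(k_maj %in% k_any))
    expect_true(all(k_cen %in% k_any))
  }
})

test_that("cell regions partition the body, one nucleus per cell", {
  nr <- 80L; nc <- 80L
  dapi <- matrix(0, nr, nc)
  body <- matrix(0, nr, nc)
  centers <- list(c(20, 20), c(20, 60), c(60, 40))
  for (ct in centers) {
    dapi[disk_indices(ct[1], ct[2], 5, nr, nc)] <- 100
    body[disk_indices(ct[1], ct[2], 12, nr, nc)] <- 40
  }
  cs <- build_cell_regions(dapi, body, pixel_size = 0.1,
                           body_threshold = 20)
  expect_equal(n_cells(cs), 3L)
  # each recovered cell equals its planted disk
  for (i in cs$table$cell_id) {
    nuc_px <- which(cs$nuclei == i)
    ct <- centers[[which(vapply(centers, function(x)
      all(abs(x - c(mean((nuc_px - 1) %% nr + 1),
                    mean((nuc_px - 1) %/% nr + 1))) < 2), logical(1)))]]
    expect_setequal(which(cs$cells == i), disk_indices(ct[1], ct[2], 12, nr, nc))
  }
})

test_that("two nuclei in one body blob are split, one nucleus per cell", {
  nr <- 60L; nc <- 100L
  dapi <- matrix(0, nr, nc)
  dapi[disk_indices(30, 30, 5, nr, nc)] <- 100
  dapi[disk_indices(30, 70, 5, nr, nc)] <- 100
  body <- matrix(0, nr, nc)
  body[15:45, 12:88] <- 40   # one blob spanning both nuclei
  cs <- build_cell_regions(dapi, body, pixel_size = 0.1, body_threshold = 20)
  expect_equal(n_cells(cs), 2L)
  # brute-force label audit: cells disjoint, union = body, nuclei inside
  expect_true(all((cs$cells > 0) == (body > 0 | dapi > 0)))
  expect_true(all(cs$cells[cs$nuclei == 1] == 1))
  expect_true(all(cs$cells[cs$nuclei == 2] == 2))
  expect_equal(sum(cs$cells == 1) + sum(cs$cells == 2), sum(body > 0))
  # split near the distance watershed: each cell keeps its own half's nucleus
  col_of <- function(i) mean(((which(cs$cells == i) - 1) %/% nr) + 1)
  expect_true(abs(col_of(1) - col_of(2)) > 20)
})

test_that("a frame with no nuclei yields an empty cell set", {
  cs <- build_cell_regions(matrix(0, 30, 30), matrix(0, 30, 30),
                           pixel_size = 0.1)
  expect_equal(n_cells(cs), 0L)
})
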