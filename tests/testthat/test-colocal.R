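test_that("shape descriptors match brute-force moments on disks and ellipses", {
  nr <- 64L; nc <- 64L
  px <- 0.02
  disk <- disk_indices(32, 32, 10, nr, nc)
  ell <- ellipse_indices(32, 32, 20, 10, nr, 64L)
  foci <- foci_from_indices(list(disk, ell), nr, nc, px)
  sh <- shape_descriptors(foci)

  expect_equal(sh$area_um2[1], pi * (10 * px)^2, tolerance = 0.02)
  expect_lte(sh$eccentricity[1], 0.1)
  expect_equal(sh$eccentricity[2], sqrt(1 - 0.25), tolerance = 0.05)
  for (i in 1:2) {
    o <- oracle_moments(foci$pixels[[i]], nr, px)
    expect_equal(sh$major_axis_um[i], o$major, tolerance = 1e-9)
    expect_equal(sh$minor_axis_um[i], o$minor, tolerance = 1e-9)
    expect_equal(sh$eccentricity[i], o$ecc, tolerance = 1e-9)
    expect_identical(sh$area_um2[i], o$area)
  }
  expect_true(all(sh$minor_axis_um <= sh$major_axis_um))
})

test_that("shape descriptors agree with EBImage moment features on random blobs", {
  set.seed(5)
  nr <- 80L
  for (i in 1:6) {
    ctr <- sample(20:60, 2)
    blob <- unique(c(disk_indices(ctr[1], ctr[2], sample(3:8, 1), nr, nr),
                     disk_indices(ctr[1] + 3, ctr[2] + 2, sample(2:6, 1),
                                  nr, nr)))
    foci <- foci_from_indices(list(blob), nr, nr, 1)
    sh <- shape_descriptors(foci)
    lab <- matrix(0L, nr, nr)
    lab[blob] <- 1L
    ref <- EBImage::computeFeatures.moment(lab)
    expect_equal(sh$major_axis_um, unname(ref[1, "m.majoraxis"]),
                 tolerance = 1e-6)
    expect_equal(sh$eccentricity, unname(ref[1, "m.eccentricity"]),
                 tolerance = 1e-6)
  }
})

test_that("single-pixel focus is degenerate: one-pixel axes, eccentricity 0", {
  foci <- foci_from_indices(list(55L), 10L, 10L, 0.02)
  sh <- shape_descriptors(foci)
  expect_identical(sh$major_axis_um, 0.02)
  expect_identical(sh$minor_axis_um, 0.02)
  expect_identical(sh$eccentricity, 0)
  expect_true(sh$degenerate)
})

test_that("overlap handles identity, disjoint and half-offset squares", {
  nr <- 40L; nc <- 40L
  sq <- function(r0, c0) as.integer(outer((r0:(r0 + 9)),
                                          (c0:(c0 + 9) - 1L) * nr, `+`))
  a <- sq(5, 5)
  q <- foci_from_indices(list(a), nr, nc)
  expect_equal(compute_overlap(q, q)$overlap_pct, 100)

  r_disj <- foci_from_indices(list(sq(25, 25)), nr, nc)
  expect_equal(compute_overlap(q, r_disj)$overlap_pct, 0)

  r_half <- foci_from_indices(list(sq(5, 10)), nr, nc)  # offset 5 of 10 cols
  expect_equal(compute_overlap(q, r_half)$overlap_pct, 50)

  empty_ref <- foci_from_indices(list(), nr, nc)
  expect_equal(compute_overlap(q, empty_ref)$overlap_pct, 0)
})

test_that("overlap equals brute-force pixel intersection on random pairs", {
  set.seed(9)
  nr <- 64L; nc <- 64L
  for (i in 1:200) {
    q_idx <- disk_indices(sample(10:54, 1), sample(10:54, 1),
                          sample(2:7, 1), nr, nc)
    ref_list <- lapply(seq_len(sample(1:3, 1)), function(j)
      disk_indices(sample(10:54, 1), sample(10:54, 1), sample(2:7, 1), nr, nc))
    # reference foci within one set must be disjoint
    ref_list <- Reduce(function(acc, x) {
      x <- setdiff(x, unlist(acc))
      if (length(x)) c(acc, list(x)) else acc
    }, ref_list, list())
    if (!length(ref_list)) next
    q <- foci_from_indices(list(q_idx), nr, nc)
    r <- foci_from_indices(ref_list, nr, nc)
    rec <- compute_overlap(q, r)
    expect_identical(rec$overlap_area_um2,
                     oracle_intersection(q_idx, ref_list) * 0.02^2)
    # symmetric-area property: |A ∩ B| = |B ∩ A|
    back <- compute_overlap(r, q)
    expect_equal(sum(back$overlap_area_um2), sum(rec$overlap_area_um2),
                 tolerance = 1e-12)
  }
})

test_that("categorisation follows the three-way rule with completeness tolerance", {
  expect_identical(as.character(categorize_overlap(c(0, 100, 40))),
                   c("none", "complete", "partial"))
  expect_identical(as.character(categorize_overlap(99)), "complete")
  expect_identical(as.character(categorize_overlap(98.9)), "partial")
  expect_identical(as.character(categorize_overlap(99, complete_tol = 0.5)),
                   "partial")
  expect_identical(as.character(categorize_overlap(0.001)), "partial")
  expect_error(categorize_overlap(101))
})

test_that("summary percentages reproduce category compositions exactly", {
  rec <- data.frame(
    reference_channel = "BrU",
    category = rep(c("none", "partial", "complete"), c(32, 65, 3)))
  s <- summarize_overlap(rec)
  expect_identical(c(s$pct_none, s$pct_partial, s$pct_complete), c(32, 65, 3))
  expect_equal(s$pct_none + s$pct_partial + s$pct_complete, 100)

  all_none <- data.frame(reference_channel = "BrU",
                         category = rep("none", 7))
  s2 <- summarize_overlap(all_none)
  expect_identical(c(s2$pct_none, s2$pct_partial, s2$pct_complete),
                   c(100, 0, 0))

  thirds <- data.frame(reference_channel = "BrU",
                       category = c("none", "partial", "complete"))
  s3 <- summarize_overlap(thirds)
  expect_equal(s3$pct_none, 100 / 3)
  expect_equal(s3$pct_none + s3$pct_partial + s3$pct_complete, 100)

  expect_error(summarize_overlap(rec[0, ]), "empty")
})

test_that("summary percentages always sum to 100 on random compositions", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    rec <- data.frame(
      reference_channel = "r",
      category = sample(c("none", "partial", "complete"), n, replace = TRUE))
    s <- summarize_overlap(rec)
    expect_equal(s$pct_none + s$pct_partial + s$pct_complete, 100,
                 tolerance = 1e-6)
    expect_identical(s$n_foci, n)
  }
})

test_that("size stratification splits areas by overlap status", {
  rec <- data.frame(focus_id = 1:2, overlap_pct = c(0, 50))
  shp <- data.frame(focus_id = 1:2, area_um2 = c(0.01, 0.03))
  tab <- size_stratified_overlap(rec, shp)
  expect_identical(tab$areas_um2[[which(tab$overlap_class == "no_overlap")]],
                   0.01)
  expect_identical(tab$areas_um2[[which(tab$overlap_class == "any_overlap")]],
                   0.03)

  rec0 <- data.frame(focus_id = 1:3, overlap_pct = c(0, 0, 0))
  shp0 <- data.frame(focus_id = 1:3, area_um2 = c(1, 2, 3))
  tab0 <- size_stratified_overlap(rec0, shp0)
  expect_identical(tab0$n[tab0$overlap_class == "any_overlap"], 0L)
  expect_true(is.na(tab0$mean_area_um2[tab0$overlap_class == "any_overlap"]))
})

test_that("per-focus categories survive default generator noise", {
  agree <- vapply(1:10, function(s) {
    sim <- generate_frame(generator_params(seed = s))
    seg <- segment_sim(sim)
    rec <- compute_overlap(seg$query, seg$reference)
    planted <- match_planted(seg$query, sim$truth, "dsRNA")
    ok <- !is.na(planted)
    mean(as.character(rec$category[ok]) ==
           sim$truth$foci$category[planted[ok]])
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
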