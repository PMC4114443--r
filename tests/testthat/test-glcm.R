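test_that("ROI sampling is reproducible and respects the mask", {
  img <- matrix(0L, 512, 512)
  rois <- sample_rois(img, n = 20, size = 50, seed = 9)
  expect_length(rois, 20)
  corners <- vapply(rois, function(r) paste(r$row, r$col), "")
  expect_false(anyDuplicated(corners) > 0)
  for (r in rois) {
    expect_true(r$row >= 0 && r$row + 50 <= 512)
    expect_true(r$col >= 0 && r$col + 50 <= 512)
    expect_identical(dim(r$pixels), c(50L, 50L))
  }
  expect_identical(
    vapply(sample_rois(img, n = 20, size = 50, seed = 9), function(r) r$row, 0L),
    vapply(rois, function(r) r$row, 0L)
  )
  # too few admissible placements: error names the deficit
  small_mask <- matrix(FALSE, 512, 512)
  small_mask[1:52, 1:52] <- TRUE # 9 placements of a 50x50 window
  expect_error(sample_rois(img, small_mask, n = 20, size = 50), "9 placements")
})

test_that("the GLCM matches brute-force pair enumeration on all 3x3 binary images", {
  offsets <- default_offsets(1)
  for (code in 0:511) {
    bits <- as.integer(intToBits(code)[1:9])
    img <- matrix(bits * 255L, 3, 3)
    g <- compute_glcm(img, K = 2, offsets = offsets, symmetric = TRUE)
    oracle <- brute_force_glcm(img, K = 2, offsets = offsets, symmetric = TRUE)
    expect_equal(g$C, oracle, tolerance = 1e-12)
  }
})

test_that("single-offset GLCMs match enumeration and the frozen 2x2 case", {
  # columns-constant 2x2 checkerboard, along-column offset: pairs (0,0) and
  # (1,1) only, so C is diagonal
  img <- matrix(c(0L, 0L, 255L, 255L), 2, 2) # col 1 = 0, col 2 = 255
  g <- compute_glcm(img, K = 2, offsets = list(c(1, 0)), symmetric = TRUE)
  expect_equal(g$C, diag(c(0.5, 0.5)))
  # same image, along-row offset: only cross pairs
  g2 <- compute_glcm(img, K = 2, offsets = list(c(0, 1)), symmetric = TRUE)
  expect_equal(g2$C, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # symmetric flag produces an exactly symmetric matrix on arbitrary input
  set.seed(4)
  rnd <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  gs <- compute_glcm(rnd, K = 8, symmetric = TRUE)
  expect_identical(gs$C, t(gs$C))
  expect_equal(sum(gs$C), 1)
  expect_error(compute_glcm(rnd, K = 8, offsets = list()), "empty")
})

test_that("Haralick features reproduce hand-computed closed forms", {
  # frozen hand evaluation for the diagonal 2-level GLCM diag(0.5, 0.5)
  img <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
  g <- compute_glcm(img, K = 2, offsets = list(c(1, 0)), symmetric = TRUE)
  f <- haralick_features(g)
  expect_equal(unname(f), c(0.5, 0, 1, 1, 1, 1, 0, 1, 0))

  # constant ROI at quantized level gq: single-entry GLCM
  img2 <- matrix(200L, 10, 10)
  gq <- floor(200 * 16 / 256)
  fc <- suppressWarnings(haralick_features(compute_glcm(img2, K = 16)))
  expect_equal(unname(fc[c("T1", "T2", "T3", "T4", "T7", "T8", "T9")]), c(1, 0, 1, 0, 0, 0, 0))
  expect_equal(unname(fc["T6"]), 2 * gq)
  expect_warning(haralick_features(compute_glcm(img2, K = 16)), "degenerate")
})

test_that("feature invariants hold on random ROIs", {
  set.seed(7)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
    g <- compute_glcm(img, K = 16)
    expect_equal(sum(g$C), 1, tolerance = 1e-12)
    f <- suppressWarnings(haralick_features(g))
    expect_true(f["T1"] > 0 && f["T1"] <= 1)
    expect_true(f["T3"] > 0 && f["T3"] <= 1)
    expect_true(all(f[c("T2", "T4", "T6", "T7", "T8", "T9")] >= 0))
    # entropy is bounded by the log of the support size
    expect_lte(f["T4"], log2(sum(g$C > 0)) + 1e-12)
  }
  # a global additive shift that crosses no quantization-bin boundary
  # leaves T2 and T3 unchanged
  img <- matrix(16L * sample(0:15, 900, replace = TRUE) + sample(0:7, 900, replace = TRUE), 30, 30)
  f_lo <- suppressWarnings(haralick_features(compute_glcm(img, K = 16)))
  f_hi <- suppressWarnings(haralick_features(compute_glcm(img + 8L, K = 16)))
  expect_equal(f_hi[c("T2", "T3")], f_lo[c("T2", "T3")])
})

test_that("feature matrices have the documented shape and row semantics", {
  set.seed(11)
  img <- matrix(sample(0:255, 300 * 300, replace = TRUE), 300, 300)
  rois <- sample_rois(img, n = 20, size = 50, seed = 3, image_id = "toy")
  fm <- feature_matrix(rois)
  expect_identical(dim(fm), c(20L, 9L))
  expect_identical(colnames(fm), paste0("T", 1:9))
  expect_identical(nrow(attr(fm, "provenance")), 20L)
  # duplicated ROI list duplicates rows; permutation permutes rows
  fm2 <- feature_matrix(rois[c(1, 1, 2)])
  expect_equal(fm2[1, ], fm2[2, ])
  perm <- c(5, 3, 1)
  expect_equal(feature_matrix(rois[perm]), fm[perm, ], ignore_attr = TRUE)
})
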