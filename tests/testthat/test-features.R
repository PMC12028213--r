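test_that("discretisation follows the anchored floor rule", {
  d <- discretize(c(0, 24.9, 25, 50), 25)
  expect_equal(d$levels, c(1L, 1L, 2L, 3L))
  expect_equal(d$n_levels, 3L)
  expect_equal(discretize(rep(7, 5), 25)$n_levels, 1L)       # constant ROI
  expect_equal(discretize(c(1, 2, 3), 100)$n_levels, 1L)     # bw > range
  expect_error(discretize(c(NA, NaN), 25), "no finite")
  expect_error(discretize(1:3, 0), "positive")
})

test_that("first-order features match hand arithmetic and the limits", {
  fo <- first_order_features(c(1, 2, 3, 4), bin_width = 1)
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Median"]], 2.5)
  expect_equal(fo[["Range"]], 3)
  expect_equal(fo[["Energy"]], 1 + 4 + 9 + 16)
  expect_equal(fo[["Uniformity"]], 4 * 0.25^2)
  expect_equal(fo[["Entropy"]], 2)      # 4 equiprobable levels = 2 bits

  cst <- first_order_features(rep(5, 10), bin_width = 1)
  expect_equal(cst[["Variance"]], 0)
  expect_equal(cst[["Entropy"]], 0)
  expect_equal(cst[["Uniformity"]], 1)
  expect_equal(cst[["Skewness"]], 0)
  expect_error(first_order_features(numeric(0)), "no finite")
})

test_that("co-occurrence features match hand-built matrices", {
  # constant 2x2x1 ROI: single-cell GLCM, joint entropy 0
  larr <- array(1L, c(2, 2, 1))
  g <- texture_features(larr, 1L, "glcm")
  expect_equal(g[["JointEntropy"]], 0)
  expect_equal(g[["JointEnergy"]], 1)
  expect_equal(g[["Contrast"]], 0)

  # 1D pattern 1,2,1,2: symmetric GLCM for the x offset has counts
  # {(1,2): 3, (2,1): 3}; contrast = sum p (i-j)^2 = 1
  p <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  g2 <- texture_features(p, 2L, "glcm")
  expect_equal(g2[["Contrast"]], 1)
  expect_equal(g2[["MaximumProbability"]], 0.5)
  expect_equal(g2[["JointEntropy"]], 1)   # two equiprobable cells

  # single voxel: no pairs in any direction
  expect_error(texture_features(array(1L, c(1, 1, 1)), 1L, "glcm"),
               "degenerate")
  expect_error(texture_features(array(1L, c(1, 1, 1)), 1L, "ngtdm"),
               "degenerate")
  # but run/zone/dependence families are defined
  expect_length(texture_features(array(1L, c(1, 1, 1)), 1L, "glrlm"), 16L)
  expect_length(texture_features(array(1L, c(1, 1, 1)), 1L, "glszm"), 16L)
  expect_length(texture_features(array(1L, c(1, 1, 1)), 1L, "gldm"), 14L)
})

test_that("run and zone families count hand-checkable structures", {
  # two runs of lengths 3 and 1 of level 1, one run of length 2 of level 2
  # along x: 1 1 1 2 2 1
  p <- array(c(1L, 1L, 1L, 2L, 2L, 1L), c(6, 1, 1))
  rl <- texture_features(p, 2L, "glrlm")
  # x direction: runs (1,len3), (2,len2), (1,len1); the 12 other directions
  # see only unit runs (6 runs each)
  expect_equal(rl[["RunPercentage"]], mean(c(3 / 6, rep(1, 12))))

  # 26-connected zones: level 1 splits into sizes 3 and 1, level 2 is one
  # zone of size 2
  sz <- texture_features(p, 2L, "glszm")
  expect_equal(sz[["ZonePercentage"]], 3 / 6)
  expect_equal(sz[["LargeAreaEmphasis"]], (9 + 1 + 4) / 3)

  # gldm with alpha 0: dependence = 1 + same-level neighbours
  gd <- texture_features(p, 2L, "gldm")
  expect_equal(gd[["GrayLevelNonUniformity"]], (4^2 + 2^2) / 6)
})

test_that("feature vectors have the 93-feature structure and naming", {
  roi <- fix_random_roi(101)
  fv <- extract_feature_vector(roi$values, roi$mask, roi$bin_width, "VP")
  expect_length(fv, 93L)
  expect_true(all(is.finite(fv)))
  groups <- table(sub("_.*", "", names(fv)))
  expect_equal(groups[["firstorder"]], 18L)
  expect_equal(groups[["glcm"]], 24L)
  expect_equal(groups[["glrlm"]], 16L)
  expect_equal(groups[["glszm"]], 16L)
  expect_equal(groups[["ngtdm"]], 5L)
  expect_equal(groups[["gldm"]], 14L)
  expect_true("glcm_Idmn.VP" %in% names(fv))
  expect_true("firstorder_Entropy.VP" %in% names(fv))

  # constant map: dispersion features 0, vector still complete
  cmap <- array(3.5, dim(roi$values))
  fvc <- extract_feature_vector(cmap, roi$mask, roi$bin_width)
  expect_length(fvc, 93L)
  expect_equal(fvc[["firstorder_Variance"]], 0)
  expect_equal(fvc[["glcm_Contrast"]], 0)
  expect_equal(fvc[["glszm_GrayLevelVariance"]], 0)
})

test_that("texture features are invariant to bin-preserving shifts and flips", {
  roi <- fix_random_roi(202)
  fv <- extract_feature_vector(roi$values, roi$mask, roi$bin_width)
  # adding an exact multiple of the bin width preserves all levels
  fv_shift <- extract_feature_vector(roi$values + 3 * roi$bin_width,
                                     roi$mask, roi$bin_width)
  tex <- grep("^(glcm|glrlm|glszm|ngtdm|gldm)_", names(fv), value = TRUE)
  expect_equal(fv[tex], fv_shift[tex], tolerance = 1e-10)

  # axis reversal preserves the co-occurrence geometry exactly
  rev_arr <- roi$values[dim(roi$values)[1]:1, , , drop = FALSE]
  rev_mask <- mask3d(roi$mask$data[dim(roi$values)[1]:1, , , drop = FALSE],
                     roi$mask$spacing)
  fv_rev <- extract_feature_vector(rev_arr, rev_mask, roi$bin_width)
  expect_equal(fv, fv_rev, tolerance = 1e-10)
})

test_that("feature tables assemble lesions x variants x maps", {
  roi <- fix_random_roi(303)
  m2 <- roi$values * 2 + 1
  lesions <- list(list(
    id = "les1",
    maps = list(VE = roi$values, VP = m2),
    rois = list(original = roi$mask,
                ero1 = roi$mask)))
  tb <- extract_feature_table(lesions,
                              bin_widths = c(VE = 5, VP = 10))
  expect_equal(nrow(tb), 2L)
  expect_equal(ncol(tb) - 2L, 186L)
  expect_true(all(grepl("\\.(VE|VP)$", names(tb)[-(1:2)])))

  # single map: 93 columns
  tb1 <- extract_feature_table(list(list(id = "a",
                                         maps = list(VE = roi$values),
                                         rois = list(original = roi$mask))),
                               bin_widths = c(VE = 5))
  expect_equal(ncol(tb1) - 2L, 93L)

  # a map without a configured bin width is an error naming it
  expect_error(extract_feature_table(
    list(list(id = "a", maps = list(XX = roi$values),
              rois = list(original = roi$mask))),
    bin_widths = c(VE = 5)), "XX")
})
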