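test_that("in-plane rotation preserves spheres and inverts approximately", {
  m <- fix_sphere(4)
  expect_identical(rotate_mask(m, 0)$data, m$data)
  for (a in c(10, -20, 30)) {
    r <- rotate_mask(m, a)
    expect_lt(abs(mask_volume(r) - mask_volume(m)) / mask_volume(m), 0.05)
  }
  back <- rotate_mask(rotate_mask(m, 10), -10)
  expect_gte(dice(back, m), 0.95)
})

test_that("dilation and erosion use the stated structuring elements", {
  one <- array(FALSE, c(9L, 9L, 9L)); one[5, 5, 5] <- TRUE
  m <- mask3d(one)
  expect_equal(mask_volume(dilate_mask(m, 1L)), 7L)    # 6-neighbour cross
  expect_equal(mask_volume(dilate_mask(m, 2L)), 19L)   # 18-neighbourhood
  expect_error(erode_mask(m), "empties")

  s <- fix_sphere(4)
  closed <- erode_mask(dilate_mask(s, 1L))
  expect_true(all(closed$data[s$data]))                # closing superset
  expect_gt(mask_volume(dilate_mask(s, 1L)), mask_volume(s))
  expect_lt(mask_volume(erode_mask(s)), mask_volume(s))
})

test_that("translations are exact inverse pairs preserving voxel count", {
  s <- fix_sphere(4)
  for (ax in c("x", "y", "z")) {
    t1 <- translate_mask(s, ax, 1L)
    expect_equal(mask_volume(t1), mask_volume(s))
    expect_identical(translate_mask(t1, ax, -1L)$data, s$data)
  }
  # a mask touching the border cannot be shifted further
  edge <- array(FALSE, c(7L, 7L, 7L)); edge[7, 4, 4] <- TRUE
  expect_error(translate_mask(mask3d(edge), "x", 1L), "exits the grid")
})

test_that("the artificial ROI set has exactly the stated composition", {
  s <- fix_sphere(4)
  ps <- generate_artificial_rois(s)
  expect_length(ps$variants, 15L)
  kinds <- table(ps$provenance$kind)
  expect_equal(kinds[["rotation"]], 6L)
  expect_equal(kinds[["dilation"]], 2L)
  expect_equal(kinds[["erosion"]], 1L)
  expect_equal(kinds[["translation"]], 6L)
  # every variant is nonempty and on the original grid
  for (v in ps$variants) {
    expect_gt(mask_volume(v), 0)
    expect_identical(dim(v$data), dim(s$data))
    expect_identical(v$spacing, s$spacing)
  }
  # morphological ordering: dil2 > dil1 > original > ero1 (strict subsets)
  expect_true(all(ps$variants$dil1$data[s$data]))
  expect_true(all(ps$variants$dil2$data[ps$variants$dil1$data]))
  expect_true(all(s$data[ps$variants$ero1$data]))
  expect_gt(mask_volume(ps$variants$dil2), mask_volume(ps$variants$dil1))
  expect_gt(mask_volume(ps$variants$dil1), mask_volume(s))
  expect_gt(mask_volume(s), mask_volume(ps$variants$ero1))
})

test_that("perturbation failures carry the variant name", {
  # too small to erode: the erosion variant must be named in the error
  one <- array(FALSE, c(9L, 9L, 9L)); one[4:5, 4:5, 4:5] <- TRUE
  expect_error(generate_artificial_rois(mask3d(one)), "ero1")
})
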