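test_that("ellipsoid masks respect geometry and the border margin", {
  # 5 mm radii on a 1 mm grid: a 1 cm lesion, the smallest admissible size
  m <- make_lesion_mask(c(21L, 21L, 21L), c(11, 11, 11), c(5, 5, 5),
                        c(1, 1, 1))
  expect_s3_class(m, "mask3d")
  expect_gt(mask_volume(m), 0)

  # degenerate ellipsoid with radii = half a voxel: single-voxel mask
  m1 <- make_lesion_mask(c(9L, 9L, 9L), c(5, 5, 5), c(0.5, 0.5, 0.5),
                         c(1, 1, 1))
  expect_equal(mask_volume(m1), 1L)
  expect_true(m1$data[5, 5, 5])

  # voxel count matches brute-force enumeration of centers with ||x-c|| <= r
  r <- 4
  m4 <- fix_sphere(r)
  grid <- expand.grid(x = 1:17, y = 1:17, z = 1:17)
  inside <- sqrt((grid$x - 9)^2 + (grid$y - 9)^2 + (grid$z - 9)^2) <= r
  expect_equal(mask_volume(m4), sum(inside))

  # touching the border errors and names the axis
  expect_error(make_lesion_mask(c(15L, 15L, 15L), c(8, 8, 8), c(6, 5, 5),
                                c(1, 1, 1)), "along x")
})

test_that("lesion_truth enforces physical invariants", {
  expect_error(fix_truth(ve = 0.8, vp = 0.3), "ve \\+ vp")
  expect_error(fix_truth(dstar = 0.5e-3), "dstar")
  expect_error(fix_truth(radii = c(4, 6, 6)), "5 mm")
  expect_error(fix_truth(f = 1.2), "\\[0, 1\\]")
})

test_that("noiseless DCE simulation reproduces the Tofts forward model", {
  acq <- fix_acq(noise = 0)
  a <- aif("weinmann")
  tr <- fix_truth()
  dce <- simulate_dce_series(tr, acq, a)
  # pre-contrast frame equals baseline exactly
  expect_equal(max(abs(dce$data[, , , 1] - acq$baseline)), 0)
  # lesion voxel curve equals alpha * Ct pointwise
  ct <- tofts_forward(list(ktrans = tr$ktrans, ve = tr$ve, vp = tr$vp),
                      a, dce_times(acq))
  s <- dce$data[16, 16, 8, ]
  expect_equal(s / acq$baseline - 1, acq$alpha * ct, tolerance = 1e-12)
  # background voxel is baseline-only
  expect_equal(dce$data[2, 2, 2, ], rep(acq$baseline, acq$dce_n_frames))
})

test_that("zero tracer exchange gives a flat lesion signal", {
  acq <- fix_acq(noise = 0)
  tr <- fix_truth(ktrans = 0, vp = 0, ve = 0.3)
  dce <- simulate_dce_series(tr, acq, aif("weinmann"))
  s <- dce$data[16, 16, 8, ]
  expect_equal(s, rep(acq$baseline, length(s)))
})

test_that("DWI simulation follows the IVIM biexponential", {
  acq <- fix_acq(noise = 0)
  tr <- fix_truth(d = 1.0e-3, dstar = 10e-3, f = 0.15)
  dwi <- simulate_dwi_series(tr, acq)
  s <- dwi$data[16, 16, 8, ]
  b <- acq$dwi_b_values
  # b = 0: S equals S0 exactly
  expect_equal(s[1], acq$baseline)
  # direct evaluation of the biexponential at b = 800
  expect_equal(s[length(b)],
               100 * (0.15 * exp(-800 * 10e-3) + 0.85 * exp(-800 * 1e-3)),
               tolerance = 1e-12)
  # f = 0 limit: log signal linear in b with slope -D
  tr0 <- fix_truth(f = 0, d = 1.2e-3)
  s0 <- simulate_dwi_series(tr0, acq)$data[16, 16, 8, ]
  sl <- diff(log(s0)) / diff(b)
  expect_equal(sl, rep(-1.2e-3, length(sl)), tolerance = 1e-10)
})

test_that("cohort generation matches the class design and is reproducible", {
  spec <- cohort_spec(rng_seed = 123L)
  co <- make_cohort(spec, fix_acq(), simulate = FALSE)
  tt <- co$truth_table
  expect_equal(nrow(tt), 43L)
  expect_equal(sum(tt$class == "malignant"), 18L)
  expect_equal(sum(tt$class != "malignant"), 25L)
  expect_equal(as.vector(table(tt$class)[c("adenoma", "warthin",
                                           "malignant")]),
               c(15L, 10L, 18L))

  # one lesion per class
  co1 <- make_cohort(cohort_spec(n_per_class = c(adenoma = 1, warthin = 1,
                                                 malignant = 1)),
                     fix_acq(), simulate = FALSE)
  expect_equal(nrow(co1$truth_table), 3L)
  expect_setequal(co1$truth_table$class,
                  c("adenoma", "warthin", "malignant"))

  # determinism: same seed gives an identical truth table
  co2 <- make_cohort(spec, fix_acq(), simulate = FALSE)
  expect_identical(co$truth_table, co2$truth_table)
  # and a different seed does not
  co3 <- make_cohort(cohort_spec(rng_seed = 124L), fix_acq(),
                     simulate = FALSE)
  expect_false(identical(co$truth_table$ktrans, co3$truth_table$ktrans))
})

test_that("cohort simulation is reproducible voxel for voxel", {
  spec <- cohort_spec(n_per_class = c(adenoma = 1, warthin = 1,
                                      malignant = 1), rng_seed = 5L)
  acq <- fix_acq(noise = 0.02)
  a <- make_cohort(spec, acq)
  b <- make_cohort(spec, acq)
  expect_identical(a$lesions[[1]]$dce$data, b$lesions[[1]]$dce$data)
  expect_identical(a$lesions[[3]]$dwi$data, b$lesions[[3]]$dwi$data)
})
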