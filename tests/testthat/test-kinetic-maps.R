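test_that("enhancement curves are relative to the pre-contrast frame", {
  acq <- fix_acq(noise = 0)
  arr <- array(100, c(acq$grid_shape, acq$dce_n_frames))
  ser <- dynamic_series(arr, times = dce_times(acq),
                        spacing = acq$voxel_spacing)
  e <- enhancement_curve(ser, c(3, 3, 3))
  expect_equal(e$values, rep(0, acq$dce_n_frames))

  arr[5, 5, 5, ] <- c(100, 150, 200, rep(200, acq$dce_n_frames - 3))
  ser <- dynamic_series(arr, times = dce_times(acq),
                        spacing = acq$voxel_spacing)
  e <- enhancement_curve(ser, c(5, 5, 5))
  expect_equal(e$values[1:4], c(0, 0.5, 1.0, 1.0))

  arr[6, 6, 6, 1] <- 0
  ser <- dynamic_series(arr, times = dce_times(acq),
                        spacing = acq$voxel_spacing)
  expect_error(enhancement_curve(ser, c(6, 6, 6)), "non-positive")
})

make_curve_series <- function(E, mask) {
  # embed one enhancement curve into every masked voxel of a series
  nf <- length(E)
  d <- dim(mask$data)
  arr <- array(100, c(d, nf))
  idx <- which(mask$data)
  for (j in seq_len(nf)) arr[idx + (j - 1) * prod(d)] <- 100 * (1 + E[j])
  dynamic_series(arr, times = (seq_len(nf) - 1) * 38, spacing = mask$spacing)
}

test_that("model-free descriptors match their chord definitions", {
  m <- fix_sphere(2, grid = c(9L, 9L, 9L))
  # peak 1.0 at t = 76 s (frame 3), last 0.5 at t = 380 s
  E <- c(0, 0.5, 1.0, seq(1.0, 0.5, length.out = 9)[-1])
  mf <- model_free_maps(make_curve_series(E, m), m)
  v <- sapply(mf$maps, function(x) x[5, 5, 5])
  expect_equal(v[["MRE"]], 100)
  expect_equal(v[["TTP"]], 76 - 38)
  expect_equal(v[["WIS"]], 100 / 38)
  expect_equal(v[["WOS"]], (1.0 - 0.5) / (380 - 76) * 100)
  expect_equal(v[["WOR"]], 0.5)
  expect_equal(v[["WIO"]], v[["WIS"]] / v[["WOS"]])

  # flat curve: MRE = 0, WOR = 0, WIO defined as 0
  mf0 <- model_free_maps(make_curve_series(rep(0, 11), m), m)
  expect_equal(mf0$maps$MRE[5, 5, 5], 0)
  expect_equal(mf0$maps$WOR[5, 5, 5], 0)
  expect_equal(mf0$maps$WIO[5, 5, 5], 0)

  # monotone increasing: TTP at the last frame, WOS = WOR = 0, WIO capped
  Em <- seq(0, 1, length.out = 11)
  mfm <- model_free_maps(make_curve_series(Em, m), m)
  expect_equal(mfm$maps$TTP[5, 5, 5], 380 - 38)
  expect_equal(mfm$maps$WOS[5, 5, 5], 0)
  expect_equal(mfm$maps$WOR[5, 5, 5], 0)
  expect_equal(mfm$maps$WIO[5, 5, 5], 1e6)
  expect_equal(mfm$qc$n_wio_capped, mask_volume(m))

  expect_error(model_free_maps(make_curve_series(E, m),
                               mask3d(array(FALSE, c(9, 9, 9)))),
               "empty")
})

test_that("exactly nine DCE maps are produced per lesion", {
  acq <- fix_acq(noise = 0)
  tr <- fix_truth()
  mask <- make_lesion_mask(acq$grid_shape, tr$center, tr$radii,
                           acq$voxel_spacing)
  dce <- simulate_dce_series(tr, acq, aif())
  mf <- model_free_maps(dce, mask)
  tf <- fit_tofts_maps(dce, mask, aif())
  expect_named(mf$maps, c("MRE", "TTP", "WIS", "WOS", "WOR", "WIO"))
  expect_named(tf$maps, c("KTRANS", "VE", "VP"))
  # MRE >= 0 and TTP within the post-contrast range, WOR in [0, 1]
  expect_true(all(mf$maps$MRE[mask$data] >= 0))
  expect_true(all(mf$maps$TTP[mask$data] >= 0 &
                    mf$maps$TTP[mask$data] <= 380 - 38))
  expect_true(all(mf$maps$WOR[mask$data] >= 0 &
                    mf$maps$WOR[mask$data] <= 1))
})

test_that("tofts_forward handles the degenerate and linear limits", {
  a <- aif("weinmann")
  ts <- (0:10) * 38
  expect_equal(tofts_forward(list(ktrans = 0, ve = 0, vp = 0), a, ts),
               rep(0, 11))
  cp <- aif_eval(a, ts)
  expect_equal(tofts_forward(list(ktrans = 0, ve = 0, vp = 0.05), a, ts),
               0.05 * cp)
  expect_error(tofts_forward(list(ktrans = 0.1, ve = 0, vp = 0), a, ts),
               "kep undefined")
})

test_that("tofts_forward matches the boxcar closed form", {
  bx <- aif("boxcar", c0 = 1, t0 = 10, t1 = 70)
  ts <- c(0, 20, 50, 100, 200, 380)
  kt <- 0.2; ve <- 0.3
  kep <- kt / ve / 60
  ct <- tofts_forward(list(ktrans = kt, ve = ve, vp = 0), bx, ts,
                      dt_fine = 0.05)
  closed <- vapply(ts, function(t) {
    if (t <= 10) 0
    else if (t <= 70) (kt / 60) * (1 - exp(-kep * (t - 10))) / kep
    else (kt / 60) * (1 - exp(-kep * 60)) / kep * exp(-kep * (t - 70))
  }, numeric(1))
  expect_equal(ct, closed, tolerance = 1e-3)
})

test_that("tofts_forward is monotone in ktrans during the first transit", {
  bx <- aif("boxcar", c0 = 1, t0 = 10, t1 = 200)
  ts <- c(0, 38, 76, 114, 152, 190)
  prev <- rep(0, length(ts))
  for (kt in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    ct <- tofts_forward(list(ktrans = kt, ve = 0.4, vp = 0), bx, ts)
    expect_true(all(ct >= prev - 1e-12))
    prev <- ct
  }
})

test_that("noiseless Tofts fits recover the simulated parameters", {
  a <- aif("weinmann")
  ts <- (0:10) * 38
  truth <- list(ktrans = 0.2, ve = 0.3, vp = 0.05)
  e <- tofts_forward(truth, a, ts)
  fit <- fit_tofts(e, a, times = ts)
  expect_lt(abs(fit$ktrans - 0.2) / 0.2, 0.01)
  expect_lt(abs(fit$ve - 0.3) / 0.3, 0.01)
  expect_lt(abs(fit$vp - 0.05) / 0.05, 0.01)
  # the fit is at least as good as the truth (optimality of the optimum)
  expect_lte(fit$fit_rss, sum((e - e)^2) + 1e-10)

  flat <- fit_tofts(rep(0, 11), a, times = ts)
  expect_lt(flat$ktrans, 1e-6)
  expect_lt(flat$vp, 1e-6)

  expect_error(fit_tofts(c(0, 0.1), a, times = c(0, 38)), "post-contrast")
})

test_that("noisy Tofts maps keep the median Ktrans error under 10%", {
  # 100 voxels at 2% Gaussian noise, the acquisition's noise design point
  a <- aif("weinmann")
  ts <- (0:10) * 38
  truth <- list(ktrans = 0.25, ve = 0.35, vp = 0.04)
  ct <- tofts_forward(truth, a, ts)
  set.seed(77)
  alpha <- acquisition_spec()$alpha
  E <- matrix(rep(alpha * ct, each = 100), 100, 11) +
    matrix(rnorm(1100, 0, 0.02), 100, 11)
  basis <- robustrad:::tofts_fit_basis(a, ts)
  fit <- robustrad:::profiled_tofts_fit(E, basis)
  par <- robustrad:::tofts_params_from_fit(fit, alpha = alpha)
  expect_lt(median(abs(par$ktrans - 0.25) / 0.25), 0.10)
})
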