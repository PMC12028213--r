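b11 <- c(0, 10, 20, 30, 50, 80, 100, 200, 300, 400, 800)

test_that("segmented IVIM fit recovers noiseless parameters", {
  # pure monoexponential: f ~ 0, D within 0.5%
  s <- 100 * exp(-b11 * 1.2e-3)
  fit <- fit_ivim(s, b11)
  expect_lt(abs(fit$d - 1.2e-3) / 1.2e-3, 0.005)
  expect_lt(fit$f, 0.005)

  # biexponential: all three within 2%
  s2 <- ivim_forward(b11, 100, 1.0e-3, 10e-3, 0.15)
  fit2 <- fit_ivim(s2, b11)
  expect_lt(abs(fit2$d - 1.0e-3) / 1.0e-3, 0.02)
  expect_lt(abs(fit2$dstar - 10e-3) / 10e-3, 0.02)
  expect_lt(abs(fit2$f - 0.15) / 0.15, 0.02)

  # constant signal: D pinned at the lower bound and flagged
  fit3 <- fit_ivim(rep(100, 11), b11)
  expect_equal(fit3$d, 1e-5)
  expect_false(fit3$converged)

  expect_error(fit_ivim(c(100, 90, -1, 70, 60, 50, 40, 30, 25, 20, 10),
                        b11), "non-positive")
  expect_error(fit_ivim(c(100, 90), c(0, 800)), ">= 4 b-values")
  expect_error(fit_ivim(c(100, 95, 90, 85), c(0, 10, 20, 300)),
               "fewer than 2")
})

test_that("segmented fit agrees with a full 4-parameter nonlinear fit", {
  # independent oracle: joint least squares over (s0, d, dstar, f)
  set.seed(3)
  for (i in 1:5) {
    d <- runif(1, 0.6e-3, 1.8e-3)
    ds <- runif(1, 8e-3, 20e-3)
    f <- runif(1, 0.05, 0.25)
    s <- ivim_forward(b11, 100, d, ds, f)
    seg <- fit_ivim(s, b11)
    full <- optim(c(100, d * 1.3, ds * 0.7, f * 1.5), function(p)
      sum((s - ivim_forward(b11, p[1], p[2], p[3], p[4]))^2),
      method = "L-BFGS-B",
      lower = c(50, 1e-5, 1e-4, 0), upper = c(200, 4e-3, 0.5, 1),
      control = list(parscale = c(100, 1e-3, 1e-2, 0.1),
                     factr = 1e4, maxit = 500))$par
    expect_lt(abs(seg$d - full[2]) / full[2], 0.05)
    expect_lt(abs(seg$f - full[4]) / max(full[4], 1e-6), 0.05)
  }
})

test_that("the forward model decays monotonically in D", {
  prev <- ivim_forward(b11[-1], 100, 0.4e-3, 10e-3, 0.1)
  for (d in c(0.8e-3, 1.2e-3, 2e-3)) {
    cur <- ivim_forward(b11[-1], 100, d, 10e-3, 0.1)
    expect_true(all(cur < prev))
    prev <- cur
  }
})

test_that("IVIM maps recover lesion medians and handle edge masks", {
  acq <- fix_acq(noise = 0)
  tr <- fix_truth(d = 1.1e-3, dstar = 12e-3, f = 0.16)
  mask <- make_lesion_mask(acq$grid_shape, tr$center, tr$radii,
                           acq$voxel_spacing)
  dwi <- simulate_dwi_series(tr, acq, mask = mask)
  iv <- ivim_maps(dwi, mask)
  expect_named(iv$maps, c("D", "DSTAR", "F"))
  med <- sapply(iv$maps, function(m) median(m[mask$data], na.rm = TRUE))
  expect_lt(abs(med[["D"]] - tr$d) / tr$d, 0.02)
  expect_lt(abs(med[["DSTAR"]] - tr$dstar) / tr$dstar, 0.02)
  expect_lt(abs(med[["F"]] - tr$f) / tr$f, 0.02)

  # single-voxel mask: three maps, each with exactly one defined voxel
  one <- array(FALSE, acq$grid_shape); one[16, 16, 8] <- TRUE
  iv1 <- ivim_maps(dwi, mask3d(one, acq$voxel_spacing))
  for (m in iv1$maps) expect_equal(sum(is.finite(m)), 1L)

  expect_error(ivim_maps(dwi, mask3d(array(FALSE, acq$grid_shape))),
               "empty")
})

test_that("noisy D maps keep the median error under 10%", {
  acq <- fix_acq(noise = 0.02)
  tr <- fix_truth(d = 1.0e-3, dstar = 14e-3, f = 0.15)
  mask <- make_lesion_mask(acq$grid_shape, tr$center, tr$radii,
                           acq$voxel_spacing)
  dwi <- simulate_dwi_series(tr, acq, mask = mask, seed = 21)
  iv <- ivim_maps(dwi, mask)
  err_d <- abs(iv$maps$D[mask$data] - tr$d) / tr$d
  expect_lt(median(err_d, na.rm = TRUE), 0.10)
})
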