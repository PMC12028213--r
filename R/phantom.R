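#' Ellipsoidal lesion mask
#'
#' Builds a binary mask of the axis-aligned ellipsoid with the given center
#' (1-based voxel coordinates) and radii (mm); a voxel is included iff its
#' center lies inside the ellipsoid.  The ellipsoid must keep a margin of at
#' least 2 voxels from every grid border so that all 15 ROI perturbations
#' stay in bounds.
#'
#' @param grid_shape Integer grid dimensions, length 3.
#' @param center Lesion center in voxel coordinates, length 3.
#' @param radii Ellipsoid radii in mm per axis, length 3.
#' @param spacing Voxel spacing in mm per axis, length 3.
#' @param margin Minimum clearance from the grid border, voxels.
#' @return A [mask3d()].
#' @export
make_lesion_mask <- function(grid_shape, center, radii, spacing = c(1, 1, 1),
                             margin = 2L) {
  stopifnot(length(grid_shape) == 3L, length(center) == 3L,
            length(radii) == 3L, length(spacing) == 3L)
  rv <- radii / spacing  # radii in voxel units
  ax <- c("x", "y", "z")
  for (a in 1:3) {
    if (center[a] - rv[a] < 1 + margin || center[a] + rv[a] > grid_shape[a] - margin)
      stop(sprintf("ellipsoid touches the grid border along %s (margin %d voxels)",
                   ax[a], margin))
  }
  u <- (seq_len(grid_shape[1L]) - center[1L]) / rv[1L]
  v <- (seq_len(grid_shape[2L]) - center[2L]) / rv[2L]
  w <- (seq_len(grid_shape[3L]) - center[3L]) / rv[3L]
  m <- outer(outer(u^2, v^2, "+"), w^2, "+") <= 1
  mask3d(array(m, grid_shape), spacing)
}

#' Simulate a DCE series for one lesion
#'
#' Forward model of the dynamic contrast-enhanced acquisition: background
#' voxels carry the baseline signal only; lesion voxels follow
#' `baseline * (1 + alpha * Ct(t))` with Ct the extended Tofts concentration
#' ([tofts_forward()]) at the lesion's ground-truth parameters.  Frame 1 is
#' pre-contrast (Ct = 0).  Independent Gaussian noise with sd
#' `noise_sigma * baseline` is added per voxel per frame.
#'
#' @param truth A [lesion_truth()].
#' @param acq An [acquisition_spec()].
#' @param aif An [aif()].
#' @param mask Optional precomputed lesion [mask3d()]; built from `truth`
#'   geometry when omitted.
#' @param seed Integer seed for the noise.
#' @return A DCE [dynamic_series()].
#' @export
simulate_dce_series <- function(truth, acq, aif, mask = NULL, seed = 1L) {
  stopifnot(inherits(truth, "lesion_truth"), inherits(acq, "acquisition_spec"))
  if (is.null(mask))
    mask <- make_lesion_mask(acq$grid_shape, truth$center, truth$radii,
                             acq$voxel_spacing)
  times <- dce_times(acq)
  ct <- tofts_forward(list(ktrans = truth$ktrans, ve = truth$ve,
                           vp = truth$vp), aif, times)
  nf <- length(times)
  vol <- array(acq$baseline, c(acq$grid_shape, nf))
  idx <- which(mask$data)
  nvox <- prod(acq$grid_shape)
  for (j in seq_len(nf))
    vol[idx + (j - 1L) * nvox] <- acq$baseline * (1 + acq$alpha * ct[j])
  if (acq$noise_sigma > 0) {
    old <- .Random.seed_save(seed)
    on.exit(.Random.seed_restore(old))
    vol <- vol + stats::rnorm(length(vol), 0, acq$noise_sigma * acq$baseline)
  }
  dynamic_series(vol, times = times, spacing = acq$voxel_spacing)
}

#' Simulate a DWI series for one lesion
#'
#' Lesion voxels follow the IVIM biexponential
#' `S(b) = S0 [f e^(-b D*) + (1 - f) e^(-b D)]` at the lesion's ground-truth
#' diffusion parameters; background voxels decay monoexponentially with a
#' tissue-like diffusion coefficient (no perfusion compartment).  Gaussian
#' noise with sd `noise_sigma * baseline` is added when `noise_sigma > 0`.
#'
#' @param truth A [lesion_truth()].
#' @param acq An [acquisition_spec()].
#' @param mask Optional precomputed lesion [mask3d()].
#' @param background_d Background diffusion coefficient, mm^2/s.
#' @param seed Integer seed for the noise.
#' @return A DWI [dynamic_series()].
#' @export
simulate_dwi_series <- function(truth, acq, mask = NULL,
                                background_d = 1.2e-3, seed = 1L) {
  stopifnot(inherits(truth, "lesion_truth"), inherits(acq, "acquisition_spec"))
  if (is.null(mask))
    mask <- make_lesion_mask(acq$grid_shape, truth$center, truth$radii,
                             acq$voxel_spacing)
  b <- acq$dwi_b_values
  s_lesion <- ivim_forward(b, acq$baseline, truth$d, truth$dstar, truth$f)
  s_bg <- acq$baseline * exp(-b * background_d)
  nb <- length(b)
  nvox <- prod(acq$grid_shape)
  vol <- array(0, c(acq$grid_shape, nb))
  idx <- which(mask$data)
  for (j in seq_len(nb)) {
    vol[, , , j] <- s_bg[j]
    vol[idx + (j - 1L) * nvox] <- s_lesion[j]
  }
  if (acq$noise_sigma > 0) {
    old <- .Random.seed_save(seed)
    on.exit(.Random.seed_restore(old))
    vol <- vol + stats::rnorm(length(vol), 0, acq$noise_sigma * acq$baseline)
  }
  dynamic_series(vol, bvalues = b, spacing = acq$voxel_spacing)
}

# Save/set and restore the RNG state so simulators are reproducible without
# clobbering the caller's stream.
.Random.seed_save <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Draw one lesion's parameters from the class distributions, resampling until
# the lesion_truth invariants hold (ve+vp<=1, dstar>d, fractions in [0,1]).
draw_lesion_truth <- function(class_label, params, grid_shape, spacing,
                              radii_range, center_jitter, max_attempts = 100L) {
  g <- function(p) stats::rnorm(1L, p[["mean"]], p[["sd"]])
  for (attempt in seq_len(max_attempts)) {
    ktrans <- max(g(params$ktrans), 1e-3)
    ve <- g(params$ve); vp <- g(params$vp)
    d <- g(params$d); dstar <- g(params$dstar); f <- g(params$f)
    radii <- stats::runif(3L, radii_range[1L], radii_range[2L])
    center <- round(grid_shape / 2) +
      round(stats::runif(3L, -center_jitter, center_jitter))
    ok <- ve > 0.01 && ve < 1 && vp > 0 && vp < 1 && ve + vp <= 1 &&
      d > 1e-5 && dstar > d && f >= 0 && f <= 1
    if (ok)
      return(lesion_truth(class_label, ktrans, ve, vp, d, dstar, f,
                          center, radii))
  }
  stop("could not draw admissible parameters for class ", class_label,
       " after ", max_attempts, " attempts")
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-lesion ground-truth parameters from the class distributions in
#' the [cohort_spec()], builds each lesion's mask, and simulates its DCE and
#' DWI series.  Fully reproducible given `spec$rng_seed`.
#'
#' @param spec A [cohort_spec()].
#' @param acq An [acquisition_spec()].
#' @param aif An [aif()] used for the DCE forward model.
#' @param simulate If `FALSE`, only truths and masks are generated (fast
#'   path for tests that do not need image data).
#' @return A list of class `phantom_cohort` with elements `lesions` (each a
#'   list with `id`, `truth`, `mask`, `dce`, `dwi`), `truth_table`
#'   (data.frame: lesion_id, class, ktrans, ve, vp, d, dstar, f, seed), and
#'   the generating `spec`/`acq`.
#' @export
make_cohort <- function(spec, acq = acquisition_spec(), aif = robustrad::aif(),
                        simulate = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(acq, "acquisition_spec"))
  old <- .Random.seed_save(spec$rng_seed)
  on.exit(.Random.seed_restore(old))
  classes <- rep(names(spec$n_per_class), spec$n_per_class)
  lesions <- vector("list", length(classes))
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    truth <- draw_lesion_truth(cl, spec$class_params[[cl]], acq$grid_shape,
                               acq$voxel_spacing, spec$radii_range,
                               spec$center_jitter)
    lesion_seed <- (spec$rng_seed + 7919L * i) %% .Machine$integer.max
    mask <- make_lesion_mask(acq$grid_shape, truth$center, truth$radii,
                             acq$voxel_spacing)
    les <- list(id = sprintf("lesion%03d", i), truth = truth, mask = mask,
                seed = lesion_seed)
    if (simulate) {
      les$dce <- simulate_dce_series(truth, acq, aif, mask = mask,
                                     seed = lesion_seed)
      les$dwi <- simulate_dwi_series(truth, acq, mask = mask,
                                     seed = lesion_seed + 1L)
    }
    lesions[[i]] <- les
    rows[[i]] <- data.frame(lesion_id = les$id, class = cl,
                            ktrans = truth$ktrans, ve = truth$ve,
                            vp = truth$vp, d = truth$d, dstar = truth$dstar,
                            f = truth$f, seed = lesion_seed)
  }
  structure(list(lesions = lesions, truth_table = do.call(rbind, rows),
                 spec = spec, acq = acq),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tab <- table(x$truth_table$class)
  cat(sprintf("<phantom_cohort> %d lesions (%s)\n", nrow(x$truth_table),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
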