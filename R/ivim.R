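#' IVIM biexponential forward model
#'
#' Signal under the intravoxel incoherent motion model with a separate
#' pseudo-diffusion term:
#' \deqn{S(b) = S_0 [ f e^{-b D^*} + (1 - f) e^{-b D} ].}
#'
#' @param b b-values in s/mm^2.
#' @param s0 Signal at b = 0.
#' @param d True diffusion coefficient, mm^2/s.
#' @param dstar Pseudo-diffusion coefficient, mm^2/s.
#' @param f Perfusion fraction in `[0, 1]`.
#' @return Signal values at `b`.
#' @export
ivim_forward <- function(b, s0, d, dstar, f) {
  s0 * (f * exp(-b * dstar) + (1 - f) * exp(-b * d))
}

# Segmented IVIM fit, vectorised across voxels.  S: nvox x nb positive
# signal matrix.  Returns a data.frame (one row per voxel).
ivim_fit_core <- function(S, b, b_split = 200, n_refine = 8L,
                          d_bounds = c(1e-5, 4e-3), dstar_max = 0.5) {
  hi <- b >= b_split
  bh <- b[hi]
  nvox <- nrow(S)
  s0 <- S[, b == 0, drop = FALSE][, 1L]
  d <- numeric(nvox); f <- numeric(nvox); dstar <- numeric(nvox)
  clipped <- logical(nvox); at_bound <- logical(nvox)
  corr <- matrix(0, nvox, sum(hi))       # estimated perfusion signal at hi b
  for (iter in seq_len(n_refine)) {
    Sh <- pmax(S[, hi, drop = FALSE] - corr, 1e-8 * s0)
    L <- log(Sh)
    # weighted log-linear fit, weights ~ S^2 (Gauss-Markov for additive
    # Gaussian noise after the log transform)
    W <- Sh^2
    sw <- rowSums(W)
    xw <- as.vector(W %*% bh) / sw
    yw <- rowSums(W * L) / sw
    dx <- sweep(matrix(bh, nvox, length(bh), byrow = TRUE), 1L, xw)
    sl <- rowSums(W * dx * sweep(L, 1L, yw)) / rowSums(W * dx^2)
    ic <- yw - sl * xw
    d <- -sl
    f <- 1 - exp(ic - log(s0))
    clipped <- d < d_bounds[1L] | d > d_bounds[2L] | f < 0 | f > 1
    d <- pmin(pmax(d, d_bounds[1L]), d_bounds[2L])
    f <- pmin(pmax(f, 0), 1)
    for (i in seq_len(nvox)) {
      if (f[i] > 0) {
        si <- S[i, ]
        rssf <- function(ds)
          sum((si - ivim_forward(b, s0[i], d[i], ds, f[i]))^2)
        opt <- stats::optimize(rssf, lower = d[i], upper = dstar_max,
                               tol = 1e-9)
        dstar[i] <- opt$minimum
        at_bound[i] <- dstar[i] <= d[i] * (1 + 1e-6) ||
          dstar[i] >= dstar_max * (1 - 1e-6)
      } else {
        dstar[i] <- d[i]; at_bound[i] <- TRUE
      }
    }
    if (iter < n_refine)
      corr <- (f * s0) * exp(-outer(dstar, bh))
  }
  rss <- vapply(seq_len(nvox), function(i)
    sum((S[i, ] - ivim_forward(b, s0[i], d[i], dstar[i], f[i]))^2),
    numeric(1))
  data.frame(d = d, dstar = dstar, f = f, s0 = s0, fit_rss = rss,
             clipped = clipped, at_bound = at_bound)
}

#' Segmented IVIM fit of one voxel signal
#'
#' Two-step segmented fit with iterative refinement, the standard strategy
#' for this b-value distribution:
#'
#' 1. Log-linear fit of S(b) over `b >= b_split` (where pseudo-diffusion has
#'    largely decayed) gives D and the intercept, whence
#'    `f = 1 - exp(intercept - log S(0))`.
#' 2. D* by one-dimensional bounded least squares on the full biexponential
#'    with D and f held fixed.
#' 3. The estimated perfusion signal `f S0 exp(-b D*)` is subtracted from
#'    the high-b segment and steps 1-2 repeated (`n_refine` passes),
#'    removing the residual perfusion contamination of the D estimate.
#'
#' Parameters are clipped to the physical bounds `D in [1e-5, 4e-3]`,
#' `D* in [D, 0.5]`, `f in [0, 1]` mm^2/s; clipping and bound-pinned D* are
#' flagged as non-converged.
#'
#' @param signal Positive signal values, one per b-value.
#' @param b b-values in s/mm^2 (>= 4 distinct values including 0).
#' @param b_split Threshold above which the signal is treated as
#'   monoexponential (default 200 s/mm^2, the natural gap in the 0-800 set).
#' @param n_refine Number of refinement passes (default 8).
#' @return List with `d`, `dstar`, `f`, `s0`, `fit_rss`, `converged`.
#' @export
fit_ivim <- function(signal, b, b_split = 200, n_refine = 8L) {
  if (length(signal) != length(b)) stop("signal/b length mismatch")
  if (length(unique(b)) < 4L || !(0 %in% b)) stop("need >= 4 b-values incl. 0")
  if (any(signal <= 0)) stop("non-positive signal")
  if (sum(b >= b_split) < 2L) stop("fewer than 2 b-values at or above b_split")
  r <- ivim_fit_core(matrix(signal, nrow = 1L), b, b_split, n_refine)
  list(d = r$d, dstar = r$dstar, f = r$f, s0 = r$s0, fit_rss = r$fit_rss,
       converged = !r$clipped && !r$at_bound)
}

#' Voxel-wise IVIM parametric maps
#'
#' Applies the segmented IVIM fit ([fit_ivim()]) in every masked voxel of a
#' multi-b-value DWI series, producing the three model-based maps D, DSTAR
#' and F.  Voxels with any non-positive signal are excluded and counted in
#' QC.
#'
#' @param series A DWI [dynamic_series()] (with `bvalues`).
#' @param mask A [mask3d()] on the same grid.
#' @param b_split See [fit_ivim()].
#' @return List with `maps` (named list of 3D arrays D, DSTAR, F) and `qc`
#'   (invalid-signal and clipped/non-converged voxel counts).
#' @export
ivim_maps <- function(series, mask, b_split = 200) {
  stopifnot(inherits(series, "dynamic_series"), !is.null(series$bvalues))
  stop_if_empty_mask(mask)
  check_same_grid(dim(series$data)[1:3], dim(mask$data))
  b <- series$bvalues
  idx <- which(mask$data)
  S <- matrix(series$data, nrow = prod(dim(mask$data)))[idx, , drop = FALSE]
  valid <- rowSums(S <= 0) == 0L
  if (!any(valid)) stop("all masked voxels have non-positive signal")
  r <- ivim_fit_core(S[valid, , drop = FALSE], b, b_split)
  shape <- dim(mask$data)
  mk <- function(v) { a <- array(NA_real_, shape); a[idx[valid]] <- v; a }
  list(maps = list(D = mk(r$d), DSTAR = mk(r$dstar), F = mk(r$f)),
       qc = list(n_voxels = length(idx), n_invalid = sum(!valid),
                 n_clipped = sum(r$clipped),
                 n_nonconverged = sum(r$clipped | r$at_bound)))
}
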