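#' Extended Tofts forward model
#'
#' Tissue contrast concentration under the extended Tofts model,
#' \deqn{C_t(t) = K^{trans} \int_0^t C_p(\tau) e^{-k_{ep}(t-\tau)} d\tau
#'       + v_p C_p(t), \qquad k_{ep} = K^{trans}/v_e,}
#' evaluated by numerically convergent convolution on a fine uniform grid
#' (stable trapezoidal recursion) and linearly interpolated at the requested
#' times.
#'
#' @param params List with `ktrans` (1/min), `ve` and `vp` (fractions).
#'   `ve = 0` is only admissible when `ktrans = 0`.
#' @param aif An [aif()].
#' @param times Sample times in seconds (need not be uniform).
#' @param dt_fine Fine-grid step in seconds for the convolution.
#' @return Numeric vector Ct at `times`, in mmol/L.
#' @export
tofts_forward <- function(params, aif, times, dt_fine = 0.5) {
  stopifnot(all(times >= 0))
  ktrans <- params$ktrans; ve <- params$ve; vp <- params$vp
  if (ktrans < 0) stop("ktrans must be >= 0")
  if (ve == 0 && ktrans > 0)
    stop("ve = 0 with ktrans > 0: rate constant kep undefined")
  cp_s <- aif_eval(aif, times)
  if (ktrans == 0) return(vp * cp_s)
  kep_s <- ktrans / ve / 60           # 1/s
  tf <- seq(0, max(times), by = dt_fine)
  if (tf[length(tf)] < max(times)) tf <- c(tf, max(times))
  cp_f <- aif_eval(aif, tf)
  I <- cpp_exp_conv(cp_f, dt_fine, kep_s)[, 1L]
  I_s <- stats::approx(tf, I, xout = times)$y
  (ktrans / 60) * I_s + vp * cp_s
}

# Precompute, for a fixed AIF and DCE time grid, everything the profiled
# voxel-wise fit needs: the convolution basis I_kep(t) over a log-spaced kep
# grid, the AIF at sample times, and the Gram components of the 2-column
# design [I_kep, Cp].
tofts_fit_basis <- function(aif, times, n_kep = 400L,
                            kep_range = c(1e-5, 0.35), dt_fine = 0.5) {
  kep <- exp(seq(log(kep_range[1L]), log(kep_range[2L]), length.out = n_kep))
  tf <- seq(0, max(times), by = dt_fine)
  if (tf[length(tf)] < max(times)) tf <- c(tf, max(times))
  cp_f <- aif_eval(aif, tf)
  If <- cpp_exp_conv(cp_f, dt_fine, kep)          # ntf x K
  idx <- vapply(times, function(t) which.min(abs(tf - t)), integer(1))
  # linear interpolation at sample times
  I <- apply(If, 2L, function(col) stats::approx(tf, col, xout = times)$y)
  I <- matrix(I, nrow = length(times))
  cp <- aif_eval(aif, times)
  list(times = times, kep = kep, I = I, cp = cp,
       G11 = colSums(I * I), G12 = colSums(I * cp), G22 = sum(cp * cp),
       tf = tf, cp_f = cp_f, dt_fine = dt_fine)
}

# Solve, for every (voxel, kep) pair, the nonnegative 2-variable least squares
# E ~ c1 * I_kep + c2 * Cp and return the best kep per voxel plus refined
# coefficients.  E: nvox x ntime matrix of enhancement curves.
profiled_tofts_fit <- function(E, basis, chunk = 2000L) {
  nvox <- nrow(E)
  K <- length(basis$kep)
  G11 <- basis$G11; G12 <- basis$G12; G22 <- basis$G22
  best_k <- integer(nvox); best_c1 <- best_c2 <- best_rss <- numeric(nvox)
  sse0 <- rowSums(E * E)
  for (start in seq(1L, nvox, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nvox)
    Ec <- E[rows, , drop = FALSE]
    B1 <- Ec %*% basis$I                     # n x K
    b2 <- as.vector(Ec %*% basis$cp)         # n
    n <- length(rows)
    G11m <- matrix(G11, n, K, byrow = TRUE)
    G12m <- matrix(G12, n, K, byrow = TRUE)
    det <- G11m * G22 - G12m^2
    det[det < 1e-300] <- 1e-300
    c1 <- (B1 * G22 - b2 * G12m) / det
    c2 <- (G11m * b2 - G12m * B1) / det
    # nonnegativity: fall back to the better of the two boundary solutions
    neg <- c1 < 0 | c2 < 0
    if (any(neg)) {
      c1b <- pmax(B1 / G11m, 0)              # c2 = 0 boundary
      c2b <- pmax(b2 / G22, 0)               # c1 = 0 boundary
      rss1 <- -(2 * c1b * B1 - c1b^2 * G11m)             # up to sse0
      rss2 <- -(2 * c2b * b2 - c2b^2 * G22)
      use1 <- rss1 <= rss2
      c1[neg] <- ifelse(use1[neg], c1b[neg], 0)
      c2[neg] <- ifelse(use1[neg], 0, matrix(c2b, n, K)[neg])
    }
    rss <- -(2 * (c1 * B1 + c2 * b2) -
               (c1^2 * G11m + 2 * c1 * c2 * G12m + c2^2 * G22))
    kbest <- max.col(-rss, ties.method = "first")
    pick <- cbind(seq_len(n), kbest)
    best_k[rows] <- kbest
    best_c1[rows] <- c1[pick]
    best_c2[rows] <- c2[pick]
    best_rss[rows] <- rss[pick] + sse0[rows]
    # parabolic refinement in log(kep) where an interior minimum exists
    refine <- which(kbest > 1L & kbest < K)
    for (i in refine) {
      kb <- kbest[i]
      r <- rss[i, (kb - 1L):(kb + 1L)]
      denom <- r[1L] - 2 * r[2L] + r[3L]
      if (denom > 0) {
        lk <- log(basis$kep[(kb - 1L):(kb + 1L)])
        shift <- 0.5 * (r[1L] - r[3L]) / denom * (lk[3L] - lk[1L]) / 2
        kep_new <- exp(lk[2L] + shift)
        sol <- tofts_solve_single(E[rows[i], ], basis, kep_new)
        if (sol$rss <= best_rss[rows[i]] + 1e-12) {
          best_k[rows[i]] <- NA_integer_
          best_c1[rows[i]] <- sol$c1
          best_c2[rows[i]] <- sol$c2
          best_rss[rows[i]] <- sol$rss
          attr(best_k, "kep_refined") <- c(attr(best_k, "kep_refined"),
                                           stats::setNames(kep_new, rows[i]))
        }
      }
    }
  }
  kep_hat <- ifelse(is.na(best_k), NA_real_, basis$kep[pmax(best_k, 1L)])
  ref <- attr(best_k, "kep_refined")
  if (!is.null(ref)) kep_hat[as.integer(names(ref))] <- ref
  list(kep = kep_hat, c1 = best_c1, c2 = best_c2, rss = best_rss,
       at_edge = !is.na(best_k) & (best_k == 1L | best_k == K))
}

# Exact 2-variable nonnegative LS at one kep value (fine-grid convolution).
tofts_solve_single <- function(e, basis, kep) {
  If <- cpp_exp_conv(basis$cp_f, basis$dt_fine, kep)[, 1L]
  I <- stats::approx(basis$tf, If, xout = basis$times)$y
  g11 <- sum(I * I); g12 <- sum(I * basis$cp); g22 <- basis$G22
  b1 <- sum(e * I); b2 <- sum(e * basis$cp)
  det <- g11 * g22 - g12^2
  if (det < 1e-300) det <- 1e-300
  c1 <- (b1 * g22 - b2 * g12) / det
  c2 <- (g11 * b2 - g12 * b1) / det
  if (c1 < 0 || c2 < 0) {
    c1a <- max(b1 / max(g11, 1e-300), 0)
    c2a <- max(b2 / max(g22, 1e-300), 0)
    r1 <- -(2 * c1a * b1 - c1a^2 * g11)
    r2 <- -(2 * c2a * b2 - c2a^2 * g22)
    if (r1 <= r2) { c1 <- c1a; c2 <- 0 } else { c1 <- 0; c2 <- c2a }
  }
  rss <- sum(e^2) - (2 * (c1 * b1 + c2 * b2) -
                       (c1^2 * g11 + 2 * c1 * c2 * g12 + c2^2 * g22))
  list(c1 = c1, c2 = c2, rss = rss)
}

#' Fit extended Tofts parameters to one enhancement curve
#'
#' Fits relative enhancement as `alpha * Ct(t)` (linear signal model) with a
#' profiled linear least-squares strategy: for each candidate rate constant
#' `kep` on a dense log-spaced grid, the model is linear in `Ktrans` and `vp`
#' and solved exactly under nonnegativity; the grid optimum is then refined
#' by parabolic interpolation in `log(kep)`.  Deterministic and seed-free.
#'
#' @param curve An [enhancement_curve()] or a numeric vector of relative
#'   enhancement values (then `times` must be given).
#' @param aif An [aif()].
#' @param times Sample times in seconds (ignored if `curve` is an
#'   enhancement_curve).
#' @param alpha Enhancement-to-concentration proportionality.
#' @param basis Optional precomputed fit basis (internal reuse).
#' @return List with `ktrans` (1/min), `ve`, `vp`, `fit_rss`, `converged`.
#' @export
fit_tofts <- function(curve, aif, times = NULL, alpha = 1, basis = NULL) {
  if (inherits(curve, "enhancement_curve")) {
    times <- curve$times; e <- curve$values
  } else e <- as.numeric(curve)
  if (is.null(times)) stop("`times` required")
  if (sum(times > 0) < 2L) stop("need at least 2 post-contrast frames")
  if (is.null(basis)) basis <- tofts_fit_basis(aif, times)
  fit <- profiled_tofts_fit(matrix(e, nrow = 1L), basis)
  tofts_params_from_fit(fit, alpha)[1L, , drop = TRUE]
}

# Map profiled-fit coefficients back to Tofts parameters, applying the
# parameter bounds (ve, vp in [0,1]; ktrans capped at a physiological upper
# bound so noise-driven background fits stay on a sane scale); returns a
# data.frame.
tofts_params_from_fit <- function(fit, alpha, ktrans_max = 2) {
  ktrans_s <- fit$c1 / alpha                 # 1/s
  ktrans <- ktrans_s * 60                    # 1/min
  ve <- ifelse(ktrans_s > 0, ktrans_s / fit$kep, 0)
  vp <- fit$c2 / alpha
  clipped <- ve > 1 | vp > 1 | ktrans > ktrans_max
  ktrans <- pmin(ktrans, ktrans_max)
  ve <- pmin(ve, 1); vp <- pmin(vp, 1)
  data.frame(ktrans = ktrans, ve = ve, vp = vp, fit_rss = fit$rss,
             converged = !(clipped | fit$at_edge & ktrans > 1e-6))
}

#' Voxel-wise extended Tofts maps
#'
#' Fits [fit_tofts()] in every masked voxel of a DCE series and assembles the
#' three model-based parametric maps KTRANS (1/min), VE and VP (fractions).
#' Voxels with non-positive pre-contrast signal are excluded and counted in
#' the QC summary; non-converged (bound-clipped) voxels carry their clipped
#' values and a QC flag.
#'
#' @param series A DCE [dynamic_series()].
#' @param mask A [mask3d()] on the same grid.
#' @param aif An [aif()].
#' @param alpha Enhancement-to-concentration proportionality.
#' @return A `parametric_maps` list with elements `maps` (named list of 3D
#'   arrays: KTRANS, VE, VP), and `qc` (invalid and non-converged counts).
#' @export
fit_tofts_maps <- function(series, mask, aif, alpha = 1) {
  stopifnot(inherits(series, "dynamic_series"), !is.null(series$times))
  stop_if_empty_mask(mask)
  check_same_grid(dim(series$data)[1:3], dim(mask$data))
  times <- series$times
  if (sum(times > 0) < 2L) stop("need at least 2 post-contrast frames")
  idx <- which(mask$data)
  nf <- length(times)
  nvoxgrid <- prod(dim(mask$data))
  S <- matrix(series$data, nrow = nvoxgrid, ncol = nf)[idx, , drop = FALSE]
  s0 <- S[, 1L]
  valid <- s0 > 0
  if (!any(valid)) stop("all masked voxels have non-positive baseline signal")
  E <- sweep(S[valid, , drop = FALSE], 1L, s0[valid], "/") - 1
  basis <- tofts_fit_basis(aif, times)
  fit <- profiled_tofts_fit(E, basis)
  par <- tofts_params_from_fit(fit, alpha)
  shape <- dim(mask$data)
  mk <- function(v) { a <- array(NA_real_, shape); a[idx[valid]] <- v; a }
  list(maps = list(KTRANS = mk(par$ktrans), VE = mk(par$ve), VP = mk(par$vp)),
       qc = list(n_voxels = length(idx),
                 n_invalid = sum(!valid),
                 n_nonconverged = sum(!par$converged)))
}
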