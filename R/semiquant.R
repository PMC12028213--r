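#' Relative enhancement curve of one voxel
#'
#' E(t) = (S(t) - S0) / S0 with S0 the pre-contrast (frame 1) intensity, so
#' E(0) = 0 by construction.
#'
#' @param series A DCE [dynamic_series()].
#' @param voxel Integer voxel index, length 3 (1-based).
#' @return An object of class `enhancement_curve` with `times`, `values` and
#'   `s0`.  Errors if S0 <= 0 (such voxels are excluded from maps and counted
#'   in QC there).
#' @export
enhancement_curve <- function(series, voxel) {
  stopifnot(inherits(series, "dynamic_series"), !is.null(series$times),
            length(voxel) == 3L)
  s <- series$data[voxel[1L], voxel[2L], voxel[3L], ]
  s0 <- s[1L]
  if (s0 <= 0) stop("pre-contrast signal is non-positive at this voxel")
  structure(list(times = series$times, values = s / s0 - 1, s0 = s0),
            class = "enhancement_curve")
}

# Semi-quantitative descriptors of one enhancement curve (vectorised core).
# E: nvox x nframes matrix of relative enhancement; times: frame seconds
# (times[1] = 0 is the pre-contrast frame).  Returns a data.frame.
semiquant_from_E <- function(E, times, wio_cap = 1e6) {
  nf <- length(times)
  post <- 2:nf
  Epost <- E[, post, drop = FALSE]
  # peak over post-contrast frames, earliest-time tie-break
  peak_j <- max.col(Epost, ties.method = "first")
  pick <- cbind(seq_len(nrow(E)), peak_j)
  e_peak <- pmax(Epost[pick], 0)
  t_peak <- times[post][peak_j]
  e_last <- E[, nf]
  t_last <- times[nf]
  mre <- e_peak * 100
  ttp <- t_peak - times[2L]                      # s from first post frame
  dt1 <- times[2L] - times[1L]
  wis <- ifelse(ttp > 0, mre / ttp, mre / dt1)    # %/s wash-in chord
  at_last <- t_peak >= t_last
  wos <- ifelse(at_last, 0, (e_peak - e_last) / (t_last - t_peak) * 100)
  wos <- pmax(wos, 0)
  # clamp to [0, 1]: e_last < 0 (noise undershoot) means complete washout
  wor <- ifelse(e_peak > 0, pmin(pmax(e_peak - e_last, 0) / e_peak, 1), 0)
  wio <- ifelse(wos > 0, wis / wos, ifelse(wis == 0, 0, wio_cap))
  data.frame(MRE = mre, TTP = ttp, WIS = wis, WOS = wos, WOR = wor,
             WIO = wio, capped = wos <= 0 & wis > 0)
}

#' Model-free DCE parametric maps
#'
#' Computes, voxel-by-voxel inside the mask, the six semi-quantitative DCE
#' descriptors:
#'
#' * `MRE` — maximum relative enhancement, percent: `max_t E(t) * 100`.
#' * `TTP` — time to peak in seconds, measured from the first post-contrast
#'   frame; the peak is the global post-contrast maximum of E, ties broken
#'   by earliest time.
#' * `WIS` — wash-in slope, %/s: the chord `MRE / TTP` (chord from the
#'   pre-contrast frame when the peak is the first post-contrast frame).
#' * `WOS` — wash-out slope, %/s: chord from peak to the final frame,
#'   `(E_peak - E_last) / (t_last - t_peak) * 100`, 0 when the peak is the
#'   last frame.
#' * `WOR` — wash-out ratio, `(E_peak - E_last)/E_peak`, clamped to `[0, 1]`
#'   (0 for flat curves; 1 when noise drives the last frame below baseline).
#' * `WIO` — wash-in/wash-out slope ratio `WIS/WOS`; voxels with no washout
#'   (`WOS = 0`, `WIS > 0`) are set to the finite sentinel `wio_cap` and
#'   counted in QC so downstream feature extraction sees finite maps.
#'
#' @param series A DCE [dynamic_series()].
#' @param mask A [mask3d()] on the same grid.
#' @param wio_cap Sentinel value for WIO when WOS = 0 (default 1e6).
#' @return List with `maps` (named list of six 3D arrays) and `qc` (invalid
#'   and sentinel-capped voxel counts).
#' @export
model_free_maps <- function(series, mask, wio_cap = 1e6) {
  stopifnot(inherits(series, "dynamic_series"), !is.null(series$times))
  stop_if_empty_mask(mask)
  check_same_grid(dim(series$data)[1:3], dim(mask$data))
  times <- series$times
  idx <- which(mask$data)
  S <- matrix(series$data, nrow = prod(dim(mask$data)))[idx, , drop = FALSE]
  s0 <- S[, 1L]
  valid <- s0 > 0
  if (!any(valid)) stop("all masked voxels invalid (non-positive baseline)")
  E <- sweep(S[valid, , drop = FALSE], 1L, s0[valid], "/") - 1
  sq <- semiquant_from_E(E, times, wio_cap)
  shape <- dim(mask$data)
  mk <- function(v) { a <- array(NA_real_, shape); a[idx[valid]] <- v; a }
  list(maps = list(MRE = mk(sq$MRE), TTP = mk(sq$TTP), WIS = mk(sq$WIS),
                   WOS = mk(sq$WOS), WOR = mk(sq$WOR), WIO = mk(sq$WIO)),
       qc = list(n_voxels = length(idx), n_invalid = sum(!valid),
                 n_wio_capped = sum(sq$capped)))
}
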