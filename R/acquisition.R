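#' Acquisition specification for the synthetic phantom
#'
#' Describes the imaging protocol emulated by the phantom generator: a DCE
#' series of one pre-contrast plus `dce_n_frames - 1` post-contrast volumes at
#' `dce_dt`-second temporal resolution, and a DWI series over `dwi_b_values`.
#' Defaults mirror a 1.5 T head-and-neck protocol: 11 DCE frames at 38 s and
#' 11 b-values from 0 to 800 s/mm^2.
#'
#' @param dce_n_frames Number of DCE frames (pre + post), >= 2.
#' @param dce_dt DCE temporal resolution in seconds.
#' @param dwi_b_values Strictly increasing b-values in s/mm^2, first = 0.
#' @param grid_shape Integer voxel grid, length 3.  The default 64 x 64 x 32
#'   is a deliberately reduced matrix for desk-scale runtime.
#' @param voxel_spacing Voxel spacing in mm, length 3.
#' @param noise_sigma Gaussian noise standard deviation as a fraction of the
#'   baseline signal, >= 0.
#' @param baseline Pre-contrast signal level in arbitrary units.
#' @param alpha Proportionality between relative enhancement and tissue
#'   contrast concentration (linear signal model), dimensionless.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(dce_n_frames = 11L,
                             dce_dt = 38,
                             dwi_b_values = c(0, 10, 20, 30, 50, 80, 100,
                                              200, 300, 400, 800),
                             grid_shape = c(64L, 64L, 32L),
                             voxel_spacing = c(1, 1, 3),
                             noise_sigma = 0.02,
                             baseline = 100,
                             alpha = 3) {
  dce_n_frames <- as.integer(dce_n_frames)
  if (dce_n_frames < 2L) stop("dce_n_frames must be >= 2")
  if (dce_dt <= 0) stop("dce_dt must be positive")
  if (dwi_b_values[1L] != 0) stop("first b-value must be 0")
  if (any(diff(dwi_b_values) <= 0)) stop("b-values must be strictly increasing")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (baseline <= 0) stop("baseline must be positive")
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  structure(list(dce_n_frames = dce_n_frames, dce_dt = dce_dt,
                 dwi_b_values = as.numeric(dwi_b_values),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 noise_sigma = noise_sigma, baseline = baseline,
                 alpha = alpha),
            class = "acquisition_spec")
}

#' DCE frame times of an acquisition
#' @param acq An [acquisition_spec()].
#' @return Seconds from the pre-contrast frame (frame 1 at t = 0).
#' @export
dce_times <- function(acq) (seq_len(acq$dce_n_frames) - 1) * acq$dce_dt

#' Ground-truth parameters of one synthetic lesion
#'
#' Holds the kinetic (extended Tofts) and diffusion (IVIM) parameters a
#' phantom lesion is simulated with, together with its geometry.  These are
#' the oracle values the map-fitting recovery tests check against.
#'
#' @param class_label One of `"adenoma"`, `"warthin"`, `"malignant"`.
#' @param ktrans Transfer constant in 1/min.
#' @param ve Extravascular extracellular volume fraction, in `[0, 1]`.
#' @param vp Plasma volume fraction, in `[0, 1]`; `ve + vp <= 1`.
#' @param d True diffusion coefficient in mm^2/s.
#' @param dstar Pseudo-diffusion coefficient in mm^2/s, `> d`.
#' @param f Perfusion fraction, in `[0, 1]`.
#' @param center Lesion center in 1-based voxel coordinates, length 3.
#' @param radii Ellipsoid radii in mm per axis, length 3; `min(radii) >= 5`
#'   (lesions at least 1 cm in diameter).
#' @return An object of class `lesion_truth`.
#' @export
lesion_truth <- function(class_label, ktrans, ve, vp, d, dstar, f,
                         center, radii) {
  class_label <- match.arg(class_label, c("adenoma", "warthin", "malignant"))
  if (ktrans < 0) stop("ktrans must be >= 0")
  if (ve < 0 || ve > 1 || vp < 0 || vp > 1) stop("ve and vp must lie in [0, 1]")
  if (ve + vp > 1) stop("ve + vp must be <= 1")
  if (!(d > 0)) stop("d must be positive")
  if (!(dstar > d)) stop("dstar must exceed d")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  stopifnot(length(center) == 3L, length(radii) == 3L)
  if (min(radii) < 5)
    stop("min(radii) must be >= 5 mm (lesion diameter >= 1 cm)")
  structure(list(class_label = class_label, ktrans = ktrans, ve = ve, vp = vp,
                 d = d, dstar = dstar, f = f,
                 center = as.numeric(center), radii = as.numeric(radii)),
            class = "lesion_truth")
}

#' Default per-class phantom parameter distributions
#'
#' Mean/sd pairs for each kinetic and diffusion parameter, per tumor class.
#' These are synthetic test fixtures chosen to make the three classes
#' separable for pipeline tests (adenoma: low Ktrans, high Ve, high D,
#' slow persistent enhancement; Warthin: high Ktrans, moderate washout,
#' high f; malignant: intermediate Ktrans but the lowest Ve -- hence the
#' fastest washout rate kep -- plus high Vp and low D); they are not
#' estimates from any patient population.
#'
#' @return Named list (by class) of named lists `list(mean=, sd=)` per
#'   parameter.
#' @export
default_class_params <- function() {
  list(
    adenoma = list(
      ktrans = c(mean = 0.08,    sd = 0.02),
      ve     = c(mean = 0.45,    sd = 0.08),
      vp     = c(mean = 0.02,    sd = 0.006),
      d      = c(mean = 1.6e-3,  sd = 0.12e-3),
      dstar  = c(mean = 12e-3,   sd = 2e-3),
      f      = c(mean = 0.06,    sd = 0.015)
    ),
    warthin = list(
      ktrans = c(mean = 0.45,    sd = 0.08),
      ve     = c(mean = 0.18,    sd = 0.04),
      vp     = c(mean = 0.04,    sd = 0.010),
      d      = c(mean = 1.05e-3, sd = 0.08e-3),
      dstar  = c(mean = 15e-3,   sd = 2.5e-3),
      f      = c(mean = 0.20,    sd = 0.025)
    ),
    malignant = list(
      ktrans = c(mean = 0.25,    sd = 0.06),
      ve     = c(mean = 0.06,    sd = 0.015),
      vp     = c(mean = 0.15,    sd = 0.015),
      d      = c(mean = 0.6e-3,  sd = 0.06e-3),
      dstar  = c(mean = 13e-3,   sd = 3e-3),
      f      = c(mean = 0.12,    sd = 0.03)
    )
  )
}

#' Cohort specification for the synthetic phantom
#'
#' The default cohort reproduces the study structure of 43 lesions in three
#' histological classes: 15 pleomorphic adenomas, 10 Warthin tumors and 18
#' malignant tumors (18 malignant vs 25 benign for the binary task).
#'
#' @param n_per_class Named integer vector with entries `adenoma`, `warthin`,
#'   `malignant`, all >= 1.
#' @param class_params Per-class parameter distributions, see
#'   [default_class_params()].
#' @param radii_range Range (mm) lesion ellipsoid radii are drawn from,
#'   uniformly per axis; minimum must be >= 5 mm.
#' @param center_jitter Maximum uniform jitter (voxels) of lesion centers
#'   around the grid center, per axis.
#' @param rng_seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(adenoma = 15L, warthin = 10L,
                                        malignant = 18L),
                        class_params = default_class_params(),
                        radii_range = c(5, 8),
                        center_jitter = c(3, 3, 1),
                        rng_seed = 20250417L) {
  need <- c("adenoma", "warthin", "malignant")
  if (!all(need %in% names(n_per_class)))
    stop("n_per_class must name adenoma, warthin and malignant")
  n_per_class <- vapply(n_per_class[need], as.integer, integer(1))
  if (any(n_per_class < 1L)) stop("all class counts must be >= 1")
  if (!all(need %in% names(class_params)))
    stop("class_params must cover all three classes")
  for (cl in need) {
    sds <- vapply(class_params[[cl]], function(p) p[["sd"]], numeric(1))
    if (any(sds < 0)) stop("parameter sds must be >= 0")
  }
  if (radii_range[1L] < 5) stop("radii_range minimum must be >= 5 mm")
  structure(list(n_per_class = n_per_class, class_params = class_params,
                 radii_range = as.numeric(radii_range),
                 center_jitter = as.numeric(center_jitter),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}
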