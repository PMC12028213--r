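#' Dynamic image series
#'
#' Container for a 4D image volume with a per-frame axis: acquisition times in
#' seconds for a dynamic contrast-enhanced (DCE) series, or b-values in
#' s/mm\eqn{^2} for a diffusion-weighted (DWI) series.  Exactly one of `times`
#' and `bvalues` must be given.
#'
#' @param data 4D numeric array, `dim = c(nx, ny, nz, nframes)`.
#' @param times Numeric vector of frame times in seconds (DCE), strictly
#'   increasing, first element 0.
#' @param bvalues Numeric vector of b-values in s/mm^2 (DWI), strictly
#'   increasing, first element 0.
#' @param spacing Voxel spacing in mm per axis, length 3.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, times = NULL, bvalues = NULL,
                           spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array")
  if (is.null(times) == is.null(bvalues))
    stop("exactly one of `times` and `bvalues` must be supplied")
  axis <- if (is.null(times)) bvalues else times
  if (length(axis) != dim(data)[4L])
    stop("frame axis length (", length(axis), ") does not match 4th dimension (",
         dim(data)[4L], ")")
  if (any(diff(axis) <= 0))
    stop("frame axis must be strictly increasing")
  if (axis[1L] != 0)
    stop("frame axis must start at 0")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, times = times, bvalues = bvalues,
                 spacing = as.numeric(spacing)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  kind <- if (is.null(x$times)) "DWI" else "DCE"
  d <- dim(x$data)
  cat(sprintf("<dynamic_series %s> %dx%dx%d voxels, %d frames, spacing %s mm\n",
              kind, d[1], d[2], d[3], d[4],
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Binary 3D lesion mask
#'
#' @param data 3D array coercible to logical; must be binary (0/1 or
#'   logical).
#' @param spacing Voxel spacing in mm per axis, length 3.
#' @return An object of class `mask3d` wrapping a logical array.
#' @export
mask3d <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  v <- as.vector(data)
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary (0/1)")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = array(as.logical(data), dim(data)),
                 spacing = as.numeric(spacing)),
            class = "mask3d")
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask3d> %dx%dx%d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A [mask3d()].
#' @return Integer voxel count.
#' @export
mask_volume <- function(mask) sum(mask$data)

# Voxel-index barycenter (centroid) of a mask, 1-based continuous coordinates.
mask_barycenter <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  colMeans(idx)
}

stop_if_empty_mask <- function(mask) {
  if (!any(mask$data)) stop("mask is empty")
  invisible(TRUE)
}

# check two grids agree
check_same_grid <- function(a_dim, b_dim, what = "mask") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("grid mismatch: image %s vs %s %s",
                 paste(a_dim, collapse = "x"),
                 paste(b_dim, collapse = "x"), what))
  invisible(TRUE)
}
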