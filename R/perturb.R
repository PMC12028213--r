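# ROI perturbation: the 15 artificial ROIs probing segmentation robustness
# (6 axial rotations, 2 dilations, 1 erosion, 6 one-voxel translations).

shift_array <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- seq_len(d[1L]); sy <- seq_len(d[2L]); sz <- seq_len(d[3L])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  kx <- fx >= 1 & fx <= d[1L]; ky <- fy >= 1 & fy <= d[2L]
  kz <- fz >= 1 & fz <= d[3L]
  out[sx[kx], sy[ky], sz[kz]] <- a[fx[kx], fy[ky], fz[kz]]
  out
}

# 3D structuring elements: connectivity 1 = 6-neighbour cross, connectivity
# 2 = 18-neighbourhood (faces + edges), as offset matrices incl. the center.
struct_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  if (connectivity == 1L) g[ord <= 1, , drop = FALSE]
  else if (connectivity == 2L) g[ord <= 2 & apply(abs(g), 1, max) <= 1, ,
                                 drop = FALSE]
  else stop("connectivity must be 1 or 2")
}

#' Rotate a mask in-plane about its barycenter
#'
#' Axial (in-plane) rotation applied slice by slice about the (x, y)
#' projection of the mask's 3D barycenter, computed in physical (mm)
#' coordinates.  The binary mask is resampled with bilinear interpolation
#' and re-binarised at 0.5 — the standard mask-rotation recipe, fixed here
#' so results are bit-stable.  Positive angles are counterclockwise in the
#' (x, y) index plane viewed from +z; clockwise rotations are negative
#' angles.
#'
#' @param mask A nonempty [mask3d()].
#' @param angle_degrees Rotation angle in degrees.
#' @return The rotated [mask3d()].  Errors if the rotated mask touches the
#'   grid border.
#' @export
rotate_mask <- function(mask, angle_degrees) {
  stop_if_empty_mask(mask)
  if (angle_degrees == 0) return(mask)
  d <- dim(mask$data)
  sp <- mask$spacing
  bc <- mask_barycenter(mask)
  cx <- bc[1L] * sp[1L]; cy <- bc[2L] * sp[2L]
  th <- -angle_degrees * pi / 180  # inverse map for output sampling
  co <- cos(th); si <- sin(th)
  xs <- seq_len(d[1L]) * sp[1L]; ys <- seq_len(d[2L]) * sp[2L]
  X <- matrix(xs, d[1L], d[2L]) - cx
  Y <- matrix(ys, d[1L], d[2L], byrow = TRUE) - cy
  SXm <- (co * X - si * Y + cx) / sp[1L]   # source index coords
  SYm <- (si * X + co * Y + cy) / sp[2L]
  i0 <- floor(SXm); j0 <- floor(SYm)
  fx <- SXm - i0; fy <- SYm - j0
  out <- array(FALSE, d)
  at <- function(sl, ii, jj) {
    v <- numeric(length(ii))
    ok <- ii >= 1 & ii <= d[1L] & jj >= 1 & jj <= d[2L]
    v[ok] <- sl[cbind(ii[ok], jj[ok])]
    v
  }
  for (z in seq_len(d[3L])) {
    sl <- mask$data[, , z] * 1
    if (!any(sl > 0)) next
    val <- at(sl, i0, j0) * (1 - fx) * (1 - fy) +
      at(sl, i0 + 1, j0) * fx * (1 - fy) +
      at(sl, i0, j0 + 1) * (1 - fx) * fy +
      at(sl, i0 + 1, j0 + 1) * fx * fy
    out[, , z] <- matrix(val, d[1L], d[2L]) >= 0.5
  }
  if (any(out[c(1L, d[1L]), , ]) || any(out[, c(1L, d[2L]), ]))
    stop("rotated mask exits the grid")
  mask3d(out, sp)
}

#' Morphological dilation and erosion of a mask
#'
#' One binary dilation (erosion) with the 3D structuring element of the
#' given connectivity: connectivity 1 is the 6-neighbour cross, connectivity
#' 2 the 18-neighbourhood.
#'
#' @param mask A nonempty [mask3d()].
#' @param connectivity 1 or 2 (dilation); erosion uses the 1-voxel cross.
#' @return The transformed [mask3d()].
#' @export
dilate_mask <- function(mask, connectivity = 1L) {
  stop_if_empty_mask(mask)
  off <- struct_offsets(as.integer(connectivity))
  acc <- array(FALSE, dim(mask$data))
  for (r in seq_len(nrow(off)))
    acc <- acc | shift_array(mask$data, off[r, 1L], off[r, 2L], off[r, 3L])
  mask3d(acc, mask$spacing)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask) {
  stop_if_empty_mask(mask)
  off <- struct_offsets(1L)
  acc <- array(TRUE, dim(mask$data))
  for (r in seq_len(nrow(off)))
    acc <- acc & shift_array(mask$data, off[r, 1L], off[r, 2L], off[r, 3L])
  if (!any(acc))
    stop("erosion empties the mask; lesions must exceed the structuring element")
  mask3d(acc, mask$spacing)
}

#' Translate a mask by one voxel
#'
#' Rigid shift of every mask voxel by exactly one voxel along one axis;
#' voxel count is preserved.  Errors if the shift would push the mask out of
#' the grid.
#'
#' @param mask A nonempty [mask3d()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param direction `+1` or `-1`.
#' @return The translated [mask3d()].
#' @export
translate_mask <- function(mask, axis = c("x", "y", "z"), direction = 1L) {
  stop_if_empty_mask(mask)
  axis <- match.arg(axis)
  if (!direction %in% c(-1L, 1L)) stop("direction must be +1 or -1")
  d <- dim(mask$data)
  ax <- match(axis, c("x", "y", "z"))
  idx <- which(mask$data, arr.ind = TRUE)
  rng <- range(idx[, ax])
  if ((direction > 0 && rng[2L] + 1 > d[ax]) ||
      (direction < 0 && rng[1L] - 1 < 1))
    stop("translation along ", axis, " exits the grid")
  sh <- c(0L, 0L, 0L); sh[ax] <- as.integer(direction)
  mask3d(shift_array(mask$data, sh[1L], sh[2L], sh[3L]), mask$spacing)
}

#' Generate the 15 artificial ROIs
#'
#' From a manually defined ROI, builds the fixed perturbation set probing
#' segmentation variability: axial rotations of 10, 20 and 30 degrees
#' clockwise and counterclockwise about the ROI barycenter (6 ROIs),
#' dilations with 3D structuring elements of connectivity 1 and 2 (2 ROIs),
#' a 1-voxel erosion (1 ROI), and 1-voxel translations along the three
#' orthogonal axes, forward and backward (6 ROIs).
#'
#' @param mask A nonempty [mask3d()] with >= 2 voxels clearance from the
#'   grid border.
#' @return An object of class `perturbation_set`: list with `original`,
#'   `variants` (named list of 15 [mask3d()]), and `provenance` (data.frame
#'   of transform parameters).
#' @export
generate_artificial_rois <- function(mask) {
  stop_if_empty_mask(mask)
  variants <- list()
  prov <- list()
  wrap <- function(name, kind, param, expr) {
    v <- tryCatch(expr, error = function(e)
      stop(sprintf("variant %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    variants[[name]] <<- v
    prov[[name]] <<- data.frame(variant = name, kind = kind, param = param)
  }
  for (a in c(10, 20, 30)) {
    wrap(sprintf("rot+%d", a), "rotation", a, rotate_mask(mask, a))
    wrap(sprintf("rot-%d", a), "rotation", -a, rotate_mask(mask, -a))
  }
  wrap("dil1", "dilation", 1, dilate_mask(mask, 1L))
  wrap("dil2", "dilation", 2, dilate_mask(mask, 2L))
  wrap("ero1", "erosion", 1, erode_mask(mask))
  for (ax in c("x", "y", "z")) {
    wrap(sprintf("t%s+1", ax), "translation", 1,
         translate_mask(mask, ax, 1L))
    wrap(sprintf("t%s-1", ax), "translation", -1,
         translate_mask(mask, ax, -1L))
  }
  stopifnot(length(variants) == 15L)
  structure(list(original = mask, variants = variants,
                 provenance = do.call(rbind, prov)),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat(sprintf("<perturbation_set> original %d voxels, %d variants\n",
              mask_volume(x$original), length(x$variants)))
  invisible(x)
}
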