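# NIfTI-1 I/O with JSON sidecars for the frame axis (times or b-values).
# Round-trip safe: write-then-read reproduces the array, spacing and sidecar
# exactly (data are stored as float64).

#' Write / read a dynamic series as NIfTI + JSON sidecar
#'
#' The 4D volume goes to `<path>` (NIfTI-1, gzipped if the name ends in
#' `.gz`); the frame axis and voxel spacing go to `<path stem>.json`.
#'
#' @param series A [dynamic_series()].
#' @param path Output file name (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (`write`); a [dynamic_series()] (`read`).
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$spacing, 1))
  RNifti::writeNifti(img, path, datatype = "double")
  side <- list(spacing = series$spacing)
  if (!is.null(series$times)) side$times <- series$times
  if (!is.null(series$bvalues)) side$bvalues <- series$bvalues
  jsonlite::write_json(side, sidecar_path(path), digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  dynamic_series(array(as.numeric(img), dim(img)),
                 times = side$times, bvalues = side$bvalues,
                 spacing = side$spacing)
}

#' Write / read a binary mask as NIfTI
#'
#' @param mask A [mask3d()].
#' @param path Output file name.
#' @return `path`, invisibly (`write`); a [mask3d()] (`read`).  Reading
#'   rejects non-binary volumes.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask3d"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)),
                         pixdim = c(mask$spacing, 1))
  RNifti::writeNifti(img, path, datatype = "uint8")
  jsonlite::write_json(list(spacing = mask$spacing), sidecar_path(path),
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  v <- as.numeric(img)
  if (!all(v %in% c(0, 1)))
    stop("mask file contains non-binary values: ", path)
  sp <- tryCatch(
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)$spacing,
    error = function(e) RNifti::pixdim(img)[1:3])
  mask3d(array(v, dim(img)), sp)
}

#' Write / read a parametric map as NIfTI
#' @param map 3D numeric array.
#' @param spacing Voxel spacing, mm.
#' @param path File name.
#' @return `path` invisibly (`write`); 3D array (`read`).
#' @export
write_map <- function(map, spacing, path) {
  img <- RNifti::asNifti(map, pixdim = c(spacing, 1))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a feature table CSV
#'
#' Rows: (lesion, ROI variant); columns: `lesion_id`, `roi_variant`, then
#' `93 * n_maps` features.  Reading validates the schema: the id columns
#' must be present and the feature count must be a multiple of 93.
#'
#' @param table Feature table from [extract_feature_table()].
#' @param path CSV file name.
#' @return `path` invisibly (`write`); the validated data.frame (`read`).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tb <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("lesion_id", "roi_variant") %in% names(tb)))
    stop("feature table must have lesion_id and roi_variant columns")
  nfeat <- ncol(tb) - 2L
  if (nfeat %% 93L != 0L)
    stop("feature table has ", nfeat,
         " feature columns; expected a multiple of 93")
  tb
}
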