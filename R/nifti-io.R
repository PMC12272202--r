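#' Read and write package objects as NIfTI-1 volumes
#'
#' Masks and label maps are stored as integer volumes, BOLD series as 4D
#' float volumes with the repetition time in `pixdim[4]`. The voxel size is
#' taken from the header `pixdim`; the origin from the `qoffset` fields when
#' present.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tr_s repetition time override in seconds; by default read from the
#'   header.
#' @return `read_bold_nifti()` a [bold4d()]; `read_mask_nifti()` a
#'   [brain_mask()]; `read_labels_nifti()` a [vessel_labels()].
#' @name nifti_io
NULL

nifti_grid <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  volume_grid(d[1:3], abs(hdr$pixdim[2:4]),
              c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

nifti_from <- function(arr, grid, tr_s = 0) {
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(-1, grid$vox_mm, tr_s, 0, 0, 0),
    qoffset_x = grid$origin[1], qoffset_y = grid$origin[2],
    qoffset_z = grid$origin[3],
    xyzt_units = 10L))
  RNifti::asNifti(arr, reference = hdr)
}

#' @rdname nifti_io
#' @export
read_bold_nifti <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D NIfTI volume: ", path)
  grid <- nifti_grid(img)
  if (is.null(tr_s)) {
    tr_s <- RNifti::niftiHeader(img)$pixdim[5]
    if (!is.finite(tr_s) || tr_s <= 0) {
      stop("no usable TR in NIfTI header; pass tr_s explicitly")
    }
  }
  bold4d(array(as.numeric(img), dim(img)), grid, tr_s)
}

#' @rdname nifti_io
#' @param bold a [bold4d()] object.
#' @export
write_bold_nifti <- function(bold, path) {
  RNifti::writeNifti(nifti_from(bold$data, bold$grid, bold$tr_s), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  brain_mask(array(as.numeric(img) != 0, dim(img)), nifti_grid(img))
}

#' @rdname nifti_io
#' @param mask a [brain_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(as.integer(unclass(mask)), dim(unclass(mask)))
  RNifti::writeNifti(nifti_from(arr, mask_grid(mask)), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  vessel_labels(array(as.integer(img), dim(img)), nifti_grid(img))
}

#' @rdname nifti_io
#' @param labels a [vessel_labels()] map.
#' @export
write_labels_nifti <- function(labels, path) {
  arr <- array(as.integer(unclass(labels)), dim(unclass(labels)))
  RNifti::writeNifti(nifti_from(arr, attr(labels, "grid")), path)
  invisible(path)
}

#' @rdname nifti_io
#' @param vol numeric 3D array to write as a scalar map.
#' @param grid a [volume_grid()].
#' @export
write_volume_nifti <- function(vol, grid, path) {
  RNifti::writeNifti(nifti_from(vol, grid), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  list(data = array(as.numeric(img), dim(img)), grid = nifti_grid(img))
}
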