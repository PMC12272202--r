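#' Volume grid: the shared spatial frame of all images in an analysis
#'
#' A `volume_grid` records the array dimensions, voxel size in mm and origin
#' (mm offset of voxel (1,1,1)) that every image entering a joint computation
#' must agree on. Grids are compared by dimensions plus affine parameters
#' within a small tolerance, so images written and re-read through NIfTI
#' headers still match.
#'
#' @param dim integer vector of length 3, array dimensions in voxels.
#' @param vox_mm positive numeric vector of length 3, voxel edge lengths (mm).
#' @param origin numeric vector of length 3, position of the first voxel (mm).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(24, 24, 16), c(4, 4, 4))
#' g
#' @export
volume_grid <- function(dim, vox_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  vox_mm <- as.numeric(vox_mm)
  origin <- as.numeric(origin)
  stopifnot(length(dim) == 3L, length(vox_mm) == 3L, length(origin) == 3L)
  if (any(dim < 1L)) stop("grid dimensions must be positive")
  if (any(!is.finite(vox_mm)) || any(vox_mm <= 0)) {
    stop("voxel sizes must be positive and finite")
  }
  structure(list(dim = dim, vox_mm = vox_mm, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels @ %g x %g x %g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$vox_mm[1], x$vox_mm[2], x$vox_mm[3]))
  invisible(x)
}

# Grid agreement within an affine tolerance (1e-4 mm); dimensions exact.
grids_equal <- function(a, b, tol = 1e-4) {
  identical(a$dim, b$dim) &&
    all(abs(a$vox_mm - b$vox_mm) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_grid_mismatch <- function(what, a, b) {
  stop(sprintf(
    "%s: grid mismatch (%s vs %s)", what,
    paste(a$dim, collapse = "x"), paste(b$dim, collapse = "x")),
    call. = FALSE)
}

#' Binary brain/tissue/vessel mask on a volume grid
#'
#' @param data logical (or coercible) 3D array matching `grid$dim`.
#' @param grid a [volume_grid()].
#' @return An object of class `brain_mask`: a logical array with the grid
#'   attached as an attribute.
#' @examples
#' g <- volume_grid(c(8, 8, 4))
#' m <- brain_mask(array(FALSE, g$dim), g)
#' mask_count(m)
#' @export
brain_mask <- function(data, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- array(as.logical(data), dim = dim(data))
  if (!identical(dim(data), as.integer(grid$dim))) {
    stop("mask data dimensions do not match grid")
  }
  if (anyNA(data)) stop("mask contains NA values")
  structure(data, grid = grid, class = "brain_mask")
}

#' @rdname brain_mask
#' @param x a `brain_mask`.
#' @export
mask_count <- function(x) sum(unclass(x))

#' @export
print.brain_mask <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("brain_mask: %d/%d voxels set on %s grid\n",
              mask_count(x), prod(g$dim), paste(g$dim, collapse = "x")))
  invisible(x)
}

mask_grid <- function(x) attr(x, "grid")

# Linear voxel indices of set voxels (column-major, 1-based).
mask_indices <- function(x) which(unclass(x))

# Rebuild a mask from linear indices.
mask_from_indices <- function(idx, grid) {
  a <- array(FALSE, grid$dim)
  a[idx] <- TRUE
  brain_mask(a, grid)
}

mask_and <- function(a, b) {
  g <- mask_grid(a)
  if (!grids_equal(g, mask_grid(b))) stop_grid_mismatch("mask_and", g, mask_grid(b))
  brain_mask(unclass(a) & unclass(b), g)
}

mask_or <- function(a, b) {
  g <- mask_grid(a)
  if (!grids_equal(g, mask_grid(b))) stop_grid_mismatch("mask_or", g, mask_grid(b))
  brain_mask(unclass(a) | unclass(b), g)
}

mask_diff <- function(a, b) {
  g <- mask_grid(a)
  if (!grids_equal(g, mask_grid(b))) stop_grid_mismatch("mask_diff", g, mask_grid(b))
  brain_mask(unclass(a) & !unclass(b), g)
}

#' Integer-labeled artery/vein map
#'
#' Label convention: 0 = background, 1 = artery, 2 = vein.
#'
#' @param data integer 3D array of labels in \{0, 1, 2\}.
#' @param grid a [volume_grid()].
#' @return An object of class `vessel_labels`.
#' @export
vessel_labels <- function(data, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- array(as.integer(data), dim = dim(data))
  if (!identical(dim(data), as.integer(grid$dim))) {
    stop("label data dimensions do not match grid")
  }
  if (!all(data %in% 0:2)) stop("vessel labels must be 0 (bg), 1 (artery) or 2 (vein)")
  structure(data, grid = grid, class = "vessel_labels")
}

#' @export
print.vessel_labels <- function(x, ...) {
  cat(sprintf("vessel_labels: %d artery, %d vein voxels\n",
              sum(unclass(x) == 1L), sum(unclass(x) == 2L)))
  invisible(x)
}

#' Extract the artery or vein compartment of a label map as a mask
#'
#' @param labels a [vessel_labels()] map.
#' @param type `"artery"` or `"vein"`.
#' @return A [brain_mask()].
#' @export
label_mask <- function(labels, type = c("artery", "vein")) {
  type <- match.arg(type)
  code <- if (type == "artery") 1L else 2L
  brain_mask(unclass(labels) == code, attr(labels, "grid"))
}

#' 4D BOLD time series with repetition time
#'
#' @param data numeric 4D array (x, y, z, time); all values must be finite.
#' @param grid a [volume_grid()] matching the first three dimensions.
#' @param tr_s repetition time in seconds (positive).
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, grid, tr_s) {
  stopifnot(inherits(grid, "volume_grid"), length(dim(data)) == 4L)
  if (!identical(dim(data)[1:3], as.integer(grid$dim))) {
    stop("BOLD spatial dimensions do not match grid")
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0) {
    stop("tr_s must be a positive number")
  }
  if (any(!is.finite(data))) stop("BOLD data contain non-finite values")
  structure(list(data = data, grid = grid, tr_s = as.numeric(tr_s),
                 n_volumes = dim(data)[4]),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("bold4d: %s grid, %d volumes, TR = %g s\n",
              paste(x$grid$dim, collapse = "x"), x$n_volumes, x$tr_s))
  invisible(x)
}

# Voxels x time matrix for a set of linear voxel indices.
bold_matrix <- function(bold, idx) {
  nt <- bold$n_volumes
  nvox <- prod(bold$grid$dim)
  m <- matrix(bold$data, nrow = nvox, ncol = nt)[idx, , drop = FALSE]
  m
}
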