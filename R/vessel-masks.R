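#' @name vessel_masks
#' @title Vessel-mask engineering
#' @description Fuse multi-orientation vessel segmentations, resample them to
#'   the fMRI grid, split artery from vein with a label map, restrict to gray
#'   matter and build perivascular shells by dilation and subtraction.
NULL

neighborhood_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26")
  }
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  ord <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(off)))
  as.matrix(off[keep, ])
}

# One binary dilation step with the chosen 3D neighborhood, via array shifts.
dilate_array <- function(a, connectivity = 26L) {
  d <- dim(a)
  out <- a
  for (i in seq_len(nrow(off <- neighborhood_offsets(connectivity)))) {
    s <- off[i, ]
    xs <- max(1, 1 + s[1]):min(d[1], d[1] + s[1])
    ys <- max(1, 1 + s[2]):min(d[2], d[2] + s[2])
    zs <- max(1, 1 + s[3]):min(d[3], d[3] + s[3])
    out[xs, ys, zs] <- out[xs, ys, zs] | a[xs - s[1], ys - s[2], zs - s[3]]
  }
  out
}

#' Morphological dilation of a mask
#'
#' @param mask a [brain_mask()].
#' @param k number of dilation steps (nonnegative integer).
#' @param connectivity 3D structuring element: 6 (faces), 18 (faces + edges)
#'   or 26 (full cube, the default, matching a 1-voxel dilation "in 3D").
#' @return The dilated [brain_mask()].
#' @export
dilate_mask <- function(mask, k = 1L, connectivity = 26L) {
  a <- unclass(mask)
  k <- as.integer(k)
  stopifnot(k >= 0L)
  for (i in seq_len(k)) a <- dilate_array(a, connectivity)
  brain_mask(a, mask_grid(mask))
}

#' Fuse vessel segmentations from multiple acquisitions
#'
#' Segmentations from different encoding directions are summed and then
#' binarized: a voxel is vessel in the fused mask iff it is vessel in at
#' least one input.
#'
#' @param masks non-empty list of [brain_mask()] objects on one grid.
#' @return The fused [brain_mask()].
#' @export
combine_segmentations <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("combine_segmentations needs a non-empty list of masks")
  }
  g <- mask_grid(masks[[1]])
  acc <- array(0L, g$dim)
  for (i in seq_along(masks)) {
    gi <- mask_grid(masks[[i]])
    if (!grids_equal(g, gi)) {
      stop(sprintf("combine_segmentations: input %d is on a different grid (%s vs %s)",
                   i, paste(gi$dim, collapse = "x"), paste(g$dim, collapse = "x")),
           call. = FALSE)
    }
    acc <- acc + unclass(masks[[i]])
  }
  brain_mask(acc > 0L, g)
}

#' Downsample a binary mask to a coarser grid
#'
#' The source grid must tile the target grid by an integer factor per axis
#' (the native angiogram-to-fMRI relation after registration). Each target
#' voxel covers a block of source voxels; it is set when the occupied
#' fraction of that block reaches `occupancy_min`, or, with the default
#' `"any"` policy, when any source voxel in the block is set. The permissive
#' default keeps 1-voxel-thin vessels alive through binarization.
#'
#' @param mask a [brain_mask()] on the fine grid.
#' @param target a [volume_grid()], coarser than the source by integer
#'   factors.
#' @param occupancy_min either the string `"any"` or a number in (0, 1].
#' @return A [brain_mask()] on `target`.
#' @export
downsample_mask <- function(mask, target, occupancy_min = "any") {
  g <- mask_grid(mask)
  fac <- g$dim / target$dim
  if (any(abs(fac - round(fac)) > 1e-8) || any(fac < 1)) {
    stop("downsample_mask: target grid must divide the source dimensions")
  }
  fac <- as.integer(round(fac))
  if (any(abs(g$vox_mm * fac - target$vox_mm) > 1e-4) ||
      any(abs(g$origin - target$origin) > 1e-4)) {
    stop("downsample_mask: grids are not nested (voxel sizes or origins disagree)")
  }
  if (is.character(occupancy_min)) {
    if (occupancy_min != "any") stop("occupancy_min must be 'any' or a number in (0, 1]")
  } else if (!is.numeric(occupancy_min) || occupancy_min <= 0 || occupancy_min > 1) {
    stop("occupancy_min must be 'any' or a number in (0, 1]")
  }
  a <- unclass(mask)
  # Block-sum by folding each axis: reshape so the fine factor is a separate
  # dimension, then sum it out.
  x <- array(as.numeric(a), c(fac[1], target$dim[1], fac[2], target$dim[2],
                              fac[3], target$dim[3]))
  frac <- apply(x, c(2, 4, 6), sum) / prod(fac)
  set <- if (identical(occupancy_min, "any")) frac > 0 else frac >= occupancy_min
  brain_mask(set, target)
}

#' Split a fused vessel mask into arterial and venous compartments
#'
#' Every vessel voxel must carry a nonzero artery/vein label; the two outputs
#' partition the input.
#'
#' @param mask a fused vessel [brain_mask()].
#' @param labels a [vessel_labels()] map on the same grid.
#' @return A list with [brain_mask()] elements `arterial` and `venous`.
#' @export
split_by_label <- function(mask, labels) {
  g <- mask_grid(mask)
  if (!grids_equal(g, attr(labels, "grid"))) {
    stop_grid_mismatch("split_by_label", g, attr(labels, "grid"))
  }
  a <- unclass(mask)
  lab <- unclass(labels)
  bad <- which(a & lab == 0L)
  if (length(bad)) {
    coords <- arrayInd(bad[seq_len(min(10L, length(bad)))], g$dim)
    stop(sprintf(
      "split_by_label: %d vessel voxels are unlabeled, e.g. (%s)",
      length(bad),
      paste(apply(coords, 1, paste, collapse = ","), collapse = "), (")),
      call. = FALSE)
  }
  list(arterial = brain_mask(a & lab == 1L, g),
       venous = brain_mask(a & lab == 2L, g))
}

#' Restrict a vessel mask to gray matter
#'
#' @param mask a [brain_mask()].
#' @param gm the gray-matter [brain_mask()] on the same grid.
#' @return The intersection as a [brain_mask()].
#' @export
restrict_to_gm <- function(mask, gm) {
  g <- mask_grid(mask)
  if (!grids_equal(g, mask_grid(gm))) stop_grid_mismatch("restrict_to_gm", g, mask_grid(gm))
  mask_and(mask, gm)
}

#' Build perivascular shells around a vessel mask
#'
#' Shell `k` holds the voxels first reached by the k-th dilation of the
#' source mask: dilate by one voxel in 3D, subtract the previous extent,
#' repeat. With the 26-connected (cube) element this is the set of voxels at
#' Chebyshev distance `k`; with the 6-connected (cross) element, city-block
#' distance `k`. Shells are pairwise disjoint and disjoint from the source.
#' When `exclude` is given (typically the union of arterial and venous
#' voxels), its voxels are removed from every shell, so an artery's shell
#' never contains vein voxels; `within` (typically the brain mask) clips
#' shells to tissue.
#'
#' @param mask the non-empty source [brain_mask()].
#' @param K number of shells (>= 1).
#' @param connectivity 6, 18 or 26 (default).
#' @param exclude optional [brain_mask()] of voxels barred from all shells.
#' @param within optional [brain_mask()] the shells are clipped to.
#' @return An object of class `shell_set`: list with `source`, `shells`
#'   (list of [brain_mask()] at distances `1..K`), `connectivity`, `K`.
#' @export
make_shells <- function(mask, K = 3L, connectivity = 26L,
                        exclude = NULL, within = NULL) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1")
  if (mask_count(mask) == 0L) stop("make_shells: source mask is empty")
  g <- mask_grid(mask)
  cur <- unclass(mask)
  shells <- vector("list", K)
  for (k in seq_len(K)) {
    nxt <- dilate_array(cur, connectivity)
    sh <- nxt & !cur
    if (!is.null(exclude)) sh <- sh & !unclass(exclude)
    if (!is.null(within)) sh <- sh & unclass(within)
    shells[[k]] <- brain_mask(sh, g)
    cur <- nxt
  }
  structure(list(source = mask, shells = shells,
                 connectivity = as.integer(connectivity), K = K),
            class = "shell_set")
}

#' @export
print.shell_set <- function(x, ...) {
  cat(sprintf("shell_set: %d shells (%d-connected), sizes %s; source %d voxels\n",
              x$K, x$connectivity,
              paste(vapply(x$shells, mask_count, 0L), collapse = ", "),
              mask_count(x$source)))
  invisible(x)
}
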