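#' @name preprocess
#' @title Minimal BOLD preprocessing
#' @description The three in-scope stages, applied in the conventional order:
#'   (1) regression of mean WM and CSF signals, (2) 0.01-0.1 Hz bandpass,
#'   (3) spatial Gaussian smoothing. Inputs are assumed already
#'   motion-corrected and coregistered.
NULL

#' Regress region-mean nuisance signals out of a BOLD series
#'
#' Fits, per voxel, an ordinary least-squares model on an intercept plus the
#' mean time series of each supplied region (typically WM and CSF) and
#' returns the residuals. Collinear regressors are dropped with a warning
#' rather than failing.
#'
#' @param bold a [bold4d()].
#' @param region_masks named list of non-empty [brain_mask()] objects on
#'   `bold`'s grid.
#' @return A [bold4d()] of residuals.
#' @export
regress_nuisance <- function(bold, region_masks) {
  stopifnot(inherits(bold, "bold4d"), is.list(region_masks),
            length(region_masks) >= 1L)
  nt <- bold$n_volumes
  regs <- matrix(0, nt, length(region_masks))
  for (i in seq_along(region_masks)) {
    m <- region_masks[[i]]
    if (!grids_equal(bold$grid, mask_grid(m))) {
      stop_grid_mismatch("regress_nuisance", bold$grid, mask_grid(m))
    }
    if (mask_count(m) == 0L) {
      stop(sprintf("regress_nuisance: region mask %s is empty",
                   names(region_masks)[i] %||% i), call. = FALSE)
    }
    regs[, i] <- colMeans(bold_matrix(bold, mask_indices(m)))
  }
  X <- cbind(1, regs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf("regress_nuisance: dropping %d collinear regressor(s)",
                    ncol(X) - qrX$rank))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  nvox <- prod(bold$grid$dim)
  Y <- t(matrix(bold$data, nvox, nt))         # time x voxels
  res <- qr.resid(qrX, Y)
  bold4d(array(t(res), c(bold$grid$dim, nt)), bold$grid, bold$tr_s)
}

#' Temporal bandpass filter
#'
#' Projects every voxel time series onto the subspace spanned by the
#' in-band Fourier basis vectors (DFT bins with `f_lo <= f <= f_hi`; DC is
#' always excluded), after orthogonalizing that basis against a linear
#' trend. Being an orthogonal projection, the filter has an exactly bounded
#' passband, no phase distortion, removes constants and drift entirely, and
#' is idempotent: applying it twice equals applying it once.
#'
#' @param bold a [bold4d()].
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= 1/(2 tr_s)`.
#' @return The filtered [bold4d()]; every voxel mean is zero.
#' @export
bandpass <- function(bold, f_lo = 0.01, f_hi = 0.1) {
  stopifnot(inherits(bold, "bold4d"))
  nyq <- 1 / (2 * bold$tr_s)
  if (!(f_lo >= 0 && f_lo < f_hi)) stop("need 0 <= f_lo < f_hi")
  if (f_hi > nyq + 1e-12) {
    stop(sprintf("f_hi = %g Hz exceeds the Nyquist frequency %g Hz at TR = %g s",
                 f_hi, nyq, bold$tr_s))
  }
  nt <- bold$n_volumes
  if (nt < 16L) stop("bandpass needs at least 16 volumes")
  nvox <- prod(bold$grid$dim)
  Y <- t(matrix(bold$data, nvox, nt))         # time x voxels
  B <- band_basis(nt, bold$tr_s, f_lo, f_hi)
  tt <- seq_len(nt)
  C <- qr.resid(qr(cbind(1, tt - mean(tt))), B)  # basis with trend removed
  out <- qr.fitted(qr(C), Y)
  bold4d(array(t(out), c(bold$grid$dim, nt)), bold$grid, bold$tr_s)
}

# Real Fourier basis (cosine/sine pairs) of the DFT bins inside the band.
band_basis <- function(nt, tr_s, f_lo, f_hi) {
  k_all <- seq_len(floor(nt / 2))
  f <- k_all / (nt * tr_s)
  k <- k_all[f >= f_lo & f <= f_hi]
  if (length(k) == 0L) {
    stop(sprintf("band [%g, %g] Hz contains no frequency bin at n = %d, TR = %g s",
                 f_lo, f_hi, nt, tr_s))
  }
  tt <- 0:(nt - 1)
  cols <- lapply(k, function(ki) {
    w <- 2 * pi * ki * tt / nt
    if (2 * ki == nt) cbind(cos(w)) else cbind(cos(w), sin(w))
  })
  do.call(cbind, cols)
}

# Separable 3D Gaussian convolution with zero padding, sigma per axis in
# voxel units, kernel truncated at 4 sigma. Radius 0 on an axis is identity.
gaussian_smooth_array <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    r <- floor(4 * s)
    if (r < 1L) next
    kern <- stats::dnorm(-r:r, sd = s)
    kern <- kern / sum(kern)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, perm), nrow = d[ax])
    n <- d[ax]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern)) {
      s0 <- j - r - 1L                        # shift in -r..r
      lo <- max(1, 1 - s0); hi <- min(n, n - s0)
      if (lo > hi) next                       # kernel wider than the axis
      rows <- lo:hi
      out[rows, ] <- out[rows, ] + kern[j] * m[rows + s0, ]
    }
    a <- aperm(array(out, d[perm]), order(perm))
  }
  a
}

#' Spatial Gaussian smoothing
#'
#' Per-volume 3D Gaussian convolution with `sigma_mm = fwhm_mm / sqrt(8 ln 2)`
#' per axis (anisotropic voxels handled in voxel units), kernel truncated at
#' 4 sigma, zero-padded borders. A FWHM below about half a voxel leaves the
#' data unchanged.
#'
#' @param bold a [bold4d()].
#' @param fwhm_mm full-width at half-maximum of the kernel in mm.
#' @return The smoothed [bold4d()].
#' @export
smooth_bold <- function(bold, fwhm_mm = 6) {
  stopifnot(inherits(bold, "bold4d"), fwhm_mm > 0)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  sigma_vox <- sigma_mm / bold$grid$vox_mm
  if (all(floor(4 * sigma_vox) < 1)) return(bold)
  out <- bold$data
  for (t in seq_len(bold$n_volumes)) {
    out[, , , t] <- gaussian_smooth_array(bold$data[, , , t], sigma_vox)
  }
  bold4d(out, bold$grid, bold$tr_s)
}

#' Run the three preprocessing stages in order
#'
#' Nuisance regression, then bandpass, then smoothing; the applied order and
#' parameters are recorded in a provenance attribute.
#'
#' @param bold a [bold4d()].
#' @param wm,csf nuisance region [brain_mask()]s.
#' @param f_lo,f_hi bandpass edges in Hz.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @return The preprocessed [bold4d()] with attribute `"provenance"`.
#' @export
preprocess_bold <- function(bold, wm, csf, f_lo = 0.01, f_hi = 0.1,
                            fwhm_mm = 6) {
  out <- regress_nuisance(bold, list(wm = wm, csf = csf))
  out <- bandpass(out, f_lo, f_hi)
  out <- smooth_bold(out, fwhm_mm)
  attr(out, "provenance") <- list(
    order = c("nuisance_regression", "bandpass", "smoothing"),
    assumes = "inputs motion-corrected, slice-timing corrected, coregistered",
    f_lo_hz = f_lo, f_hi_hz = f_hi, fwhm_mm = fwhm_mm)
  out
}
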