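#' Specification of a synthetic vascular sLFO phantom
#'
#' Defines the geometry, acquisition parameters and signal model of a
#' ground-truthed 4D phantom. The phantom carries a shared band-limited
#' systemic low-frequency oscillation (sLFO) with opposite sign in veins and
#' arteries, extravascular coupling that decays exponentially with Chebyshev
#' distance from the vessel wall, a global gray-matter fluctuation, spatially
#' smooth background noise and white measurement noise.
#'
#' @param grid_dims integer triple, phantom dimensions in voxels.
#' @param voxel_size_mm positive triple, voxel size in mm.
#' @param tr_s repetition time in seconds.
#' @param n_volumes number of time points (at least 32).
#' @param band_lo_hz,band_hi_hz passband of the sLFO in Hz; must satisfy
#'   `0 < lo < hi < 1/(2 tr_s)`.
#' @param venous_gain,arterial_gain intravascular sLFO amplitude by vessel
#'   type. Opposite signs make artery and vein cores anti-correlated.
#' @param venous_lag_s,arterial_lag_s temporal lag of the sLFO per vessel
#'   type, in seconds.
#' @param coupling_c0 extravascular coupling amplitude at distance 1 relative
#'   to the intravascular signal, in `[0, 1]`.
#' @param coupling_lambda_vox e-folding length of the extravascular coupling
#'   in voxels; coupling is truncated to zero beyond `4 * coupling_lambda_vox`.
#' @param gm_global_gain amplitude of the shared sLFO carried by gray matter
#'   at large distance from vessels, in `[0, 1)`. White matter and CSF carry
#'   half of it, so nuisance regression has a real but partial effect.
#' @param bg_noise_sd standard deviation of the spatially smooth background
#'   noise present in all brain tissue.
#' @param noise_sd standard deviation of white measurement noise.
#' @param rng_seed integer seed; all randomness is drawn from substreams
#'   derived from it, so phantoms are bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [make_slfo()], [lay_vessels()]
#' @export
phantom_spec <- function(grid_dims = c(24L, 24L, 16L),
                         voxel_size_mm = c(4, 4, 4),
                         tr_s = 2.2,
                         n_volumes = 200L,
                         band_lo_hz = 0.01,
                         band_hi_hz = 0.1,
                         venous_gain = 1.0,
                         arterial_gain = -0.5,
                         venous_lag_s = 0,
                         arterial_lag_s = 0,
                         coupling_c0 = 0.6,
                         coupling_lambda_vox = 1.0,
                         gm_global_gain = 0.1,
                         bg_noise_sd = 0.3,
                         noise_sd = 0.5,
                         rng_seed = 1L) {
  spec <- list(grid_dims = as.integer(grid_dims),
               voxel_size_mm = as.numeric(voxel_size_mm),
               tr_s = as.numeric(tr_s),
               n_volumes = as.integer(n_volumes),
               band_lo_hz = as.numeric(band_lo_hz),
               band_hi_hz = as.numeric(band_hi_hz),
               venous_gain = as.numeric(venous_gain),
               arterial_gain = as.numeric(arterial_gain),
               venous_lag_s = as.numeric(venous_lag_s),
               arterial_lag_s = as.numeric(arterial_lag_s),
               coupling_c0 = as.numeric(coupling_c0),
               coupling_lambda_vox = as.numeric(coupling_lambda_vox),
               gm_global_gain = as.numeric(gm_global_gain),
               bg_noise_sd = as.numeric(bg_noise_sd),
               noise_sd = as.numeric(noise_sd),
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_dims) != 3L || any(grid_dims < 1L)) {
      stop("grid_dims must be a positive integer triple")
    }
    if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
    if (tr_s <= 0) stop("tr_s must be positive")
    if (n_volumes < 32L) stop("n_volumes must be at least 32")
    nyq <- 1 / (2 * tr_s)
    if (!(band_lo_hz > 0 && band_lo_hz < band_hi_hz && band_hi_hz < nyq)) {
      stop(sprintf(
        "invalid sLFO band [%g, %g] Hz: need 0 < lo < hi < Nyquist = %g Hz",
        band_lo_hz, band_hi_hz, nyq))
    }
    gains <- c(venous_gain, arterial_gain, gm_global_gain)
    if (any(!is.finite(gains))) stop("gains must be finite")
    if (coupling_c0 < 0 || coupling_c0 > 1) stop("coupling_c0 must be in [0, 1]")
    if (coupling_lambda_vox <= 0) stop("coupling_lambda_vox must be positive")
    if (gm_global_gain < 0 || gm_global_gain >= 1) {
      stop("gm_global_gain must be in [0, 1)")
    }
    if (bg_noise_sd < 0 || noise_sd < 0) stop("noise SDs must be nonnegative")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %s voxels @ %g mm, %d volumes, TR %g s, band %g-%g Hz\n",
    paste(x$grid_dims, collapse = "x"), x$voxel_size_mm[1], x$n_volumes,
    x$tr_s, x$band_lo_hz, x$band_hi_hz))
  cat(sprintf(
    "  gains: vein %+g, artery %+g, GM %g; coupling c0 %g, lambda %g vox\n",
    x$venous_gain, x$arterial_gain, x$gm_global_gain,
    x$coupling_c0, x$coupling_lambda_vox))
  cat(sprintf("  noise: background %g, measurement %g; seed %d\n",
              x$bg_noise_sd, x$noise_sd, x$rng_seed))
  invisible(x)
}

#' Named phantom presets
#'
#' `"desk"` is the small default used throughout the tests; `"msc-like"`
#' mirrors the acquisition profile of a 30-minute resting-state run at 4 mm
#' isotropic resolution with 36 slices and TR 2.2 s (818 volumes).
#'
#' @param name preset name.
#' @param ... overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("desk", "msc-like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "desk" = list(),
    "msc-like" = list(grid_dims = c(48L, 48L, 36L), n_volumes = 818L))
  do.call(phantom_spec, utils::modifyList(base, list(...)))
}

#' Generate a band-limited systemic low-frequency oscillation
#'
#' White Gaussian noise is hard band-limited in the frequency domain to the
#' spec's passband (DC always removed), transformed back and standardized to
#' zero mean and unit sample variance. The spectral mask is symmetric, so the
#' result is real and its power is confined to the passband by construction.
#'
#' @param spec a [phantom_spec()].
#' @return Numeric vector of length `spec$n_volumes` with `mean == 0` and
#'   `var == 1`; identical for identical `rng_seed`.
#' @export
make_slfo <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$n_volumes
  f <- bin_frequencies(n, spec$tr_s)
  keep <- f >= spec$band_lo_hz & f <= spec$band_hi_hz
  if (!any(keep)) {
    stop(sprintf("sLFO band [%g, %g] Hz contains no frequency bin at n = %d, TR = %g s",
                 spec$band_lo_hz, spec$band_hi_hz, n, spec$tr_s))
  }
  z <- with_substream(spec$rng_seed, 1L, stats::rnorm(n))
  s <- Re(stats::fft(stats::fft(z) * keep, inverse = TRUE)) / n
  s <- s - mean(s)
  s / stats::sd(s)
}

# Frequency (Hz) of each DFT bin, folded so bin k and n-k share |f|.
bin_frequencies <- function(n, tr_s) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * tr_s)
}

# Circular time shift of a series by lag_s seconds via a frequency-domain
# phase ramp; exact for band-limited signals.
shift_timecourse <- function(s, lag_s, tr_s) {
  if (lag_s == 0) return(s)
  n <- length(s)
  k <- 0:(n - 1)
  fsig <- ifelse(k <= n / 2, k, k - n) / (n * tr_s)
  Re(stats::fft(stats::fft(s) * exp(-2i * pi * fsig * lag_s), inverse = TRUE)) / n
}

#' Lay synthetic artery and vein tubes into a label map
#'
#' Places one arterial and one venous tube of 1-voxel thickness in the
#' phantom parenchyma: both run along x at different y positions; the vein
#' carries a short z elbow so the two vessels differ in size and shape. The
#' tubes are disjoint, connected, and surrounded by enough tissue for
#' perivascular shells up to 3 voxels.
#'
#' @param spec a [phantom_spec()].
#' @return A [vessel_labels()] map with attributes `n_artery` and `n_vein`.
#' @export
lay_vessels <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_dims
  if (any(d < c(13L, 12L, 8L))) {
    stop("grid too small to hold artery and vein tubes of length >= 5")
  }
  grid <- volume_grid(d, spec$voxel_size_mm)
  arr <- array(0L, d)
  x0 <- 5L
  x1 <- d[1] - 4L
  ya <- max(3L, round(d[2] / 3))
  yv <- min(d[2] - 2L, round(2 * d[2] / 3))
  z0 <- round(d[3] / 2)
  if (x1 - x0 + 1L < 5L || yv - ya < 2L) {
    stop("grid too small to hold artery and vein tubes of length >= 5")
  }
  arr[x0:x1, ya, z0] <- 1L                      # artery: straight tube
  arr[x0:x1, yv, z0] <- 2L                      # vein: tube plus z elbow
  zq <- seq.int(z0 + 1L, min(z0 + 4L, d[3] - 2L))
  if (length(zq) > 0) arr[x1, yv, zq] <- 2L
  labels <- vessel_labels(arr, grid)
  attr(labels, "n_artery") <- sum(arr == 1L)
  attr(labels, "n_vein") <- sum(arr == 2L)
  labels
}

# Exact Chebyshev (or city-block) distance to a voxel set, by iterated
# dilation. Small grids only; used for phantom ground truth and shells.
distance_to_mask <- function(maskarr, connectivity = 26L, max_d = NULL) {
  d <- dim(maskarr)
  dist <- array(Inf, d)
  dist[maskarr] <- 0
  cur <- maskarr
  if (is.null(max_d)) max_d <- sum(d)
  k <- 0L
  while (k < max_d && !all(cur)) {
    k <- k + 1L
    nxt <- dilate_array(cur, connectivity)
    newly <- nxt & !cur
    if (!any(newly)) break
    dist[newly] <- k
    cur <- nxt
  }
  dist
}

#' Generate a ground-truthed synthetic vascular phantom
#'
#' Builds the full phantom: vessel label map, brain/GM/WM/CSF compartments,
#' the 4D BOLD array following the signal model, and the ground truth needed
#' for parameter-recovery tests.
#'
#' The voxel signal model is
#' `y(v, t) = g_type(v) * c(d(v)) * s(t - lag_type) + b(v, t) + e(v, t)`,
#' where `s` is the sLFO, `d(v)` the Chebyshev distance to the nearest vessel
#' voxel, `c(0) = 1` inside vessels and `c(d) = c0 * exp(-d / lambda)` up to
#' the truncation radius `4 * lambda`, `b` the compartment background
#' (GM: `gm_global_gain * s` plus smooth noise; WM/CSF: half the global gain
#' plus smooth noise; vessel cores carry no background) and `e` white
#' measurement noise. Ties between artery and vein distance resolve to vein,
#' reflecting the venous dominance of BOLD.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `vasc_phantom` with elements `bold` ([bold4d()]),
#'   `labels` ([vessel_labels()]), `masks` (list of [brain_mask()]: `brain`,
#'   `gm`, `wm`, `csf`), `truth` (list: `distance_map`, `vessel_type_map`,
#'   `coupling`, `slfo`) and `spec`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_dims
  nt <- spec$n_volumes
  grid <- volume_grid(d, spec$voxel_size_mm)
  labels <- lay_vessels(spec)
  lab <- unclass(labels)

  # Compartments: 1-voxel air border, then a 1-voxel CSF rim, WM core box,
  # GM elsewhere. Vessel voxels always belong to GM tissue.
  brain <- array(FALSE, d)
  brain[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  interior <- array(FALSE, d)
  interior[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  csf <- brain & !interior
  wm <- array(FALSE, d)
  wx <- wm_range(d[1]); wy <- wm_range(d[2]); wz <- wm_range(d[3])
  wm[wx, wy, wz] <- TRUE
  wm <- wm & interior
  vess <- lab > 0L
  csf[vess] <- FALSE
  wm[vess] <- FALSE
  gm <- brain & !csf & !wm

  # Ground-truth geometry and coupling.
  dist <- distance_to_mask(vess, 26L)
  dist[!brain] <- Inf
  da <- distance_to_mask(lab == 1L, 26L)
  dv <- distance_to_mask(lab == 2L, 26L)
  trunc_d <- 4 * spec$coupling_lambda_vox
  coupling <- ifelse(dist == 0, 1,
                     ifelse(dist <= trunc_d,
                            spec$coupling_c0 * exp(-dist / spec$coupling_lambda_vox),
                            0))
  coupling[!brain] <- 0
  type <- array(0L, d)
  type[dv <= da] <- 2L
  type[da < dv] <- 1L
  type[dist > trunc_d | !brain] <- 0L
  type[lab > 0L] <- lab[lab > 0L]

  s <- make_slfo(spec)
  sv <- shift_timecourse(s, spec$venous_lag_s, spec$tr_s)
  sa <- shift_timecourse(s, spec$arterial_lag_s, spec$tr_s)

  nvox <- prod(d)
  y <- matrix(0, nvox, nt)
  art_on <- which(type == 1L & coupling > 0)
  ven_on <- which(type == 2L & coupling > 0)
  if (length(art_on)) {
    y[art_on, ] <- (spec$arterial_gain * coupling[art_on]) %o% sa
  }
  if (length(ven_on)) {
    y[ven_on, ] <- y[ven_on, , drop = FALSE] +
      (spec$venous_gain * coupling[ven_on]) %o% sv
  }

  # Compartment background: global sLFO share plus spatially smooth noise.
  gm_bg <- which(gm & !vess)
  wmcsf <- which(wm | csf)
  y[gm_bg, ] <- y[gm_bg, , drop = FALSE] +
    matrix(spec$gm_global_gain * s, length(gm_bg), nt, byrow = TRUE)
  y[wmcsf, ] <- y[wmcsf, , drop = FALSE] +
    matrix(spec$gm_global_gain / 2 * s, length(wmcsf), nt, byrow = TRUE)

  if (spec$bg_noise_sd > 0) {
    bg <- with_substream(spec$rng_seed, 2L, array(stats::rnorm(nvox * nt), c(d, nt)))
    for (t in seq_len(nt)) {
      bg[, , , t] <- gaussian_smooth_array(bg[, , , t], sigma_vox = rep(0.8, 3))
    }
    bg <- matrix(bg, nvox, nt)
    tissue <- which(brain & !vess)
    bgt <- bg[tissue, , drop = FALSE]
    y[tissue, ] <- y[tissue, , drop = FALSE] +
      bgt * (spec$bg_noise_sd / stats::sd(as.vector(bgt)))
  }

  if (spec$noise_sd > 0) {
    eps <- with_substream(spec$rng_seed, 3L,
                          matrix(stats::rnorm(sum(brain) * nt), ncol = nt))
    y[which(brain), ] <- y[which(brain), , drop = FALSE] + spec$noise_sd * eps
  }

  truth <- list(distance_map = dist, vessel_type_map = type,
                coupling = coupling, slfo = s)
  structure(list(
    bold = bold4d(array(y, c(d, nt)), grid, spec$tr_s),
    labels = labels,
    masks = list(brain = brain_mask(brain, grid),
                 gm = brain_mask(gm, grid),
                 wm = brain_mask(wm, grid),
                 csf = brain_mask(csf, grid)),
    truth = truth,
    spec = spec), class = "vasc_phantom")
}

# Central index range holding the WM core box (middle ~third of an axis).
wm_range <- function(n) {
  lo <- max(3L, floor(n * 0.42))
  hi <- min(n - 2L, ceiling(n * 0.58))
  lo:hi
}

#' @export
print.vasc_phantom <- function(x, ...) {
  cat("vasc_phantom\n")
  print(x$spec)
  cat(sprintf("  %d artery, %d vein, %d GM, %d WM, %d CSF voxels\n",
              attr(x$labels, "n_artery"), attr(x$labels, "n_vein"),
              mask_count(x$masks$gm), mask_count(x$masks$wm),
              mask_count(x$masks$csf)))
  invisible(x)
}

#' Write a phantom to disk as NIfTI volumes plus a JSON sidecar
#'
#' @param phantom a `vasc_phantom` from [make_phantom()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- phantom$bold$grid
  paths <- c(bold = file.path(dir, "bold.nii.gz"),
             labels = file.path(dir, "vessel_labels.nii.gz"),
             brain = file.path(dir, "mask_brain.nii.gz"),
             gm = file.path(dir, "mask_gm.nii.gz"),
             wm = file.path(dir, "mask_wm.nii.gz"),
             csf = file.path(dir, "mask_csf.nii.gz"),
             distance = file.path(dir, "truth_distance.nii.gz"),
             vessel_type = file.path(dir, "truth_vessel_type.nii.gz"),
             coupling = file.path(dir, "truth_coupling.nii.gz"),
             truth = file.path(dir, "truth.json"))
  write_bold_nifti(phantom$bold, paths["bold"])
  write_labels_nifti(phantom$labels, paths["labels"])
  for (m in c("brain", "gm", "wm", "csf")) {
    write_mask_nifti(phantom$masks[[m]], paths[m])
  }
  dist_out <- phantom$truth$distance_map
  dist_out[!is.finite(dist_out)] <- -1   # -1 encodes "outside brain"
  write_volume_nifti(dist_out, g, paths["distance"])
  write_volume_nifti(phantom$truth$vessel_type_map, g, paths["vessel_type"])
  write_volume_nifti(phantom$truth$coupling, g, paths["coupling"])
  jsonlite::write_json(
    list(spec = unclass(phantom$spec), slfo = phantom$truth$slfo,
         n_artery = attr(phantom$labels, "n_artery"),
         n_vein = attr(phantom$labels, "n_vein")),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
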