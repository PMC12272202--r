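#' Percentage of a resting-state network occupied by macrovasculature
#'
#' Thresholds an RSN z-map at `z > z_thresh` and a macrovascular frequency
#' map at its `pct_thresh`-th percentile (computed over the map's nonzero
#' voxels; ties at the percentile value are kept), then reports the
#' percentage of RSN voxels falling inside the vascular mask.
#'
#' @param rsn_zmap numeric 3D array, RSN z-statistic map.
#' @param freq_map numeric 3D array on the same grid, macrovascular
#'   frequency/likelihood map.
#' @param z_thresh z threshold for the RSN mask (default 3).
#' @param pct_thresh percentile threshold for the vascular mask, in (0, 100)
#'   (default 90).
#' @param rsn_name label carried into the output row.
#' @return A one-row data.frame (`OccupancyRow`): `rsn_name`, `rsn_voxels`,
#'   `overlap_voxels`, `percent`.
#' @export
occupancy <- function(rsn_zmap, freq_map, z_thresh = 3, pct_thresh = 90,
                      rsn_name = "RSN") {
  if (!identical(dim(rsn_zmap), dim(freq_map))) {
    stop("occupancy: RSN and frequency maps have different dimensions")
  }
  if (!(pct_thresh > 0 && pct_thresh < 100)) {
    stop("pct_thresh must be strictly between 0 and 100")
  }
  rsn <- rsn_zmap > z_thresh
  n_rsn <- sum(rsn)
  if (n_rsn == 0L) {
    stop(sprintf("occupancy: RSN '%s' is empty after thresholding at z > %g",
                 rsn_name, z_thresh), call. = FALSE)
  }
  support <- freq_map[freq_map != 0]
  if (length(support) == 0L) stop("occupancy: frequency map is identically zero")
  cut <- stats::quantile(support, pct_thresh / 100, type = 7, names = FALSE)
  vasc <- freq_map != 0 & freq_map >= cut
  overlap <- sum(rsn & vasc)
  data.frame(rsn_name = rsn_name, rsn_voxels = n_rsn,
             overlap_voxels = overlap, percent = 100 * overlap / n_rsn)
}

#' Occupancy table over a set of RSNs
#'
#' Applies [occupancy()] to each named z-map and returns the rows sorted in
#' decreasing order of occupancy percentage.
#'
#' @param rsn_zmaps named list of RSN z-map arrays.
#' @inheritParams occupancy
#' @return A data.frame of occupancy rows, sorted by `percent` descending.
#' @export
occupancy_table <- function(rsn_zmaps, freq_map, z_thresh = 3, pct_thresh = 90) {
  stopifnot(is.list(rsn_zmaps), length(rsn_zmaps) >= 1L)
  nm <- names(rsn_zmaps) %||% paste0("RSN", seq_along(rsn_zmaps))
  rows <- mapply(function(z, name) occupancy(z, freq_map, z_thresh, pct_thresh, name),
                 rsn_zmaps, nm, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(-out$percent), ]
  rownames(out) <- NULL
  out
}
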