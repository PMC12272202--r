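#' Distance-resolved perivascular connectivity profile
#'
#' Quantifies how far macrovascular connectivity reaches into the
#' surrounding tissue. For each perivascular distance `d` (shell seeds at
#' `d = 1..K`, plus the vessel voxels themselves at `d = 0`), the seed set is
#' correlated against the vessel targets and against the whole-GM reference,
#' and the macrovascular-to-GM ratios (degree and signed variance) are
#' averaged over seeds into one profile row per distance.
#'
#' Empty shells are omitted with a warning rather than fabricated. Ratio
#' voxels with a zero denominator are excluded from the means, with the
#' number of defined voxels reported per row.
#'
#' @param bold a preprocessed [bold4d()].
#' @param shells a `shell_set` from [make_shells()], built from the same
#'   vessel mask as `vessel_targets` and disjoint from all vessel voxels.
#' @param vessel_targets [brain_mask()] of the vessel type under study.
#' @param gm gray-matter reference [brain_mask()].
#' @param vessel_type label stored in the profile (`"artery"` or `"vein"`).
#' @param threshold,mode degree parameters, see [degree_map()].
#' @param block_size seed block size of the streaming engine.
#' @param include_d0 include the vessel voxels themselves as distance 0.
#' @return An object of class `shell_profile`: data.frame with columns
#'   `vessel_type`, `distance`, `n_seeds`, `n_defined`, `mu_D_ratio`,
#'   `mu_var_ratio_pos`, `mu_var_ratio_neg`, `mu_D_vessel`, `mu_D_gm`; the
#'   per-distance `ratio_maps` objects are attached as attribute `"maps"`.
#' @export
shell_metrics <- function(bold, shells, vessel_targets, gm,
                          vessel_type = c("vein", "artery"),
                          threshold = 0.15, mode = c("absolute", "positive"),
                          block_size = 256L, include_d0 = TRUE) {
  vessel_type <- match.arg(vessel_type)
  mode <- match.arg(mode)
  stopifnot(inherits(shells, "shell_set"))
  for (k in seq_len(shells$K)) {
    if (mask_count(mask_and(shells$shells[[k]], vessel_targets)) > 0L) {
      stop("shell_metrics: shell ", k, " overlaps the vessel targets")
    }
  }
  dists <- if (include_d0) 0:shells$K else seq_len(shells$K)
  rows <- list()
  maps <- list()
  for (d in dists) {
    seeds <- if (d == 0L) shells$source else shells$shells[[d]]
    if (mask_count(seeds) == 0L) {
      warning(sprintf("shell_metrics: shell at distance %d is empty; omitted", d))
      next
    }
    to_vessel <- connectivity_stats(bold, seeds, vessel_targets, threshold,
                                    mode, block_size,
                                    sprintf("%s_shell%d_to_vessel", vessel_type, d))
    to_gm <- connectivity_stats(bold, seeds, gm, threshold, mode, block_size,
                                sprintf("%s_shell%d_to_gm", vessel_type, d))
    rm <- ratio_maps(to_vessel, to_gm)
    mu <- spatial_means(rm)
    rows[[length(rows) + 1L]] <- data.frame(
      vessel_type = vessel_type, distance = d, n_seeds = mask_count(seeds),
      n_defined = attr(mu, "n_defined")[["D_ratio"]],
      mu_D_ratio = mu[["mu_D_ratio"]],
      mu_var_ratio_pos = mu[["mu_var_ratio_pos"]],
      mu_var_ratio_neg = mu[["mu_var_ratio_neg"]],
      mu_D_vessel = mean(to_vessel$D, na.rm = TRUE),
      mu_D_gm = mean(to_gm$D, na.rm = TRUE))
    maps[[as.character(d)]] <- rm
  }
  if (length(rows) == 0L) stop("shell_metrics: no non-empty shells")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "maps") <- maps
  class(out) <- c("shell_profile", "data.frame")
  out
}

#' Build shells and profiles for both vessel types in one call
#'
#' Convenience wrapper: constructs K perivascular shells around the arterial
#' and venous masks (each excluding the union of all vessel voxels, clipped
#' to the brain mask) and computes both [shell_metrics()] profiles.
#'
#' @inheritParams shell_metrics
#' @param arterial,venous vessel [brain_mask()]s.
#' @param brain optional brain [brain_mask()] the shells are clipped to.
#' @param K number of shell distances.
#' @param connectivity structuring element, see [make_shells()].
#' @return Named list of two `shell_profile` objects (`artery`, `vein`).
#' @export
perivascular_profiles <- function(bold, arterial, venous, gm, brain = NULL,
                                  K = 3L, connectivity = 26L,
                                  threshold = 0.15,
                                  mode = c("absolute", "positive"),
                                  block_size = 256L) {
  mode <- match.arg(mode)
  vess <- mask_or(arterial, venous)
  sh_a <- make_shells(arterial, K, connectivity, exclude = vess, within = brain)
  sh_v <- make_shells(venous, K, connectivity, exclude = vess, within = brain)
  out <- list(
    artery = shell_metrics(bold, sh_a, arterial, gm, "artery",
                           threshold, mode, block_size),
    vein = shell_metrics(bold, sh_v, venous, gm, "vein",
                         threshold, mode, block_size))
  # The two vessel classes are dilated independently, so a voxel may sit in
  # an arterial and a venous shell at once; it then contributes to both
  # profiles, and the overlap fraction per distance is reported here.
  attr(out, "shell_overlap") <- vapply(seq_len(K), function(k) {
    na <- mask_count(sh_a$shells[[k]])
    if (na == 0L) return(0)
    mask_count(mask_and(sh_a$shells[[k]], sh_v$shells[[k]])) / na
  }, 0)
  out
}
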