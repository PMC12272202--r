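#' @name connectivity
#' @title Seed-target connectivity metrics
#' @description Blocked Pearson correlation between seed and target voxel
#'   sets, summarized per seed voxel as degree of connectivity (number of
#'   suprathreshold correlations), signed strength (mean of positive-only /
#'   negative-only correlations) and signed spatial variance. The engine
#'   streams over seed blocks, so the working set is bounded by
#'   `block_size x n_targets` correlations, never the full seed-target
#'   matrix.
NULL

# Rows of the BOLD matrix demeaned and scaled to unit norm; zero-variance
# rows flagged invalid. Returns list(z, valid).
unit_rows <- function(m) {
  m <- m - rowMeans(m)
  ss <- sqrt(rowSums(m^2))
  valid <- ss > 0
  m[valid, ] <- m[valid, , drop = FALSE] / ss[valid]
  list(z = m, valid = valid)
}

#' Pearson correlations between all seed and target voxels
#'
#' Materializes the full seed-by-target correlation matrix, computed in seed
#' blocks; intended for modest mask sizes and for verifying the streaming
#' metric engine against a dense recomputation. Zero-variance target voxels
#' are dropped (shrinking `n_targets_valid`); zero-variance seeds yield NA
#' rows. Self-pairs (a voxel correlated with itself) are kept in the matrix
#' but flagged so downstream statistics can exclude them.
#'
#' @param bold a [bold4d()].
#' @param seeds,targets [brain_mask()]s on `bold`'s grid.
#' @param block_size number of seed voxels correlated per block.
#' @return An object of class `corr_rows`: list with `r` (n_seeds x
#'   n_valid_targets matrix), `seed_idx`, `target_idx` (linear voxel indices,
#'   targets restricted to valid ones), `seed_valid`, `self` (n_seeds vector:
#'   column of the seed's own voxel in `r`, or NA).
#' @export
seed_target_correlations <- function(bold, seeds, targets, block_size = 256L) {
  check_seed_target(bold, seeds, targets, block_size)
  seed_idx <- mask_indices(seeds)
  target_idx <- mask_indices(targets)
  zt <- unit_rows(bold_matrix(bold, target_idx))
  target_idx <- target_idx[zt$valid]
  Zt <- zt$z[zt$valid, , drop = FALSE]
  zs <- unit_rows(bold_matrix(bold, seed_idx))
  if (!any(zs$valid)) stop("seed_target_correlations: every seed voxel has zero variance")
  ns <- length(seed_idx)
  r <- matrix(NA_real_, ns, length(target_idx))
  for (b in block_starts(ns, block_size)) {
    rows <- b:min(ns, b + block_size - 1L)
    use <- rows[zs$valid[rows]]
    if (length(use)) {
      r[use, ] <- tcrossprod(zs$z[use, , drop = FALSE], Zt)
    }
  }
  structure(list(r = r, seed_idx = seed_idx, target_idx = target_idx,
                 seed_valid = zs$valid,
                 self = match(seed_idx, target_idx)),
            class = "corr_rows")
}

block_starts <- function(n, block_size) seq.int(1L, n, by = max(1L, block_size))

check_seed_target <- function(bold, seeds, targets, block_size) {
  stopifnot(inherits(bold, "bold4d"), block_size >= 1L)
  for (m in list(seeds, targets)) {
    if (!grids_equal(bold$grid, mask_grid(m))) {
      stop_grid_mismatch("connectivity", bold$grid, mask_grid(m))
    }
  }
  if (mask_count(seeds) == 0L || mask_count(targets) == 0L) {
    stop("seed and target masks must be non-empty")
  }
}

# Per-seed statistics for a block of correlation rows. `r` has self-pairs
# already set to NA. Positive and negative classes are strict (r == 0
# belongs to neither).
row_stats <- function(r, threshold, mode) {
  n_valid <- rowSums(!is.na(r))
  pos <- !is.na(r) & r > 0
  neg <- !is.na(r) & r < 0
  n_pos <- rowSums(pos)
  n_neg <- rowSums(neg)
  sum_pos <- rowSums(r * pos, na.rm = TRUE)
  sum_neg <- rowSums(r * neg, na.rm = TRUE)
  S_pos <- ifelse(n_pos > 0, sum_pos / n_pos, NA_real_)
  S_neg <- ifelse(n_neg > 0, sum_neg / n_neg, NA_real_)
  var_pos <- ifelse(n_pos > 0, rowSums(r^2 * pos, na.rm = TRUE) / n_pos - S_pos^2, NA_real_)
  var_neg <- ifelse(n_neg > 0, rowSums(r^2 * neg, na.rm = TRUE) / n_neg - S_neg^2, NA_real_)
  D <- if (mode == "absolute") {
    rowSums(!is.na(r) & abs(r) > threshold)
  } else {
    rowSums(!is.na(r) & r > threshold)
  }
  list(D = D, S_pos = S_pos, S_neg = S_neg,
       var_pos = pmax(var_pos, 0), var_neg = pmax(var_neg, 0),
       n_pos = n_pos, n_neg = n_neg, n_targets_valid = n_valid)
}

#' Degree of connectivity from correlation rows
#'
#' Counts, per seed, the target voxels whose correlation exceeds the
#' threshold: `|r| > threshold` in `"absolute"` mode (default; keeps the
#' anti-correlations that carry the artery-vein signal), `r > threshold` in
#' `"positive"` mode. Self-pairs are excluded.
#'
#' @param rows a `corr_rows` object from [seed_target_correlations()].
#' @param threshold correlation threshold in (0, 1); default 0.15, the
#'   conventional degree-of-connectivity cutoff.
#' @param mode `"absolute"` or `"positive"`.
#' @return Integer vector of degrees (NA for zero-variance seeds).
#' @export
degree_map <- function(rows, threshold = 0.15, mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rows, "corr_rows"), threshold > 0, threshold < 1)
  r <- drop_self(rows)
  st <- row_stats(r, threshold, mode)
  ifelse(rows$seed_valid, st$D, NA_integer_)
}

#' Signed strength and spatial variance from correlation rows
#'
#' `S_pos` is the mean of the strictly positive correlations of each seed,
#' `var_pos` their population (divide-by-N) spatial variance; likewise for
#' the negatives. An empty sign class yields NA with `n = 0`.
#'
#' @inheritParams degree_map
#' @return A data.frame with one row per seed: `S_pos`, `S_neg`, `var_pos`,
#'   `var_neg`, `n_pos`, `n_neg`, `n_targets_valid`.
#' @export
strength_variance_maps <- function(rows) {
  stopifnot(inherits(rows, "corr_rows"))
  r <- drop_self(rows)
  st <- row_stats(r, 0.15, "absolute")
  bad <- !rows$seed_valid
  out <- data.frame(S_pos = st$S_pos, S_neg = st$S_neg,
                    var_pos = st$var_pos, var_neg = st$var_neg,
                    n_pos = st$n_pos, n_neg = st$n_neg,
                    n_targets_valid = st$n_targets_valid)
  out[bad, ] <- NA
  out
}

drop_self <- function(rows) {
  r <- rows$r
  sf <- rows$self
  hit <- which(!is.na(sf))
  if (length(hit)) r[cbind(hit, sf[hit])] <- NA_real_
  r
}

# Streaming engine: per-seed metrics without materializing the full matrix.
connectivity_stats <- function(bold, seeds, targets, threshold = 0.15,
                               mode = c("absolute", "positive"),
                               block_size = 256L, category = "custom") {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  check_seed_target(bold, seeds, targets, block_size)
  seed_idx <- mask_indices(seeds)
  target_idx <- mask_indices(targets)
  zt <- unit_rows(bold_matrix(bold, target_idx))
  target_idx <- target_idx[zt$valid]
  Zt <- zt$z[zt$valid, , drop = FALSE]
  if (length(target_idx) == 0L) stop("all target voxels have zero variance")
  zs <- unit_rows(bold_matrix(bold, seed_idx))
  if (!any(zs$valid)) stop("all seed voxels have zero variance")
  ns <- length(seed_idx)
  self_col <- match(seed_idx, target_idx)
  acc <- list(D = rep(NA_real_, ns), S_pos = rep(NA_real_, ns),
              S_neg = rep(NA_real_, ns), var_pos = rep(NA_real_, ns),
              var_neg = rep(NA_real_, ns), n_pos = rep(NA_integer_, ns),
              n_neg = rep(NA_integer_, ns),
              n_targets_valid = rep(NA_integer_, ns))
  for (b in block_starts(ns, block_size)) {
    rows <- b:min(ns, b + block_size - 1L)
    use <- rows[zs$valid[rows]]
    if (!length(use)) next
    r <- tcrossprod(zs$z[use, , drop = FALSE], Zt)
    sf <- self_col[use]
    hit <- which(!is.na(sf))
    if (length(hit)) r[cbind(hit, sf[hit])] <- NA_real_
    st <- row_stats(r, threshold, mode)
    for (nm in names(acc)) acc[[nm]][use] <- st[[nm]]
  }
  structure(c(list(category = category, seed_idx = seed_idx,
                   n_seeds = ns, n_targets = length(target_idx),
                   threshold = threshold, mode = mode,
                   grid = bold$grid), acc),
            class = "conn_maps")
}

#' @export
print.conn_maps <- function(x, ...) {
  cat(sprintf(
    "conn_maps [%s]: %d seeds x %d targets, threshold %g (%s); mean D = %.2f\n",
    x$category, x$n_seeds, x$n_targets, x$threshold, x$mode,
    mean(x$D, na.rm = TRUE)))
  invisible(x)
}

#' Connectivity metrics for the artery/vein/GM category pairs
#'
#' Computes, for one session, the seven seed-target categories: venous-venous
#' (VV), arterial-arterial (AA), arterial-venous (AV), venous-arterial (VA),
#' venous-to-GM (V_GM), arterial-to-GM (A_GM) and the whole-GM reference
#' (GM_GM). A voxel is never correlated with itself; for the within-set
#' categories the seed is thereby excluded from its own targets.
#'
#' @param bold a preprocessed [bold4d()].
#' @param arterial,venous disjoint vessel [brain_mask()]s (GM-restricted when
#'   the maps feed macrovascular-to-GM ratios).
#' @param gm gray-matter [brain_mask()].
#' @param threshold,mode degree threshold and counting mode, see
#'   [degree_map()].
#' @param block_size seed block size of the streaming engine.
#' @param with_gm set `FALSE` to skip the three GM-target categories.
#' @return Named list of `conn_maps` objects.
#' @export
category_metrics <- function(bold, arterial, venous, gm, threshold = 0.15,
                             mode = c("absolute", "positive"),
                             block_size = 256L, with_gm = TRUE) {
  mode <- match.arg(mode)
  if (mask_count(mask_and(arterial, venous)) > 0L) {
    stop("arterial and venous masks overlap")
  }
  run <- function(seeds, targets, name) {
    connectivity_stats(bold, seeds, targets, threshold, mode, block_size, name)
  }
  out <- list(VV = run(venous, venous, "VV"),
              AA = run(arterial, arterial, "AA"),
              AV = run(arterial, venous, "AV"),
              VA = run(venous, arterial, "VA"))
  if (with_gm) {
    out$V_GM <- run(venous, gm, "V_GM")
    out$A_GM <- run(arterial, gm, "A_GM")
    out$GM_GM <- run(gm, gm, "GM_GM")
  }
  out
}

#' Macrovascular-to-GM ratio maps
#'
#' Divides, seed voxel by seed voxel, the degree (and the signed spatial
#' variances) of a vascular category by those of the matching GM reference
#' category, e.g. `D_VV : D_V_GM`. Numerator and denominator must share the
#' seed mask and threshold. Ratios are undefined (NA) where the denominator
#' is zero or either side is undefined.
#'
#' @param numerator,denominator `conn_maps` objects with identical seed
#'   voxels and thresholds.
#' @return An object of class `ratio_maps` with per-seed `D_ratio`,
#'   `var_ratio_pos`, `var_ratio_neg`.
#' @export
ratio_maps <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "conn_maps"), inherits(denominator, "conn_maps"))
  if (!identical(numerator$seed_idx, denominator$seed_idx)) {
    stop("ratio_maps: numerator and denominator use different seed masks")
  }
  if (numerator$threshold != denominator$threshold) {
    stop("ratio_maps: thresholds differ")
  }
  safe_div <- function(a, b) ifelse(!is.na(b) & b != 0, a / b, NA_real_)
  structure(list(
    category = paste0(numerator$category, ":", denominator$category),
    seed_idx = numerator$seed_idx,
    n_seeds = numerator$n_seeds,
    threshold = numerator$threshold,
    grid = numerator$grid,
    D_ratio = safe_div(numerator$D, denominator$D),
    var_ratio_pos = safe_div(numerator$var_pos, denominator$var_pos),
    var_ratio_neg = safe_div(numerator$var_neg, denominator$var_neg)),
    class = "ratio_maps")
}

#' @export
print.ratio_maps <- function(x, ...) {
  cat(sprintf("ratio_maps [%s]: %d seeds, mean D ratio = %.4f\n",
              x$category, x$n_seeds, mean(x$D_ratio, na.rm = TRUE)))
  invisible(x)
}

#' Spatial means of a metric object
#'
#' Means over seed voxels with defined values; the counts of defined voxels
#' are attached as an attribute.
#'
#' @param x a `conn_maps` or `ratio_maps` object.
#' @return Named numeric vector of `mu(...)` values.
#' @export
spatial_means <- function(x) {
  metrics <- if (inherits(x, "conn_maps")) {
    c("D", "S_pos", "S_neg", "var_pos", "var_neg")
  } else if (inherits(x, "ratio_maps")) {
    c("D_ratio", "var_ratio_pos", "var_ratio_neg")
  } else stop("spatial_means expects conn_maps or ratio_maps")
  vals <- vapply(metrics, function(m) {
    v <- x[[m]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  names(vals) <- paste0("mu_", metrics)
  attr(vals, "n_defined") <- vapply(metrics, function(m) sum(!is.na(x[[m]])), 0L)
  vals
}

#' Summarize connectivity metrics across sessions
#'
#' Takes per-session metric objects, computes the spatial mean of every
#' metric per session, and summarizes across sessions with the unweighted
#' mean, median and quartiles (linear interpolation between order
#' statistics). Undefined voxels are excluded from the spatial means;
#' a metric undefined in every voxel of a session stays NA rather than
#' becoming zero.
#'
#' @param sessions list with one element per session; each element is either
#'   a single `conn_maps`/`ratio_maps` object or a named list of them (one
#'   per category).
#' @return An object of class `group_summary`: list with `per_session` (long
#'   data.frame: session, category, metric, value) and `group` (data.frame:
#'   category, metric, mean, median, q1, q3, min, max, n_sessions).
#' @export
group_summarize <- function(sessions) {
  stopifnot(is.list(sessions), length(sessions) >= 1L)
  rows <- list()
  for (i in seq_along(sessions)) {
    el <- sessions[[i]]
    cats <- if (inherits(el, c("conn_maps", "ratio_maps"))) {
      stats::setNames(list(el), el$category)
    } else el
    for (nm in names(cats)) {
      mu <- spatial_means(cats[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        session = i, category = nm, metric = names(mu), value = as.numeric(mu),
        row.names = NULL)
    }
  }
  per_session <- do.call(rbind, rows)
  grp <- lapply(split(per_session, per_session[c("category", "metric")], drop = TRUE),
                function(d) {
    v <- d$value[!is.na(d$value)]
    if (length(v) == 0L) {
      data.frame(category = d$category[1], metric = d$metric[1], mean = NA_real_,
                 median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                 min = NA_real_, max = NA_real_, n_sessions = 0L)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(category = d$category[1], metric = d$metric[1], mean = mean(v),
                 median = q[2], q1 = q[1], q3 = q[3],
                 min = min(v), max = max(v), n_sessions = length(v))
    }
  })
  grp <- do.call(rbind, grp)
  rownames(grp) <- NULL
  structure(list(per_session = per_session, group = grp),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary: %d sessions, %d category x metric cells\n",
              max(x$per_session$session), nrow(x$group)))
  print(utils::head(x$group, 12))
  invisible(x)
}

#' Render one per-seed metric as a 3D volume
#'
#' @param x a `conn_maps` or `ratio_maps` object.
#' @param metric metric name, e.g. `"D"`, `"S_pos"`, `"D_ratio"`.
#' @return Numeric 3D array (NA outside seed voxels) on the object's grid.
#' @export
metric_volume <- function(x, metric) {
  if (is.null(x[[metric]])) stop("unknown metric: ", metric)
  vol <- array(NA_real_, x$grid$dim)
  vol[x$seed_idx] <- as.numeric(x[[metric]])
  vol
}
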