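# Shared fixtures and independent oracles, all built in code.

toy_grid <- function(dim = c(8L, 8L, 8L), vox = c(4, 4, 4)) {
  volume_grid(dim, vox)
}

# Random binary mask with a fixed expected fill fraction.
random_mask <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  brain_mask(array(runif(prod(grid$dim)) < p, grid$dim), grid)
}

# Random BOLD series with iid normal voxel time courses.
random_bold <- function(grid, nt = 30L, tr = 2.2, seed = 1) {
  set.seed(seed)
  bold4d(array(rnorm(prod(grid$dim) * nt), c(grid$dim, nt)), grid, tr)
}

# Dense oracle: full Pearson correlation matrix via stats::cor on the raw
# voxel-by-time matrices, independent of the package's blocked engine.
dense_cor_oracle <- function(bold, seeds, targets) {
  sm <- t(vasconn:::bold_matrix(bold, mask_indices(seeds)))
  tm <- t(vasconn:::bold_matrix(bold, mask_indices(targets)))
  suppressWarnings(stats::cor(sm, tm))
}

# Oracle per-seed stats from a dense correlation matrix: plain loops and
# base summaries, population variance by definition.
oracle_stats <- function(rmat, seed_idx, target_idx, threshold, mode) {
  ns <- nrow(rmat)
  out <- data.frame(D = integer(ns), S_pos = NA_real_, S_neg = NA_real_,
                    var_pos = NA_real_, var_neg = NA_real_,
                    n_pos = 0L, n_neg = 0L, n_valid = 0L)
  for (i in seq_len(ns)) {
    r <- rmat[i, ]
    r <- r[!(target_idx == seed_idx[i])]        # drop self-pair
    r <- r[!is.na(r)]
    out$n_valid[i] <- length(r)
    pos <- r[r > 0]; neg <- r[r < 0]
    out$n_pos[i] <- length(pos); out$n_neg[i] <- length(neg)
    if (length(pos)) {
      out$S_pos[i] <- mean(pos)
      out$var_pos[i] <- mean((pos - mean(pos))^2)
    }
    if (length(neg)) {
      out$S_neg[i] <- mean(neg)
      out$var_neg[i] <- mean((neg - mean(neg))^2)
    }
    out$D[i] <- if (mode == "absolute") sum(abs(r) > threshold) else sum(r > threshold)
  }
  out
}

# Hand-rolled corr_rows object for unit tests of the row summarizers.
fake_rows <- function(r, target_idx = seq_len(ncol(r)) + 100L,
                      seed_idx = seq_len(nrow(r)), self = rep(NA_integer_, nrow(r))) {
  structure(list(r = r, seed_idx = seed_idx, target_idx = target_idx,
                 seed_valid = rep(TRUE, nrow(r)), self = self),
            class = "corr_rows")
}

# Mean of all correlations (both signs pooled) across the seeds of a
# conn_maps object; the overall strength of a category.
overall_strength <- function(cm) {
  n_pos <- ifelse(is.na(cm$n_pos), 0L, cm$n_pos)
  n_neg <- ifelse(is.na(cm$n_neg), 0L, cm$n_neg)
  tot <- n_pos + n_neg
  s <- ifelse(is.na(cm$S_pos), 0, cm$S_pos * n_pos) +
    ifelse(is.na(cm$S_neg), 0, cm$S_neg * n_neg)
  mean((s / tot)[tot > 0])
}

# GM-restricted artery and vein masks of a phantom.
phantom_vessels <- function(ph) {
  list(artery = restrict_to_gm(label_mask(ph$labels, "artery"), ph$masks$gm),
       vein = restrict_to_gm(label_mask(ph$labels, "vein"), ph$masks$gm))
}

# The noiseless decaying-coupling condition used by the perivascular
# recovery checks: no measurement noise, no global GM signal, background
# noise strong enough that shell-vessel correlations traverse the degree
# threshold's partial-detection window across d = 1..3.
decay_spec <- function(seed, ...) {
  phantom_spec(noise_sd = 0, gm_global_gain = 0, bg_noise_sd = 2.4,
               rng_seed = seed, ...)
}

# Fraction of a vector's spectral power inside [lo, hi] Hz (periodogram).
band_power_fraction <- function(x, tr, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * tr)
  sum(P[f >= lo & f <= hi]) / sum(P[f > 0])
}

# Shared, lazily computed perivascular profiles on the decay condition:
# computed once per test run, reused by the decay and dominance checks.
decay_profile_runs <- local({
  cache <- NULL
  function(n_runs = 10L) {
    if (!is.null(cache) && length(cache) >= n_runs) return(cache[seq_len(n_runs)])
    cache <<- lapply(seq_len(n_runs), function(seed) {
      ph <- make_phantom(decay_spec(seed))
      vs <- phantom_vessels(ph)
      pre <- preprocess_bold(ph$bold, ph$masks$wm, ph$masks$csf)
      perivascular_profiles(pre, vs$artery, vs$vein, ph$masks$gm,
                            brain = ph$masks$brain)
    })
    cache
  }
})

# Strip class/grid attributes so masks compare against plain logical arrays.
mask_arr <- function(m) {
  a <- unclass(m)
  attributes(a) <- list(dim = dim(a))
  a
}
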