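test_that("Pearson identities hold on three-point series", {
  g <- volume_grid(c(2L, 1L, 1L))
  up <- bold4d(array(c(1, 1, 2, 2, 3, 3), c(2, 1, 1, 3)), g, 1)
  m1 <- brain_mask(array(c(TRUE, FALSE), g$dim), g)
  m2 <- brain_mask(array(c(FALSE, TRUE), g$dim), g)
  expect_equal(seed_target_correlations(up, m1, m2)$r[1, 1], 1, tolerance = 1e-12)
  down <- bold4d(array(c(1, 3, 2, 2, 3, 1), c(2, 1, 1, 3)), g, 1)
  expect_equal(seed_target_correlations(down, m1, m2)$r[1, 1], -1, tolerance = 1e-12)
})

test_that("blocked correlations equal the dense oracle for any block size", {
  g <- volume_grid(c(10L, 10L, 6L))
  bold <- random_bold(g, nt = 40L, seed = 21)
  seeds <- random_mask(g, 0.035, seed = 22)     # ~20 seeds
  targets <- random_mask(g, 0.05, seed = 23)    # ~30 targets
  oracle <- dense_cor_oracle(bold, seeds, targets)
  for (bs in c(1L, 7L, 1024L)) {
    rows <- seed_target_correlations(bold, seeds, targets, block_size = bs)
    expect_lt(max(abs(rows$r - oracle)), 1e-10)
  }
  # correlation symmetry: swapping seed and target transposes the matrix
  rev_rows <- seed_target_correlations(bold, targets, seeds)
  expect_lt(max(abs(t(rev_rows$r) - oracle)), 1e-12)
})

test_that("zero-variance voxels are dropped as targets, flagged as seeds", {
  g <- volume_grid(c(4L, 1L, 1L))
  dat <- array(rnorm(4 * 20), c(4, 1, 1, 20))
  dat[2, 1, 1, ] <- 3                          # flat voxel
  bold <- bold4d(dat, g, 1)
  all4 <- brain_mask(array(TRUE, g$dim), g)
  rows <- seed_target_correlations(bold, all4, all4)
  expect_equal(length(rows$target_idx), 3L)    # flat target dropped
  expect_false(rows$seed_valid[2])
  expect_true(all(is.na(rows$r[2, ])))
  st <- vasconn:::connectivity_stats(bold, all4, all4)
  expect_equal(st$n_targets_valid[1], 2L)      # 3 valid minus self
  expect_true(is.na(st$D[2]))
  flat <- brain_mask(array(c(FALSE, TRUE, FALSE, FALSE), g$dim), g)
  expect_error(seed_target_correlations(bold, flat, all4), "zero variance")
})

test_that("degree counting follows threshold and mode", {
  rows <- fake_rows(matrix(c(0.9, 0.1, -0.3), 1))
  expect_equal(degree_map(rows, 0.15, "absolute"), 2)
  expect_equal(degree_map(rows, 0.15, "positive"), 1)
  # raising the threshold never increases degree
  set.seed(31)
  rnd <- fake_rows(matrix(runif(200, -1, 1), 10))
  d_prev <- degree_map(rnd, 0.05)
  for (thr in c(0.15, 0.4, 0.8)) {
    d <- degree_map(rnd, thr)
    expect_true(all(d <= d_prev))
    d_prev <- d
  }
})

test_that("strength and variance split by sign with population variance", {
  st <- strength_variance_maps(fake_rows(matrix(c(0.4, -0.2, 0.6), 1)))
  expect_equal(st$S_pos, 0.5)
  expect_equal(st$S_neg, -0.2)
  expect_equal(st$var_pos, 0.01)               # population variance of {.4, .6}
  expect_equal(st$var_neg, 0)
  expect_equal(st$n_pos, 2L)
  # all-negative rows leave the positive class undefined
  st <- strength_variance_maps(fake_rows(matrix(c(-0.1, -0.5), 1)))
  expect_true(is.na(st$S_pos))
  expect_equal(st$n_pos, 0L)
  # constant positive class has zero variance
  st <- strength_variance_maps(fake_rows(matrix(c(0.3, 0.3, 0.3), 1)))
  expect_equal(st$var_pos, 0)
})

test_that("self-pairs are excluded from every statistic", {
  g <- volume_grid(c(3L, 1L, 1L))
  bold <- random_bold(g, nt = 30L, seed = 33)
  all3 <- brain_mask(array(TRUE, g$dim), g)
  rows <- seed_target_correlations(bold, all3, all3)
  expect_equal(diag(rows$r), rep(1, 3), tolerance = 1e-12)
  st <- vasconn:::connectivity_stats(bold, all3, all3, threshold = 0.99)
  expect_true(all(st$D == 0 | st$D == 1))      # the r = 1 self-pair never counts
  expect_true(all(st$n_targets_valid == 2L))
})

test_that("category metrics match a dense recomputation on a toy", {
  g <- volume_grid(c(6L, 5L, 4L))
  bold <- random_bold(g, nt = 35L, seed = 41)
  set.seed(40)
  arr <- array(0L, g$dim)
  arr[sample(seq_len(prod(g$dim)), 10L)] <- rep(1:2, 5)
  labels <- vessel_labels(arr, g)
  art <- label_mask(labels, "artery"); ven <- label_mask(labels, "vein")
  gm <- brain_mask(array(TRUE, g$dim), g)
  cats <- category_metrics(bold, art, ven, gm, threshold = 0.15)
  pairs <- list(VV = list(ven, ven), AA = list(art, art), AV = list(art, ven),
                VA = list(ven, art), V_GM = list(ven, gm), A_GM = list(art, gm),
                GM_GM = list(gm, gm))
  for (nm in names(pairs)) {
    rmat <- dense_cor_oracle(bold, pairs[[nm]][[1]], pairs[[nm]][[2]])
    ref <- oracle_stats(rmat, mask_indices(pairs[[nm]][[1]]),
                        mask_indices(pairs[[nm]][[2]]), 0.15, "absolute")
    got <- cats[[nm]]
    expect_equal(got$D, as.numeric(ref$D), tolerance = 1e-10)
    expect_equal(got$S_pos, ref$S_pos, tolerance = 1e-10)
    expect_equal(got$S_neg, ref$S_neg, tolerance = 1e-10)
    expect_equal(got$var_pos, ref$var_pos, tolerance = 1e-10)
    expect_equal(got$var_neg, ref$var_neg, tolerance = 1e-10)
    expect_equal(got$n_targets_valid, ref$n_valid)
  }
  expect_error(category_metrics(bold, ven, ven, gm), "overlap")
})

test_that("arterial-venous degree sums are conserved under transposition", {
  for (seed in c(51, 52, 53)) {
    g <- volume_grid(c(6L, 6L, 4L))
    bold <- random_bold(g, nt = 25L, seed = seed)
    art <- random_mask(g, 0.06, seed = seed + 100)
    ven_raw <- random_mask(g, 0.08, seed = seed + 200)
    ven <- mask_diff(ven_raw, art)
    gm <- brain_mask(array(TRUE, g$dim), g)
    cats <- category_metrics(bold, art, ven, gm, with_gm = FALSE)
    expect_identical(sum(cats$AV$D), sum(cats$VA$D))
  }
})

test_that("noise-free phantom saturates within-type degree at any threshold", {
  ph <- make_phantom(phantom_spec(noise_sd = 0, n_volumes = 48L))
  vs <- phantom_vessels(ph)
  cats <- category_metrics(ph$bold, vs$artery, vs$vein, ph$masks$gm,
                           threshold = 0.9, with_gm = FALSE)
  nv <- mask_count(vs$vein)
  expect_equal(cats$VV$D, rep(nv - 1, nv))
  expect_equal(cats$AV$D, rep(nv, mask_count(vs$artery)))
})

test_that("ratio maps divide metrics and respect subset bounds", {
  g <- volume_grid(c(6L, 5L, 4L))
  bold <- random_bold(g, nt = 30L, seed = 61)
  arr <- array(0L, g$dim); arr[2:7] <- 2L; arr[30:33] <- 1L
  labels <- vessel_labels(arr, g)
  ven <- label_mask(labels, "vein"); art <- label_mask(labels, "artery")
  gm <- brain_mask(array(TRUE, g$dim), g)
  cats <- category_metrics(bold, art, ven, gm, threshold = 0.15)
  rat <- ratio_maps(cats$VV, cats$V_GM)
  ok <- !is.na(rat$D_ratio)
  expect_true(all(rat$D_ratio[ok] >= 0 & rat$D_ratio[ok] <= 1))
  expect_equal(rat$D_ratio[ok], (cats$VV$D / cats$V_GM$D)[ok])
  # hand arithmetic on a synthetic pair
  num <- cats$VV; den <- cats$V_GM
  num$D <- rep(10, num$n_seeds); den$D <- rep(40, den$n_seeds)
  expect_equal(ratio_maps(num, den)$D_ratio, rep(0.25, num$n_seeds))
  den$D[1] <- 0
  expect_true(is.na(ratio_maps(num, den)$D_ratio[1]))
  expect_error(ratio_maps(cats$VV, cats$A_GM), "seed masks")
})

test_that("group summaries average sessions and match a quartile oracle", {
  fake_cm <- function(D) {
    structure(list(category = "VV", seed_idx = seq_along(D), n_seeds = length(D),
                   n_targets = 10L, threshold = 0.15, mode = "absolute",
                   grid = toy_grid(), D = D,
                   S_pos = rep(NA_real_, length(D)), S_neg = rep(NA_real_, length(D)),
                   var_pos = rep(NA_real_, length(D)), var_neg = rep(NA_real_, length(D)),
                   n_pos = rep(0L, length(D)), n_neg = rep(0L, length(D)),
                   n_targets_valid = rep(10L, length(D))), class = "conn_maps")
  }
  gs <- group_summarize(list(fake_cm(c(1, 3)), fake_cm(c(3, 5))))
  d_row <- gs$group[gs$group$metric == "mu_D", ]
  expect_equal(d_row$mean, 3)
  expect_equal(d_row$median, 3)
  # single session: group mean equals the session value
  gs1 <- group_summarize(list(fake_cm(c(2, 6))))
  expect_equal(gs1$group[gs1$group$metric == "mu_D", "mean"], 4)
  # undefined metrics stay NA, not zero
  expect_true(is.na(d_row$q1) == FALSE)
  s_row <- gs$group[gs$group$metric == "mu_S_pos", ]
  expect_true(is.na(s_row$mean))
  expect_equal(s_row$n_sessions, 0L)
  # quartiles on eight sessions against an order-statistics oracle
  set.seed(77)
  vals <- round(runif(8), 3)
  gs8 <- group_summarize(lapply(vals, function(v) fake_cm(rep(v, 3))))
  row8 <- gs8$group[gs8$group$metric == "mu_D", ]
  sv <- sort(vals)
  interp <- function(p) {                      # linear interpolation, type 7
    h <- (length(sv) - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[min(lo + 1, length(sv))] - sv[lo])
  }
  expect_equal(row8$q1, interp(0.25))
  expect_equal(row8$median, interp(0.5))
  expect_equal(row8$q3, interp(0.75))
  expect_equal(row8$min, min(vals))
  expect_equal(row8$max, max(vals))
})

test_that("metric volumes place per-seed values at seed voxels", {
  g <- volume_grid(c(4L, 4L, 3L))
  bold <- random_bold(g, nt = 20L, seed = 71)
  seeds <- random_mask(g, 0.2, seed = 72)
  targets <- random_mask(g, 0.4, seed = 73)
  cm <- vasconn:::connectivity_stats(bold, seeds, targets)
  vol <- metric_volume(cm, "D")
  expect_equal(vol[mask_indices(seeds)], as.numeric(cm$D))
  expect_true(all(is.na(vol[!unclass(seeds)])))
  expect_error(metric_volume(cm, "nope"), "unknown metric")
})
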