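test_that("segmentation fusion is a voxelwise union", {
  g <- toy_grid()
  a <- random_mask(g, 0.2, seed = 11)
  expect_identical(mask_arr(combine_segmentations(list(a, a))), mask_arr(a))
  # two disjoint single-voxel masks
  m1 <- array(FALSE, g$dim); m1[2, 2, 2] <- TRUE
  m2 <- array(FALSE, g$dim); m2[5, 5, 5] <- TRUE
  fused <- combine_segmentations(list(brain_mask(m1, g), brain_mask(m2, g)))
  expect_equal(mask_count(fused), 2L)
  # random masks match the logical-or oracle voxel by voxel
  ms <- lapply(1:3, function(s) random_mask(g, 0.3, seed = s))
  oracle <- mask_arr(ms[[1]]) | mask_arr(ms[[2]]) | mask_arr(ms[[3]])
  expect_identical(mask_arr(combine_segmentations(ms)), oracle)
  # commutative and associative
  expect_identical(mask_arr(combine_segmentations(ms)),
                   mask_arr(combine_segmentations(rev(ms))))
  ab <- combine_segmentations(ms[1:2])
  expect_identical(mask_arr(combine_segmentations(list(ab, ms[[3]]))),
                   mask_arr(combine_segmentations(ms)))
})

test_that("fusion rejects mismatched grids, naming the offender", {
  g <- toy_grid()
  g2 <- toy_grid(c(8L, 8L, 8L), vox = c(2, 2, 2))
  expect_error(
    combine_segmentations(list(random_mask(g, 0.2, 1), random_mask(g2, 0.2, 1))),
    "input 2")
  expect_error(combine_segmentations(list()), "non-empty")
})

test_that("mask downsampling follows the occupancy rule", {
  fine <- volume_grid(c(4L, 4L, 4L), c(2, 2, 2))
  coarse <- volume_grid(c(2L, 2L, 2L), c(4, 4, 4))
  # fully covered block -> set at any occupancy
  a <- array(FALSE, fine$dim); a[1:2, 1:2, 1:2] <- TRUE
  for (occ in list("any", 0.5, 1)) {
    out <- downsample_mask(brain_mask(a, fine), coarse, occ)
    expect_true(unclass(out)[1, 1, 1])
    expect_equal(mask_count(out), 1L)
  }
  # 5/8 of the block: fraction 0.625
  a <- array(FALSE, fine$dim)
  a[cbind(c(1, 2, 1, 2, 1), c(1, 1, 2, 2, 1), c(1, 1, 1, 1, 2))] <- TRUE
  m <- brain_mask(a, fine)
  expect_true(unclass(downsample_mask(m, coarse, 0.5))[1, 1, 1])
  expect_false(unclass(downsample_mask(m, coarse, 0.75))[1, 1, 1])
  # empty in, empty out
  empty <- brain_mask(array(FALSE, fine$dim), fine)
  expect_equal(mask_count(downsample_mask(empty, coarse)), 0L)
  # "any" keeps a single fine voxel alive
  a <- array(FALSE, fine$dim); a[3, 3, 3] <- TRUE
  expect_equal(mask_count(downsample_mask(brain_mask(a, fine), coarse, "any")), 1L)
})

test_that("downsampling is antitone in the occupancy threshold", {
  fine <- volume_grid(c(12L, 12L, 8L), c(1, 1, 1))
  coarse <- volume_grid(c(6L, 6L, 4L), c(2, 2, 2))
  m <- random_mask(fine, 0.4, seed = 5)
  prev <- downsample_mask(m, coarse, 0.25)
  for (occ in c(0.5, 0.75, 1)) {
    cur <- downsample_mask(m, coarse, occ)
    expect_true(all(unclass(prev)[unclass(cur)]))   # cur subset of prev
    prev <- cur
  }
  expect_error(downsample_mask(m, volume_grid(c(5L, 6L, 4L), c(2.4, 2, 2))),
               "divide")
})

test_that("label splitting partitions the vessel mask", {
  g <- toy_grid()
  lab_arr <- array(0L, g$dim)
  lab_arr[1:10] <- c(rep(1L, 6), rep(2L, 4))
  mask <- brain_mask(array(seq_len(prod(g$dim)) <= 10, g$dim), g)
  parts <- split_by_label(mask, vessel_labels(lab_arr, g))
  expect_equal(mask_count(parts$arterial), 6L)
  expect_equal(mask_count(parts$venous), 4L)
  expect_identical(mask_arr(mask_or(parts$arterial, parts$venous)), mask_arr(mask))
  expect_equal(mask_count(mask_and(parts$arterial, parts$venous)), 0L)
  # all-vein labels leave the arterial side empty
  lab_arr[1:10] <- 2L
  parts <- split_by_label(mask, vessel_labels(lab_arr, g))
  expect_equal(mask_count(parts$arterial), 0L)
  expect_equal(mask_count(parts$venous), 10L)
  # unlabeled vessel voxel is an error listing coordinates
  lab_arr[2] <- 0L
  expect_error(split_by_label(mask, vessel_labels(lab_arr, g)),
               "unlabeled.*\\(2,1,1\\)")
})

test_that("label splitting holds on random labelings", {
  g <- toy_grid()
  set.seed(42)
  lab_arr <- array(sample(0:2, prod(g$dim), replace = TRUE), g$dim)
  mask <- brain_mask(lab_arr > 0L, g)
  parts <- split_by_label(mask, vessel_labels(lab_arr, g))
  expect_identical(mask_arr(parts$arterial), lab_arr == 1L)
  expect_identical(mask_arr(parts$venous), lab_arr == 2L)
})

test_that("GM restriction is plain intersection", {
  g <- toy_grid()
  m <- random_mask(g, 0.3, seed = 1)
  gm <- random_mask(g, 0.5, seed = 2)
  expect_identical(mask_arr(restrict_to_gm(m, gm)), mask_arr(m) & mask_arr(gm))
  # mask inside gm unchanged; disjoint mask empties
  inner <- brain_mask(unclass(m) & unclass(gm), g)
  expect_identical(mask_arr(restrict_to_gm(inner, gm)), mask_arr(inner))
  outside <- brain_mask(unclass(m) & !unclass(gm), g)
  expect_equal(mask_count(restrict_to_gm(outside, gm)), 0L)
})

test_that("shells around a single voxel have the analytic sizes", {
  g <- toy_grid(c(9L, 9L, 9L))
  a <- array(FALSE, g$dim); a[5, 5, 5] <- TRUE
  src <- brain_mask(a, g)
  sh26 <- make_shells(src, K = 3, connectivity = 26)
  expect_equal(vapply(sh26$shells, mask_count, 0L), c(26L, 98L, 218L))
  sh6 <- make_shells(src, K = 1, connectivity = 6)
  expect_equal(mask_count(sh6$shells[[1]]), 6L)
  expect_error(make_shells(brain_mask(array(FALSE, g$dim), g), K = 1), "empty")
})

test_that("shells equal brute-force distance classification", {
  g <- toy_grid(c(10L, 10L, 7L))
  m <- random_mask(g, 0.03, seed = 9)
  src <- which(unclass(m), arr.ind = TRUE)
  cheb <- function(p) min(pmax(abs(src[, 1] - p[1]), abs(src[, 2] - p[2]),
                               abs(src[, 3] - p[3])))
  city <- function(p) min(abs(src[, 1] - p[1]) + abs(src[, 2] - p[2]) +
                            abs(src[, 3] - p[3]))
  all_vox <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:7))
  d26 <- apply(all_vox, 1, cheb)
  d6 <- apply(all_vox, 1, city)
  sh26 <- make_shells(m, K = 3, connectivity = 26)
  sh6 <- make_shells(m, K = 2, connectivity = 6)
  for (k in 1:3) {
    expect_identical(which(unclass(sh26$shells[[k]])), which(d26 == k))
  }
  for (k in 1:2) {
    expect_identical(which(unclass(sh6$shells[[k]])), which(d6 == k))
  }
})

test_that("shell sets satisfy disjointness, partition and clipping", {
  g <- toy_grid(c(10L, 10L, 8L))
  m <- random_mask(g, 0.05, seed = 3)
  K <- 3
  sh <- make_shells(m, K = K)
  acc <- unclass(m)
  for (k in seq_len(K)) {
    s <- unclass(sh$shells[[k]])
    expect_false(any(s & acc))                 # disjoint from source + earlier
    acc <- acc | s
  }
  expect_identical(array(acc, dim(acc)), mask_arr(dilate_mask(m, K)))  # partition of dilation
  # dilation monotonicity
  expect_true(all(unclass(dilate_mask(m, 1))[unclass(m)]))
  expect_true(all(unclass(dilate_mask(m, 2))[unclass(dilate_mask(m, 1))]))
  # exclude and within constraints are honored
  excl <- random_mask(g, 0.2, seed = 4)
  within <- random_mask(g, 0.7, seed = 5)
  sh2 <- make_shells(m, K = 2, exclude = excl, within = within)
  for (k in 1:2) {
    s <- unclass(sh2$shells[[k]])
    expect_false(any(s & unclass(excl)))
    expect_true(all(unclass(within)[s]))
  }
})
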