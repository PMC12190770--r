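test_that("mask thresholding is strict and matches a voxelwise oracle", {
  withr::local_seed(101)
  vol <- random_tiny_volume(c(4, 4, 4))
  arr <- get_channel(vol, "DAPI")
  expect_true(all(make_region_mask(vol, "DAPI", min(arr) - 1)$voxels))
  expect_false(any(make_region_mask(vol, "DAPI", max(arr))$voxels))
  thr <- median(arr)
  m <- make_region_mask(vol, "DAPI", thr)
  oracle <- array(FALSE, dim(arr))
  for (z in 1:4) for (y in 1:4) for (x in 1:4) {
    oracle[z, y, x] <- arr[z, y, x] > thr
  }
  expect_identical(m$voxels, oracle)
})

test_that("raising the threshold never adds voxels to a mask", {
  withr::local_seed(7)
  vol <- random_tiny_volume(c(5, 5, 5))
  thresholds <- sort(runif(6, 0, 1000))
  prev <- make_region_mask(vol, "GFP", thresholds[1])$voxels
  for (t in thresholds[-1]) {
    cur <- make_region_mask(vol, "GFP", t)$voxels
    expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("Otsu threshold matches the exhaustive within-class-SS oracle", {
  # 6-voxel toy histogram and seeded random cases
  toy <- c(10, 12, 11, 200, 210, 205)
  expect_equal(auto_threshold(array(toy, c(1, 2, 3))), otsu_oracle(toy))
  withr::local_seed(33)
  for (i in 1:20) {
    x <- sample(c(rpois(20, 10), rpois(20, 150)))
    expect_equal(auto_threshold(array(x, c(2, 4, 5))), otsu_oracle(x))
  }
  # separation property on a bimodal image
  bim <- c(rep(10, 30), rep(200, 20))
  t <- auto_threshold(array(bim, c(2, 5, 5)))
  expect_gt(t, 9.999); expect_lt(t, 200)
  expect_equal(auto_threshold(NULL, method = "manual", value = 37), 37)
  expect_error(auto_threshold(array(5, c(1, 2, 2))), "constant")
})

test_that("mask intersection is the elementwise conjunction", {
  withr::local_seed(5)
  m1 <- random_mask(name = "DAPI"); m2 <- random_mask(name = "GFP")
  expect_identical(intersect_masks(m1, m1)$voxels, m1$voxels)
  inter <- intersect_masks(m1, m2)
  expect_identical(inter$voxels, m1$voxels & m2$voxels)
  expect_identical(inter$region_name, "DAPI_GFP")
  expect_true(all(inter$voxels <= m1$voxels) && all(inter$voxels <= m2$voxels))
  disjoint <- region_mask(!m1$voxels, "GFP")
  expect_false(any(intersect_masks(m1, disjoint)$voxels))
  bad <- random_mask(c(4, 4, 4))
  expect_error(intersect_masks(m1, bad), "shape")
})

test_that("voxelwise normalization divides, excludes zero-reporter voxels, and is homogeneous", {
  vox <- array(0, c(3, 1, 1, 2))
  vox[1, , , ] <- c(5, 5); vox[2, , , ] <- c(2, 3); vox[3, , , ] <- c(4, 9)
  vol <- channel_volume(vox, c("DAPI", "GFP", "EFFECTOR"), bit_depth = 16)
  expect_equal(as.vector(normalize_effector(vol)), c(2, 3))
  # identity divisor
  vox[2, , , ] <- 1
  expect_equal(as.vector(normalize_effector(channel_volume(vox, c("DAPI", "GFP", "EFFECTOR")))),
               c(4, 9))
  # homogeneity in the effector
  vox[3, , , ] <- c(8, 18)
  expect_equal(as.vector(normalize_effector(channel_volume(vox, c("DAPI", "GFP", "EFFECTOR")))),
               c(8, 18))
  # zero-reporter voxels are NA, all-zero reporter warns
  vox[2, , , ] <- c(0, 2)
  out <- normalize_effector(channel_volume(vox, c("DAPI", "GFP", "EFFECTOR")))
  expect_true(is.na(out[1, 1, 1])); expect_equal(out[1, 1, 2], 9)
  vox[2, , , ] <- 0
  expect_warning(normalize_effector(channel_volume(vox, c("DAPI", "GFP", "EFFECTOR"))),
                 "zero everywhere")
})

test_that("region medians match a sort-based oracle and handle empty masks", {
  withr::local_seed(88)
  vol <- random_tiny_volume(c(5, 5, 5))
  norm <- normalize_effector(vol)
  masks <- list(DAPI = random_mask(p = 0.4, name = "DAPI"),
                GFP = random_mask(p = 0.4, name = "GFP"))
  masks$DAPI_GFP <- intersect_masks(masks$DAPI, masks$GFP)
  med <- region_medians(vol, norm, masks)
  eff <- get_channel(vol, "EFFECTOR")
  sort_median <- function(v) {
    v <- sort(v[!is.na(v)])
    n <- length(v)
    if (n == 0) return(NA_real_)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  expect_equal(med$raw_dapi, sort_median(eff[masks$DAPI$voxels]))
  expect_equal(med$norm_gfp, sort_median(norm[masks$GFP$voxels]))
  expect_equal(med$raw_dapi_gfp, sort_median(eff[masks$DAPI_GFP$voxels]))
  expect_equal(med$norm_dapi_gfp, sort_median(norm[masks$DAPI_GFP$voxels]))
  # definitional check on an odd set
  expect_equal(sort_median(c(1, 2, 3, 9, 10)), 3)
  # empty mask yields NA + note, never silent zero
  masks$GFP <- region_mask(array(FALSE, c(5, 5, 5)), "GFP")
  masks$DAPI_GFP <- intersect_masks(masks$DAPI, masks$GFP)
  med2 <- region_medians(vol, norm, masks)
  expect_true(is.na(med2$raw_gfp))
  expect_match(med2$median_notes, "empty_region_gfp")
})

test_that("medians are invariant to slice permutation and to joint channel scaling", {
  withr::local_seed(12)
  vol <- random_tiny_volume(c(6, 4, 4))
  masks <- list(DAPI = random_mask(c(6, 4, 4), 0.5, "DAPI"),
                GFP = random_mask(c(6, 4, 4), 0.5, "GFP"))
  masks$DAPI_GFP <- intersect_masks(masks$DAPI, masks$GFP)
  med <- region_medians(vol, normalize_effector(vol), masks)
  perm <- sample(6)
  vox_p <- vol$voxels[, perm, , , drop = FALSE]
  masks_p <- lapply(masks, function(m) region_mask(m$voxels[perm, , , drop = FALSE], m$region_name))
  vol_p <- channel_volume(vox_p, vol$channel_names, vol$voxel_size_um, vol$bit_depth)
  med_p <- region_medians(vol_p, normalize_effector(vol_p), masks_p)
  expect_equal(med_p[1:6], med[1:6])
  # scaling effector and reporter jointly leaves normalized medians unchanged
  vox_s <- vol$voxels
  vox_s[2, , , ] <- vox_s[2, , , ] * 3
  vox_s[3, , , ] <- vox_s[3, , , ] * 3
  vol_s <- channel_volume(vox_s, vol$channel_names, vol$voxel_size_um, vol$bit_depth)
  med_s <- region_medians(vol_s, normalize_effector(vol_s), masks)
  expect_equal(med_s$norm_dapi, med$norm_dapi)
  expect_equal(med_s$norm_gfp, med$norm_gfp)
  expect_equal(med_s$norm_dapi_gfp, med$norm_dapi_gfp)
})

test_that("max projection takes the per-pixel maximum over z", {
  withr::local_seed(9)
  vol <- random_tiny_volume(c(3, 4, 4))
  proj <- max_projection(vol, "EFFECTOR")
  arr <- get_channel(vol, "EFFECTOR")
  oracle <- matrix(0, 4, 4)
  for (y in 1:4) for (x in 1:4) oracle[y, x] <- max(arr[, y, x])
  expect_equal(proj, oracle)
  # single slice: the projection is the slice
  one <- channel_volume(vol$voxels[, 1, , , drop = FALSE],
                        vol$channel_names, vol$voxel_size_um, vol$bit_depth)
  expect_equal(max_projection(one, "EFFECTOR"), matrix(arr[1, , ], 4, 4))
  # masked ("nuclear") projection zeroes outside the mask before projecting
  m <- random_mask(c(3, 4, 4), 0.5, "DAPI")
  projm <- max_projection(vol, "EFFECTOR", m)
  oracle_m <- matrix(0, 4, 4)
  marr <- arr * m$voxels
  for (y in 1:4) for (x in 1:4) oracle_m[y, x] <- max(marr[, y, x])
  expect_equal(projm, oracle_m)
})

test_that("two disjoint bright slices project to their union", {
  vox <- array(0, c(1, 2, 3, 3))
  vox[1, 1, 1, 1] <- 100
  vox[1, 2, 3, 3] <- 50
  vol <- channel_volume(vox, "A", bit_depth = 8)
  proj <- max_projection(vol, "A")
  expect_equal(proj[1, 1], 100)
  expect_equal(proj[3, 3], 50)
  expect_equal(sum(proj > 0), 2)
})

test_that("roi_overlap reports inside/outside fractions and Dice", {
  d <- c(2, 3, 3)
  a <- array(FALSE, d); r <- array(FALSE, d)
  a[1, 1:2, 1:2] <- TRUE              # |A| = 4
  r[1, 1:2, 1] <- TRUE; r[1, 1:2, 3] <- TRUE; r[2, 1:2, 1] <- TRUE  # |R| = 6
  ov <- roi_overlap(region_mask(a, "ACT"), region_mask(r, "ROI"))
  expect_equal(ov$inside_fraction, 0.5)
  expect_equal(ov$outside_fraction, 0.5)
  expect_equal(ov$dice, 0.4)
  same <- roi_overlap(region_mask(a, "ACT"), region_mask(a, "ROI"))
  expect_equal(same$inside_fraction, 1)
  expect_equal(same$dice, 1)
  disj <- roi_overlap(region_mask(a, "ACT"), region_mask(!a, "ROI"))
  expect_equal(disj$inside_fraction, 0)
  none <- roi_overlap(region_mask(array(FALSE, d), "ACT"), region_mask(r, "ROI"))
  expect_equal(none$dice, 0)
  expect_match(none$note, "empty_activation_mask")
})
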