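test_that("smoothness estimation recovers a known kernel and bounds white noise", {
  set.seed(61)
  d <- c(16, 16, 16); g <- grid_geometry(d, 3); mask <- all_mask(d)
  est <- replicate(50, {
    maps <- lapply(1:4, function(i) smooth_gaussian(array(rnorm(prod(d)), d), 6, 3))
    mean(estimate_smoothness(maps, mask, g)$fwhm_mm)
  })
  expect_lt(abs(mean(est) - 6) / 6, 0.15)
  # unsmoothed white noise: estimate bounded by 1.5 voxels
  un <- estimate_smoothness(lapply(1:6, function(i) array(rnorm(prod(d)), d)),
                            mask, g)
  expect_true(all(un$fwhm_mm <= 3 * 1.5))
  expect_error(estimate_smoothness(lapply(1:4, function(i) array(rnorm(8), c(2, 2, 2))),
                                   all_mask(c(2, 2, 2)),
                                   grid_geometry(c(2, 2, 2), 3)),
               "3 voxels")
})

test_that("resels double when the mask volume doubles at fixed smoothness", {
  set.seed(62)
  d <- c(12, 12, 12); g <- grid_geometry(d, 3)
  maps <- lapply(1:4, function(i) smooth_gaussian(array(rnorm(prod(d)), d), 6, 3))
  m1 <- array(FALSE, d); m1[, , 1:6] <- TRUE
  m2 <- array(TRUE, d)
  s1 <- estimate_smoothness(maps, m1, g)
  s2 <- estimate_smoothness(maps, m2, g)
  ratio <- (s2$resels / s1$resels) /
    ((s2$n_mask_voxels / s1$n_mask_voxels) *
       prod(s1$fwhm_mm) / prod(s2$fwhm_mm))
  expect_equal(ratio, 1, tolerance = 1e-10)
})

test_that("an empty supra-threshold set yields zero clusters, not an error", {
  g <- grid_geometry(c(6, 6, 6), 3)
  zm <- stat_map(array(0, c(6, 6, 6)), "Z", geometry = g,
                 mask = all_mask(c(6, 6, 6)))
  sm <- list(fwhm_mm = rep(6, 3), resels = 27, n_mask_voxels = 216)
  cr <- grf_cluster_correct(zm, sm)
  expect_identical(nrow(cr$clusters), 0L)
  expect_true(all(cr$label_field == 0))
})

test_that("corrected p decreases with cluster size and respects alpha", {
  g <- grid_geometry(c(12, 12, 12), 3)
  sm <- list(fwhm_mm = rep(6, 3), resels = 12^3 * 27 / 216,
             n_mask_voxels = 12^3)
  mk <- function(len) {
    v <- array(0, c(12, 12, 12)); v[1:len, 1, 1] <- 3
    cr <- grf_cluster_correct(stat_map(v, "Z", geometry = g,
                                       mask = all_mask(c(12, 12, 12))), sm)
    cr$clusters$p_corrected
  }
  p_small <- mk(2); p_big <- mk(10)
  expect_lt(p_big, p_small)
})

test_that("peak localization picks the maximum with smallest-index ties", {
  g <- grid_geometry(c(6, 6, 6), 3)
  v <- array(0, c(6, 6, 6))
  cl <- array(FALSE, c(6, 6, 6))
  cl[2, 3, 4] <- TRUE
  v[2, 3, 4] <- 5
  pk <- find_peak(cl, v, g)
  expect_identical(pk$voxel, c(2L, 3L, 4L))
  expect_identical(pk$value, 5)
  expect_equal(pk$mni, as.numeric(voxel_to_mni(c(2, 3, 4), g)))
  # tie: two equal maxima -> smallest linear index wins
  cl[5, 3, 4] <- TRUE; v[5, 3, 4] <- 5
  expect_identical(find_peak(cl, v, g)$voxel, c(2L, 3L, 4L))
  expect_error(find_peak(array(FALSE, c(6, 6, 6)), v, g), "empty")
})

test_that("planted peaks are recovered within one voxel", {
  set.seed(63)
  d <- c(12, 12, 12); g <- grid_geometry(d, 3)
  target <- c(7.5, -4.5, 1.5)
  vox <- mni_to_voxel(target, g)
  v <- smooth_gaussian(array(rnorm(prod(d), sd = 0.05), d), 4, 3)
  v[vox[1], vox[2], vox[3]] <- v[vox[1], vox[2], vox[3]] + 3
  pk <- find_peak(array(TRUE, d), v, g)
  expect_lte(max(abs(pk$mni - target)), 3)
})

test_that("sphere extraction: constant maps, gradients, and errors", {
  g <- grid_geometry(c(10, 10, 10), 3)
  const <- array(4.2, c(10, 10, 10))
  expect_equal(extract_sphere_mean(const, c(4.5, 1.5, -1.5), g, 5), 4.2)
  # linear gradient: mean over the symmetric voxel set equals center value
  grad <- array(0, c(10, 10, 10))
  for (i in 1:10) grad[i, , ] <- i * 2
  ctr_val <- grad[7, 5, 5]
  mm <- voxel_to_mni(c(7, 5, 5), g)
  expect_equal(extract_sphere_mean(grad, as.numeric(mm), g, 5), ctr_val)
  expect_error(extract_sphere_mean(const, c(500, 0, 0), g, 5), "no voxel")
})

test_that("permutation null is deterministic and detects planted effects", {
  set.seed(64)
  d <- c(8, 8, 8); g <- grid_geometry(d, 3); mask <- all_mask(d)
  groups <- rep(c("AVH", "Control"), each = 8)
  cov <- runif(16)
  eff <- array(0, d); eff[3:6, 3:6, 3:6] <- 1.2
  zm <- lapply(1:16, function(i) {
    base <- smooth_gaussian(array(rnorm(prod(d)), d), 5, 3)
    if (groups[i] == "AVH") base + eff else base
  })
  n1 <- permutation_cluster_null(zm, groups, cov, mask, g, n_perm = 120,
                                 seed = 5, statistic = "two_sample")
  n2 <- permutation_cluster_null(zm, groups, cov, mask, g, n_perm = 120,
                                 seed = 5, statistic = "two_sample")
  expect_identical(n1, n2)
  # observed max cluster with the true labels beats the permutation null
  tm <- stat_to_z(two_sample_t_map(zm[groups == "AVH"], zm[groups == "Control"],
                                   cov, mask, g))
  obs <- max(label_clusters(tm$values > 2.3)$sizes)
  expect_gt(obs, quantile(n1, 0.95))
  expect_lte(permutation_cluster_p(n1, obs), 0.05)
})
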