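test_that("first-level map: nulls vanish, strong effects survive, extent filters", {
  set.seed(41)
  d <- c(10, 10, 6); g <- grid_geometry(d, 3); mask <- all_mask(d)
  # null: tiny symmetric noise
  null_maps <- lapply(1:20, function(i) array(rnorm(prod(d), sd = 1e-3), d))
  res0 <- one_sample_group_map(null_maps, mask, g)
  expect_identical(sum(res0$significant), 0L)
  expect_identical(nrow(res0$clusters), 0L)
  # mean z = 1.0 in a 100-voxel block, n = 20, noise sd 0.3 -> survives
  eff <- array(0, d); eff[3:7, 3:7, 2:5] <- 1
  alt_maps <- lapply(1:20, function(i) eff + array(rnorm(prod(d), sd = 0.3), d))
  res1 <- one_sample_group_map(alt_maps, mask, g)
  expect_true(all(res1$significant[3:7, 3:7, 2:5]))
  expect_gte(nrow(res1$clusters), 1L)
  # a 19-voxel surviving component is removed by the >= 20 extent rule
  eff19 <- array(0, d)
  lin <- which(array(TRUE, d))[1:19]
  idx <- arrayInd(lin, d)
  eff19[idx] <- 1
  maps19 <- lapply(1:20, function(i) eff19 + array(rnorm(prod(d), sd = 0.05), d))
  res19 <- one_sample_group_map(maps19, mask, g, extent = 20)
  expect_identical(sum(res19$significant), 0L)
  res18 <- one_sample_group_map(maps19, mask, g, extent = 19)
  expect_gte(sum(res18$significant), 19L)
  expect_error(one_sample_group_map(null_maps[1:2], mask, g), "3 subjects")
})

test_that("ANCOVA F map equals a hand-sized two-model least-squares oracle", {
  set.seed(42)
  d <- c(4, 4, 4); g <- grid_geometry(d, 3); mask <- all_mask(d)
  groups <- c("AVH", "AVH", "NonAVH", "NonAVH", "Control", "Control")
  cov <- c(0.10, 0.15, 0.08, 0.12, 0.20, 0.05)
  zm <- lapply(1:6, function(i) array(rnorm(prod(d)), d))
  fm <- ancova_f_map(zm, groups, cov, mask, g)
  expect_equal(fm$df, c(2, 2))
  for (v in c(1, 17, 50)) {
    y <- vapply(zm, function(a) a[v], numeric(1))
    gf <- factor(groups, levels = c("Control", "AVH", "NonAVH"))
    full <- lm(y ~ gf + I(cov - mean(cov)))
    red <- lm(y ~ I(cov - mean(cov)))
    Fo <- ((sum(resid(red)^2) - sum(resid(full)^2)) / 2) /
      (sum(resid(full)^2) / 2)
    expect_equal(fm$values[v], Fo, tolerance = 1e-8)
  }
  expect_error(ancova_f_map(zm[1:5], groups[1:5], cov[1:5], mask, g),
               "at least 2")
})

test_that("with two groups the ANCOVA F equals the squared adjusted t", {
  set.seed(43)
  d <- c(6, 6, 6); g <- grid_geometry(d, 3); mask <- all_mask(d)
  zm <- lapply(1:14, function(i) array(rnorm(prod(d)), d))
  groups <- rep(c("AVH", "Control"), each = 7)
  cov <- runif(14)
  fm <- ancova_f_map(zm, groups, cov, mask, g)
  tm <- two_sample_t_map(zm[1:7], zm[8:14], cov, mask, g)
  expect_equal(fm$values, tm$values^2, tolerance = 1e-10)
  expect_identical(fm$df[2], tm$df)
})

test_that("a zero covariate reduces to plain one-way ANOVA with df (2, n-3)", {
  set.seed(44)
  d <- c(4, 4, 4); g <- grid_geometry(d, 3); mask <- all_mask(d)
  groups <- rep(c("AVH", "NonAVH", "Control"), each = 5)
  zm <- lapply(1:15, function(i) array(rnorm(prod(d)), d))
  fm <- ancova_f_map(zm, groups, rep(0, 15), mask, g)
  expect_equal(fm$df, c(2, 12))
  v <- 23
  y <- vapply(zm, function(a) a[v], numeric(1))
  a1 <- anova(lm(y ~ factor(groups)))
  expect_equal(fm$values[v], a1$`F value`[1], tolerance = 1e-10)
})

test_that("two-sample t map is antisymmetric and zero for identical groups", {
  set.seed(45)
  d <- c(4, 4, 4); g <- grid_geometry(d, 3); mask <- all_mask(d)
  zm <- lapply(1:5, function(i) array(rnorm(prod(d)), d))
  cov <- runif(10)
  # identical groups, no covariate: the group contrast is exactly zero
  same <- two_sample_t_map(zm, zm, NULL, mask, g)
  expect_lt(max(abs(same$values)), 1e-8)
  zb <- lapply(1:5, function(i) array(rnorm(prod(d)), d))
  ab <- two_sample_t_map(zm, zb, cov, mask, g)
  ba <- two_sample_t_map(zb, zm, cov[c(6:10, 1:5)], mask, g)
  expect_equal(ab$values, -ba$values, tolerance = 1e-10)
})

test_that("statistic-to-Z conversion preserves tail probability and order", {
  g <- grid_geometry(c(4, 4, 4), 3)
  tmap <- stat_map(array(c(0, 1, -1, 2.5, rep(0, 60)), c(4, 4, 4)), "t",
                   df = 20, geometry = g)
  z <- stat_to_z(tmap)
  expect_identical(z$values[1], 0)                # median preserved
  expect_equal(z$values[2], -z$values[3])         # sign preserved
  expect_equal(pnorm(z$values[4], lower.tail = FALSE),
               pt(2.5, 20, lower.tail = FALSE), tolerance = 1e-10)
  fv <- sort(runif(10, 0.5, 12))
  fmap <- stat_map(array(c(fv, rep(0, 54)), c(4, 4, 4)), "F", df = c(2, 50),
                   geometry = g)
  zf <- stat_to_z(fmap)$values[1:10]
  expect_true(all(diff(zf) > 0))                  # monotone in F
  expect_equal(stat_to_z(fmap)$values[which.max(c(fv, rep(0, 54)))],
               qnorm(pf(max(fv), 2, 50, lower.tail = FALSE),
                     lower.tail = FALSE), tolerance = 1e-10)
})

test_that("ANCOVA type-I error is calibrated at p < 0.05 under the null", {
  set.seed(46)
  n <- 54
  groups <- rep(c("AVH", "NonAVH", "Control"), times = c(16, 18, 20))
  cov <- runif(n, 0.05, 0.2)
  d <- c(10, 10, 20); g <- grid_geometry(d, 3)   # 2000 voxels
  zm <- lapply(1:n, function(i) array(rnorm(prod(d)), d))
  fm <- ancova_f_map(zm, groups, cov, all_mask(d), g)
  p <- pf(fm$values, fm$df[1], fm$df[2], lower.tail = FALSE)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("Bonferroni post hocs match pairwise.t.test with pooled SD", {
  set.seed(47)
  vals <- c(1.2, 0.9, 1.1, 1.4, 1.0, 0.6, 0.8, 0.5, 0.7, 0.4,
            1.6, 1.8, 1.5, 1.9, 1.7)
  groups <- rep(c("AVH", "NonAVH", "Control"), each = 5)
  ph <- posthoc_bonferroni(vals, groups)
  oracle <- pairwise.t.test(vals, groups, p.adjust.method = "bonferroni",
                            pool.sd = TRUE)
  lookup <- function(a, b) {
    pv <- oracle$p.value
    if (a %in% rownames(pv) && b %in% colnames(pv) && !is.na(pv[a, b])) pv[a, b]
    else pv[b, a]
  }
  for (i in seq_len(nrow(ph$contrasts))) {
    pr <- strsplit(ph$contrasts$contrast[i], " vs ")[[1]]
    expect_equal(ph$contrasts$p_bonferroni[i], lookup(pr[1], pr[2]),
                 tolerance = 1e-8)
  }
  expect_true(all(ph$contrasts$p_bonferroni >= ph$contrasts$p_uncorrected))
  # identical groups: all corrected p cap at 1
  same <- posthoc_bonferroni(rep(c(1, 2, 3, 4, 5), 3), groups)
  expect_identical(same$contrasts$p_bonferroni, rep(1, 3))
  # F agrees with aov
  expect_equal(ph$f_stat, summary(aov(vals ~ factor(groups)))[[1]]$`F value`[1],
               tolerance = 1e-10)
})
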