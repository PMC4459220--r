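test_that("shared-component construction hits the target mirror correlation", {
  # Monte-Carlo check of x = sqrt(rho) c + sqrt(1-rho) e against planted rho
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    spec <- small_spec(rho = rho, background_rho = 0, rho_subject_sd = 0)
    means <- vapply(1:6, function(s) {
      sub <- simulate_subject(spec, "Control", 1000 + s)
      b <- discard_initial_volumes(sub$bold, 10)
      gm <- gray_matter_mask(gm_probability(grid_geometry(spec$grid_shape,
                                                          spec$voxel_mm)))
      region_mean_r(compute_vmhc(b, gm), c(6, 0, 0), 5)
    }, numeric(1))
    expect_lt(abs(mean(means) - rho), 0.05)
  }
})

test_that("a zero-correlation region yields near-zero sample correlations", {
  spec <- small_spec(rho = 0, background_rho = 0, rho_subject_sd = 0)
  sub <- simulate_subject(spec, "AVH", 99)
  b <- discard_initial_volumes(sub$bold, 10)
  gm <- gray_matter_mask(gm_probability(grid_geometry(spec$grid_shape, 3)))
  r <- region_mean_r(compute_vmhc(b, gm), c(6, 0, 0), 5)
  expect_lt(abs(r), 2 / sqrt(230))
})

test_that("simulation is bit-identical under the same seed", {
  spec <- small_spec()
  a <- simulate_subject(spec, "NonAVH", 7)
  b <- simulate_subject(spec, "NonAVH", 7)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$motion, b$motion)
  expect_false(identical(a$bold$data,
                         simulate_subject(spec, "NonAVH", 8)$bold$data))
})

test_that("generated background noise has the requested lag-1 autocorrelation", {
  for (phi in c(0.2, 0.5)) {
    set.seed(42)
    x <- homoconn:::.ar1_matrix(500, 200, phi)
    ac <- mean(vapply(seq_len(ncol(x)), function(j) {
      stats::cor(x[-1, j], x[-nrow(x), j])
    }, numeric(1)))
    expect_lt(abs(ac - phi), 0.05)
  }
})

test_that("gray-matter probability and nuisance masks are exactly flip-symmetric", {
  g <- grid_geometry(c(14, 16, 14), 3)
  gm <- gm_probability(g)
  expect_identical(gm, flip_lr(gm))
  nm <- nuisance_masks(g)
  expect_identical(nm$ventricle, flip_lr(nm$ventricle))
  expect_identical(nm$white_matter, flip_lr(nm$white_matter))
  expect_true(any(nm$ventricle) && any(nm$white_matter))
  expect_identical(sum(nm$ventricle & gm >= 0.4), 0L)
})

test_that("motion traces respect the outlier contract", {
  spec <- small_spec()
  m <- simulate_motion(spec, outlier = FALSE, seed = 3)
  expect_lt(max(abs(m)), 2.0)
  mo <- simulate_motion(spec, outlier = TRUE, seed = 3)
  expect_gt(max(abs(mo)), 2.0)
  flags <- exclusion_flags(list(ok = discard_initial_rows(m, 10),
                                bad = discard_initial_rows(mo, 10)))
  expect_identical(flags$excluded, c(FALSE, TRUE))
})

test_that("a 56-subject cohort with 2 planted outliers retains 54", {
  spec <- cohort_spec(master_seed = 11)    # defaults: 18/18/20, 2 outliers
  co <- simulate_cohort(spec, keep_bold = FALSE)
  expect_identical(nrow(co$subjects), 56L)
  ret <- lapply(co$motion, discard_initial_rows, n_discard = 10)
  flags <- exclusion_flags(ret)
  expect_identical(sum(!flags$excluded), 54L)
  expect_identical(flags$subject_id[flags$excluded],
                   co$subjects$subject_id[co$subjects$motion_outlier])
  # retained group sizes mirror the post-exclusion cohort: 16/18/20
  inc <- co$subjects[!flags$excluded, ]
  expect_identical(as.integer(table(inc$group)[c("AVH", "NonAVH", "Control")]),
                   c(16L, 18L, 20L))
})

test_that("score couplings honor group restrictions and targets", {
  expect_error(score_coupling("ahrs", "r1", -0.4, 26, 8,
                              groups = c("AVH", "NonAVH")),
               "AVH")
  set.seed(5)
  truth <- tibble::tibble(subject_id = sprintf("s%02d", 1:34),
                          group = rep(c("AVH", "NonAVH"), 17),
                          region = "r1", z_true = rnorm(34, 0.7, 0.17))
  # zero coupling: score uncorrelated with connectivity
  sc0 <- generate_scores(truth, list(
    score_coupling("panss_total", "r1", 0, 97, 21)), seed = 8)
  expect_lt(abs(cor(sc0$panss_total, truth$z_true)), 2 / sqrt(34))
  # AHRS assigned only to AVH subjects
  sc <- generate_scores(truth, list(
    score_coupling("ahrs", "r1", -0.48, 26, 8, groups = "AVH")), seed = 9)
  expect_true(all(is.na(sc$ahrs[truth$group != "AVH"])))
  expect_true(all(!is.na(sc$ahrs[truth$group == "AVH"])))
})

test_that("cohort writing round-trips through the manifest and refuses overwrite", {
  dir <- withr::local_tempdir()
  spec <- small_spec(grid = c(6, 6, 6), n_volumes = 20)
  co <- simulate_cohort(spec, out_dir = dir)
  expect_true(file.exists(co$manifest_path))
  man <- read_manifest(co$manifest_path)
  expect_identical(man[["master_seed"]], as.character(spec$master_seed))
  expect_identical(man[["grid_shape"]], "6x6x6")
  expect_error(simulate_cohort(spec, out_dir = dir), "overwrite")
  co2 <- simulate_cohort(spec, out_dir = dir, overwrite = TRUE)
  back <- read_cohort(dir)
  expect_equal(back$subjects$subject_id, co$subjects$subject_id)
  expect_equal(back$truth$rho_true, co$truth$rho_true, tolerance = 1e-6)
  id <- co$subjects$subject_id[1]
  expect_equal(back$bold[[id]]$data, co$bold[[id]]$data, tolerance = 1e-5)
  expect_equal(back$motion[[id]], co$motion[[id]], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("invalid region placements are rejected with the region name", {
  expect_error(
    cohort_spec(regions = list(region_effect("far", c(200, 0, 0), 5,
                                             c(AVH = .5, NonAVH = .5,
                                               Control = .5))),
                score_model = list()),
    "far", fixed = TRUE)
  expect_error(
    cohort_spec(regions = list(region_effect("edge", c(28, 0, 0), 6,
                                             c(AVH = .5, NonAVH = .5,
                                               Control = .5))),
                score_model = list()),
    "edge")
  expect_error(region_effect("mid", c(2, 0, 0), 5,
                             c(AVH = .5, NonAVH = .5, Control = .5)),
               "hemisphere")
})
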