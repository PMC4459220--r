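# shared fixture builders (all data generated in code)

zr3 <- function(avh, non, con) tanh(c(AVH = avh, NonAVH = non, Control = con))

# minimal one-region spec on a small grid (region scaled to fit)
small_spec <- function(rho = 0.6, grid = c(8, 8, 8), n_volumes = 240,
                       background_rho = 0.2, seed = 1,
                       rho_subject_sd = 0.17) {
  tight <- grid[1] * 3 / 2 < 11
  ctr <- if (tight) c(4.5, 0, 0) else c(6, 0, 0)
  rad <- if (tight) 4 else 5
  cohort_spec(
    n_per_group = c(AVH = 2, NonAVH = 2, Control = 2),
    grid_shape = grid, n_volumes = n_volumes,
    regions = list(region_effect("r1", ctr, rad,
                                 c(AVH = rho, NonAVH = rho, Control = rho))),
    noise = noise_spec(background_rho = background_rho,
                       rho_subject_sd = rho_subject_sd),
    score_model = list(), n_motion_outliers = 0, master_seed = seed)
}

# three-category classification spec used for end-to-end recovery
three_category_spec <- function(seed) {
  cohort_spec(
    n_per_group = c(AVH = 16, NonAVH = 18, Control = 20),
    grid_shape = c(14, 16, 14), n_motion_outliers = 0,
    regions = list(
      region_effect("avh_only", c(9, 9, 3), 6, zr3(0.50, 0.85, 0.85)),
      region_effect("non_only", c(9, -9, 3), 6, zr3(0.85, 0.50, 0.85)),
      region_effect("shared", c(9, 0, -9), 6, zr3(0.50, 0.50, 0.85))),
    score_model = list(), master_seed = seed)
}

# random bold series for operator-level tests
random_bold <- function(dims = c(6, 6, 6), n_t = 40, tr = 2, seed = 1) {
  set.seed(seed)
  bold_series(array(rnorm(prod(dims) * n_t), c(dims, n_t)), tr, 3)
}

all_mask <- function(dims) array(TRUE, dims)
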