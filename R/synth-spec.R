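# Cohort specification objects for the synthetic resting-state generator.

GROUPS <- c("AVH", "NonAVH", "Control")

#' Regional homotopic-connectivity effect
#'
#' Defines a spherical region on the right side of the grid (its left-hemisphere
#' mirror is implied, never stored) together with the target homotopic
#' correlation for each group. Time series of a voxel and its mirror inside the
#' region are built to have population Pearson correlation equal to the group's
#' `rho`.
#'
#' @param name region label (free text, e.g. `"acc"`).
#' @param center_mni sphere center in mm; the x component must be positive and
#'   at least `radius_mm` so the region does not straddle the midline.
#' @param radius_mm sphere radius, mm.
#' @param rho_by_group named numeric vector with entries `AVH`, `NonAVH`,
#'   `Control`, each in [0, 1).
#' @return A `region_effect` object.
#' @export
region_effect <- function(name, center_mni, radius_mm, rho_by_group) {
  stopifnot(is.character(name), length(center_mni) == 3, radius_mm > 0)
  if (center_mni[1] <= 0 || center_mni[1] < radius_mm) {
    stop("region '", name, "': center x must be positive and >= radius_mm ",
         "so the region stays within one hemisphere")
  }
  if (!all(GROUPS %in% names(rho_by_group))) {
    stop("region '", name, "': rho_by_group must name all of ",
         paste(GROUPS, collapse = ", "))
  }
  rho_by_group <- rho_by_group[GROUPS]
  if (any(rho_by_group < 0 | rho_by_group >= 1)) {
    stop("region '", name, "': rho values must lie in [0, 1)")
  }
  structure(list(name = name, center_mni = as.numeric(center_mni),
                 radius_mm = as.numeric(radius_mm),
                 rho_by_group = rho_by_group),
            class = "region_effect")
}

#' Temporal and spatial noise specification
#'
#' @param ar1_coefficient lag-1 autocorrelation of the generated unit-variance
#'   AR(1) component processes; in [0, 1).
#' @param spatial_fwhm_mm optional within-hemisphere spatial smoothing of the
#'   generated fields, mm FWHM (0 disables it). Smoothing is applied to each
#'   hemisphere separately so it cannot leak homotopic correlation across the
#'   midline.
#' @param background_rho homotopic correlation planted at gray-matter voxels
#'   outside every region; in [0, 1).
#' @param rho_subject_sd between-subject standard deviation of true regional
#'   connectivity on the Fisher-z scale. Subject-level region values are drawn
#'   as `tanh(atanh(rho_group) + N(0, rho_subject_sd))`; this is what makes
#'   score-connectivity coupling meaningful and sets the within-group spread of
#'   sphere means.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(ar1_coefficient = 0.3, spatial_fwhm_mm = 0,
                       background_rho = 0.2, rho_subject_sd = 0.17) {
  stopifnot(ar1_coefficient >= 0, ar1_coefficient < 1,
            spatial_fwhm_mm >= 0,
            background_rho >= 0, background_rho < 1,
            rho_subject_sd >= 0)
  structure(list(ar1_coefficient = ar1_coefficient,
                 spatial_fwhm_mm = spatial_fwhm_mm,
                 background_rho = background_rho,
                 rho_subject_sd = rho_subject_sd),
            class = "noise_spec")
}

#' Clinical score coupled to regional connectivity
#'
#' Scores are generated as
#' `score = mean + sd * (target_r * standardized true regional z + sqrt(1 - target_r^2) * noise)`
#' over the subjects in `groups`, so the population correlation between the
#' score and true regional z-VMHC equals `target_r`.
#'
#' @param score_name one of `panss_pos`, `panss_neg`, `panss_gen`,
#'   `panss_total`, `ahrs`.
#' @param region_name name of the coupled [region_effect()].
#' @param target_r target score-connectivity correlation in (-1, 1).
#' @param score_mean,score_sd marginal mean and SD of the generated score.
#' @param groups groups that receive the score; `ahrs` may only be assigned to
#'   AVH subjects.
#' @return A `score_coupling` object.
#' @export
score_coupling <- function(score_name, region_name, target_r,
                           score_mean, score_sd,
                           groups = c("AVH", "NonAVH")) {
  score_name <- match.arg(score_name,
                          c("panss_pos", "panss_neg", "panss_gen",
                            "panss_total", "ahrs"))
  stopifnot(abs(target_r) < 1, score_sd > 0, all(groups %in% GROUPS))
  if (score_name == "ahrs" && !identical(sort(groups), "AVH")) {
    stop("ahrs scores may only be assigned to the AVH group")
  }
  structure(list(score_name = score_name, region_name = region_name,
                 target_r = target_r, score_mean = score_mean,
                 score_sd = score_sd, groups = groups),
            class = "score_coupling")
}

#' Default regional effects
#'
#' Five regions spanning the three qualitative dysconnectivity categories the
#' pipeline classifies. Group targets are Fisher-z connectivity levels (converted to r
#' with `tanh`): an anterior-cingulate-like and precuneus-like effect present
#' in AVH patients only, superior-temporal and precentral effects in NonAVH
#' patients only, and a parahippocampal-like effect shared by both patient
#' groups. Centers are synthetic grid coordinates (mm), not anatomical
#' locations.
#'
#' @return List of [region_effect()] objects.
#' @export
default_regions <- function() {
  z <- function(avh, non, con) tanh(c(AVH = avh, NonAVH = non, Control = con))
  list(
    region_effect("acc",  c(9, 15, 6),    6, z(0.67, 0.83, 0.86)),
    region_effect("pcu",  c(12, -12, 9),  6, z(0.90, 1.04, 1.15)),
    region_effect("stg",  c(15, -12, 0),  6, z(0.46, 0.75, 0.54)),
    region_effect("preg", c(12, -6, 12),  6, z(0.28, 0.23, 0.40)),
    region_effect("ppg",  c(12, -9, -9),  6, z(0.21, 0.25, 0.42))
  )
}

#' Default score-coupling model
#'
#' Couples PANSS subscale/total scores to the default regions with medium
#' negative correlations and the AHRS score (AVH patients only) to the
#' precentral-like region; marginal means and SDs are plausibility defaults
#' for first-episode patient cohorts.
#'
#' @return List of [score_coupling()] objects.
#' @export
default_score_model <- function() {
  list(
    score_coupling("panss_pos",   "acc",  -0.41, 25, 10),
    score_coupling("panss_neg",   "acc",  -0.34, 24, 8),
    score_coupling("panss_gen",   "pcu",  -0.43, 48, 9),
    score_coupling("panss_total", "acc",  -0.46, 97, 21),
    score_coupling("ahrs",        "preg", -0.48, 26, 8, groups = "AVH")
  )
}

#' Synthetic cohort specification
#'
#' Bundles all ground-truth parameters of a synthetic resting-state cohort:
#' group sizes, acquisition length and repetition time, grid geometry,
#' regional homotopic effects, noise model, score couplings, planted motion
#' outliers, and the master seed from which all randomness derives.
#'
#' @param n_per_group named integer vector `c(AVH=, NonAVH=, Control=)` of
#'   pre-exclusion group sizes (each >= 2).
#' @param n_volumes acquired volumes per subject (> `n_discard`).
#' @param n_discard leading volumes flagged for discard before analysis.
#' @param tr_seconds repetition time, s.
#' @param grid_shape grid dimensions; first (left-right) dimension even.
#' @param voxel_mm isotropic voxel size, mm.
#' @param regions list of [region_effect()].
#' @param noise a [noise_spec()].
#' @param score_model list of [score_coupling()].
#' @param n_motion_outliers number of subjects (planted in the AVH group)
#'   whose motion traces exceed the exclusion thresholds.
#' @param master_seed integer master seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(AVH = 18, NonAVH = 18, Control = 20),
                        n_volumes = 240, n_discard = 10, tr_seconds = 2,
                        grid_shape = c(20, 24, 20), voxel_mm = 3,
                        regions = default_regions(),
                        noise = noise_spec(),
                        score_model = default_score_model(),
                        n_motion_outliers = 2,
                        master_seed = 20150608) {
  stopifnot(all(GROUPS %in% names(n_per_group)))
  n_per_group <- as.integer(n_per_group[GROUPS])
  names(n_per_group) <- GROUPS
  if (any(n_per_group < 2)) stop("all group sizes must be >= 2")
  if (n_volumes <= n_discard) stop("n_volumes must exceed n_discard")
  if (n_motion_outliers < 0 || n_motion_outliers > n_per_group[["AVH"]]) {
    stop("n_motion_outliers must be between 0 and the AVH group size")
  }
  geom <- grid_geometry(grid_shape, voxel_mm)   # validates even first axis
  spec <- structure(list(
    n_per_group = n_per_group, n_volumes = as.integer(n_volumes),
    n_discard = as.integer(n_discard), tr_seconds = tr_seconds,
    grid_shape = geom$dim, voxel_mm = geom$voxel_mm,
    regions = regions, noise = noise, score_model = score_model,
    n_motion_outliers = as.integer(n_motion_outliers),
    master_seed = as.integer(master_seed)
  ), class = "cohort_spec")
  region_names <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(region_names)) stop("region names must be unique")
  for (r in regions) .check_region_in_grid(r, geom)
  for (s in score_model) {
    if (!s$region_name %in% region_names) {
      stop("score '", s$score_name, "' couples to unknown region '",
           s$region_name, "'")
    }
  }
  spec
}

.check_region_in_grid <- function(region, geom) {
  half <- geom$dim * geom$voxel_mm / 2
  lo <- region$center_mni - region$radius_mm
  hi <- region$center_mni + region$radius_mm
  if (any(lo < -half) || any(hi > half)) {
    stop("region '", region$name, "' extends outside the grid")
  }
  vox <- sphere_voxels(region$center_mni, region$radius_mm, geom)
  if (nrow(vox) == 0) stop("region '", region$name, "' contains no voxel center")
  if (any(vox[, 1] <= geom$dim[1] / 2)) {
    stop("region '", region$name, "' crosses the midline")
  }
  invisible(TRUE)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                         collapse = ", "), "\n")
  cat(sprintf("  volumes: %d (discard %d), TR %gs\n",
              x$n_volumes, x$n_discard, x$tr_seconds))
  cat(sprintf("  grid: %s voxels at %g mm\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_mm[1]))
  cat(sprintf("  regions: %s\n",
              paste(vapply(x$regions, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  motion outliers: %d, master seed: %d\n",
              x$n_motion_outliers, x$master_seed))
  invisible(x)
}
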