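# Synthetic cohort generator: AR(1) shared-component BOLD fields with planted
# homotopic correlations, random-walk motion traces with optional planted
# outliers, symmetric tissue volumes, and clinical scores coupled to true
# regional connectivity.

# stationary unit-variance AR(1) series, one per column
.ar1_matrix <- function(n_time, n_series, phi) {
  x <- matrix(stats::rnorm(n_time * n_series), n_time, n_series)
  if (phi > 0 && n_time > 1) {
    s <- sqrt(1 - phi^2)
    for (t in 2:n_time) x[t, ] <- phi * x[t - 1, ] + s * x[t, ]
  }
  x
}

# deterministic per-subject / per-stream seed below 2^31
.derive_seed <- function(master_seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 1009)
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 + h * 8191 + index * 7919
  as.integer(s %% 2147483629 + 1)
}

# normalized elliptical radius of every voxel center (exactly flip-symmetric
# because it depends on x only through x^2)
.elliptical_radius <- function(geom) {
  half <- geom$dim * geom$voxel_mm / 2
  ax <- 0.95 * half
  cc <- lapply(1:3, function(a) {
    ((seq_len(geom$dim[a]) - (geom$dim[a] + 1) / 2) * geom$voxel_mm[a]) / ax[a]
  })
  d <- geom$dim
  r2 <- outer(outer(cc[[1]]^2, cc[[2]]^2, "+"), cc[[3]]^2, "+")
  array(sqrt(r2), d)
}

#' Synthetic gray-matter probability volume
#'
#' A smooth elliptical-shell probability field, exactly symmetric under
#' left-right flip: high probability over a cortical band, falling to zero at
#' the deep core and outside the brain ellipsoid.
#'
#' @param geom a [grid_geometry()].
#' @return 3-D array of probabilities in [0, 1].
#' @export
gm_probability <- function(geom) {
  rn <- .elliptical_radius(geom)
  exp(-((rn - 0.62) / 0.30)^4)
}

#' Synthetic nuisance-tissue masks
#'
#' Binary ventricle (central box) and deep-white-matter (inner shell) masks on
#' the analysis grid, both exactly flip-symmetric; used as the sources of the
#' mean nuisance signals removed in preprocessing.
#'
#' @param geom a [grid_geometry()].
#' @return List with logical 3-D arrays `ventricle` and `white_matter`.
#' @export
nuisance_masks <- function(geom) {
  cc <- lapply(1:3, function(a) {
    (seq_len(geom$dim[a]) - (geom$dim[a] + 1) / 2) * geom$voxel_mm[a]
  })
  d <- geom$dim
  ax <- array(rep(abs(cc[[1]]), times = d[2] * d[3]), d)
  ay <- array(rep(rep(abs(cc[[2]]), each = d[1]), times = d[3]), d)
  az <- array(rep(abs(cc[[3]]), each = d[1] * d[2]), d)
  vent <- ax < 4 & ay < 4 & az < 4
  rn <- .elliptical_radius(geom)
  wm <- rn < 0.33 & !vent
  if (!any(wm)) {
    # very small grids: deepest non-ventricle voxels stand in for deep WM
    cut <- sort(rn[!vent])[min(27, sum(!vent))]
    wm <- rn <= cut & !vent
  }
  list(ventricle = vent, white_matter = wm)
}

# pair table for a spec: right-hemisphere linear indices, their mirrors, and
# the per-pair baseline rho (region rho overrides background rho inside GM)
.pair_table <- function(spec, group, region_rho = NULL) {
  geom <- grid_geometry(spec$grid_shape, spec$voxel_mm)
  d <- geom$dim
  right <- as.matrix(expand.grid(i = (d[1] / 2 + 1):d[1],
                                 j = seq_len(d[2]), k = seq_len(d[3])))
  left <- right
  left[, 1] <- mirror_index(right[, 1], d[1])
  rlin <- .linear_index(right, d)
  llin <- .linear_index(left, d)
  gm <- gm_probability(geom)
  rho <- ifelse(gm[rlin] >= 0.4, spec$noise$background_rho, 0)
  region_id <- integer(length(rlin))
  for (ri in seq_along(spec$regions)) {
    reg <- spec$regions[[ri]]
    vox <- sphere_voxels(reg$center_mni, reg$radius_mm, geom)
    hit <- match(.linear_index(vox, d), rlin)
    hit <- hit[!is.na(hit)]
    rv <- if (!is.null(region_rho)) region_rho[[reg$name]] else
      reg$rho_by_group[[group]]
    rho[hit] <- rv
    region_id[hit] <- ri
  }
  list(geom = geom, right = rlin, left = llin, rho = rho,
       region_id = region_id)
}

#' Simulate one subject's 4-D BOLD series and motion trace
#'
#' Each mirror voxel pair receives time series
#' `x = sqrt(rho) c + sqrt(1 - rho) e1` and `y = sqrt(rho) c + sqrt(1 - rho) e2`
#' with `c`, `e1`, `e2` independent unit-variance AR(1) processes, so the
#' population Pearson correlation between the pair equals `rho`: the planted
#' regional value inside regions, the background value at other gray-matter
#' voxels, and zero elsewhere. The series are affinely rescaled to a baseline
#' of 1000 arbitrary units, which leaves every correlation untouched. Identical
#' seeds give bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param group group label (`AVH`, `NonAVH`, `Control`).
#' @param subject_seed integer seed for this subject.
#' @param region_rho optional named list/vector overriding the per-region
#'   correlation for this subject (used by [simulate_cohort()] to add
#'   between-subject variability).
#' @param motion_outlier if `TRUE` the motion trace exceeds the exclusion
#'   thresholds.
#' @return List with `bold` (a [bold_series()]) and `motion` (T x 6 matrix).
#' @export
simulate_subject <- function(spec, group, subject_seed, region_rho = NULL,
                             motion_outlier = FALSE) {
  group <- match.arg(group, GROUPS)
  pt <- .pair_table(spec, group, region_rho)
  d <- pt$geom$dim
  n_t <- spec$n_volumes
  n_p <- length(pt$right)
  set.seed(as.integer(subject_seed))
  phi <- spec$noise$ar1_coefficient
  cshared <- .ar1_matrix(n_t, n_p, phi)
  e1 <- .ar1_matrix(n_t, n_p, phi)
  e2 <- .ar1_matrix(n_t, n_p, phi)
  sr <- rep(sqrt(pt$rho), each = n_t)
  se <- rep(sqrt(1 - pt$rho), each = n_t)
  x <- cshared * sr + e1 * se
  y <- cshared * sr + e2 * se
  vol <- matrix(0, prod(d), n_t)
  vol[pt$right, ] <- t(x)
  vol[pt$left, ] <- t(y)
  vol <- 1000 + 10 * vol
  data <- array(vol, c(d, n_t))
  if (spec$noise$spatial_fwhm_mm > 0) {
    half <- d[1] / 2
    hs <- .smoother(c(half, d[2], d[3]), spec$noise$spatial_fwhm_mm,
                    pt$geom$voxel_mm)
    for (t in seq_len(n_t)) {
      data[1:half, , , t] <- hs(data[1:half, , , t, drop = TRUE])
      data[(half + 1):d[1], , , t] <- hs(data[(half + 1):d[1], , , t, drop = TRUE])
    }
  }
  motion <- simulate_motion(spec, outlier = motion_outlier,
                            seed = .derive_seed(subject_seed, "motion"))
  list(bold = bold_series(data, spec$tr_seconds, pt$geom$voxel_mm),
       motion = motion)
}

#' Simulate a rigid-motion parameter trace
#'
#' A bounded random walk of T rows x 6 columns (x/y/z translation in mm, then
#' pitch/roll/yaw in degrees). Non-outlier traces are rescaled so every
#' parameter stays strictly below 0.9 mm / 0.9 degrees in magnitude, keeping
#' the worst-case excursion from any reference frame strictly under the
#' 2.0 mm / 2.0 degree exclusion thresholds. Outlier traces receive a smooth
#' excursion of 4.5 units on one random axis, which guarantees exceedance.
#'
#' @param spec a [cohort_spec()] (supplies the number of volumes).
#' @param outlier plant an exclusion-triggering excursion?
#' @param seed integer seed.
#' @return Numeric matrix, `n_volumes` x 6, with column names
#'   `trans_x, trans_y, trans_z, rot_pitch, rot_roll, rot_yaw`.
#' @export
simulate_motion <- function(spec, outlier = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  n_t <- spec$n_volumes
  tr <- matrix(stats::rnorm(n_t * 6, sd = 0.02), n_t, 6)
  tr[1, ] <- 0
  tr <- apply(tr, 2, cumsum)
  cap <- 0.9
  for (j in 1:6) {
    m <- max(abs(tr[, j]))
    if (m >= cap) tr[, j] <- tr[, j] * (cap * 0.99 / m)
  }
  if (outlier) {
    axis <- sample.int(6, 1)
    t0 <- sample(seq(floor(n_t / 3), floor(2 * n_t / 3)), 1)
    bump <- 4.5 * sign(stats::rnorm(1)) *
      exp(-((seq_len(n_t) - t0)^2) / (2 * (n_t / 20)^2))
    tr[, axis] <- tr[, axis] + bump
  }
  colnames(tr) <- c("trans_x", "trans_y", "trans_z",
                    "rot_pitch", "rot_roll", "rot_yaw")
  tr
}

#' Generate clinical scores coupled to true regional connectivity
#'
#' For each coupling, the true Fisher-z connectivity of the coupled region is
#' standardized across the subjects of the coupling's groups and the score is
#' drawn as `mean + sd * (target_r * z_std + sqrt(1 - target_r^2) * noise)`,
#' giving population correlation `target_r` between score and true regional
#' z-VMHC. Subjects outside a coupling's groups get `NA`.
#'
#' @param truth tibble with columns `subject_id`, `group`, `region`, `z_true`
#'   (one row per subject x region), as produced by [simulate_cohort()].
#' @param score_model list of [score_coupling()].
#' @param seed integer seed.
#' @return Tibble, one row per subject, one column per score.
#' @export
generate_scores <- function(truth, score_model, seed = 1L) {
  set.seed(as.integer(seed))
  subjects <- dplyr::distinct(truth, .data$subject_id, .data$group)
  out <- subjects["subject_id"]
  for (cp in score_model) {
    sel <- truth$region == cp$region_name & truth$group %in% cp$groups
    tz <- truth[sel, ]
    zstd <- as.numeric(scale(tz$z_true))
    noise <- stats::rnorm(nrow(tz))
    val <- cp$score_mean + cp$score_sd *
      (cp$target_r * zstd + sqrt(1 - cp$target_r^2) * noise)
    col <- rep(NA_real_, nrow(subjects))
    col[match(tz$subject_id, subjects$subject_id)] <- val
    out[[cp$score_name]] <- col
  }
  tibble::as_tibble(out)
}

#' Simulate a complete synthetic cohort
#'
#' Generates every subject's BOLD series and motion trace, the symmetric
#' gray-matter probability volume and nuisance masks, subject-level true
#' regional connectivity (group target plus between-subject variation on the
#' Fisher-z scale), and clinical scores coupled to it. Motion outliers are
#' planted in the first `n_motion_outliers` AVH subjects. With `out_dir` set,
#' all files (NIfTI volumes, motion text, subject TSV, ground-truth TSV, and a
#' key-value manifest) are written to disk; otherwise everything is returned
#' in memory.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory, or `NULL` for an in-memory cohort.
#' @param overwrite overwrite an existing manifest in `out_dir`?
#' @param keep_bold generate BOLD volumes? Set `FALSE` for motion/score-only
#'   cohorts (e.g. exclusion bookkeeping checks).
#' @return A `synthetic_cohort` list: `spec`, `geometry`, `subjects` tibble
#'   (ids, groups, planted outlier flags, scores), `truth` tibble (per subject
#'   x region true rho and Fisher z), `motion` (named list of T x 6 matrices),
#'   `bold` (named list of [bold_series()], if kept), `gm_prob`, `masks`, and
#'   (when written) `files` + `manifest_path`.
#' @export
simulate_cohort <- function(spec, out_dir = NULL, overwrite = FALSE,
                            keep_bold = TRUE) {
  geom <- grid_geometry(spec$grid_shape, spec$voxel_mm)
  groups <- rep(GROUPS, times = spec$n_per_group)
  idx <- unlist(lapply(spec$n_per_group, seq_len), use.names = FALSE)
  ids <- sprintf("%s%02d", c(AVH = "avh", NonAVH = "nonavh",
                             Control = "con")[groups], idx)
  outlier <- groups == "AVH" & idx <= spec$n_motion_outliers
  seeds <- vapply(seq_along(ids), function(s) {
    .derive_seed(spec$master_seed, paste0("subject_", ids[s]))
  }, integer(1))

  region_names <- vapply(spec$regions, `[[`, "", "name")
  truth <- vector("list", length(ids))
  motion <- stats::setNames(vector("list", length(ids)), ids)
  bold <- if (keep_bold) stats::setNames(vector("list", length(ids)), ids)
  for (s in seq_along(ids)) {
    set.seed(.derive_seed(seeds[s], "rho"))
    z_grp <- vapply(spec$regions, function(r) atanh(r$rho_by_group[[groups[s]]]),
                    numeric(1))
    z_true <- z_grp + stats::rnorm(length(z_grp), sd = spec$noise$rho_subject_sd)
    z_true <- pmax(z_true, 0)
    rho_true <- tanh(z_true)
    truth[[s]] <- tibble::tibble(subject_id = ids[s], group = groups[s],
                                 region = region_names,
                                 rho_true = rho_true, z_true = z_true)
    if (keep_bold) {
      sim <- simulate_subject(spec, groups[s], seeds[s],
                              region_rho = stats::setNames(as.list(rho_true),
                                                           region_names),
                              motion_outlier = outlier[s])
      bold[[ids[s]]] <- sim$bold
      motion[[ids[s]]] <- sim$motion
    } else {
      motion[[ids[s]]] <- simulate_motion(spec, outlier = outlier[s],
                                          seed = .derive_seed(seeds[s], "motion"))
    }
  }
  truth <- dplyr::bind_rows(truth)
  scores <- generate_scores(truth, spec$score_model,
                            seed = .derive_seed(spec$master_seed, "scores"))
  subjects <- tibble::tibble(subject_id = ids, group = groups,
                             motion_outlier = outlier, seed = seeds)
  subjects <- dplyr::left_join(subjects, scores, by = "subject_id")

  cohort <- structure(list(
    spec = spec, geometry = geom, subjects = subjects, truth = truth,
    motion = motion, bold = bold, gm_prob = gm_probability(geom),
    masks = nuisance_masks(geom)
  ), class = "synthetic_cohort")

  if (!is.null(out_dir)) {
    cohort <- .write_cohort(cohort, out_dir, overwrite)
  }
  cohort
}

.write_nifti <- function(arr, path, voxel_mm, tr = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4) c(voxel_mm, tr) else voxel_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "float")
  path
}

.write_cohort <- function(cohort, out_dir, overwrite) {
  spec <- cohort$spec
  manifest_path <- file.path(out_dir, "manifest.txt")
  if (file.exists(manifest_path) && !overwrite) {
    stop("a cohort manifest already exists at ", manifest_path,
         "; pass overwrite = TRUE to replace it")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vox <- cohort$geometry$voxel_mm
  files <- character(0)
  for (id in cohort$subjects$subject_id) {
    if (!is.null(cohort$bold)) {
      f <- file.path(out_dir, paste0(id, "_bold.nii.gz"))
      .write_nifti(cohort$bold[[id]]$data, f, vox, spec$tr_seconds)
      files <- c(files, f)
    }
    mf <- file.path(out_dir, paste0(id, "_motion.txt"))
    utils::write.table(format(cohort$motion[[id]], digits = 10), mf,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, mf)
  }
  gmf <- file.path(out_dir, "gm_prob.nii.gz")
  .write_nifti(cohort$gm_prob, gmf, vox)
  vf <- file.path(out_dir, "ventricle_mask.nii.gz")
  .write_nifti(cohort$masks$ventricle + 0, vf, vox)
  wf <- file.path(out_dir, "wm_mask.nii.gz")
  .write_nifti(cohort$masks$white_matter + 0, wf, vox)
  sf <- file.path(out_dir, "subjects.tsv")
  utils::write.table(cohort$subjects[, setdiff(names(cohort$subjects), "seed")],
                     sf, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  tf <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(cohort$truth, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, gmf, vf, wf, sf, tf)

  kv <- c(
    schema_version = "1",
    master_seed = spec$master_seed,
    n_avh = spec$n_per_group[["AVH"]],
    n_nonavh = spec$n_per_group[["NonAVH"]],
    n_control = spec$n_per_group[["Control"]],
    n_volumes = spec$n_volumes, n_discard = spec$n_discard,
    tr_seconds = spec$tr_seconds,
    grid_shape = paste(spec$grid_shape, collapse = "x"),
    voxel_mm = spec$voxel_mm[1],
    ar1_coefficient = spec$noise$ar1_coefficient,
    spatial_fwhm_mm = spec$noise$spatial_fwhm_mm,
    background_rho = spec$noise$background_rho,
    rho_subject_sd = spec$noise$rho_subject_sd,
    n_motion_outliers = spec$n_motion_outliers
  )
  for (r in spec$regions) {
    kv[paste0("region.", r$name, ".center_mni")] <-
      paste(r$center_mni, collapse = ",")
    kv[paste0("region.", r$name, ".radius_mm")] <- r$radius_mm
    kv[paste0("region.", r$name, ".rho")] <-
      paste(sprintf("%s=%.10g", names(r$rho_by_group), r$rho_by_group),
            collapse = ",")
  }
  md5 <- tools::md5sum(files)
  for (f in files) {
    kv[paste0("file.", basename(f))] <- unname(md5[f])
  }
  write_manifest(kv, manifest_path)
  cohort$files <- files
  cohort$manifest_path <- manifest_path
  cohort
}

#' Write / read a key-value manifest file
#'
#' One `key<TAB>value` pair per line; values are plain strings. Reading back a
#' written manifest returns exactly the written mapping.
#'
#' @param kv named character vector.
#' @param path file path.
#' @return `write_manifest` returns `path`; `read_manifest` the named vector.
#' @export
write_manifest <- function(kv, path) {
  writeLines(paste(names(kv), as.character(kv), sep = "\t"), path)
  path
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  ln <- readLines(path)
  parts <- regmatches(ln, regexpr("\t", ln), invert = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

#' Read a cohort written by [simulate_cohort()] back from disk
#'
#' @param dir cohort directory containing `manifest.txt`.
#' @param ids optional subset of subject ids to load BOLD for.
#' @return A list with `subjects`, `truth`, `motion`, `bold`, `gm_prob`,
#'   `masks`, `geometry`, `manifest`.
#' @export
read_cohort <- function(dir, ids = NULL) {
  man <- read_manifest(file.path(dir, "manifest.txt"))
  subjects <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "subjects.tsv"), sep = "\t", na.strings = ""))
  truth <- tibble::as_tibble(utils::read.delim(file.path(dir, "ground_truth.tsv")))
  if (is.null(ids)) ids <- subjects$subject_id
  strip <- function(img) { a <- as.array(img); array(as.numeric(a), dim(a)) }
  gm <- strip(RNifti::readNifti(file.path(dir, "gm_prob.nii.gz")))
  geom <- grid_geometry(dim(gm), as.numeric(man[["voxel_mm"]]))
  tr <- as.numeric(man[["tr_seconds"]])
  motion <- lapply(stats::setNames(ids, ids), function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0(id, "_motion.txt"))))
  })
  bold <- lapply(stats::setNames(ids, ids), function(id) {
    f <- file.path(dir, paste0(id, "_bold.nii.gz"))
    if (!file.exists(f)) return(NULL)
    bold_series(strip(RNifti::readNifti(f)), tr, geom$voxel_mm)
  })
  masks <- list(
    ventricle = strip(RNifti::readNifti(
      file.path(dir, "ventricle_mask.nii.gz"))) > 0.5,
    white_matter = strip(RNifti::readNifti(
      file.path(dir, "wm_mask.nii.gz"))) > 0.5
  )
  list(subjects = subjects, truth = truth, motion = motion, bold = bold,
       gm_prob = gm, masks = masks, geometry = geom, manifest = man)
}
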