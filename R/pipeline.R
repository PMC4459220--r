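# Pipeline orchestration: configuration, per-stage drivers, dysconnectivity
# classification, report generation.

#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the pipeline; the defaults are the
#' analysis constants used throughout (10 discarded volumes, 4 mm smoothing,
#' 0.01-0.08 Hz band, 50 mm FD sphere, 2.0 mm / 2.0 degree exclusion,
#' first-level FDR q = 0.01 with 20-voxel extent, cluster-forming Z = 2.3
#' with cluster alpha = 0.05, 40% gray-matter threshold, 5 mm spheres).
#'
#' @param n_discard leading volumes to discard.
#' @param fwhm_mm spatial smoothing FWHM, mm.
#' @param band band-pass edges, Hz (length 2).
#' @param fd_radius_mm sphere radius for the FD rotation arc length, mm.
#' @param trans_limit_mm,rot_limit_deg motion exclusion thresholds.
#' @param first_level_q first-level FDR level.
#' @param first_level_extent first-level extent threshold, voxels.
#' @param cluster_forming_z cluster-forming threshold, Z scale.
#' @param cluster_alpha cluster-level significance level.
#' @param gm_threshold gray-matter probability threshold.
#' @param sphere_radius_mm ROI sphere radius, mm.
#' @param n_perm permutations for the optional permutation oracle (0 = skip).
#' @param seed seed for the permutation oracle.
#' @return A `run_config` list.
#' @export
run_config <- function(n_discard = 10, fwhm_mm = 4, band = c(0.01, 0.08),
                       fd_radius_mm = 50, trans_limit_mm = 2,
                       rot_limit_deg = 2, first_level_q = 0.01,
                       first_level_extent = 20, cluster_forming_z = 2.3,
                       cluster_alpha = 0.05, gm_threshold = 0.40,
                       sphere_radius_mm = 5, n_perm = 0, seed = 1L) {
  stopifnot(length(band) == 2, band[1] < band[2])
  structure(list(n_discard = n_discard, fwhm_mm = fwhm_mm, band = band,
                 fd_radius_mm = fd_radius_mm, trans_limit_mm = trans_limit_mm,
                 rot_limit_deg = rot_limit_deg, first_level_q = first_level_q,
                 first_level_extent = first_level_extent,
                 cluster_forming_z = cluster_forming_z,
                 cluster_alpha = cluster_alpha, gm_threshold = gm_threshold,
                 sphere_radius_mm = sphere_radius_mm, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Preprocess a cohort and compute per-subject z-VMHC maps
#'
#' Applies, per subject: volume discard, FD computation, motion-based
#' exclusion, nuisance regression (6 motion parameters + mean ventricle and
#' white-matter signals), smoothing, detrending, band-pass, and VMHC within
#' the gray-matter mask. Excluded subjects get no map.
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()]) or the list
#'   returned by [read_cohort()].
#' @param config a [run_config()].
#' @return List: `zmaps` (named list of 3-D z maps, included subjects only),
#'   `motion_table` (tibble from [exclusion_flags()]), `subjects` (subject
#'   tibble joined with mean FD and inclusion), `mask` ([gray_matter_mask()]),
#'   `geometry`.
#' @export
compute_cohort_vmhc <- function(cohort, config = run_config()) {
  geom <- cohort$geometry
  ids <- cohort$subjects$subject_id
  motion_ret <- lapply(stats::setNames(ids, ids), function(id) {
    discard_initial_rows(cohort$motion[[id]], config$n_discard)
  })
  mot <- exclusion_flags(motion_ret, config$trans_limit_mm,
                         config$rot_limit_deg, config$fd_radius_mm)
  mask <- gray_matter_mask(cohort$gm_prob, config$gm_threshold)
  included <- mot$subject_id[!mot$excluded]
  zmaps <- list()
  for (id in included) {
    if (is.null(cohort$bold[[id]])) {
      stop("no BOLD data for subject ", id,
           "; run the simulate stage (with BOLD volumes) first")
    }
    pp <- preprocess_bold(cohort$bold[[id]], cohort$motion[[id]],
                          cohort$masks, n_discard = config$n_discard,
                          fwhm_mm = config$fwhm_mm,
                          low_hz = config$band[1], high_hz = config$band[2])
    zmaps[[id]] <- compute_vmhc(pp$bold, mask)$z_map
  }
  subjects <- dplyr::left_join(cohort$subjects, mot, by = "subject_id")
  subjects$included <- !subjects$excluded
  list(zmaps = zmaps, motion_table = mot, subjects = subjects,
       mask = mask, geometry = geom)
}

#' Classify regional dysconnectivity from post hoc contrasts
#'
#' Applies the three-way rule: a region is aberrant in AVH patients only if
#' the AVH-vs-Control contrast is significant and the NonAVH-vs-Control is
#' not; in NonAVH patients only for the converse; shared when both patient
#' groups differ from controls.
#'
#' @param contrasts tibble from [posthoc_bonferroni()]'s `contrasts` field.
#' @param alpha significance level on the Bonferroni-corrected p (default
#'   0.05).
#' @return One of `"AVH_only"`, `"NonAVH_only"`, `"shared"`, `"none"`.
#' @export
classify_dysconnectivity <- function(contrasts, alpha = 0.05) {
  p_of <- function(a, b) {
    hit <- contrasts$contrast %in% c(paste(a, "vs", b), paste(b, "vs", a))
    contrasts$p_bonferroni[hit][1]
  }
  avh <- p_of("AVH", "Control") < alpha
  non <- p_of("NonAVH", "Control") < alpha
  if (avh && non) "shared"
  else if (avh) "AVH_only"
  else if (non) "NonAVH_only"
  else "none"
}

# assign free-text region labels to clusters by nearest labeled center
# (mirror-invariant in x: labeled centers describe a bilateral region pair)
.label_cluster_peaks <- function(clusters, region_labels, max_dist_mm) {
  labs <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    pk <- c(clusters$peak_mni_x[i], clusters$peak_mni_y[i],
            clusters$peak_mni_z[i])
    labs[i] <- sprintf("cluster%02d", clusters$cluster_id[i])
    if (!is.null(region_labels)) {
      dd <- sqrt((abs(region_labels$x) - abs(pk[1]))^2 +
                   (region_labels$y - pk[2])^2 +
                   (region_labels$z - pk[3])^2)
      j <- which.min(dd)
      if (dd[j] <= max_dist_mm) labs[i] <- region_labels$region[j]
    }
  }
  labs
}

# for each labeled region, the peak statistic voxel among significant-cluster
# voxels that fall inside the (bilateral) region sphere; robust to adjacent
# regions merging into one supra-threshold cluster
.region_peaks <- function(grf, zvalues, region_labels, geometry,
                          default_radius_mm) {
  sig_ids <- grf$clusters$cluster_id[grf$clusters$significant]
  if (length(sig_ids) == 0) return(NULL)
  rows <- list()
  for (i in seq_len(nrow(region_labels))) {
    rad <- if ("radius" %in% names(region_labels))
      region_labels$radius[i] else default_radius_mm
    ctr <- c(region_labels$x[i], region_labels$y[i], region_labels$z[i])
    vox <- sphere_voxels(ctr, rad, geometry)
    mvox <- vox; mvox[, 1] <- mirror_index(vox[, 1], geometry$dim[1])
    lin <- .linear_index(rbind(vox, mvox), geometry$dim)
    lin <- lin[grf$label_field[lin] %in% sig_ids]
    if (length(lin) == 0) next
    best <- lin[which.max(zvalues[lin])]
    ijk <- arrayInd(best, geometry$dim)
    mm <- as.numeric(voxel_to_mni(ijk, geometry))
    cid <- grf$label_field[best]
    rows[[length(rows) + 1]] <- tibble::tibble(
      region = region_labels$region[i], cluster_id = cid,
      size_voxels = grf$clusters$size_voxels[grf$clusters$cluster_id == cid],
      peak_value = zvalues[best],
      peak_mni_x = mm[1], peak_mni_y = mm[2], peak_mni_z = mm[3],
      p_corrected = grf$clusters$p_corrected[grf$clusters$cluster_id == cid])
  }
  if (length(rows)) dplyr::bind_rows(rows) else NULL
}

#' Voxelwise group analysis on z-VMHC maps
#'
#' FD-covaried one-way ANOVA (ANCOVA) F map over the mask, Z conversion,
#' residual-based smoothness estimation, GRF cluster-extent correction,
#' pairwise covariate-adjusted two-sample t maps with the same correction,
#' sphere-ROI extraction at the significant ANOVA cluster peaks, Bonferroni
#' post hocs, and three-way dysconnectivity classification.
#'
#' @param zmaps named list of subject z maps.
#' @param groups group label per subject.
#' @param covariate mean FD per subject (the motion covariate).
#' @param mask a [gray_matter_mask()] or 3-D logical array.
#' @param geometry a [grid_geometry()].
#' @param config a [run_config()].
#' @param region_labels optional tibble (`region`, `x`, `y`, `z`, and
#'   optionally `radius` in mm) of bilateral region centers (positive x, the
#'   mirror implied). Clusters are named by their nearest labeled center, and
#'   the ROI analysis extracts one sphere per region at the peak of the
#'   significant-cluster voxels inside it; synthetic runs pass the planted
#'   region centers.
#' @param label_dist_mm maximum peak-to-center distance for cluster naming,
#'   and the default region radius when `region_labels` has no `radius`
#'   column, mm.
#' @return List: `anova` (`stat`, `zmap`, `smoothness`, `clusters` incl.
#'   significance and labels), `pairwise` (named list of two-sample
#'   `cluster_result`s), `sphere_means` tibble, `posthoc` tibble (per region:
#'   group means, F, three Bonferroni p values, classification),
#'   `permutation` (max-cluster null, when `config$n_perm > 0`).
#' @export
group_analysis <- function(zmaps, groups, covariate, mask, geometry,
                           config = run_config(), region_labels = NULL,
                           label_dist_mm = 12) {
  bin <- if (inherits(mask, "gm_mask")) mask$binary else mask
  fmap <- ancova_f_map(zmaps, groups, covariate, bin, geometry)
  zstat <- stat_to_z(fmap)
  smoothness <- estimate_smoothness(fmap$residuals, bin, geometry)
  grf <- grf_cluster_correct(zstat, smoothness,
                             cluster_forming_z = config$cluster_forming_z,
                             alpha = config$cluster_alpha)
  clusters <- grf$clusters
  if (nrow(clusters)) {
    clusters$region <- .label_cluster_peaks(clusters, region_labels,
                                            label_dist_mm)
  } else {
    clusters$region <- character(0)
  }
  grf$clusters <- clusters

  pair_defs <- list(
    AVH_vs_Control = c("AVH", "Control"),
    NonAVH_vs_Control = c("NonAVH", "Control"),
    AVH_vs_NonAVH = c("AVH", "NonAVH")
  )
  pairwise <- list()
  for (nm in names(pair_defs)) {
    ga <- pair_defs[[nm]][1]; gb <- pair_defs[[nm]][2]
    sel_a <- groups == ga; sel_b <- groups == gb
    if (sum(sel_a) < 2 || sum(sel_b) < 2) next
    tmap <- two_sample_t_map(zmaps[sel_a], zmaps[sel_b],
                             c(covariate[sel_a], covariate[sel_b]),
                             bin, geometry)
    tz <- stat_to_z(tmap)
    sm <- estimate_smoothness(tmap$residuals, bin, geometry)
    # clusters formed on |Z|: assess both tails by correcting Z and -Z
    pos <- grf_cluster_correct(tz, sm, config$cluster_forming_z,
                               config$cluster_alpha)
    neg_map <- tz; neg_map$values <- -neg_map$values
    neg <- grf_cluster_correct(neg_map, sm, config$cluster_forming_z,
                               config$cluster_alpha)
    neg$clusters$peak_value <- -neg$clusters$peak_value
    pairwise[[nm]] <- list(positive = pos, negative = neg)
  }

  # ROI analysis: one sphere per labeled region at the peak of the
  # significant-cluster voxels inside it; falls back to one sphere per
  # significant cluster (deduplicated across mirror pairs) without labels
  if (!is.null(region_labels)) {
    sig <- .region_peaks(grf, zstat$values, region_labels, geometry,
                         label_dist_mm)
    if (is.null(sig)) sig <- clusters[0, ]
  } else {
    sig <- clusters[clusters$significant, , drop = FALSE]
    if (nrow(sig)) {
      # mirror-symmetric field: keep one representative per pair
      sig <- sig[order(sig$region, -sig$peak_mni_x), , drop = FALSE]
      sig <- sig[!duplicated(sig$region), , drop = FALSE]
    }
  }
  sphere_means <- NULL
  posthoc <- NULL
  if (nrow(sig)) {
    sphere_means <- sphere_means_table(zmaps, sig, geometry,
                                       config$sphere_radius_mm)
    rows <- list()
    for (r in seq_len(nrow(sig))) {
      reg <- sig$region[r]
      ph <- posthoc_bonferroni(sphere_means[[reg]], groups)
      pb <- function(a, b) {
        hit <- ph$contrasts$contrast %in% c(paste(a, "vs", b),
                                            paste(b, "vs", a))
        ph$contrasts$p_bonferroni[hit][1]
      }
      rows[[r]] <- tibble::tibble(
        region = reg,
        mean_con = ph$group_means[["Control"]],
        mean_nonavh = ph$group_means[["NonAVH"]],
        mean_avh = ph$group_means[["AVH"]],
        f_stat = ph$f_stat,
        p_avh_vs_con = pb("AVH", "Control"),
        p_nonavh_vs_con = pb("NonAVH", "Control"),
        p_avh_vs_nonavh = pb("AVH", "NonAVH"),
        classification = classify_dysconnectivity(ph$contrasts,
                                                  config$cluster_alpha))
    }
    posthoc <- dplyr::bind_rows(rows)
  }

  permutation <- NULL
  if (config$n_perm > 0) {
    permutation <- permutation_cluster_null(
      zmaps, groups, covariate, bin, geometry, n_perm = config$n_perm,
      cluster_forming_z = config$cluster_forming_z, seed = config$seed)
  }

  list(anova = list(stat = fmap, zmap = zstat, smoothness = smoothness,
                    clusters = clusters, grf = grf),
       pairwise = pairwise, sphere_means = sphere_means, posthoc = posthoc,
       permutation = permutation)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulation (unless a cohort is supplied), preprocessing + VMHC, FD group
#' comparison, group statistics with GRF correction, sphere post hocs,
#' score correlations, and (with `out_dir`) the written report.
#'
#' @param cohort a `synthetic_cohort`, the list from [read_cohort()], or a
#'   [cohort_spec()] (which is then simulated in memory).
#' @param config a [run_config()].
#' @param out_dir optional output directory for the report and tables.
#' @return Results list: `vmhc` (stage output of [compute_cohort_vmhc()]),
#'   `fd_anova` (F and p of the one-way ANOVA on mean FD across retained
#'   groups), `group` (output of [group_analysis()]), `correlations` (named
#'   list of tibbles), `config`.
#' @export
run_vmhc_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  if (inherits(cohort, "cohort_spec")) cohort <- simulate_cohort(cohort)
  stage <- compute_cohort_vmhc(cohort, config)
  inc <- stage$subjects[stage$subjects$included, ]
  inc <- inc[match(names(stage$zmaps), inc$subject_id), ]
  fd_fit <- stats::anova(stats::lm(mean_fd ~ group, data = inc))
  fd_anova <- list(f = fd_fit$`F value`[1], p = fd_fit$`Pr(>F)`[1])

  region_labels <- NULL
  if (!is.null(cohort$spec)) {
    region_labels <- dplyr::bind_rows(lapply(cohort$spec$regions, function(r) {
      tibble::tibble(region = r$name, x = r$center_mni[1],
                     y = r$center_mni[2], z = r$center_mni[3],
                     radius = r$radius_mm)
    }))
  }
  grp <- group_analysis(stage$zmaps, inc$group, inc$mean_fd, stage$mask,
                        stage$geometry, config, region_labels)

  correlations <- list()
  if (!is.null(grp$sphere_means)) {
    sm <- grp$sphere_means
    correlations$all_patients <- correlation_table(sm, inc, "all_patients")
    if ("ahrs" %in% names(inc) && any(!is.na(inc$ahrs))) {
      correlations$avh_only <- correlation_table(sm, inc, "avh_only")
    }
  }

  results <- list(vmhc = stage, fd_anova = fd_anova, group = grp,
                  correlations = correlations, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(results, file.path(out_dir, "report.md"))
    utils::write.table(stage$motion_table,
                       file.path(out_dir, "fd_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(grp$sphere_means)) {
      utils::write.table(grp$sphere_means,
                         file.path(out_dir, "sphere_means.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(grp$anova$clusters)) {
      ct <- grp$anova$clusters
      utils::write.table(
        data.frame(region_label = ct$region,
                   cluster_size_voxels = ct$size_voxels,
                   peak_value = ct$peak_value,
                   peak_mni_x = ct$peak_mni_x, peak_mni_y = ct$peak_mni_y,
                   peak_mni_z = ct$peak_mni_z,
                   corrected_p = ct$p_corrected),
        file.path(out_dir, "cluster_table.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (nm in names(correlations)) {
      write_correlation_tsv(
        correlations[[nm]],
        path_wide = file.path(out_dir, paste0("correlations_", nm, "_wide.tsv")),
        path_long = file.path(out_dir, paste0("correlations_", nm, ".tsv")))
    }
  }
  results
}

# normalize a matrix to [0, 1] for PNG export
.to_gray <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

#' Export orthogonal mid-slices of a volume as a PNG
#'
#' Writes the three central orthogonal slices (sagittal, coronal, axial)
#' side by side as a grayscale PNG.
#'
#' @param vol 3-D array.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(vol, path) {
  d <- dim(vol)
  sag <- .to_gray(vol[ceiling(d[1] / 2), , ])
  cor <- .to_gray(vol[, ceiling(d[2] / 2), ])
  axi <- .to_gray(vol[, , ceiling(d[3] / 2)])
  h <- max(ncol(sag), ncol(cor), ncol(axi))
  pad <- function(m) {
    out <- matrix(0, nrow(m), h); out[, seq_len(ncol(m))] <- m; out
  }
  img <- rbind(pad(sag), pad(cor), pad(axi))
  # image rows top-to-bottom; flip the second axis for a conventional view
  png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE], path)
  invisible(path)
}

#' Write the human-readable analysis report
#'
#' A single markdown report: run parameters, exclusion summary, FD group
#' comparison, the significant-cluster table, post hoc three-way
#' dysconnectivity classification, score-correlation matrices, and
#' orthogonal-slice PNGs of the ANOVA F map. Pure function of `results`:
#' regenerating from saved intermediates reproduces the file.
#'
#' @param results list from [run_vmhc_pipeline()].
#' @param path output path for the markdown report; PNGs are written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  cfg <- results$config
  st <- results$vmhc
  ln <- c("# Homotopic connectivity analysis report", "")
  ln <- c(ln, "## Run parameters", "")
  ln <- c(ln, vapply(names(unclass(cfg)), function(k) {
    sprintf("- %s: %s", k, paste(cfg[[k]], collapse = ", "))
  }, character(1)), "")

  mot <- st$motion_table
  ln <- c(ln, "## Motion exclusion", "",
          sprintf("%d of %d subjects retained; excluded: %s",
                  sum(!mot$excluded), nrow(mot),
                  if (any(mot$excluded))
                    paste(mot$subject_id[mot$excluded], collapse = ", ")
                  else "none"), "")
  ln <- c(ln, sprintf("Group comparison of mean FD: F = %.2f, p = %.2f",
                      results$fd_anova$f, results$fd_anova$p), "")

  cl <- results$group$anova$clusters
  ln <- c(ln, "## Group differences (ANCOVA, GRF cluster-corrected)", "")
  sig <- cl[cl$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    ln <- c(ln, "No significant clusters.", "")
  } else {
    ln <- c(ln, "| Region | Cluster size | Peak intensity | x | y | z | corrected p |",
            "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(sig))) {
      ln <- c(ln, sprintf("| %s | %d | %.2f | %g | %g | %g | %.4f |",
                          sig$region[i], sig$size_voxels[i], sig$peak_value[i],
                          sig$peak_mni_x[i], sig$peak_mni_y[i],
                          sig$peak_mni_z[i], sig$p_corrected[i]))
    }
    ln <- c(ln, "")
  }

  ph <- results$group$posthoc
  ln <- c(ln, "## Post hoc classification", "")
  if (is.null(ph) || nrow(ph) == 0) {
    ln <- c(ln, "No regions to classify.", "")
  } else {
    ln <- c(ln, "| Region | Con | NonAVH | AVH | F | AVH vs Con | NonAVH vs Con | AVH vs NonAVH | Category |",
            "|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(ph))) {
      ln <- c(ln, sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %.3f | %.3f | %.3f | %s |",
                          ph$region[i], ph$mean_con[i], ph$mean_nonavh[i],
                          ph$mean_avh[i], ph$f_stat[i], ph$p_avh_vs_con[i],
                          ph$p_nonavh_vs_con[i], ph$p_avh_vs_nonavh[i],
                          ph$classification[i]))
    }
    ln <- c(ln, "")
  }

  for (nm in names(results$correlations)) {
    tab <- results$correlations[[nm]]
    ln <- c(ln, sprintf("## Score correlations (%s)", nm), "",
            "| Region | Score | r | n | p |", "|---|---|---|---|---|")
    for (i in seq_len(nrow(tab))) {
      ln <- c(ln, sprintf("| %s | %s | %.2f | %d | %.2f |",
                          tab$region[i], tab$score[i], tab$r[i], tab$n[i],
                          tab$p_two_tailed[i]))
    }
    ln <- c(ln, "")
  }

  png_path <- file.path(dirname(path), "anova_f_slices.png")
  write_slice_png(results$group$anova$stat$values, png_path)
  ln <- c(ln, "## Maps", "",
          sprintf("Orthogonal slices of the ANOVA F map: %s",
                  basename(png_path)), "")
  writeLines(ln, path)
  invisible(path)
}
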