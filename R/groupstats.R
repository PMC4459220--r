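# Voxelwise group inference on z-VMHC maps: one-sample first-level maps with
# FDR + extent thresholding, FD-covaried ANOVA (ANCOVA) F maps, covariate-
# adjusted two-sample t maps, Z conversion, and sphere-ROI Bonferroni post
# hocs.

#' Voxelwise statistic map
#'
#' @param values 3-D array of statistic values (0 outside the mask).
#' @param kind one of `"F"`, `"t"`, `"Z"`.
#' @param df degrees of freedom: length-2 for F, scalar for t, `NULL` for Z.
#' @param mask 3-D logical analysis mask.
#' @param geometry a [grid_geometry()].
#' @param residuals optional n x V matrix of model residuals over mask voxels
#'   (used for smoothness estimation).
#' @return A `stat_map` object.
#' @export
stat_map <- function(values, kind, df = NULL, mask = NULL, geometry = NULL,
                     residuals = NULL) {
  kind <- match.arg(kind, c("F", "t", "Z"))
  structure(list(values = values, kind = kind, df = df, mask = mask,
                 geometry = geometry, residuals = residuals),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  rng <- range(x$values[if (is.null(x$mask)) TRUE else x$mask])
  cat(sprintf("<stat_map> kind %s, df %s, range [%.3f, %.3f]\n", x$kind,
              paste(x$df, collapse = ","), rng[1], rng[2]))
  invisible(x)
}

# stack a list of 3-D maps (or vmhc_map objects) into an n x V matrix over
# mask voxels
.stack_maps <- function(maps, mask) {
  lin <- which(mask)
  Y <- t(vapply(maps, function(m) {
    arr <- if (inherits(m, "vmhc_map")) m$z_map else m
    arr[lin]
  }, numeric(length(lin))))
  list(Y = Y, lin = lin)
}

.prune_design <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
  X
}

.fill_map <- function(values, lin, dim3) {
  out <- array(0, dim3)
  out[lin] <- values
  out
}

#' First-level one-sample group map with FDR and extent thresholding
#'
#' Voxelwise one-sample t test of the z maps against zero with two-tailed
#' p values, Benjamini-Hochberg FDR control at `q` within the mask, and an
#' additional connected-component extent filter (>= `extent` voxels,
#' 26-connectivity).
#'
#' @param zmaps list of subject z maps (3-D arrays or `vmhc_map` objects).
#' @param mask 3-D logical analysis mask.
#' @param geometry a [grid_geometry()].
#' @param q FDR level (default 0.01).
#' @param extent minimum surviving cluster size in voxels (default 20).
#' @return List with `stat` (t [stat_map()]), `significant` (3-D logical of
#'   voxels surviving FDR + extent), and `clusters` (tibble of surviving
#'   components: id, size, peak value/coordinates).
#' @export
one_sample_group_map <- function(zmaps, mask, geometry, q = 0.01,
                                 extent = 20) {
  n <- length(zmaps)
  if (n < 3) stop("one-sample group map needs at least 3 subjects")
  st <- .stack_maps(zmaps, mask)
  mu <- colMeans(st$Y)
  se <- apply(st$Y, 2, stats::sd) / sqrt(n)
  tval <- ifelse(se > 0, mu / se, 0)
  p <- 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  surv <- padj <= q
  sig <- array(FALSE, geometry$dim)
  sig[st$lin[surv]] <- TRUE
  lab <- label_clusters(sig)
  keep_ids <- which(lab$sizes >= extent)
  sig_ext <- array(FALSE, geometry$dim)
  rows <- list()
  tmap <- .fill_map(tval, st$lin, geometry$dim)
  for (id in keep_ids) {
    vox <- lab$labels == id
    sig_ext[vox] <- TRUE
    pk <- find_peak(vox, tmap, geometry)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cluster_id = id, size_voxels = lab$sizes[id],
      peak_value = pk$value, peak_mni_x = pk$mni[1],
      peak_mni_y = pk$mni[2], peak_mni_z = pk$mni[3])
  }
  list(stat = stat_map(tmap, "t", df = n - 1, mask = mask,
                       geometry = geometry),
       significant = sig_ext,
       clusters = if (length(rows)) dplyr::bind_rows(rows) else
         tibble::tibble(cluster_id = integer(), size_voxels = integer(),
                        peak_value = numeric(), peak_mni_x = numeric(),
                        peak_mni_y = numeric(), peak_mni_z = numeric()))
}

# full / reduced design pair for the group factor with an FD covariate
# (Control is the reference level; the F statistic is coding-invariant)
.group_designs <- function(groups, covariate) {
  g <- factor(groups, levels = intersect(GROUPS, unique(groups)))
  dummies <- stats::model.matrix(~g)[, -1, drop = FALSE]
  n <- length(groups)
  Xr <- cbind(intercept = rep(1, n))
  if (!is.null(covariate)) Xr <- cbind(Xr, fd = covariate - mean(covariate))
  Xf <- cbind(Xr[, 1, drop = FALSE], dummies)
  if (!is.null(covariate)) Xf <- cbind(Xf, fd = covariate - mean(covariate))
  list(full = .prune_design(Xf), reduced = .prune_design(Xr))
}

#' Voxelwise one-way ANOVA with a covariate (ANCOVA F map)
#'
#' Per voxel, the F statistic for the group factor in the linear model
#' `z ~ intercept + group dummies + demeaned covariate`, computed from the
#' residual-sum-of-squares comparison between the full model and the reduced
#' model (intercept + covariate). With three groups and a non-degenerate
#' covariate the df are (2, n - 4); degenerate covariates are pruned and the
#' df adjust accordingly.
#'
#' @param zmaps list of subject z maps (3-D arrays or `vmhc_map`s).
#' @param groups group label per subject.
#' @param covariate numeric covariate per subject (e.g. mean FD), or `NULL`.
#' @param mask 3-D logical analysis mask.
#' @param geometry a [grid_geometry()].
#' @return An F [stat_map()] carrying the full-model residuals for smoothness
#'   estimation.
#' @export
ancova_f_map <- function(zmaps, groups, covariate, mask, geometry) {
  n <- length(zmaps)
  stopifnot(n == length(groups))
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("every group needs at least 2 subjects; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  st <- .stack_maps(zmaps, mask)
  dz <- .group_designs(groups, covariate)
  qf <- qr(dz$full); qr_ <- qr(dz$reduced)
  res_full <- qr.resid(qf, st$Y)
  rss1 <- colSums(res_full^2)
  rss0 <- colSums(qr.resid(qr_, st$Y)^2)
  df1 <- qf$rank - qr_$rank
  df2 <- n - qf$rank
  fval <- pmax(0, (rss0 - rss1) / df1) / (rss1 / df2)
  fval[rss1 <= 0] <- 0
  stat_map(.fill_map(fval, st$lin, geometry$dim), "F", df = c(df1, df2),
           mask = mask, geometry = geometry, residuals = res_full)
}

#' Covariate-adjusted two-sample t map
#'
#' Per voxel, the t statistic for the group-a-minus-group-b contrast in the
#' model `z ~ intercept + indicator(a) + demeaned covariate`; with a
#' non-degenerate covariate the df are n - 3. Swapping the two groups negates
#' the map.
#'
#' @param zmaps_a,zmaps_b lists of subject z maps for the two groups.
#' @param covariate numeric covariate over subjects of a then b, or `NULL`.
#' @param mask 3-D logical analysis mask.
#' @param geometry a [grid_geometry()].
#' @return A t [stat_map()] with full-model residuals attached.
#' @export
two_sample_t_map <- function(zmaps_a, zmaps_b, covariate, mask, geometry) {
  na <- length(zmaps_a); nb <- length(zmaps_b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 subjects")
  n <- na + nb
  st <- .stack_maps(c(zmaps_a, zmaps_b), mask)
  ind <- c(rep(1, na), rep(0, nb))
  cov_dm <- if (is.null(covariate)) NULL else covariate - mean(covariate)
  X <- .prune_design(cbind(intercept = 1, group_a = ind, fd = cov_dm))
  ci <- which(colnames(X) == "group_a")
  qx <- qr(X)
  beta <- qr.coef(qx, st$Y)
  res <- qr.resid(qx, st$Y)
  df <- n - qx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[ci, ci])
  tval <- ifelse(se > 0, beta[ci, ] / se, 0)
  stat_map(.fill_map(tval, st$lin, geometry$dim), "t", df = df,
           mask = mask, geometry = geometry, residuals = res)
}

#' Convert an F or t map to a Z map
#'
#' Probability transform: each value is mapped to the standard-normal deviate
#' with the same tail probability. F values map one-sided (upper tail); t
#' values map preserving sign. Computed on the log scale for numerical
#' stability far in the tails.
#'
#' @param map an F or t [stat_map()] with known df.
#' @return A Z [stat_map()] (df dropped, residuals carried over).
#' @export
stat_to_z <- function(map) {
  if (map$kind == "Z") return(map)
  if (is.null(map$df)) stop("df needed to convert a ", map$kind, " map")
  v <- map$values
  if (map$kind == "F") {
    logp <- stats::pf(v, map$df[1], map$df[2], lower.tail = FALSE,
                      log.p = TRUE)
    z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  } else {
    logp <- stats::pt(abs(v), map$df, lower.tail = FALSE, log.p = TRUE)
    z <- sign(v) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  }
  z[!is.finite(z)] <- 0
  if (!is.null(map$mask)) z[!map$mask] <- 0
  stat_map(z, "Z", df = NULL, mask = map$mask, geometry = map$geometry,
           residuals = map$residuals)
}

#' Pairwise group comparisons with Bonferroni correction
#'
#' Pairwise t statistics using the pooled within-group variance from the
#' one-way ANOVA on the supplied values (df = n - k); each two-tailed p is
#' multiplied by the number of comparisons (3) and capped at 1.
#'
#' @param values numeric vector (e.g. sphere-mean z-VMHC per subject).
#' @param groups group label per subject (3 groups expected).
#' @return List with `group_means` (named), `f_stat`, `p_anova`, and
#'   `contrasts` (tibble: contrast, estimate, t, df, p_uncorrected,
#'   p_bonferroni).
#' @export
posthoc_bonferroni <- function(values, groups) {
  g <- factor(groups, levels = intersect(GROUPS, unique(groups)))
  if (nlevels(g) != 3) stop("post hoc comparisons expect 3 groups")
  n <- length(values)
  k <- 3L
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  msw <- ssw / (n - k)
  ssb <- sum(ns * (means - mean(values))^2)
  f_stat <- (ssb / (k - 1)) / msw
  p_anova <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  pairs <- utils::combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- means[[a]] - means[[b]]
    se <- sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), n - k, lower.tail = FALSE)
    tibble::tibble(contrast = paste(a, "vs", b), estimate = est,
                   t = tval, df = n - k, p_uncorrected = p,
                   p_bonferroni = min(1, 3 * p))
  })
  list(group_means = stats::setNames(as.numeric(means), levels(g)),
       f_stat = unname(f_stat), p_anova = unname(p_anova),
       contrasts = dplyr::bind_rows(rows))
}
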