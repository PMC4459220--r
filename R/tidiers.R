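# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster result
#'
#' @param x a `cluster_result` from [grf_cluster_correct()].
#' @param ... unused.
#' @return The cluster tibble (id, size, peak value and mm coordinates,
#'   corrected p, significance flag).
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' One-row summary of a cluster result
#'
#' @inheritParams tidy.cluster_result
#' @return Tibble with cluster counts, thresholds, and the smoothness
#'   estimate used.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    cluster_forming_z = x$cluster_forming_z,
    alpha = x$alpha,
    fwhm_x_mm = x$smoothness$fwhm_mm[1],
    fwhm_y_mm = x$smoothness$fwhm_mm[2],
    fwhm_z_mm = x$smoothness$fwhm_mm[3],
    resels = x$smoothness$resels
  )
}

#' Tidy a statistic map
#'
#' @param x a [stat_map()].
#' @param mask_only keep only voxels inside the map's mask (default `TRUE`).
#' @param ... unused.
#' @return Long tibble: voxel indices `i, j, k`, mm coordinates
#'   `mni_x, mni_y, mni_z`, and `value`.
#' @export
tidy.stat_map <- function(x, mask_only = TRUE, ...) {
  sel <- if (mask_only && !is.null(x$mask)) which(x$mask) else
    seq_along(x$values)
  ijk <- arrayInd(sel, dim(x$values))
  mm <- voxel_to_mni(ijk, x$geometry)
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 mni_x = mm[, 1], mni_y = mm[, 2], mni_z = mm[, 3],
                 value = x$values[sel])
}

#' Tidy a subject's VMHC map
#'
#' @param x a `vmhc_map` from [compute_vmhc()].
#' @param ... unused.
#' @return Long tibble of valid voxels with `r` and Fisher `z`.
#' @export
tidy.vmhc_map <- function(x, ...) {
  sel <- which(x$valid_mask)
  ijk <- arrayInd(sel, dim(x$r_map))
  mm <- voxel_to_mni(ijk, x$geometry)
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 mni_x = mm[, 1], mni_y = mm[, 2], mni_z = mm[, 3],
                 r = x$r_map[sel], z = x$z_map[sel])
}

#' One-row summary of a VMHC map
#'
#' @inheritParams tidy.vmhc_map
#' @return Tibble with valid-voxel count and mean/median r and z.
#' @export
glance.vmhc_map <- function(x, ...) {
  v <- x$valid_mask
  tibble::tibble(n_valid = sum(v),
                 mean_r = mean(x$r_map[v]), median_r = stats::median(x$r_map[v]),
                 mean_z = mean(x$z_map[v]))
}

.slice_df <- function(arr, k, geometry) {
  d <- dim(arr)
  ij <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
  mm <- voxel_to_mni(cbind(ij, k), geometry)
  tibble::tibble(x = mm[, 1], y = mm[, 2],
                 value = arr[cbind(ij, k)])
}

#' Plot an axial slice of a statistic map
#'
#' @param object a [stat_map()].
#' @param k axial slice index (default: middle slice).
#' @param ... unused.
#' @return A ggplot raster of the slice.
#' @export
autoplot.stat_map <- function(object, k = NULL, ...) {
  d <- dim(object$values)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  df <- .slice_df(object$values, k, object$geometry)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s map, axial slice k = %d",
                                  object$kind, k))
}

#' Plot an axial slice of a VMHC map
#'
#' @param object a `vmhc_map`.
#' @param k axial slice index (default: middle slice).
#' @param which plot the `"z"` (default) or `"r"` map.
#' @param ... unused.
#' @return A ggplot raster of the slice.
#' @export
autoplot.vmhc_map <- function(object, k = NULL, which = c("z", "r"), ...) {
  which <- match.arg(which)
  arr <- if (which == "z") object$z_map else object$r_map
  d <- dim(arr)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  df <- .slice_df(arr, k, object$geometry)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = paste0(which, "VMHC")) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%sVMHC, axial slice k = %d", which, k))
}
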