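# Voxel-mirrored homotopic connectivity: per-subject mirror-voxel Pearson
# correlation maps and their Fisher r-to-z transforms within a gray-matter
# mask.

#' Gray-matter mask from a probability volume
#'
#' Binarizes a (flip-symmetric) gray-matter probability volume at a threshold;
#' the default 40% matches common practice for symmetric-template masks.
#'
#' @param probability 3-D array of probabilities in [0, 1].
#' @param threshold inclusion threshold (voxel is gray matter iff
#'   `probability >= threshold`); default 0.40.
#' @return List of class `gm_mask` with `probability`, `threshold`, `binary`.
#' @export
gray_matter_mask <- function(probability, threshold = 0.40) {
  stopifnot(length(dim(probability)) == 3,
            all(probability >= 0 & probability <= 1),
            threshold > 0, threshold < 1)
  structure(list(probability = probability, threshold = threshold,
                 binary = probability >= threshold),
            class = "gm_mask")
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)` after clipping `|r|` at `1 - 1e-7` so correlations of
#' exactly +/-1 map to large finite values instead of infinities. Monotone
#' and odd.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
}

#' Compute a subject's voxel-mirrored homotopic connectivity map
#'
#' For every gray-matter voxel `v`, the Pearson correlation between the time
#' series at `v` and at its left-right mirror `mirror(v)` is computed; the
#' statistic is symmetric in its two arguments, so the r map equals its own
#' flip exactly. Voxels outside gray matter, or whose pair member has zero
#' temporal variance, are marked invalid and set to 0 in both maps.
#'
#' @param bold a preprocessed [bold_series()] on a flip-symmetric grid with an
#'   even left-right dimension.
#' @param mask a [gray_matter_mask()] on the same grid.
#' @return A `vmhc_map`: list with `r_map`, `z_map` (3-D arrays),
#'   `valid_mask` (3-D logical), `geometry`.
#' @export
compute_vmhc <- function(bold, mask) {
  d <- dim(bold$data)
  if (d[4] < 3) stop("VMHC needs at least 3 time points")
  if (!identical(dim(mask$binary), d[1:3])) {
    stop("gray-matter mask grid does not match the BOLD grid")
  }
  geom <- grid_geometry(d[1:3], bold$voxel_mm)   # errors on odd x dimension
  right <- as.matrix(expand.grid(i = (d[1] / 2 + 1):d[1],
                                 j = seq_len(d[2]), k = seq_len(d[3])))
  left <- right
  left[, 1] <- mirror_index(right[, 1], d[1])
  rlin <- .linear_index(right, d[1:3])
  llin <- .linear_index(left, d[1:3])
  m <- .as_vox_time(bold)
  xr <- m[rlin, , drop = FALSE]
  xl <- m[llin, , drop = FALSE]
  xr <- xr - rowMeans(xr)
  xl <- xl - rowMeans(xl)
  vr <- rowSums(xr^2)
  vl <- rowSums(xl^2)
  ok <- vr > 0 & vl > 0 & mask$binary[rlin] & mask$binary[llin]
  r <- numeric(length(rlin))
  r[ok] <- rowSums(xr[ok, , drop = FALSE] * xl[ok, , drop = FALSE]) /
    sqrt(vr[ok] * vl[ok])
  r_map <- array(0, d[1:3]); z_map <- array(0, d[1:3])
  valid <- array(FALSE, d[1:3])
  r_map[rlin] <- r; r_map[llin] <- r
  z <- ifelse(ok, fisher_z(r), 0)
  z_map[rlin] <- z; z_map[llin] <- z
  valid[rlin] <- ok; valid[llin] <- ok
  structure(list(r_map = r_map, z_map = z_map, valid_mask = valid,
                 geometry = geom),
            class = "vmhc_map")
}

#' @export
print.vmhc_map <- function(x, ...) {
  cat(sprintf("<vmhc_map> %s voxels, %d valid; mean r (valid) = %.3f\n",
              paste(dim(x$r_map), collapse = "x"), sum(x$valid_mask),
              mean(x$r_map[x$valid_mask])))
  invisible(x)
}

#' Mean VMHC correlation inside a planted region
#'
#' Convenience accessor used in recovery checks: the mean of the r map over
#' the valid voxels of a region (and, by symmetry, its mirror).
#'
#' @param vmhc a `vmhc_map`.
#' @param center_mni,radius_mm sphere definition, mm.
#' @return Mean r over valid region voxels.
#' @export
region_mean_r <- function(vmhc, center_mni, radius_mm) {
  vox <- sphere_voxels(center_mni, radius_mm, vmhc$geometry)
  lin <- .linear_index(vox, vmhc$geometry$dim)
  lin <- lin[vmhc$valid_mask[lin]]
  if (length(lin) == 0) stop("no valid voxels inside the region")
  mean(vmhc$r_map[lin])
}

#' Write a subject's z-VMHC map to NIfTI
#'
#' Stored as 32-bit scalar NIfTI named `<subject_id>_zvmhc.nii.gz`.
#'
#' @param vmhc a `vmhc_map`.
#' @param subject_id subject identifier.
#' @param dir output directory.
#' @return The written path, invisibly.
#' @export
write_zvmhc <- function(vmhc, subject_id, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(subject_id, "_zvmhc.nii.gz"))
  .write_nifti(vmhc$z_map, path, vmhc$geometry$voxel_mm)
  vpath <- file.path(dir, paste0(subject_id, "_valid.nii.gz"))
  .write_nifti(vmhc$valid_mask + 0, vpath, vmhc$geometry$voxel_mm)
  invisible(path)
}
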