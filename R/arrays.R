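# Volume primitives: left-right flip, separable Gaussian smoothing with
# half-sample reflective padding, 26-connectivity component labeling.

#' Flip a volume across the mid-sagittal plane
#'
#' Reverses the first (left-right) array axis.
#'
#' @param vol 3-D or 4-D numeric array.
#' @return Array of the same shape with the first axis reversed.
#' @export
flip_lr <- function(vol) {
  d <- dim(vol)
  idx <- rev(seq_len(d[1]))
  if (length(d) == 3) vol[idx, , , drop = FALSE]
  else if (length(d) == 4) vol[idx, , , , drop = FALSE]
  else stop("flip_lr expects a 3-D or 4-D array")
}

# 1-D Gaussian kernel, unit sum; sigma in voxel units
.gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# n x n convolution matrix with half-sample symmetric (reflective) padding;
# symmetric by construction, so row and column sums are both 1 and the total
# signal mass is conserved exactly.
.conv_matrix <- function(n, sigma_vox) {
  k <- .gauss_kernel(sigma_vox)
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  fold <- function(p) {
    # reflect indices into 1..n: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
    while (any(p < 1L | p > n)) {
      p <- ifelse(p < 1L, 1L - p, p)
      p <- ifelse(p > n, 2L * n + 1L - p, p)
    }
    p
  }
  for (i in seq_len(n)) {
    p <- fold(i + (-r):r)
    for (q in seq_along(p)) M[i, p[q]] <- M[i, p[q]] + k[q]
  }
  M
}

.apply_axis <- function(vol, M, axis) {
  d <- dim(vol)
  if (axis == 1) {
    array(M %*% matrix(vol, d[1], d[2] * d[3]), d)
  } else if (axis == 2) {
    v <- aperm(vol, c(2, 1, 3))
    v <- array(M %*% matrix(v, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    aperm(v, c(2, 1, 3))
  } else {
    v <- aperm(vol, c(3, 1, 2))
    v <- array(M %*% matrix(v, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    aperm(v, c(2, 3, 1))
  }
}

#' Spatial Gaussian smoothing of a 3-D volume
#'
#' Separable Gaussian convolution with kernel standard deviation
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, scaled by the voxel size.
#' Boundaries use half-sample reflective padding, which makes the per-axis
#' convolution operator symmetric and hence conserves the total sum of the
#' volume to machine precision. `fwhm_mm = 0` is the identity.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, mm; scalar or
#'   length 3 (per axis).
#' @param voxel_mm voxel size, mm; scalar or length 3.
#' @return Smoothed array, same shape.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 4, voxel_mm = 3) {
  stopifnot(length(dim(vol)) == 3)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be non-negative")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  for (a in 1:3) {
    if (sigma_vox[a] > 0) {
      vol <- .apply_axis(vol, .conv_matrix(dim(vol)[a], sigma_vox[a]), a)
    }
  }
  vol
}

# cached per-axis convolution matrices for repeated smoothing of same-shaped
# volumes (e.g. every frame of a 4-D series)
.smoother <- function(dim3, fwhm_mm, voxel_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  mats <- lapply(1:3, function(a) {
    if (sigma_vox[a] > 0) .conv_matrix(dim3[a], sigma_vox[a]) else NULL
  })
  function(vol) {
    for (a in 1:3) if (!is.null(mats[[a]])) vol <- .apply_axis(vol, mats[[a]], a)
    vol
  }
}

#' Label connected components of a supra-threshold voxel set
#'
#' Components are defined under 26-connectivity (face, edge, and corner
#' neighbors), the common neuroimaging-toolbox default.
#'
#' @param mask 3-D logical array of supra-threshold voxels.
#' @return List with `labels` (integer array, 0 = background, components
#'   numbered 1..m in decreasing size order) and `sizes` (integer vector of
#'   component voxel counts).
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  labels <- array(0L, d)
  supra <- which(mask)
  if (length(supra) == 0) return(list(labels = labels, sizes = integer(0)))
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]            # 26 offsets
  in_set <- array(FALSE, d); in_set[supra] <- TRUE
  lab <- 0L
  sizes <- integer(0)
  for (s in supra) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    frontier <- s
    labels[s] <- lab
    count <- 1L
    while (length(frontier) > 0) {
      ijk <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(r) {
        sweep(ijk, 2, off[r, ], "+")
      }))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(.linear_index(nb, d))
      lin <- lin[in_set[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      count <- count + length(lin)
      frontier <- lin
    }
    sizes <- c(sizes, count)
  }
  # renumber components largest-first for stable downstream reporting
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(length(sizes)); remap[ord] <- seq_along(sizes)
  nz <- labels != 0L
  labels[nz] <- remap[labels[nz]]
  list(labels = labels, sizes = sizes[ord])
}
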