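#' Grid geometry for a symmetric analysis grid
#'
#' Describes a voxel grid that is left-right symmetric about the mid-sagittal
#' plane. The first array axis is the left-right axis and must have an even
#' number of voxels so that every voxel has a distinct mirror under index
#' reversal. Voxel centers are placed symmetrically about the grid center, so
#' the stereotaxic (MNI-style) x coordinate of a voxel and of its mirror are
#' exact negatives.
#'
#' @param dim integer vector of length 3, grid dimensions (x, y, z); `dim[1]`
#'   must be even.
#' @param voxel_mm voxel edge length(s) in mm; scalar or length 3.
#' @return An object of class `grid_geometry` with fields `dim` and `voxel_mm`.
#' @export
grid_geometry <- function(dim, voxel_mm = 3) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 2))
  if (dim[1] %% 2L != 0L) {
    stop("left-right dimension must be even (no self-mirrored voxel column permitted), got ",
         dim[1])
  }
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  stopifnot(all(voxel_mm > 0))
  structure(list(dim = dim, voxel_mm = voxel_mm), class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d voxels at %g x %g x %g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' Mirror a voxel index across the mid-sagittal plane
#'
#' Pure index reversal along the left-right axis: 1-based index `i` maps to
#' `nx + 1 - i`. The map is an involution, and with an even `nx` no voxel is
#' its own mirror.
#'
#' @param i voxel index (1-based) along the left-right axis.
#' @param nx length of the left-right axis; must be even.
#' @return Mirrored index, same length as `i`.
#' @export
mirror_index <- function(i, nx) {
  nx <- as.integer(nx)
  if (nx %% 2L != 0L) {
    stop("mirroring requires an even left-right axis length, got ", nx)
  }
  if (any(i < 1L | i > nx)) stop("voxel index out of range 1..", nx)
  nx + 1L - as.integer(i)
}

#' Convert voxel indices to stereotaxic mm coordinates
#'
#' @param ijk integer matrix (n x 3) or vector of length 3 of 1-based voxel
#'   indices.
#' @param geom a [grid_geometry()].
#' @return Numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mni <- function(ijk, geom) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  ctr <- (geom$dim + 1) / 2
  sweep(sweep(ijk, 2, ctr, "-"), 2, geom$voxel_mm, "*")
}

#' Convert stereotaxic mm coordinates to the nearest voxel index
#'
#' @param xyz numeric matrix (n x 3) or vector of length 3, mm.
#' @inheritParams voxel_to_mni
#' @return Integer matrix (n x 3) of 1-based indices.
#' @export
mni_to_voxel <- function(xyz, geom) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  ctr <- (geom$dim + 1) / 2
  idx <- round(sweep(sweep(xyz, 2, geom$voxel_mm, "/"), 2, ctr, "+"))
  storage.mode(idx) <- "integer"
  idx
}

#' Voxels whose centers fall inside a sphere
#'
#' Sphere membership is decided by the Euclidean mm distance from the voxel
#' center to the sphere center, with no partial-volume weighting. A 5 mm
#' radius on a 3 mm isotropic grid with the center on a voxel center yields
#' 19 voxels (center + 6 face + 12 edge neighbors).
#'
#' @param center_mni numeric length 3, sphere center in mm.
#' @param radius_mm sphere radius in mm.
#' @inheritParams voxel_to_mni
#' @return Integer matrix (n x 3) of voxel indices; zero rows if the sphere
#'   misses every voxel center.
#' @export
sphere_voxels <- function(center_mni, radius_mm, geom) {
  stopifnot(radius_mm > 0)
  half <- ceiling(radius_mm / geom$voxel_mm) + 1
  c_idx <- (center_mni / geom$voxel_mm) + (geom$dim + 1) / 2
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(c_idx[a] - half[a]))
    hi <- min(geom$dim[a], ceiling(c_idx[a] + half[a]))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0)) return(matrix(integer(0), 0, 3))
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- voxel_to_mni(grid, geom)
  d2 <- rowSums(sweep(mm, 2, center_mni, "-")^2)
  out <- grid[d2 <= radius_mm^2, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# linear index into a 3-D array from an (n x 3) index matrix
.linear_index <- function(ijk, dim) {
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * dim[1] +
               (ijk[, 3] - 1L) * dim[1] * dim[2])
}
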