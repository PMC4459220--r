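# Retained preprocessing chain: volume discard, framewise displacement and
# motion-based exclusion, nuisance regression, spatial smoothing, linear
# detrending, ideal band-pass filtering, symmetric template construction.
# Fixed stage order: discard -> (FD, exclusion) -> nuisance regression ->
# smoothing -> detrend -> band-pass.

#' A subject's 4-D BOLD series
#'
#' @param data 4-D numeric array (x, y, z, t) on a grid that is left-right
#'   symmetric about the mid-sagittal plane.
#' @param tr_seconds repetition time, s.
#' @param voxel_mm voxel size, mm (scalar or length 3).
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr_seconds, voxel_mm) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 2, tr_seconds > 0)
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_mm = rep_len(as.numeric(voxel_mm), 3)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels x %d volumes, TR %gs, %g mm\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, x$voxel_mm[1]))
  invisible(x)
}

# internal: 4-D array <-> voxels x time matrix
.as_vox_time <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, prod(d[1:3]), d[4])
}
.from_vox_time <- function(bold, m) {
  bold$data <- array(m, dim(bold$data))
  bold
}

#' Discard initial volumes of a BOLD series
#'
#' Drops the first `n_discard` frames (acquired before longitudinal
#' equilibrium); remaining frames are unchanged.
#'
#' @param bold a [bold_series()].
#' @param n_discard number of leading frames to drop (default 10).
#' @return A [bold_series()] with `t - n_discard` frames.
#' @export
discard_initial_volumes <- function(bold, n_discard = 10) {
  n_t <- dim(bold$data)[4]
  if (n_discard >= n_t) {
    stop("cannot discard ", n_discard, " of ", n_t, " volumes")
  }
  if (n_discard == 0) return(bold)
  bold$data <- bold$data[, , , (n_discard + 1):n_t, drop = FALSE]
  bold
}

#' Discard initial rows of a motion trace
#'
#' Companion to [discard_initial_volumes()], so the trace row count always
#' equals the retained volume count.
#'
#' @param motion T x 6 motion-parameter matrix.
#' @inheritParams discard_initial_volumes
#' @return Matrix with the first `n_discard` rows dropped.
#' @export
discard_initial_rows <- function(motion, n_discard = 10) {
  if (n_discard >= nrow(motion)) stop("cannot discard all motion rows")
  motion[(n_discard + 1):nrow(motion), , drop = FALSE]
}

#' Framewise displacement from a motion trace
#'
#' Power-style scalar FD: the sum of absolute backward differences of the
#' three translations (mm) plus the three rotations converted to arc length
#' on a sphere (rotations stored in degrees are converted to radians and
#' multiplied by the sphere radius). The first frame's FD is defined as 0.
#' Adding a constant offset to all frames leaves FD unchanged.
#'
#' @param motion T x 6 matrix: translations (mm) in columns 1-3, rotations
#'   (degrees) in columns 4-6.
#' @param sphere_radius_mm radius used for the rotation arc length (default
#'   50 mm).
#' @return List with `values` (length-T FD series, mm; first entry 0) and
#'   `mean_fd` (its arithmetic mean).
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("FD needs at least 2 motion rows")
  stopifnot(ncol(motion) == 6)
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE] * pi / 180))
  list(values = fd, mean_fd = mean(fd))
}

#' Motion summary and exclusion flags for a set of subjects
#'
#' A subject is excluded iff the maximum absolute excursion from the first
#' retained frame strictly exceeds 2.0 mm on any translation axis or
#' 2.0 degrees on any rotation axis (strict inequality: exactly 2.0 is
#' retained). Also reports each subject's mean framewise displacement.
#'
#' @param motion named list of T x 6 motion matrices (rows = retained
#'   volumes, i.e. after discard).
#' @param trans_limit_mm,rot_limit_deg exclusion thresholds (defaults 2.0).
#' @param sphere_radius_mm passed to [compute_fd()].
#' @return Tibble with columns `subject_id`, `mean_fd`, `max_translation_mm`,
#'   `max_rotation_deg`, `excluded`.
#' @export
exclusion_flags <- function(motion, trans_limit_mm = 2, rot_limit_deg = 2,
                            sphere_radius_mm = 50) {
  stopifnot(is.list(motion))
  ids <- names(motion)
  if (is.null(ids)) ids <- sprintf("subject%03d", seq_along(motion))
  rows <- lapply(seq_along(motion), function(s) {
    m <- as.matrix(motion[[s]])
    exc <- sweep(m, 2, m[1, ], "-")
    max_t <- max(abs(exc[, 1:3]))
    max_r <- max(abs(exc[, 4:6]))
    tibble::tibble(
      subject_id = ids[s],
      mean_fd = compute_fd(m, sphere_radius_mm)$mean_fd,
      max_translation_mm = max_t,
      max_rotation_deg = max_r,
      excluded = max_t > trans_limit_mm | max_r > rot_limit_deg
    )
  })
  dplyr::bind_rows(rows)
}

#' Remove nuisance signals by linear regression
#'
#' Every voxel time series is replaced by its least-squares residual against
#' an intercept plus the supplied regressors (e.g. the six rigid motion
#' parameters and mean ventricle / white-matter signals). Residuals are
#' orthogonal to every regressor column. Rank-deficient designs are pruned
#' deterministically (leftmost columns kept) with a warning.
#'
#' @param bold a [bold_series()].
#' @param regressors T x k numeric matrix, rows matching the retained frames.
#' @return A [bold_series()] of residuals (per-voxel means removed).
#' @export
regress_nuisance <- function(bold, regressors) {
  regressors <- as.matrix(regressors)
  n_t <- dim(bold$data)[4]
  if (nrow(regressors) != n_t) {
    stop("regressor rows (", nrow(regressors), ") must equal the number of ",
         "frames (", n_t, ")")
  }
  if (ncol(regressors) >= n_t) stop("more regressors than frames")
  X <- cbind(intercept = 1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("rank-deficient nuisance design: dropping ",
            ncol(X) - qrX$rank, " dependent column(s)")
    qrX <- qr(X[, sort(keep), drop = FALSE])
  }
  m <- t(.as_vox_time(bold))                   # time x voxels
  res <- qr.resid(qrX, m)
  .from_vox_time(bold, t(res))
}

#' Remove per-voxel linear trends
#'
#' Subtracts the least-squares line (intercept + slope * frame) from every
#' voxel time series.
#'
#' @param bold a [bold_series()].
#' @return Detrended [bold_series()].
#' @export
detrend_linear <- function(bold) {
  n_t <- dim(bold$data)[4]
  if (n_t < 3) stop("detrending needs at least 3 frames")
  X <- cbind(1, seq_len(n_t))
  qrX <- qr(X)
  m <- t(.as_vox_time(bold))
  .from_vox_time(bold, t(qr.resid(qrX, m)))
}

#' Ideal frequency-domain band-pass filter
#'
#' Discrete-Fourier components with frequency inside `[low_hz, high_hz]` are
#' retained; all others, including the DC component, are zeroed (the
#' rectangular-mask filter of the legacy resting-state toolboxes). The output
#' is real-valued and the operation is exactly idempotent.
#'
#' @param bold a [bold_series()].
#' @param low_hz,high_hz pass-band edges, Hz (defaults 0.01 and 0.08);
#'   `high_hz` must be below the Nyquist frequency `1 / (2 TR)`.
#' @return Filtered [bold_series()].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  n_t <- dim(bold$data)[4]
  nyquist <- 1 / (2 * bold$tr_seconds)
  if (low_hz >= high_hz) stop("low_hz must be below high_hz")
  if (high_hz >= nyquist) {
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
         nyquist, " Hz)")
  }
  freq <- (seq_len(n_t) - 1) / (n_t * bold$tr_seconds)
  freq <- pmin(freq, 1 / bold$tr_seconds - freq)   # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  m <- t(.as_vox_time(bold))                       # time x voxels
  ft <- stats::mvfft(m)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / n_t
  .from_vox_time(bold, t(out))
}

#' Smooth every frame of a BOLD series
#'
#' Applies [smooth_gaussian()] to each volume of the series.
#'
#' @param bold a [bold_series()].
#' @param fwhm_mm kernel FWHM, mm (default 4).
#' @return Smoothed [bold_series()].
#' @export
smooth_bold <- function(bold, fwhm_mm = 4) {
  if (all(fwhm_mm == 0)) return(bold)
  d <- dim(bold$data)
  sm <- .smoother(d[1:3], fwhm_mm, bold$voxel_mm)
  for (t in seq_len(d[4])) {
    bold$data[, , , t] <- sm(bold$data[, , , t, drop = TRUE])
  }
  bold
}

#' Build a left-right symmetric template
#'
#' Averages the supplied volumes across subjects, then averages the mean with
#' its left-right flipped copy. The result equals its own flip exactly.
#'
#' @param volumes list of 3-D arrays on a common grid.
#' @return 3-D array, exactly flip-symmetric.
#' @export
build_symmetric_template <- function(volumes) {
  if (!is.list(volumes)) volumes <- list(volumes)
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]])
  for (v in seq_along(volumes)) {
    if (!identical(dim(volumes[[v]]), d)) {
      stop("volume ", v, " is not on the common grid")
    }
  }
  mean_vol <- Reduce(`+`, volumes) / length(volumes)
  out <- (mean_vol + flip_lr(mean_vol)) / 2
  # enforce bitwise flip symmetry (floating-point addition is commutative,
  # but make the contract explicit)
  flipped <- flip_lr(out)
  (out + flipped) / 2
}

#' Run the full retained preprocessing chain on one subject
#'
#' Stage order: discard initial volumes -> framewise displacement ->
#' nuisance regression (six motion parameters plus mean ventricle and
#' white-matter signals) -> spatial smoothing -> linear detrend -> band-pass.
#'
#' @param bold a [bold_series()] (full acquisition).
#' @param motion T x 6 motion matrix (full acquisition).
#' @param masks list with logical arrays `ventricle` and `white_matter`.
#' @param n_discard leading volumes to drop (default 10).
#' @param fwhm_mm smoothing kernel FWHM, mm (default 4).
#' @param low_hz,high_hz band-pass edges, Hz.
#' @return List with `bold` (preprocessed series), `motion` (retained rows),
#'   `fd` (output of [compute_fd()]).
#' @export
preprocess_bold <- function(bold, motion, masks, n_discard = 10,
                            fwhm_mm = 4, low_hz = 0.01, high_hz = 0.08) {
  bold <- discard_initial_volumes(bold, n_discard)
  motion <- discard_initial_rows(motion, n_discard)
  fd <- compute_fd(motion)
  m <- .as_vox_time(bold)
  nuis <- cbind(motion,
                ventricle = colMeans(m[as.vector(masks$ventricle), , drop = FALSE]),
                white_matter = colMeans(m[as.vector(masks$white_matter), ,
                                          drop = FALSE]))
  bold <- regress_nuisance(bold, nuis)
  bold <- smooth_bold(bold, fwhm_mm)
  bold <- detrend_linear(bold)
  bold <- bandpass(bold, low_hz, high_hz)
  list(bold = bold, motion = motion, fd = fd)
}
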