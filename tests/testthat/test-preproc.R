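test_that("initial-volume discard keeps remaining frames unchanged", {
  b <- random_bold(n_t = 240)
  out <- discard_initial_volumes(b, 10)
  expect_identical(dim(out$data)[4], 230L)
  expect_identical(out$data[, , , 1], b$data[, , , 11])
  expect_identical(discard_initial_volumes(b, 0)$data, b$data)
  one <- discard_initial_volumes(b, 239)
  expect_identical(dim(one$data)[4], 1L)
  expect_error(discard_initial_volumes(b, 240), "discard")
  expect_error(detrend_linear(bold_series(b$data[, , , 1:2, drop = FALSE], 2, 3)),
               "3 frames")
})

test_that("framewise displacement matches hand-evaluated cases", {
  z <- matrix(0, 10, 6)
  fd0 <- compute_fd(z)
  expect_identical(fd0$values, rep(0, 10))
  expect_identical(fd0$mean_fd, 0)

  tr <- matrix(0, 10, 6); tr[3:10, 1] <- 0.5   # single +0.5 mm step at frame 3
  fd <- compute_fd(tr)
  expect_equal(fd$values[3], 0.5)
  expect_equal(sum(fd$values[-3]), 0)
  expect_equal(fd$mean_fd, mean(fd$values))

  rot <- matrix(0, 5, 6); rot[3:5, 5] <- 1.1459156  # 0.02 rad on one axis
  expect_equal(compute_fd(rot)$values[3], 50 * 0.02, tolerance = 1e-6)

  expect_error(compute_fd(matrix(0, 1, 6)), "2 motion rows")
})

test_that("FD is invariant to constant offsets of the whole trace", {
  set.seed(3)
  tr <- matrix(rnorm(60, sd = 0.1), 10, 6)
  shifted <- sweep(tr, 2, c(1, -2, 0.5, 3, -1, 0.7), "+")
  expect_equal(compute_fd(tr)$values, compute_fd(shifted)$values)
})

test_that("exclusion uses strict thresholds per axis", {
  base <- matrix(0, 20, 6)
  at <- function(col, v) { m <- base; m[10, col] <- v; m }
  flags <- exclusion_flags(list(
    over_t = at(1, 2.5),      # translation above threshold
    at_t = at(2, 2.0),        # exactly 2.0 mm: retained (strict >)
    over_r = at(5, 2.01),     # rotation above threshold
    at_r = at(6, 2.0),
    quiet = base))
  expect_identical(flags$excluded, c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("nuisance regression equals the normal-equations oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n_t <- 20
    b <- bold_series(array(rnorm(2 * 2 * 2 * n_t), c(2, 2, 2, n_t)), 2, 3)
    X <- matrix(rnorm(n_t * 2), n_t, 2)
    out <- regress_nuisance(b, X)
    Xi <- cbind(1, X)
    H <- Xi %*% solve(t(Xi) %*% Xi) %*% t(Xi)
    for (v in 1:8) {
      y <- matrix(b$data, 8, n_t)[v, ]
      expect_equal(matrix(out$data, 8, n_t)[v, ], as.numeric(y - H %*% y),
                   tolerance = 1e-8)
    }
  }
})

test_that("residuals are orthogonal to regressors; spanned series vanish", {
  set.seed(12)
  n_t <- 30
  X <- matrix(rnorm(n_t * 3), n_t, 3)
  # every voxel series is a linear combination of the regressors
  co <- matrix(rnorm(8 * 4), 8, 4)
  m <- cbind(1, X) %*% t(co)
  b <- bold_series(array(t(m), c(2, 2, 2, n_t)), 2, 3)
  out <- regress_nuisance(b, X)
  expect_lt(max(abs(out$data)), 1e-10)
  # random series: residuals orthogonal to each column
  b2 <- random_bold(c(2, 2, 2), n_t, seed = 13)
  r2 <- matrix(regress_nuisance(b2, X)$data, 8, n_t)
  expect_lt(max(abs(r2 %*% X)) / max(abs(r2)), 1e-8)
})

test_that("rank-deficient nuisance designs are pruned with a warning", {
  b <- random_bold(c(2, 2, 2), 20, seed = 14)
  X <- cbind(a = rnorm(20), b = 0)    # constant column collinear w/ intercept
  expect_warning(out <- regress_nuisance(b, X), "rank-deficient")
  expect_true(all(is.finite(out$data)))
})

test_that("linear detrending removes lines and leaves whole-period sinusoids", {
  n_t <- 40
  tvec <- seq_len(n_t)
  ramp <- bold_series(array(rep(2 + 3 * tvec, each = 8), c(2, 2, 2, n_t)), 2, 3)
  expect_lt(max(abs(detrend_linear(ramp)$data)), 1e-9)
  const <- bold_series(array(5, c(2, 2, 2, n_t)), 2, 3)
  expect_lt(max(abs(detrend_linear(const)$data)), 1e-9)
  # zero-mean cosine over whole periods, even about the series center, is
  # orthogonal to both intercept and slope and therefore (near) untouched
  s <- cos(2 * pi * 4 * (tvec - (n_t + 1) / 2) / n_t)
  sb <- bold_series(array(rep(s, each = 8), c(2, 2, 2, n_t)), 2, 3)
  out <- matrix(detrend_linear(sb)$data, 8, n_t)[1, ]
  expect_lt(max(abs(out - s)) / max(abs(s)), 1e-6)
})

test_that("ideal band-pass keeps in-band and kills out-of-band sinusoids", {
  n_t <- 230; tr <- 2
  tm <- (seq_len(n_t) - 1) * tr
  mk <- function(f) bold_series(array(rep(sin(2 * pi * f * tm), each = 8),
                                      c(2, 2, 2, n_t)), tr, 3)
  amp <- function(b) max(abs(matrix(b$data, 8, n_t)[1, ]))
  expect_gte(amp(bandpass(mk(0.05))), 0.95)
  expect_lte(amp(bandpass(mk(0.2))), 0.05)
  const <- bold_series(array(7, c(2, 2, 2, n_t)), tr, 3)
  expect_lt(max(abs(bandpass(const)$data)), 1e-9)
  expect_error(bandpass(mk(0.05), 0.08, 0.01), "below")
  expect_error(bandpass(mk(0.05), 0.01, 0.3), "Nyquist")
})

test_that("band-pass matches an FFT oracle on random data and is idempotent", {
  set.seed(15)
  b <- random_bold(c(2, 2, 2), 64, seed = 15)
  out <- bandpass(b, 0.01, 0.08)
  # oracle: direct per-series FFT mask
  y <- matrix(b$data, 8, 64)[3, ]
  f <- (0:63) / (64 * 2); f <- pmin(f, 0.25 - (f - 0.25))
  ft <- fft(y); ft[!(f >= 0.01 & f <= 0.08)] <- 0
  expect_equal(matrix(out$data, 8, 64)[3, ], Re(fft(ft, inverse = TRUE)) / 64,
               tolerance = 1e-10)
  twice <- bandpass(out, 0.01, 0.08)
  expect_lt(max(abs(twice$data - out$data)) / max(abs(out$data)), 1e-6)
  # detrend idempotence
  dt <- detrend_linear(b)
  expect_lt(max(abs(detrend_linear(dt)$data - dt$data)) / max(abs(dt$data)),
            1e-6)
})

test_that("symmetric template construction averages with its flip", {
  # direct formula on a 4 x 2 x 2 toy grid
  v <- array(seq_len(16), c(4, 2, 2))
  tm <- build_symmetric_template(list(v))
  expect_identical(tm, flip_lr(tm))
  expect_equal(tm[1, 1, 1], (v[1, 1, 1] + v[4, 1, 1]) / 2)
  expect_equal(tm[2, 2, 1], (v[2, 2, 1] + v[3, 2, 1]) / 2)
  # fixed point for symmetric input
  s <- (v + flip_lr(v)) / 2
  expect_equal(build_symmetric_template(list(s)), s)
  # n identical copies behave like n = 1
  expect_equal(build_symmetric_template(list(v, v, v)), tm)
  expect_error(build_symmetric_template(list(v, array(0, c(2, 2, 2)))),
               "volume 2")
})

test_that("preprocess_bold output is finite and FD rows match retained frames", {
  spec <- small_spec(grid = c(6, 6, 6), n_volumes = 60)
  sub <- simulate_subject(spec, "Control", 5)
  pp <- preprocess_bold(sub$bold, sub$motion, nuisance_masks(
    grid_geometry(c(6, 6, 6), 3)), n_discard = 10)
  expect_identical(dim(pp$bold$data)[4], 50L)
  expect_identical(nrow(pp$motion), 50L)
  expect_identical(length(pp$fd$values), 50L)
  expect_true(all(is.finite(pp$bold$data)))
})
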