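rand_bold <- function(shape = c(4, 4, 4), T = 60, tr = 2, sd = 1) {
  volume4d(array(rnorm(prod(shape) * T, 0, sd), c(shape, T)), tr = tr)
}

test_that("framewise displacement follows the Power 50 mm convention exactly", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  m[5:10, 2] <- 0.1                       # single 0.1 mm translation step
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, 9))
  m2 <- matrix(0, 6, 6); m2[3:6, 5] <- 0.01   # 0.01 rad rotation step
  expect_equal(framewise_displacement(m2)[3], 0.5)   # 50 mm x 0.01
  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 motion columns")
  # motion file round trip
  tf <- withr::local_tempfile()
  write.table(m, tf, row.names = FALSE, col.names = FALSE)
  expect_equal(read_motion_params(tf), m)
})

test_that("censoring flags FD and global-signal exceedances with one spike each", {
  cfg <- denoise_config(fd_threshold = 0.5, global_z_threshold = 3)
  fd <- rep(0, 50)
  cen0 <- censor_volumes(fd, rep(c(99, 101), 25), cfg)
  expect_true(all(cen0$keep))
  expect_equal(ncol(cen0$spikes), 0)

  fd[20] <- 0.9
  cen1 <- censor_volumes(fd, rep(c(99, 101), 25), cfg)
  expect_equal(cen1$flagged, 20L)
  expect_equal(sum(cen1$spikes), 1)
  expect_equal(which(cen1$spikes[, 1] == 1), 20L)

  set.seed(55)
  fd2 <- runif(100, 0, 0.4)
  planted <- sample(100, 10)
  fd2[planted] <- runif(10, 0.6, 1.5)
  cen2 <- censor_volumes(fd2, rnorm(100), denoise_config())
  expect_setequal(cen2$flagged, planted)
  expect_error(censor_volumes(rep(1, 10), rnorm(10), cfg), "unusable")
})

test_that("CompCor recovers planted latent structure in variance order", {
  set.seed(61)
  shape <- c(5, 5, 4); T <- 80
  roi <- volume3d(array(c(rep(1, 90), rep(0, 10)), shape), role = "binary")
  # rank-1: one latent broadcast over the ROI
  lat <- rnorm(T)
  Y <- outer(lat, runif(90, 0.5, 2))
  dat <- matrix(rnorm(prod(shape) * T, 0, 1e-3), T, prod(shape))
  dat[, 1:90] <- dat[, 1:90] + Y
  bold <- volume4d(array(t(dat), c(shape, T)))
  cc <- compcor_components(bold, roi, k = 1)
  expect_gt(abs(cor(cc[, 1], lat)), 0.999)
  expect_equal(sum(cc[, 1]^2), 1, tolerance = 1e-8)   # unit norm
  expect_gt(cc[which.max(abs(cc[, 1])), 1], 0)        # sign convention

  # two orthogonal sinusoids, unequal footprint -> recovered in variance order
  t <- seq_len(T)
  s1 <- sin(2 * pi * 4 * t / T); s2 <- cos(2 * pi * 9 * t / T)
  dat2 <- matrix(rnorm(prod(shape) * T, 0, 1e-2), T, prod(shape))
  dat2[, 1:60] <- dat2[, 1:60] + outer(s1, runif(60, 0.8, 1.2))
  dat2[, 61:90] <- dat2[, 61:90] + outer(s2, runif(30, 0.8, 1.2))
  cc2 <- compcor_components(volume4d(array(t(dat2), c(shape, T))), roi, k = 2)
  expect_gt(abs(cor(cc2[, 1], s1)), 0.95)
  expect_gt(abs(cor(cc2[, 2], s2)), 0.95)

  expect_equal(ncol(compcor_components(bold, roi, k = 0)), 0)
  expect_error(compcor_components(bold, roi, k = 1000), "configuration")
  empty <- volume3d(array(0, shape), role = "binary")
  expect_error(compcor_components(bold, empty, k = 1), "empty noise ROI")
})

test_that("nuisance regression projects out confounds exactly", {
  set.seed(63)
  T <- 60; shape <- c(3, 3, 3)
  conf <- cbind(a = rnorm(T), b = rnorm(T))
  dat <- matrix(rnorm(prod(shape) * T), T, prod(shape))
  dat[, 1] <- conf[, "a"]                       # voxel equal to a confound
  s <- rnorm(T)
  dat[, 2] <- s + 0.8 * conf[, "b"]             # planted mixture
  bold <- volume4d(array(t(dat), c(shape, T)))
  res <- nuisance_regress(bold, conf)
  R <- t(matrix(res$series, prod(shape), T))
  expect_lt(max(abs(R[, 1])), 1e-10)            # residual identically 0
  for (j in 1:2) expect_lt(max(abs(cor(R[, -1], conf[, j]))), 1e-8)
  # mixture voxel: residual correlates with s at the no-confound level
  expect_gt(cor(R[, 2], s), 0.95)
  # rank-deficient design names the collinear column
  expect_error(nuisance_regress(bold, cbind(conf, dup = conf[, "a"])),
               "collinear.*dup")
  expect_error(nuisance_regress(bold, conf[1:10, ]), "confound rows")
})

test_that("bandpass keeps in-band bins, removes DC and out-of-band power", {
  shape <- c(2, 2, 2); T <- 200; tr <- 3
  z <- bandpass_filter(volume4d(array(0, c(shape, T)), tr = tr))
  expect_true(all(z$series == 0))
  t <- seq_len(T) * tr
  pure <- sin(2 * pi * 0.05 * t)
  b <- volume4d(array(t(matrix(pure, T, prod(shape))), c(shape, T)), tr = tr)
  out <- bandpass_filter(b)
  amp <- function(x) sqrt(mean(x^2))
  expect_gte(amp(out$series[1, 1, 1, ]) / amp(pure), 0.95)
  # constant series -> all-zero output (DC removed)
  cst <- volume4d(array(5, c(shape, T)), tr = tr)
  expect_lt(max(abs(bandpass_filter(cst)$series)), 1e-10)
  # 0.005 Hz is below the passband
  slow <- sin(2 * pi * 0.005 * t)
  bs <- volume4d(array(t(matrix(slow, T, prod(shape))), c(shape, T)), tr = tr)
  expect_lt(amp(bandpass_filter(bs)$series[1, 1, 1, ]) / amp(slow), 0.05)
  expect_error(bandpass_filter(b, c(0.01, 0.2)), "Nyquist")
  expect_error(denoise_config(band = c(0.05, 0.01)), "low < high")
})

test_that("regress-then-filter leaves <1% out-of-band power on white noise", {
  set.seed(65)
  shape <- c(3, 3, 3); T <- 120; tr <- 2
  bold <- rand_bold(shape, T, tr)
  conf <- cbind(rnorm(T), rnorm(T))
  res <- bandpass_filter(nuisance_regress(bold, conf), c(0.01, 0.1))
  Y <- t(matrix(res$series, prod(shape), T))
  P <- Mod(mvfft(Y))^2
  freqs <- (seq_len(T) - 1) / (T * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  out_band <- freqs < 0.01 | freqs > 0.1
  expect_lt(sum(P[out_band, ]) / sum(P), 0.01)
})

test_that("full denoising zeroes flagged frames and strips ROI structure", {
  set.seed(67)
  spec <- simulation_spec(grid_shape = c(8, 8, 8),
                          subsystem_sizes = c(MT = 30, Core = 60, FT = 70),
                          n_participants = 4, T_rest = 100, seed = 17)
  at <- make_atlas(spec)
  rest <- make_rest(spec, at, spike_frames = c(25, 60))
  den <- denoise_rest(rest$bold, rest$motion, rest$noise_roi)
  expect_equal(which(!den$keep), c(25L, 60L))
  # spike regression nulls the flagged frames before filtering
  res <- nuisance_regress(rest$bold, den$confounds)
  Y <- t(matrix(res$series, prod(spec$grid_shape), spec$T_rest))
  expect_lt(max(abs(Y[c(25, 60), ])), 1e-8)
  # CompCor at full planted rank removes >99% of the ROI mean-signal variance
  roi_mean_before <- rowMeans(bold_mat_for_test(rest$bold, rest$noise_roi))
  roi_mean_after <- rowMeans(bold_mat_for_test(res, rest$noise_roi))
  expect_gt(1 - var(roi_mean_after) / var(roi_mean_before), 0.9)
})
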