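test_that("nuisance regression removes covariates and matches a direct solve", {
  set.seed(1)
  tt <- 50
  motion <- matrix(rnorm(tt * 6), tt, 6)
  nuis <- nuisance_set(motion = motion, wm_signal = rnorm(tt),
                       csf_signal = rnorm(tt))
  # a voxel equal to a covariate column regresses to (numerical) zero
  series <- cbind(nuis$wm_signal, matrix(rnorm(tt * 19), tt, 19))
  img <- img_from_series(series, c(5, 2, 2))
  res <- regress_nuisance(img, nuis)
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-10)
  # residuals match an independent normal-equations solve on a 20-voxel toy
  design <- cbind(1, friston24(motion), nuis$wm_signal, nuis$csf_signal,
                  seq_len(tt) - (tt + 1) / 2)
  beta <- solve(t(design) %*% design, t(design) %*% series)
  oracle <- series - design %*% beta
  got <- t(matrix(res$data, ncol = tt))
  expect_equal(got, oracle, ignore_attr = TRUE, tolerance = 1e-8)
  # residuals orthogonal to every covariate column
  expect_lt(max(abs(t(design) %*% got)), 1e-6)
})

test_that("global signal regression removes a shared component and is idempotent", {
  set.seed(2)
  tt <- 60
  common <- sin(2 * pi * 0.03 * (1:tt))
  series <- outer(common, runif(12, 0.5, 2)) + matrix(rnorm(tt * 12, sd = 0.1), tt)
  img <- img_from_series(series, c(3, 2, 2))
  nn <- nuisance_set(linear_drift = FALSE)
  res1 <- regress_nuisance(img, nn, include_gsr = TRUE)
  gs <- rowMeans(t(matrix(res1$data, ncol = tt)))
  expect_lt(sd(gs), 0.05 * sd(common))          # mean series ~ constant
  res2 <- regress_nuisance(res1, nn, include_gsr = TRUE)
  expect_equal(res2$data, res1$data, tolerance = 1e-6)
  expect_error(regress_nuisance(img, nuisance_set(wm_signal = rnorm(10))),
               "length mismatch")
})

test_that("ideal band-pass keeps the band and zeroes the rest", {
  tt <- 100; tr <- 2
  t_s <- (0:(tt - 1)) * tr
  in_band <- sin(2 * pi * 0.05 * t_s)
  out_band <- sin(2 * pi * 0.2 * t_s)
  mixed <- 2 * in_band + 3 * out_band
  img <- img_from_series(cbind(in_band, out_band, mixed, mixed), c(2, 2, 1), tr = tr)
  bp <- bandpass(img, 0.01, 0.10)
  expect_equal(bp$data[1, 1, 1, ], in_band, tolerance = 1e-8)
  expect_lt(max(abs(bp$data[2, 1, 1, ])), 1e-8)
  # output spectrum equals the masked input spectrum (FFT oracle)
  f <- pmin(0:(tt - 1), tt - 0:(tt - 1)) / (tt * tr)
  keep <- f >= 0.01 & f <= 0.10
  oracle <- Re(fft(fft(mixed) * keep, inverse = TRUE)) / tt
  expect_equal(bp$data[1, 2, 1, ], oracle, tolerance = 1e-8)
  expect_error(bandpass(img, 0.01, 0.3), "Nyquist")
})

test_that("ALFF is linear in amplitude and zero for constant series", {
  tt <- 120; tr <- 2
  t_s <- (0:(tt - 1)) * tr
  series <- cbind(sin(2 * pi * 0.05 * t_s), 2 * sin(2 * pi * 0.05 * t_s),
                  rep(1, tt), rnorm(tt))
  img <- img_from_series(series, c(2, 2, 1), tr = tr)
  a <- compute_alff(img, 0.01, 0.10)
  expect_equal(a$values[2, 1, 1] / a$values[1, 1, 1], 2, tolerance = 1e-8)
  expect_equal(a$values[1, 2, 1], 0)
  # white noise: positive, and scales with noise SD (Monte-Carlo oracle)
  set.seed(4)
  noise1 <- matrix(rnorm(tt * 64), tt)
  img1 <- img_from_series(noise1, c(4, 4, 4), tr = tr)
  img3 <- img_from_series(3 * noise1, c(4, 4, 4), tr = tr)
  a1 <- mean(compute_alff(img1)$values); a3 <- mean(compute_alff(img3)$values)
  expect_gt(a1, 0)
  expect_equal(a3 / a1, 3, tolerance = 1e-10)
})

test_that("ReHo is Kendall's W over the neighbourhood ranks", {
  # perfect concordance: all neighbours share one series
  tt <- 30
  s <- rnorm(tt)
  series <- matrix(rep(s, 27), tt, 27)
  img <- img_from_series(series, c(3, 3, 3))
  w <- compute_reho(img, 27)
  expect_equal(w$values[2, 2, 2], 1)
  # K = 3 toy against a direct rank-sum computation
  set.seed(7)
  ser3 <- matrix(rnorm(tt * 3), tt, 3)
  img3 <- ts_image(array(t(ser3), c(3, 1, 1, tt)), 2)
  got <- compute_reho(img3, 7)$values[2, 1, 1]   # centre sees all 3 in-mask
  rk <- apply(ser3, 2, rank)
  rs <- rowSums(rk)
  oracle <- 12 * sum((rs - mean(rs))^2) / (9 * (tt^3 - tt))
  expect_equal(got, oracle)
  # independent neighbours at large t: W near null expectation, in [0, 1]
  set.seed(8)
  big <- img_from_series(matrix(rnorm(200 * 27), 200), c(3, 3, 3))
  w0 <- compute_reho(big, 27)$values[2, 2, 2]
  expect_gt(w0, 0); expect_lt(w0, 0.2)
  expect_error(compute_reho(img, 11), "neighborhood")
})

test_that("degree centrality counts suprathreshold correlations one-sidedly", {
  tt <- 40
  s <- rnorm(tt)
  img <- img_from_series(cbind(s, s, s), c(3, 1, 1))
  dc <- compute_dc(img, 0.25)
  expect_equal(as.vector(dc$values), c(2, 2, 2))
  # anti-correlated pair: r = -1 is not > 0.25
  img2 <- img_from_series(cbind(s, -s), c(2, 1, 1))
  expect_equal(as.vector(compute_dc(img2, 0.25)$values), c(0, 0))
  # 10-voxel toy equals a brute-force pairwise count
  set.seed(9)
  ser <- matrix(rnorm(tt * 10), tt, 10)
  img10 <- img_from_series(ser, c(10, 1, 1))
  got <- as.vector(compute_dc(img10, 0.25)$values)
  oracle <- sapply(1:10, function(v)
    sum(sapply(setdiff(1:10, v), function(u) cor(ser[, v], ser[, u]) > 0.25)))
  expect_equal(got, oracle)
  # weighted variant sums the suprathreshold r values
  gotw <- as.vector(compute_dc(img10, 0.25, weighted = TRUE)$values)
  oraclew <- sapply(1:10, function(v) {
    r <- sapply(setdiff(1:10, v), function(u) cor(ser[, v], ser[, u]))
    sum(r[r > 0.25])
  })
  expect_equal(gotw, oraclew)
})

test_that("VMHC is the mirrored-voxel correlation and mirror-symmetric", {
  set.seed(10)
  tt <- 50
  half <- matrix(rnorm(tt * 4), tt, 4)   # 2 x 2 x 1 half grid
  series <- cbind(half, half[, c(2, 1, 4, 3)])  # build by x-mirror
  dims <- c(4, 2, 1)
  arr <- array(0, c(dims, tt))
  # place columns so that x index 1..4 mirrors 4..1
  arr[1, 1, 1, ] <- half[, 1]; arr[2, 1, 1, ] <- half[, 2]
  arr[3, 1, 1, ] <- half[, 2]; arr[4, 1, 1, ] <- half[, 1]
  arr[1, 2, 1, ] <- half[, 3]; arr[2, 2, 1, ] <- half[, 4]
  arr[3, 2, 1, ] <- half[, 4]; arr[4, 2, 1, ] <- half[, 3]
  img <- ts_image(arr, 2)
  v <- compute_vmhc(img)
  expect_true(all(abs(v$values - 1) < 1e-10))
  # sign-flipped mirror gives r = -1
  arr[4, 1, 1, ] <- -half[, 1]; arr[1, 1, 1, ] <- half[, 1]
  v2 <- compute_vmhc(ts_image(arr, 2))
  expect_equal(v2$values[1, 1, 1], -1)
  expect_equal(v2$values[4, 1, 1], -1)
  # random image: map equals the per-pair correlation oracle and is symmetric
  set.seed(11)
  arr3 <- array(rnorm(4 * 2 * 2 * tt), c(4, 2, 2, tt))
  v3 <- compute_vmhc(ts_image(arr3, 2))$values
  for (yy in 1:2) for (zz in 1:2) for (xx in 1:4) {
    expect_equal(v3[xx, yy, zz], cor(arr3[xx, yy, zz, ], arr3[5 - xx, yy, zz, ]))
    expect_equal(v3[xx, yy, zz], v3[5 - xx, yy, zz])
  }
})

test_that("map standardization follows the Fisher-Z / z-map conventions", {
  vals <- array(c(0, 0.5, -0.5, 0.9), c(2, 2, 1))
  m <- metric_map(vals, "VMHC")
  z <- standardize_map(m, "fisher_z")
  expect_equal(z$values[1, 1, 1], 0)
  expect_equal(z$values[2, 1, 1], 0.5493, tolerance = 1e-4)  # atanh(0.5)
  expect_equal(as.vector(z$values), atanh(as.vector(vals)))
  expect_true(z$standardized)
  expect_error(standardize_map(metric_map(vals * 3, "VMHC"), "fisher_z"),
               "correlation-valued")
  # mean/SD z-standardization: in-mask mean 0, SD 1
  set.seed(12)
  m2 <- metric_map(array(rnorm(60, 5, 2), c(5, 4, 3)), "ALFF")
  z2 <- standardize_map(m2, "mean_sd_z")
  expect_equal(mean(z2$values), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(z2$values)), 1, tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves constants, mass, and the identity at fwhm 0", {
  set.seed(13)
  m <- metric_map(array(rnorm(8 * 8 * 4), c(8, 8, 4)), "ALFF")
  expect_identical(smooth_gaussian(m, 0), m)
  mc <- metric_map(array(3.7, c(8, 8, 4)), "ALFF")
  expect_equal(smooth_gaussian(mc, 6)$values, mc$values, tolerance = 1e-12)
  # delta at the centre: kernel mass sums to 1
  d <- array(0, c(9, 9, 9)); d[5, 5, 5] <- 1
  sm <- smooth_gaussian(metric_map(d, "ALFF"), 4, voxel_size_mm = c(3, 3, 3))
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  expect_error(smooth_gaussian(m, -1), "nonnegative")
})
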