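make_movie_from_frames <- function(frames, fs = 1000) {
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  voltage_movie(arr, fs, 0.17)
}

test_that("Gaussian binning matches a direct convolution oracle", {
  # constant frame passes through unchanged (kernel sums to 1)
  const <- make_movie_from_frames(replicate(3, matrix(2.5, 9, 9),
                                            simplify = FALSE))
  for (ks in c(3L, 5L)) {
    out <- spatial_bin(const, ks)
    expect_equal(out$data, const$data, tolerance = 1e-12)
  }
  # unit impulse and a random frame against the brute-force oracle
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  set.seed(3)
  rnd <- matrix(runif(81), 9, 9)
  mv <- make_movie_from_frames(list(imp, rnd, imp))
  for (ks in c(3L, 5L)) {
    k <- opmapr:::gaussian_kernel(ks)
    out <- spatial_bin(mv, ks)
    expect_equal(out$data[, , 1], conv2_oracle(imp, k), tolerance = 1e-12)
    expect_equal(out$data[, , 2], conv2_oracle(rnd, k), tolerance = 1e-12)
  }
  expect_error(spatial_bin(mv, 4L), "kernel_size")
})

test_that("kernel sizes 3 and 5 differ but both conserve interior mass", {
  set.seed(9)
  frame <- matrix(0, 12, 12)
  frame[3:10, 3:10] <- runif(64)  # zero border: no replication influence
  mv <- make_movie_from_frames(replicate(3, frame, simplify = FALSE))
  o3 <- spatial_bin(mv, 3L)$data[, , 1]
  o5 <- spatial_bin(mv, 5L)$data[, , 1]
  expect_gt(max(abs(o3 - o5)), 1e-6)
  expect_equal(mean(o3), mean(frame), tolerance = 1e-12)
  expect_equal(mean(o5), mean(frame), tolerance = 1e-12)
})

test_that("binning and temporal filtering are linear operators", {
  set.seed(4)
  d <- c(8, 8, 64)
  X <- voltage_movie(array(rnorm(prod(d)), d), 1000, 0.17)
  Y <- voltage_movie(array(rnorm(prod(d)), d), 1000, 0.17)
  comb <- voltage_movie(2 * X$data - 3 * Y$data, 1000, 0.17)
  for (op in list(function(m) spatial_bin(m, 3L),
                  function(m) temporal_filter(m, 0, 100))) {
    lhs <- op(comb)$data
    rhs <- 2 * op(X)$data - 3 * op(Y)$data
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("the 0-100 Hz filter passes the band and rejects above it", {
  fs <- 3000
  t_s <- (0:(2 * fs - 1)) / fs
  mk_sine <- function(f) {
    tr <- sin(2 * pi * f * t_s)
    voltage_movie(array(rep(tr, each = 4), c(2, 2, length(tr))), fs, 0.17)
  }
  mid <- seq(fs %/% 2, 3 * fs %/% 2)  # steady-state portion
  # 50 Hz: deep passband, amplitude preserved within 5%
  out50 <- temporal_filter(mk_sine(50))$data[1, 1, ]
  expect_gt(max(abs(out50[mid])), 0.95)
  # 600 Hz: attenuation agrees with the transfer function evaluated
  # analytically on the unit circle (zero-phase application squares the
  # magnitude response)
  filt <- signal::butter(4, 100 / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * 600 / fs * (seq_along(filt$b) - 1))
  H600 <- Mod(sum(filt$b * z) / sum(filt$a * z))
  out600 <- temporal_filter(mk_sine(600))$data[1, 1, ]
  meas <- max(abs(out600[mid]))
  expect_lt(meas, 1e-3)
  expect_lt(abs(meas - H600^2) / H600^2, 0.5)
  # DC (constant trace) is in the passband: unchanged
  const <- voltage_movie(array(0.7, c(2, 2, 300)), fs, 0.17)
  expect_equal(temporal_filter(const)$data, const$data, tolerance = 1e-6)
  expect_error(temporal_filter(mk_sine(50), 0, 2000), "Nyquist")
})

test_that("drift correction recovers the clean AP shape and is idempotent", {
  t_ms <- 0:199
  clean <- opmapr:::ap_trace(t_ms, 40, 2, 50)
  arr <- array(rep(clean, each = 36), c(6, 6, 200)) +
    rep(1.5 * t_ms / 1000, each = 36)        # 1.5 amplitude-units/s ramp
  corrected <- drift_correct_normalize(voltage_movie(arr, 1000, 0.17))
  expect_gt(cor(corrected$data[3, 3, ], clean), 0.99)
  # output confined to [0, 1]
  expect_true(all(corrected$data >= 0 & corrected$data <= 1))
  # idempotence: a second application changes nothing
  twice <- drift_correct_normalize(corrected)
  expect_equal(twice$data, corrected$data, tolerance = 1e-12)
  # constant traces map to zeros, not NaN
  const <- drift_correct_normalize(voltage_movie(array(5, c(6, 6, 50)),
                                                 1000, 0.17))
  expect_true(all(const$data == 0))
})

test_that("SNR mask keeps active tissue and rejects noise-only pixels", {
  spec <- quick_scene(n = 30, noise_sd = 0.05, drift_per_s = 0.1,
                      inactive_margin_px = 5, seed = 7)
  sim <- make_movie(spec)
  tissue <- sim$truth$tissue
  pp <- preprocess_movie(sim$movie)
  expect_true(all(pp$mask[tissue]))
  # margin pixels not touched by binning bleed (>= 2 px from tissue) are out
  deep_margin <- matrix(TRUE, 30, 30)
  deep_margin[4:27, 4:27] <- FALSE
  expect_false(any(pp$mask[deep_margin]))
  # noise-free movie: every active pixel retained even at low threshold
  clean <- make_movie(quick_scene(n = 20))
  expect_true(all(snr_mask(clean$movie, snr_threshold = 2)))
  # absurd threshold: everything fails, loudly
  expect_error(snr_mask(clean$movie, snr_threshold = 1e9), "empty mask")
  expect_error(snr_mask(clean$movie, snr_threshold = -1), "positive")
})

test_that("the full preprocess chain shifts no upstroke by more than one frame", {
  sim <- make_movie(quick_scene(n = 20))
  pp <- preprocess_movie(sim$movie)
  argmax_dv <- function(arr, i, j) which.max(diff(arr[i, j, ]))
  for (px in list(c(5, 5), c(10, 15), c(18, 3))) {
    raw_idx <- argmax_dv(sim$movie$data, px[1], px[2])
    out_idx <- argmax_dv(pp$movie$data, px[1], px[2])
    expect_lte(abs(raw_idx - out_idx), 1)
  }
})
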