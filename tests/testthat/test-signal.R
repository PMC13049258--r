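# Forward signal model and Rician noise.

test_that("scalar model reproduces closed-form values", {
  expect_equal(predict_signal_scalar(1, 2, 1, 0.7, TR = Inf, b = 0), 1)
  expect_equal(predict_signal_scalar(1, 1, 0, 1, TR = 1, b = 1),
               (1 - exp(-1)) * exp(-1))
  expect_equal(predict_signal_scalar(2, 1, 1, 1, TR = Inf, b = 1),
               2 * exp(-0.5))
  # undefined TR (first coverage) behaves as fully relaxed
  expect_equal(predict_signal_scalar(3, 1, 0, 1, TR = NA, b = 0), 3)
})

test_that("thick-slice model reduces to the scalar model for one-hot rows", {
  cfg <- scheme_config(n = 10, k = 1, m = 30, seed = 2)
  sch <- direct_scheme(cfg)
  ph <- line_phantom(line_phantom_config(n = 10, seed = 4))
  s <- predict_signal(ph, sch)
  mats <- scheme_matrices(sch)
  for (j in c(1, 15, 30)) {
    i <- which(mats$W[j, ] > 0)
    expect_equal(s$signal[j],
                 predict_signal_scalar(ph$S0[i], ph$D[i], ph$V[i], ph$T1[i],
                                       TR = mats$TR[j, i], b = mats$b[j]))
  }
})

test_that("homogeneous fully-relaxed slices sum k identical scalar terms", {
  n <- 12L; k <- 3L
  ph <- homogeneous_column(n)
  sch <- slice_shift_scheme(scheme_config(n = n, k = k, m = 8, n_shifts = 2,
                                          discard_per_fov = 0))
  s <- predict_signal(ph, sch)
  # the first tiling pass has no revisits: every coverage is a first
  # coverage (fully relaxed), so each shot sums k identical scalar terms
  first_pass <- 1:(n %/% k)
  scalar <- predict_signal_scalar(2, 1, 0.5, 1.2, TR = Inf, b = sch$b[first_pass])
  expect_equal(s$signal[first_pass], k * scalar)
})

test_that("thick-slice model equals the per-sub-voxel loop oracle", {
  for (seed in 1:3) {
    cfg <- tiny_scheme_config(n = 15, k = 4, m = 20, seed = seed)
    sch <- sero_scheme(cfg)
    ph <- line_phantom(line_phantom_config(n = 15, seed = seed + 10))
    expect_equal(predict_signal(ph, sch)$signal,
                 loop_forward_oracle(ph, sch), tolerance = 1e-12)
  }
})

test_that("signal is monotone in TR and b as the model prescribes", {
  trs <- seq(0.1, 8, length.out = 40)
  s_tr <- predict_signal_scalar(1, 1, 0, 1.5, TR = trs, b = 0.5)
  expect_true(all(diff(s_tr) > 0))
  bs <- seq(0, 1.4, length.out = 30)
  expect_true(all(diff(predict_signal_scalar(1, 1, 0, 1, TR = Inf, b = bs)) < 0))
  # with variance, decay holds while b < D/V
  D <- 1; V <- 1.25
  bs2 <- seq(0, D / V - 1e-6, length.out = 20)
  expect_true(all(diff(predict_signal_scalar(1, D, V, 1, TR = Inf, b = bs2)) < 0))
})

test_that("noiseless signals scale linearly in S0", {
  cfg <- tiny_scheme_config(n = 15, k = 3, m = 40, seed = 5)
  sch <- sero_scheme(cfg)
  ph <- line_phantom(line_phantom_config(n = 15, seed = 6))
  ph2 <- ph; ph2$S0 <- 3 * ph$S0
  expect_equal(predict_signal(ph2, sch)$signal,
               3 * predict_signal(ph, sch)$signal)
})

test_that("noise level follows sigma = mean S0 / SNR over the support", {
  expect_equal(sigma_from_snr(homogeneous_column(5, S0 = 1), snr = 10), 0.1)
  ph <- param_column(S0 = c(1, 3), D = c(1, 1), V = c(0, 0), T1 = c(1, 1))
  expect_equal(sigma_from_snr(ph, snr = 2), 1.0)
  zero <- param_column(S0 = c(0, 0), D = c(1, 1), V = c(0, 0), T1 = c(1, 1))
  expect_error(sigma_from_snr(zero, snr = 5), "degenerate")
})

test_that("thick slices carry a roughly k-fold signal advantage at matched sigma", {
  n <- 24L; k <- 4L
  ph <- homogeneous_column(n, T1 = 0.3)  # short T1: near-full recovery
  sero <- sero_scheme(scheme_config(n = n, k = k, m = 400, shot_spacing = 0.5,
                                    min_mean_tr = 0, seed = 8))
  direct <- direct_scheme(scheme_config(n = n, k = 1, m = 384,
                                        shot_spacing = 0.5, seed = 8))
  ratio <- mean(predict_signal(ph, sero)$signal) /
    mean(predict_signal(ph, direct)$signal)
  expect_gt(ratio, 0.75 * k)
  expect_lt(ratio, 1.05 * k)
})

test_that("Rician noise has the Rayleigh mean at S = 0 and Gaussian limit at high S", {
  n <- 2e5
  zero <- add_rician_noise(rep(0, n), sigma = 1, seed = 1)
  mc_err <- 3 * sqrt((2 - pi / 2)) / sqrt(n)
  expect_equal(mean(zero$signal), sqrt(pi / 2), tolerance = 3 * mc_err)
  high <- add_rician_noise(rep(100, n), sigma = 1, seed = 2)
  expect_equal(mean(high$signal), 100, tolerance = 0.01)
  expect_equal(sd(high$signal), 1, tolerance = 0.02)
  expect_true(all(zero$signal >= 0))
})

test_that("Rician magnitudes are positively biased, most at low signal", {
  s <- rep(0.5, 2e4)
  noisy <- add_rician_noise(s, sigma = 1, seed = 3)
  expect_gt(mean(noisy$signal), 0.5)  # noise floor lifts the mean
})

test_that("zero noise is the identity and seeds reproduce draws exactly", {
  s <- c(0.3, 1.2, 4)
  expect_equal(add_rician_noise(s, 0)$signal, s)
  a <- add_rician_noise(s, 0.5, seed = 7)
  b <- add_rician_noise(s, 0.5, seed = 7)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, add_rician_noise(s, 0.5, seed = 8)$signal))
})
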