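# Super-resolution solver: normalization, initialization, Jacobian
# correctness, noiseless recovery, regularization limits, and conditioning.

test_that("normalization divides by the global maximum and round-trips S0", {
  norm <- normalize_signals(c(1, 2, 4))
  expect_equal(norm$constant, 4)
  expect_equal(norm$signals$signal, c(0.25, 0.5, 1))
  already <- normalize_signals(c(0.2, 1))
  expect_equal(already$constant, 1)
  expect_equal(already$signals$signal, c(0.2, 1))
  expect_error(normalize_signals(c(0, 0)), "positive")
  # dual-run round trip: fitting scaled signals recovers the same S0 in a.u.
  cfg <- tiny_scheme_config(n = 10, k = 2, m = 120, seed = 3)
  sch <- sero_scheme(cfg)
  ph <- line_phantom(line_phantom_config(n = 10, seed = 1))
  s <- predict_signal(ph, sch)
  f1 <- fit_column(s, sch, fit_config(lambda = 0))
  f2 <- fit_column(new_signals <- 0.25 * s$signal, sch, fit_config(lambda = 0))
  expect_equal(f1$estimates$S0, f2$estimates$S0 / 0.25, tolerance = 1e-6)
})

test_that("penalty residuals encode sqrt(lambda) times first differences", {
  const <- homogeneous_column(6)
  expect_equal(regularization_residuals(const, lambda = 0.01),
               rep(0, 4 * 5))
  step <- homogeneous_column(6)
  step$D[4:6] <- step$D[4:6] + 1
  r <- regularization_residuals(step, lambda = 0.01)
  expect_equal(sum(r^2), 0.01)  # one unit step contributes lambda * 1^2
})

test_that("analytic Jacobian matches finite differences at random interior points", {
  cfg <- tiny_scheme_config(n = 8, k = 2, m = 40, seed = 6)
  sch <- sero_scheme(cfg)
  mats <- scheme_matrices(sch)
  am <- mats; am$keep <- rep(TRUE, 40)
  y <- rep(0, 40)
  set.seed(4)
  for (trial in 1:3) {
    theta <- c(runif(8, 0.5, 3), runif(8, 0.5, 2.5),
               runif(8, 0.2, 1.2), runif(8, 0.6, 3))
    J <- serosrr:::fit_jacobian(theta, 8L, am, y, lambda = 0.01,
                                weights = c(S0 = 1, D = 1, V = 1, T1 = 1),
                                t1_frozen = FALSE, t1_value = 1)
    f0 <- serosrr:::fit_residuals(theta, 8L, am, y, 0.01,
                                  c(S0 = 1, D = 1, V = 1, T1 = 1), FALSE, 1)
    h <- 1e-6
    for (idx in sample(length(theta), 8)) {
      tp <- theta; tp[idx] <- tp[idx] + h
      fd <- (serosrr:::fit_residuals(tp, 8L, am, y, 0.01,
                                     c(S0 = 1, D = 1, V = 1, T1 = 1),
                                     FALSE, 1) - f0) / h
      expect_equal(J[, idx], fd, tolerance = 1e-5)
    }
  }
})

test_that("local fit recovers a homogeneous noiseless column and is k-invariant", {
  # constructed instance where the slice-averaged-TR approximation is
  # accurate: shot spacing >> T1, so every sub-voxel is near fully relaxed
  n <- 24L
  ph <- homogeneous_column(n, T1 = 0.4)
  sch4 <- sero_scheme(scheme_config(n = n, k = 4, m = 500, seed = 2,
                                    shot_spacing = 1.5, min_mean_tr = 1.5))
  init4 <- local_fit_init(predict_signal(ph, sch4), sch4)
  inner <- 3:(n - 2)
  expect_equal(init4$S0[inner], ph$S0[inner], tolerance = 0.05)
  expect_equal(init4$D[inner], ph$D[inner], tolerance = 0.05)
  # doubling the slice thickness leaves the initialization S0 unchanged
  sch8 <- sero_scheme(scheme_config(n = n, k = 8, m = 500, seed = 2,
                                    shot_spacing = 1.5, min_mean_tr = 1.5))
  init8 <- local_fit_init(predict_signal(ph, sch8), sch8)
  expect_equal(mean(init8$S0[inner]), mean(init4$S0[inner]), tolerance = 0.1)
})

test_that("under-determined positions fall back to bound midpoints and are flagged", {
  cfg <- tiny_scheme_config(n = 10, k = 2, m = 40, b_levels = 0.5, seed = 1)
  sch <- sero_scheme(cfg)
  ph <- homogeneous_column(10)
  init <- local_fit_init(predict_signal(ph, sch), sch)
  expect_true(all(attr(init, "fallback")))
  b <- default_fit_bounds()
  expect_equal(unique(init$D), mean(b$D))
})

test_that("noiseless direct fits recover the saturation product and D, V", {
  n <- 20L
  truth <- line_phantom(line_phantom_config(n = n, seed = 8))
  truth$T1 <- rep(1, n)   # matches the frozen nominal value
  sch <- direct_scheme(scheme_config(n = n, k = 1, m = 400, seed = 1))
  s <- predict_signal(truth, sch)
  fit <- fit_column(s, sch, fit_config(lambda = 0))
  expect_true(fit$t1_frozen)
  expect_equal(fit$estimates$D, truth$D, tolerance = 1e-3)
  expect_equal(fit$estimates$V, truth$V, tolerance = 1e-3)
  expect_equal(fit$estimates$S0, truth$S0, tolerance = 1e-3)
})

test_that("noiseless random-overlap fits recover all four parameters within 1%", {
  sch <- sero_scheme(scheme_config(seed = 1))
  truth <- line_phantom(line_phantom_config(seed = 2))
  fit <- fit_column(predict_signal(truth, sch), sch, fit_config(lambda = 0))
  for (p in c("S0", "D", "V", "T1")) {
    expect_equal(fit$estimates[[p]], truth[[p]], tolerance = 0.01)
  }
  expect_true(fit$converged)
})

test_that("a huge penalty drives the estimates to spatial constancy", {
  cfg <- tiny_scheme_config(n = 16, k = 2, m = 200, seed = 4)
  sch <- sero_scheme(cfg)
  truth <- line_phantom(line_phantom_config(n = 16, seed = 3))
  fit <- fit_column(predict_signal(truth, sch), sch,
                    fit_config(lambda = 1e6))
  for (p in c("S0", "D", "V", "T1")) {
    expect_lt(max(abs(diff(fit$estimates[[p]]))), 1e-3)
  }
})

test_that("the fit never worsens the objective and honors the bounds", {
  cfg <- tiny_scheme_config(n = 16, k = 2, m = 200, seed = 14)
  sch <- sero_scheme(cfg)
  truth <- line_phantom(line_phantom_config(n = 16, seed = 5))
  noisy <- add_rician_noise(predict_signal(truth, sch),
                            sigma_from_snr(truth, 5), seed = 6)
  init <- local_fit_init(noisy, sch)
  fcfg <- fit_config(lambda = 0.01)
  fit <- fit_column(noisy, sch, fcfg, init = init)
  # objective at the (clamped, normalized) starting point
  const <- fit$norm_constant
  init_norm <- init; init_norm$S0 <- init$S0 / const
  pred0 <- predict_signal(init_norm, sch)$signal[sch$analysis_mask]
  y <- noisy$signal[sch$analysis_mask] / const
  obj0 <- sum((pred0 - y)^2) +
    sum(regularization_residuals(init_norm, 0.01)^2)
  expect_lte(fit$objective, obj0 + 1e-10)
  b <- default_fit_bounds()
  for (p in c("S0", "D", "V", "T1")) {
    lo <- if (p == "S0") b$S0[1] * const else b[[p]][1]
    hi <- if (p == "S0") b$S0[2] * const else b[[p]][2]
    expect_true(all(fit$estimates[[p]] >= lo - 1e-9 &
                      fit$estimates[[p]] <= hi + 1e-9))
  }
})

test_that("random overlap conditions the inverse problem better than slice shifting", {
  n <- 50L
  ph <- homogeneous_column(n)
  sero <- sero_scheme(scheme_config(n = n, k = 4, m = 1000, seed = 1))
  shift <- slice_shift_scheme(scheme_config(n = n, k = 4, m = 1000))
  c_sero <- scheme_conditioning(ph, sero)$condition
  c_shift <- scheme_conditioning(ph, shift)$condition
  expect_lt(c_sero, c_shift)
})

test_that("volume fitting is column-independent and reproducible", {
  n <- 10L
  cfg <- tiny_scheme_config(n = n, k = 2, m = 120, seed = 2)
  sch <- sero_scheme(cfg)
  ph <- line_phantom(line_phantom_config(n = n, seed = 7))
  s <- predict_signal(ph, sch)$signal
  stack <- array(0, c(2, 2, 120))
  for (ix in 1:2) for (iy in 1:2) stack[ix, iy, ] <- s
  res <- fit_volume(stack, sch, fit_config(lambda = 0))
  expect_equal(res$maps$D[1, 1, ], res$maps$D[2, 2, ])
  expect_equal(res$maps$T1[1, 2, ], res$maps$T1[2, 1, ])
  expect_true(all(res$qc$converged))
  # permuting which column is computed first cannot matter: refit one column
  single <- fit_column(s, sch, fit_config(lambda = 0),
                       norm_const = res$norm_constant)
  expect_equal(single$estimates$D, res$maps$D[1, 1, ])
})
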