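# Sampling-scheme construction: support bounds, coverage accounting,
# TR histories, rejection soundness, and reference-scheme structure.

test_that("SERO start indices stay on the uniform support and W rows sum to k", {
  sch <- sero_scheme(scheme_config(n = 50, k = 4, m = 300, seed = 3))
  expect_true(all(sch$start_index >= 0 & sch$start_index <= 46))
  W <- scheme_matrices(sch)$W
  expect_true(all(rowSums(W) == 4))
  expect_true(all(apply(W, 1, function(r) {
    on <- which(r > 0)
    length(on) == 4 && all(diff(on) == 1)   # contiguous rectangular profile
  })))
})

test_that("coverage is conserved: per-position counts sum to shots x k", {
  for (seed in 1:3) {
    cfg <- tiny_scheme_config(n = 20, k = 3, m = 150, seed = seed)
    st <- scheme_statistics(sero_scheme(cfg))
    expect_equal(sum(st$coverage$count), 150 * 3)
    expect_equal(st$mean_coverage, 150 * 3 / 20)
  }
})

test_that("accepted SERO shots respect the slice-averaged TR rejection rule", {
  cfg <- scheme_config(n = 50, k = 4, m = 400, seed = 11, min_mean_tr = 1.5)
  sch <- sero_scheme(cfg)
  mats <- scheme_matrices(sch)
  surrogate <- 100
  for (j in seq_len(nrow(sch))) {
    row_tr <- mats$TR[j, ]
    covered <- mats$W[j, ] > 0
    gap <- ifelse(is.na(row_tr[covered]),
                  sch$time_s[j] + surrogate, row_tr[covered])
    expect_gte(mean(gap), 1.5)
  }
})

test_that("infeasible rejection thresholds raise an error", {
  cfg <- scheme_config(n = 6, k = 4, m = 50, shot_spacing = 0.1,
                       min_mean_tr = 1e6, seed = 1)
  expect_error(sero_scheme(cfg, max_attempts = 50), "infeasible")
})

test_that("TR matrix matches the brute-force last-excitation scan", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 8L; k <- 2L; m <- 10L
    start <- sample(0:(n - k), m, replace = TRUE)
    times <- cumsum(runif(m, 0.05, 0.3))
    got <- compute_tr_matrix(start, times, k, n)
    want <- brute_force_tr(start, times, k, n)
    expect_equal(got$TR, want$TR)
    expect_equal(got$first_coverage, want$first_coverage)
  }
})

test_that("defined TRs are at least one shot spacing and shots are evenly spaced", {
  cfg <- tiny_scheme_config(n = 30, k = 3, m = 200, seed = 7)
  sch <- sero_scheme(cfg)
  expect_equal(diff(sch$time_s), rep(cfg$shot_spacing, 199))
  tr <- scheme_matrices(sch)$TR
  expect_true(all(tr[!is.na(tr)] >= cfg$shot_spacing - 1e-12))
})

test_that("schemes are reproducible for a fixed seed", {
  cfg <- tiny_scheme_config(n = 40, k = 4, m = 250, seed = 42)
  expect_identical(sero_scheme(cfg), sero_scheme(cfg))
  cfg2 <- tiny_scheme_config(n = 40, k = 4, m = 250, seed = 43)
  expect_false(identical(sero_scheme(cfg)$start_index,
                         sero_scheme(cfg2)$start_index))
})

test_that("direct sampling visits every position cyclically at fixed TR", {
  cfg <- scheme_config(n = 50, k = 1, m = 1000, seed = 1)
  sch <- direct_scheme(cfg)
  st <- scheme_statistics(sch)
  expect_true(all(st$coverage$count == 20))
  expect_equal(unname(st$tr_quantiles), rep(7.5, 5))
  W <- scheme_matrices(sch)$W
  expect_true(all(rowSums(W) == 1))
  # a single cycle has no revisits: every coverage is a first coverage
  one <- direct_scheme(scheme_config(n = 10, k = 1, m = 10))
  expect_error(scheme_statistics(one), "degenerate")
  expect_true(all(scheme_matrices(one)$first_coverage[scheme_matrices(one)$W > 0]))
})

test_that("slice shifting uses sub-voxel FOV offsets and discards settling shots", {
  cfg <- scheme_config(n = 50, k = 4, m = 1000, n_shifts = 4,
                       discard_per_fov = 2, voxel_size = 1.5)
  sch <- slice_shift_scheme(cfg)
  expect_equal(sum(sch$analysis_mask), 992)
  block <- 250L
  first_starts <- sch$start_index[1 + block * (0:3)]
  expect_equal(first_starts * 1.5, c(0, 1.5, 3.0, 4.5))  # mm offsets
  # within-block revisit interval: floor(n/k) slices x spacing = 1.8 s
  tr <- scheme_matrices(sch)$TR
  inner <- tr[3:250, ]    # steady-state part of the first block
  expect_true(all(abs(inner[!is.na(inner)] - 12 * 0.15) < 1e-9))
  expect_error(slice_shift_scheme(scheme_config(m = 1001, n_shifts = 4)),
               "divisible")
})

test_that("slice-shift TR history matches an independent replay on a small case", {
  cfg <- scheme_config(n = 8, k = 2, m = 24, n_shifts = 2,
                       discard_per_fov = 1, shot_spacing = 0.2)
  sch <- slice_shift_scheme(cfg)
  got <- scheme_matrices(sch)
  want <- brute_force_tr(sch$start_index, sch$time_s, 2L, 8L)
  expect_equal(got$TR, want$TR)
  expect_equal(got$first_coverage, want$first_coverage)
})

test_that("scheme CSV + sidecar round-trips losslessly", {
  dir <- withr::local_tempdir()
  sch <- sero_scheme(tiny_scheme_config(n = 20, k = 2, m = 80, seed = 9))
  p1 <- file.path(dir, "scheme.csv")
  p2 <- file.path(dir, "scheme2.csv")
  write_scheme(sch, p1)
  back <- read_scheme(p1)
  write_scheme(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$start_index, sch$start_index)
  expect_equal(attr(back, "config")$b_levels, attr(sch, "config")$b_levels)
})
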