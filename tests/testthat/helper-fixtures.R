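# Shared fixtures: small schemes and phantoms built in code, plus a cached
# reduced-scale simulation study reused by the acceptance tests.

tiny_scheme_config <- function(n = 12L, k = 2L, m = 60L, seed = 1L, ...) {
  # small grids cannot satisfy the protocol rejection threshold; disable it
  scheme_config(n = n, k = k, m = m, seed = seed, min_mean_tr = 0, ...)
}

homogeneous_column <- function(n, S0 = 2, D = 1, V = 0.5, T1 = 1.2) {
  param_column(S0 = rep(S0, n), D = rep(D, n), V = rep(V, n), T1 = rep(T1, n))
}

# Independent brute-force last-excitation scan: for every shot and covered
# position, search all earlier shots for the most recent coverage.
brute_force_tr <- function(start_index, shot_time, k, n) {
  m <- length(start_index)
  TR <- matrix(NA_real_, m, n)
  first_cov <- matrix(FALSE, m, n)
  cover <- function(s) {
    idx <- s + seq_len(k) - 1L
    idx[idx >= 0L & idx < n] + 1L
  }
  for (j in seq_len(m)) {
    for (i in cover(start_index[j])) {
      prev <- Filter(function(jj) i %in% cover(start_index[jj]),
                     seq_len(j - 1L))
      if (length(prev) == 0L) {
        first_cov[j, i] <- TRUE
      } else {
        TR[j, i] <- shot_time[j] - shot_time[max(prev)]
      }
    }
  }
  list(TR = TR, first_coverage = first_cov)
}

# Explicit per-sub-voxel loop oracle for the thick-slice forward model.
loop_forward_oracle <- function(params, scheme) {
  mats <- scheme_matrices(scheme)
  m <- nrow(mats$W)
  n <- ncol(mats$W)
  out <- numeric(m)
  for (j in seq_len(m)) {
    acc <- 0
    for (i in seq_len(n)) {
      if (mats$W[j, i] == 0) next
      tr <- mats$TR[j, i]
      sat <- if (is.na(tr)) 1 else 1 - exp(-tr / params$T1[i])
      acc <- acc + mats$W[j, i] * params$S0[i] * sat *
        exp(-mats$b[j] * params$D[i] + mats$b[j]^2 * params$V[i] / 2)
    }
    out[j] <- acc
  }
  out
}

# Reduced-scale line-phantom study shared by the end-to-end study checks.
# Computed once per test run and cached; uses the protocol configuration
# (n = 50, m = 1000, 150 ms spacing) with 10 phantoms x 5 noise realizations.
study_cache <- new.env(parent = emptyenv())

reduced_study <- function() {
  if (!is.null(study_cache$metrics)) return(study_cache$metrics)
  cells <- dplyr::bind_rows(
    tidyr::expand_grid(method = "sero", snr = c(3, 5, 10), lambda = c(0, 0.01)),
    tibble::tibble(method = "sero", snr = 15, lambda = 0.01),
    tidyr::expand_grid(method = "direct", snr = c(3, 5, 10), lambda = 0.01),
    tibble::tibble(method = "direct", snr = 5, lambda = 0),
    tibble::tibble(method = "shift", snr = 5, lambda = 0),
    tibble::tibble(method = "shift", snr = 3, lambda = 0.01)
  )
  study_cache$metrics <- run_snr_sweep(cells = cells, n_phantoms = 10L,
                                       n_reps = 5L, seed = 20260925L)
  study_cache$metrics
}

metric_cell <- function(mt, method_, lambda_, snr_, parameter_,
                        what = "rmse") {
  row <- dplyr::filter(mt, .data$method == method_, .data$lambda == lambda_,
                       .data$snr == snr_, .data$parameter == parameter_)
  stopifnot(nrow(row) == 1L)
  row[[what]]
}
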