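# Scheme construction: random-overlap (SERO), slice-shifting, and direct
# high-resolution sampling. A scheme is a per-shot tibble; the dense weight
# and TR matrices are re-derived from it on demand (scheme_matrices()).

new_scheme <- function(shots, config, method) {
  tibble::new_tibble(shots, config = config, method = method,
                     class = "sero_scheme")
}

#' @export
print.sero_scheme <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<sero_scheme> method:", attr(x, "method"),
      " n =", cfg$n, " k =", cfg$k, " m =", nrow(x), "\n")
  NextMethod()
}

scheme_config_of <- function(scheme) {
  cfg <- attr(scheme, "config")
  stop_if_not(!is.null(cfg), "not a scheme: missing config attribute")
  cfg
}

covered_positions <- function(start, k, n) {
  idx <- start + seq_len(k) - 1L
  idx[idx >= 0L & idx < n]
}

#' Generate a random-overlap (SERO) sampling scheme
#'
#' Draws, for each shot, a slice start position uniformly on `{0, ..., n-k}`
#' and a b-value uniformly from `b_levels`. A proposed position is rejected
#' and redrawn whenever the slice-averaged TR (mean over the k covered
#' sub-voxels of the time since their last excitation) falls below
#' `min_mean_tr`; sub-voxels never excited before contribute the elapsed scan
#' time plus a large fixed offset (100 s) so that early shots are acceptable.
#' Overlapping histories make the per-sub-voxel TR heterogeneous both within
#' and between slices, which is what carries the T1 encoding.
#'
#' @param config A [scheme_config()]. `n - k >= 1` is required so that more
#'   than one position exists.
#' @param max_attempts Redraw cap per shot before the configuration is
#'   declared infeasible.
#' @return A `sero_scheme` tibble with columns `shot`, `time_s`,
#'   `start_index`, `k`, `b`, `analysis_mask`.
#' @examples
#' sch <- sero_scheme(scheme_config(n = 20, k = 2, m = 50, seed = 7))
#' scheme_statistics(sch)
#' @seealso [scheme_matrices()], [scheme_statistics()]
#' @export
sero_scheme <- function(config, max_attempts = 10000L) {
  stop_if_not(inherits(config, "scheme_config"), "`config` must be a scheme_config")
  stop_if_not(config$n - config$k >= 1L,
              "SERO needs n - k >= 1 (more than one slice position)")
  n <- config$n; k <- config$k; m <- config$m
  spacing <- config$shot_spacing
  surrogate_offset <- 100  # never-excited sub-voxels look fully relaxed
  start <- integer(m); b <- numeric(m)
  time_s <- (seq_len(m) - 1L) * spacing
  with_seed(config$seed, {
    last <- rep(NA_real_, n)
    for (j in seq_len(m)) {
      t_j <- time_s[j]
      accepted <- FALSE
      for (attempt in seq_len(max_attempts)) {
        prop <- sample.int(n - k + 1L, 1L) - 1L
        idx <- prop + seq_len(k)
        gap <- t_j - last[idx]
        gap[is.na(gap)] <- t_j + surrogate_offset
        if (mean(gap) >= config$min_mean_tr) {
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        abort(paste0("SERO rejection loop exceeded ", max_attempts,
                     " attempts at shot ", j,
                     ": min_mean_tr infeasible for this FOV/k/spacing"))
      }
      start[j] <- prop
      b[j] <- config$b_levels[sample.int(length(config$b_levels), 1L)]
      last[idx] <- t_j
    }
  })
  new_scheme(
    tibble::tibble(shot = seq_len(m), time_s = time_s, start_index = start,
                   k = k, b = b, analysis_mask = TRUE),
    config, "sero"
  )
}

#' Generate a slice-shifting reference scheme
#'
#' Shots are split into `n_shifts` contiguous blocks. Within each block the
#' FOV is shifted by 0, 1, ..., `n_shifts - 1` sub-voxels and tiled by
#' `floor(n / k)` contiguous thick slices visited cyclically, so every
#' position is revisited at a fixed interval of `floor(n / k) * shot_spacing`
#' seconds. Slices whose top extends past the FOV are clipped. b-values cycle
#' over `b_levels` volume-by-volume (one volume = one pass over the tiling).
#' The first `discard_per_fov` shots of each block are excluded from analysis
#' to emulate steady-state settling.
#'
#' @inheritParams sero_scheme
#' @return A `sero_scheme` tibble (method `"shift"`).
#' @export
slice_shift_scheme <- function(config) {
  stop_if_not(inherits(config, "scheme_config"), "`config` must be a scheme_config")
  stop_if_not(config$n_shifts >= 2L, "slice shifting needs n_shifts >= 2")
  n <- config$n; k <- config$k; m <- config$m; ns <- config$n_shifts
  if (m %% ns != 0L) {
    abort("`m` must be divisible by `n_shifts` for slice shifting")
  }
  block_len <- m %/% ns
  slices_per_pass <- n %/% k
  stop_if_not(slices_per_pass >= 1L, "k-voxel slices must fit the FOV")
  start <- integer(0); b <- numeric(0); mask <- logical(0)
  for (s in seq_len(ns) - 1L) {
    within <- seq_len(block_len) - 1L
    slice_idx <- within %% slices_per_pass          # position in the tiling
    volume_idx <- within %/% slices_per_pass        # pass number in block
    start_blk <- s + k * slice_idx
    b_blk <- config$b_levels[(volume_idx %% length(config$b_levels)) + 1L]
    mask_blk <- within >= config$discard_per_fov
    start <- c(start, start_blk)
    b <- c(b, b_blk)
    mask <- c(mask, mask_blk)
  }
  new_scheme(
    tibble::tibble(shot = seq_len(m), time_s = (seq_len(m) - 1L) * config$shot_spacing,
                   start_index = as.integer(start), k = k, b = b,
                   analysis_mask = mask),
    config, "shift"
  )
}

#' Generate a direct high-resolution reference scheme
#'
#' Conventional slice-by-slice sampling at the target resolution (`k = 1`):
#' positions `0, ..., n-1` are visited cyclically so every position is
#' revisited every `n * shot_spacing` seconds (7.5 s for the default
#' 50-position, 150 ms protocol). b-values cycle over `b_levels`
#' volume-by-volume. No super-resolution is needed; the single fixed TR makes
#' T1 unidentifiable (see the solver's single-TR handling).
#'
#' @inheritParams sero_scheme
#' @return A `sero_scheme` tibble (method `"direct"`).
#' @export
direct_scheme <- function(config) {
  stop_if_not(inherits(config, "scheme_config"), "`config` must be a scheme_config")
  stop_if_not(config$k == 1L, "direct sampling requires k = 1")
  n <- config$n; m <- config$m
  within <- seq_len(m) - 1L
  start <- within %% n
  volume_idx <- within %/% n
  b <- config$b_levels[(volume_idx %% length(config$b_levels)) + 1L]
  new_scheme(
    tibble::tibble(shot = seq_len(m), time_s = within * config$shot_spacing,
                   start_index = as.integer(start), k = 1L, b = b,
                   analysis_mask = TRUE),
    config, "direct"
  )
}

#' Per-sub-voxel repetition-time matrix
#'
#' For every shot and covered position, the local TR is the time since the
#' most recent earlier shot that covered the same position. Positions covered
#' for the first time carry no finite TR and are flagged instead; the forward
#' model treats them as fully relaxed (saturation factor 1).
#'
#' @param start_index Integer vector of per-shot first covered sub-voxels.
#' @param shot_time Strictly increasing per-shot times, seconds.
#' @param k Slice thickness in sub-voxels.
#' @param n Grid length.
#' @return List with `TR` (m x n, `NA` where undefined) and `first_coverage`
#'   (m x n logical).
#' @examples
#' compute_tr_matrix(c(0L, 1L), c(0, 0.15), k = 2, n = 4)
#' @export
compute_tr_matrix <- function(start_index, shot_time, k, n) {
  m <- length(start_index)
  stop_if_not(length(shot_time) == m, "start_index/shot_time length mismatch")
  stop_if_not(m < 2L || all(diff(shot_time) > 0), "shot times must increase")
  TR <- matrix(NA_real_, m, n)
  first_cov <- matrix(FALSE, m, n)
  last <- rep(NA_real_, n)
  for (j in seq_len(m)) {
    ii <- covered_positions(start_index[j], k, n) + 1L  # 1-based columns
    new_pos <- is.na(last[ii])
    first_cov[j, ii[new_pos]] <- TRUE
    TR[j, ii[!new_pos]] <- shot_time[j] - last[ii[!new_pos]]
    last[ii] <- shot_time[j]
  }
  list(TR = TR, first_coverage = first_cov)
}

#' Dense forward-model matrices of a scheme
#'
#' Re-derives the slice-profile weight matrix `W` (m x n; rectangular-profile
#' ones over the covered, in-FOV sub-voxels, or the configured profile), the
#' per-sub-voxel TR matrix, and the first-coverage mask from the per-shot
#' table. These are the experimental parameters entering the thick-slice
#' forward model and the fit.
#'
#' @param scheme A `sero_scheme`.
#' @return List with `W`, `TR`, `first_coverage`, `b` (length m) and
#'   `analysis_mask` (length m).
#' @export
scheme_matrices <- function(scheme) {
  cfg <- scheme_config_of(scheme)
  n <- cfg$n; k <- cfg$k; m <- nrow(scheme)
  W <- matrix(0, m, n)
  prof <- cfg$profile %||% rep(1, k)
  for (j in seq_len(m)) {
    idx <- scheme$start_index[j] + seq_len(k) - 1L
    keep <- idx >= 0L & idx < n
    W[j, idx[keep] + 1L] <- prof[keep]
  }
  tr <- compute_tr_matrix(scheme$start_index, scheme$time_s, k, n)
  list(W = W, TR = tr$TR, first_coverage = tr$first_coverage,
       b = scheme$b, analysis_mask = scheme$analysis_mask)
}
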