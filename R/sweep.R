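# Simulation study orchestration: for each (method, SNR, lambda) cell,
# generate line phantoms, simulate the scheme's signals, add Rician noise at
# the cell's SNR, fit, and accumulate RMSE/RMV. All randomness derives from
# one base seed through named substreams, so the sweep is fully
# deterministic; identical noisy signals are re-fitted for every lambda so
# regularization effects are paired.

parse_method <- function(method, default_k = 4L) {
  if (method == "direct") return(list(name = "direct", k = 1L))
  if (method == "shift") return(list(name = "shift", k = default_k))
  m <- regmatches(method, regexec("^sero([0-9]*)$", method))[[1]]
  if (length(m) == 0L) abort(paste0("unknown method: ", method))
  k <- if (nzchar(m[2])) as.integer(m[2]) else default_k
  list(name = "sero", k = k)
}

build_method_scheme <- function(method, base, seed) {
  pm <- parse_method(method, default_k = base$k)
  # The slice-averaged-TR rejection threshold must stay below the
  # steady-state mean TR (n * spacing / k); for non-default aspect ratios it
  # is rescaled in proportion (k = 2 -> 3.0 s, k = 4 -> 1.5 s, k = 6 -> 1.0 s
  # under the 50-position, 150 ms protocol), keeping the same fraction of
  # the short-TR tail rejected.
  min_tr <- if (pm$name == "sero") base$min_mean_tr * 4 / pm$k else base$min_mean_tr
  cfg <- scheme_config(n = base$n, k = pm$k, m = base$m,
                       shot_spacing = base$shot_spacing,
                       voxel_size = base$voxel_size,
                       b_levels = base$b_levels,
                       min_mean_tr = min_tr,
                       fixed_tr = base$fixed_tr,
                       n_shifts = base$n_shifts,
                       discard_per_fov = base$discard_per_fov,
                       seed = seed)
  switch(pm$name,
         direct = direct_scheme(cfg),
         shift = slice_shift_scheme(cfg),
         sero = sero_scheme(cfg))
}

#' Run the accuracy/precision SNR sweep on line phantoms
#'
#' For every requested (method, SNR, lambda) cell, simulates `n_phantoms`
#' randomized line phantoms with `n_reps` independent Rician noise
#' realizations each, fits every realization, and reports the mean RMSE
#' (accuracy, averaged over phantoms and realizations) and the RMV
#' (precision, across realizations, averaged over voxels then phantoms) per
#' parameter. The same noisy signals are fitted at every `lambda`, so
#' regularized and unregularized results are paired. T1 rows are `NA` for
#' single-TR methods where T1 is not identifiable.
#'
#' @param methods Character vector among `"direct"`, `"shift"`, `"sero"`
#'   (aspect ratio via suffix, e.g. `"sero2"`, `"sero6"`; bare `"sero"` and
#'   `"shift"` use k = 4).
#' @param snr Numeric SNR grid (isotropic high-resolution voxel convention).
#' @param lambdas Regularization weights to fit at.
#' @param n_phantoms,n_reps Phantoms per cell and noise realizations per
#'   phantom.
#' @param seed Base seed; every phantom/scheme/noise draw derives from it.
#' @param cells Optional tibble with columns `method`, `snr`, `lambda`
#'   restricting the sweep to specific cells (overrides the full crossing).
#' @param scheme_base A [scheme_config()] template for the acquisition
#'   protocol (n, m, spacing, b-levels, rejection threshold).
#' @param phantom_base A [line_phantom_config()] template (its seed is
#'   overridden per phantom).
#' @param fit_base A [fit_config()] template (its lambda is overridden per
#'   cell).
#' @param keep_estimates Keep per-realization estimates in the `details`
#'   attribute (memory-heavy; off by default).
#' @return A `metrics_table` tibble keyed by
#'   (`method`, `k`, `lambda`, `snr`, `parameter`) with `rmse`, `rmv`,
#'   `n_phantoms`, `n_reps`.
#' @export
run_snr_sweep <- function(methods = c("direct", "shift", "sero"),
                          snr = c(3, 5, 10, 15),
                          lambdas = c(0, 0.01),
                          n_phantoms = 10L, n_reps = 5L, seed = 1L,
                          cells = NULL,
                          scheme_base = scheme_config(),
                          phantom_base = line_phantom_config(n = scheme_base$n),
                          fit_base = fit_config(),
                          keep_estimates = FALSE) {
  if (is.null(cells)) {
    cells <- tidyr::expand_grid(method = methods, snr = snr, lambda = lambdas)
  }
  stop_if_not(all(c("method", "snr", "lambda") %in% names(cells)),
              "`cells` needs method, snr, lambda columns")
  methods <- unique(cells$method)
  schemes <- lapply(seq_along(methods), function(i) {
    build_method_scheme(methods[i], scheme_base,
                        derive_seed(seed, "scheme", i))
  })
  names(schemes) <- methods
  phantoms <- lapply(seq_len(n_phantoms), function(p) {
    pcfg <- phantom_base
    pcfg$seed <- derive_seed(seed, "phantom", p)
    line_phantom(pcfg)
  })
  noiseless <- lapply(methods, function(m) {
    lapply(phantoms, function(ph) predict_signal(ph, schemes[[m]])$signal)
  })
  names(noiseless) <- methods

  rows <- list()
  details <- list()
  snr_levels <- sort(unique(cells$snr))
  for (m in methods) {
    scheme <- schemes[[m]]
    m_cells <- cells[cells$method == m, ]
    pm <- parse_method(m, default_k = scheme_base$k)
    for (s_i in seq_along(snr_levels)) {
      s <- snr_levels[s_i]
      lam_here <- sort(unique(m_cells$lambda[m_cells$snr == s]))
      if (length(lam_here) == 0L) next
      for (p in seq_len(n_phantoms)) {
        truth <- phantoms[[p]]
        sigma <- sigma_from_snr(truth, s)
        ests <- setNames(vector("list", length(lam_here)),
                         as.character(lam_here))
        for (r in seq_len(n_reps)) {
          noise_seed <- derive_seed(seed, paste0("noise-", m),
                                    (p * 97L + s_i) * 1009L + r)
          noisy <- add_rician_noise(noiseless[[m]][[p]], sigma,
                                    seed = noise_seed)
          init <- local_fit_init(noisy, scheme, bounds = fit_base$bounds,
                                 config = fit_base)
          for (lam in lam_here) {
            fcfg <- fit_base
            fcfg$lambda <- lam
            fit <- fit_column(noisy, scheme, fcfg, init = init)
            err <- rmse(truth, fit$estimates)
            if (fit$t1_frozen) err$rmse[err$parameter == "T1"] <- NA_real_
            rows[[length(rows) + 1L]] <- dplyr::mutate(
              err, method = m, k = pm$k, lambda = lam, snr = s,
              phantom = p, rep = r, t1_frozen = fit$t1_frozen)
            ests[[as.character(lam)]][[r]] <- fit$estimates
            if (keep_estimates) {
              details[[length(details) + 1L]] <- list(
                method = m, lambda = lam, snr = s, phantom = p, rep = r,
                fit = fit)
            }
          }
        }
        for (lam in lam_here) {
          if (n_reps >= 2L) {
            prec <- rmv(ests[[as.character(lam)]])
            rows[[length(rows) + 1L]] <- dplyr::mutate(
              prec, method = m, k = pm$k, lambda = lam, snr = s,
              phantom = p, rep = NA_integer_,
              t1_frozen = attr(ests[[as.character(lam)]][[1]],
                               "t1_frozen") %||% FALSE)
          }
        }
      }
    }
  }
  long <- dplyr::bind_rows(rows)
  acc <- long |>
    dplyr::filter(!is.na(.data$rep)) |>
    dplyr::group_by(.data$method, .data$k, .data$lambda, .data$snr,
                    .data$parameter) |>
    dplyr::summarise(rmse = mean(.data$rmse),
                     t1_frozen = any(.data$t1_frozen), .groups = "drop")
  out <- acc
  if (n_reps >= 2L) {
    prec <- long |>
      dplyr::filter(is.na(.data$rep)) |>
      dplyr::group_by(.data$method, .data$k, .data$lambda, .data$snr,
                      .data$parameter) |>
      dplyr::summarise(rmv = sqrt(mean(.data$rmv^2)), .groups = "drop")
    out <- dplyr::left_join(acc, prec,
                            by = c("method", "k", "lambda", "snr", "parameter"))
  } else {
    out$rmv <- NA_real_
  }
  out <- dplyr::mutate(
    out,
    rmv = dplyr::if_else(.data$t1_frozen & .data$parameter == "T1",
                         NA_real_, .data$rmv)) |>
    dplyr::select(-"t1_frozen") |>
    dplyr::mutate(n_phantoms = n_phantoms, n_reps = n_reps)
  tibble::new_tibble(out, seed = seed,
                     details = if (keep_estimates) details else NULL,
                     class = "metrics_table")
}

#' Plot RMSE/RMV against SNR
#'
#' Mirrors the accuracy/precision panels of the simulation study: one facet
#' per parameter and metric, colored by method, line type by lambda.
#'
#' @param metrics A `metrics_table` from [run_snr_sweep()].
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  df <- tidyr::pivot_longer(metrics, cols = c("rmse", "rmv"),
                            names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snr, y = .data$value,
                                   color = .data$method,
                                   linetype = factor(.data$lambda))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(metric ~ parameter, scales = "free_y") +
    ggplot2::labs(x = "SNR (high-resolution voxel)", y = NULL,
                  linetype = "lambda") +
    ggplot2::theme_minimal()
}
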