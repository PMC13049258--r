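#' Per-parameter root-mean-square error
#'
#' `sqrt(mean((truth - estimate)^2))` per parameter, in the parameter's own
#' units.
#'
#' @param truth,estimate Parameter columns of equal length.
#' @return Tibble with columns `parameter`, `rmse`.
#' @examples
#' a <- param_column(S0 = c(0, 0), D = c(1, 1), V = c(0, 0), T1 = c(1, 1))
#' b <- param_column(S0 = c(3, 4), D = c(1, 1), V = c(0, 0), T1 = c(1, 1))
#' rmse(a, b)  # S0: sqrt(25/2)
#' @export
rmse <- function(truth, estimate) {
  check_param_column(truth); check_param_column(estimate)
  stop_if_not(nrow(truth) == nrow(estimate),
              "truth and estimate must have equal length")
  purrr::map_dfr(param_names, function(p) {
    tibble::tibble(parameter = p,
                   rmse = sqrt(mean((truth[[p]] - estimate[[p]])^2)))
  })
}

#' Per-parameter root mean variance across noise realizations
#'
#' Precision metric: the across-replicate sample variance (divisor `R - 1`)
#' at each voxel, averaged over voxels, then square-rooted.
#'
#' @param estimates List of parameter columns, one per noise realization of
#'   the same object (>= 2).
#' @return Tibble with columns `parameter`, `rmv`.
#' @examples
#' reps <- list(param_column(S0 = c(1, 1), D = c(1, 1), V = c(0, 0), T1 = c(1, 1)),
#'              param_column(S0 = c(3, 3), D = c(1, 1), V = c(0, 0), T1 = c(1, 1)))
#' rmv(reps)  # S0: sqrt(2)
#' @export
rmv <- function(estimates) {
  stop_if_not(is.list(estimates) && length(estimates) >= 2L,
              "`rmv` needs at least two replicates")
  purrr::map_dfr(param_names, function(p) {
    mat <- vapply(estimates, function(e) e[[p]],
                  numeric(nrow(estimates[[1]])))
    tibble::tibble(parameter = p,
                   rmv = sqrt(mean(apply(mat, 1L, var))))
  })
}

#' Residual-based SNR estimate
#'
#' Best-effort SNR surrogate from a converged fit: the mean fitted baseline
#' (fully relaxed, unweighted sub-voxel) signal over the column, divided by a
#' robust standard deviation (1.4826 x MAD) of the data residuals. Returns
#' `NA` when the residual spread is numerically zero (noiseless data), in
#' which case SNR is not estimable.
#'
#' @param signals The measured `shot_signals` used in the fit.
#' @param fit The `sero_fit` result.
#' @param scheme The `sero_scheme`.
#' @return Scalar SNR estimate (or `NA_real_`).
#' @export
estimate_snr_from_residuals <- function(signals, fit, scheme) {
  values <- if (is.numeric(signals)) signals else signals$signal
  pred <- predict_signal(fit$estimates, scheme)$signal
  keep <- scheme$analysis_mask
  r <- values[keep] - pred[keep]
  sigma_hat <- mad(r)
  if (sigma_hat < 1e-10 * max(abs(values))) return(NA_real_)
  mean(fit$estimates$S0) / sigma_hat
}
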