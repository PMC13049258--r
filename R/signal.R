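# Forward signal model: saturation-recovery T1-weighting combined with the
# second-order cumulant representation of diffusion attenuation, evaluated
# either for a single (sub-)voxel or as a thick-slice weighted sum.

#' Scalar saturation-recovery cumulant signal
#'
#' Evaluates `S0 * (1 - exp(-TR / T1)) * exp(-b * D + b^2 * V / 2)`.
#' An infinite (or `NA`) TR means full longitudinal recovery: the saturation
#' factor is exactly 1. All arguments recycle.
#'
#' @param S0 Baseline signal, arbitrary units.
#' @param D Apparent diffusivity, um^2/ms.
#' @param V Diffusional variance (second cumulant), um^4/ms^2.
#' @param T1 Longitudinal relaxation time, seconds (> 0).
#' @param TR Repetition time, seconds (> 0, `Inf`, or `NA` for full recovery).
#' @param b Diffusion weighting, ms/um^2 (>= 0).
#' @return Noiseless signal magnitude(s).
#' @examples
#' predict_signal_scalar(1, 1, 0, 1, TR = 1, b = 1)  # (1 - e^-1) * e^-1
#' @export
predict_signal_scalar <- function(S0, D, V, T1, TR, b) {
  stop_if_not(all(T1 > 0), "T1 must be > 0")
  stop_if_not(all(b >= 0), "b must be >= 0")
  sat <- ifelse(is.na(TR) | is.infinite(TR), 1, 1 - exp(-TR / T1))
  S0 * sat * exp(-b * D + b^2 * V / 2)
}

#' Thick-slice forward signal for a parameter column
#'
#' Each shot's signal is the slice-profile-weighted sum over its covered
#' sub-voxels of the scalar model, evaluated with that sub-voxel's local TR
#' and the shot's b-value. First coverages (no prior excitation) use
#' saturation factor 1 (fully relaxed start).
#'
#' @param params A parameter column as produced by [param_column()] /
#'   [line_phantom()]: tibble with columns `S0`, `D`, `V`, `T1`, one row per
#'   high-resolution position.
#' @param scheme A `sero_scheme` whose grid length matches `nrow(params)`.
#' @return A `shot_signals` tibble with columns `shot`, `signal`; attributes
#'   `sigma = 0`, `noiseless = TRUE`.
#' @examples
#' sch <- direct_scheme(scheme_config(n = 8, k = 1, m = 16))
#' ph <- param_column(S0 = rep(1, 8), D = rep(1, 8), V = rep(0.5, 8),
#'                    T1 = rep(1, 8))
#' predict_signal(ph, sch)
#' @export
predict_signal <- function(params, scheme) {
  cfg <- scheme_config_of(scheme)
  check_param_column(params)
  if (nrow(params) != cfg$n) {
    abort(sprintf("parameter column has %d positions but scheme expects n = %d",
                  nrow(params), cfg$n))
  }
  mats <- scheme_matrices(scheme)
  s <- forward_signal(pack_params(params), mats)
  new_shot_signals(s, sigma = 0, noiseless = TRUE, seed = NULL)
}

# Vectorized forward model on packed parameters (list with S0, D, V, T1
# length-n vectors) and precomputed scheme matrices. Shared by simulation
# and the solver.
forward_signal <- function(p, mats) {
  sat <- 1 - exp(-mats$TR * rep(1 / p$T1, each = nrow(mats$TR)))
  sat[is.na(mats$TR)] <- 1                       # first coverage / uncovered
  att <- exp(outer(-mats$b, p$D) + outer(mats$b^2 / 2, p$V))
  as.vector((mats$W * sat * att) %*% p$S0)
}

new_shot_signals <- function(values, sigma, noiseless, seed) {
  tibble::new_tibble(
    tibble::tibble(shot = seq_along(values), signal = as.numeric(values)),
    sigma = sigma, noiseless = noiseless, seed = seed,
    class = "shot_signals"
  )
}

#' Noise standard deviation for a prescribed SNR
#'
#' The noise level is `sigma = mean(S0) / SNR`, where the mean baseline
#' amplitude is taken over the object support (all positions of a line
#' phantom; non-background voxels of a labelled volume). SNR always refers to
#' the isotropic high-resolution voxel, so thick-slice shots carry a roughly
#' k-fold larger noiseless signal at matched sigma.
#'
#' @param params Parameter column (tibble with `S0`) or a `param_volume`.
#' @param snr Positive signal-to-noise ratio.
#' @param support Optional logical vector/array selecting the object support;
#'   defaults to all positions (columns) or non-background labels (volumes).
#' @return Noise standard deviation in signal units.
#' @examples
#' sigma_from_snr(param_column(S0 = c(1, 3), D = c(1, 1),
#'                             V = c(0, 0), T1 = c(1, 1)), snr = 2)
#' @export
sigma_from_snr <- function(params, snr, support = NULL) {
  stop_if_not(is.numeric(snr) && snr > 0, "`snr` must be > 0")
  if (inherits(params, "param_volume")) {
    s0 <- params$maps$S0
    if (is.null(support)) support <- params$labels != 0L
  } else {
    check_param_column(params)
    s0 <- params$S0
    if (is.null(support)) support <- rep(TRUE, length(s0))
  }
  vals <- s0[support]
  if (length(vals) == 0L || mean(vals) <= 0) {
    abort("degenerate phantom: object-support mean S0 is zero")
  }
  mean(vals) / snr
}

#' Add Rician noise to magnitude signals
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma` to
#' the real and imaginary channels of a zero-phase signal and takes the
#' magnitude: `|S + g1 + i g2|`. `sigma = 0` returns the input unchanged.
#'
#' @param signals A `shot_signals` tibble or numeric vector.
#' @param sigma Noise standard deviation (>= 0), signal units.
#' @param seed Optional integer seed for reproducible noise.
#' @return A `shot_signals` tibble of noisy magnitudes.
#' @examples
#' s <- predict_signal(
#'   line_phantom(line_phantom_config(n = 10, seed = 1)),
#'   direct_scheme(scheme_config(n = 10, k = 1, m = 20)))
#' add_rician_noise(s, sigma = 0.1, seed = 2)
#' @export
add_rician_noise <- function(signals, sigma, seed = NULL) {
  stop_if_not(is.numeric(sigma) && sigma >= 0, "`sigma` must be >= 0")
  values <- if (is.numeric(signals)) signals else signals$signal
  if (sigma == 0) {
    return(new_shot_signals(values, sigma = 0,
                            noiseless = TRUE, seed = seed))
  }
  noisy <- with_seed(seed, {
    g1 <- rnorm(length(values), sd = sigma)
    g2 <- rnorm(length(values), sd = sigma)
    sqrt((values + g1)^2 + g2^2)
  })
  new_shot_signals(noisy, sigma = sigma, noiseless = FALSE, seed = seed)
}
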