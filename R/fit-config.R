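#' Default parameter box bounds for fitting
#'
#' `S0` in [0, 4] a.u. (on the normalized-signal scale), `D` in [0.3, 4]
#' um^2/ms, `V` in [0, 4] um^4/ms^2, `T1` in [0.3, 5] s.
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_fit_bounds <- function() {
  list(S0 = c(0, 4), D = c(0.3, 4), V = c(0, 4), T1 = c(0.3, 5))
}

#' Solver configuration for the super-resolution fit
#'
#' @param lambda Smoothness-prior weight on first spatial differences of each
#'   parameter vector (dimensionless; 0 disables regularization).
#' @param bounds Per-parameter `[lo, hi]` box bounds, see
#'   [default_fit_bounds()].
#' @param ftol,ptol,gtol Function/step/gradient convergence tolerances.
#' @param max_iter Maximum solver iterations.
#' @param jacobian `"analytic"` (default) or `"numeric"` (finite differences).
#' @param penalty_weights Optional per-parameter multipliers on the penalty
#'   blocks (named, defaults all 1); the reference behavior is a single
#'   scalar `lambda` on raw parameter differences.
#' @param t1_fixed_value Nominal T1 (s) used when a scheme's TR spread is
#'   below `single_tr_tol` and T1 is therefore unidentifiable (e.g. direct
#'   sampling at one fixed TR).
#' @param single_tr_tol TR spread (s) below which the scheme is treated as
#'   single-TR and the T1 block is frozen.
#' @param drop_first_coverage_shots Exclude shots containing any
#'   first-coverage sub-voxel from the data term (default keeps them with
#'   saturation factor 1).
#' @param seed Optional seed for randomized restarts (none by default).
#' @return A `fit_config` list.
#' @export
fit_config <- function(lambda = 0.01, bounds = default_fit_bounds(),
                       ftol = 1e-8, ptol = 1e-8, gtol = 1e-8,
                       max_iter = 200L,
                       jacobian = c("analytic", "numeric"),
                       penalty_weights = c(S0 = 1, D = 1, V = 1, T1 = 1),
                       t1_fixed_value = 1.0, single_tr_tol = 1e-3,
                       drop_first_coverage_shots = FALSE,
                       seed = NULL) {
  stop_if_not(is.numeric(lambda) && lambda >= 0, "`lambda` must be >= 0")
  for (p in c("S0", "D", "V", "T1")) {
    stop_if_not(!is.null(bounds[[p]]) && bounds[[p]][1] < bounds[[p]][2],
                paste0("bounds for ", p, " must satisfy lo < hi"))
  }
  structure(list(lambda = lambda, bounds = bounds[c("S0", "D", "V", "T1")],
                 ftol = ftol, ptol = ptol, gtol = gtol,
                 max_iter = as.integer(max_iter),
                 jacobian = match.arg(jacobian),
                 penalty_weights = penalty_weights,
                 t1_fixed_value = t1_fixed_value,
                 single_tr_tol = single_tr_tol,
                 drop_first_coverage_shots = drop_first_coverage_shots,
                 seed = seed),
            class = "fit_config")
}

#' Normalize signals by their global maximum
#'
#' The baseline signal is fitted on a normalized scale to improve numerical
#' conditioning: measured signals are divided by their global maximum and the
#' constant is recorded so fitted S0 can be reported on either scale.
#'
#' @param signals A `shot_signals` tibble (or numeric vector).
#' @return List with `signals` (normalized `shot_signals`) and `constant`.
#' @examples
#' normalize_signals(c(1, 2, 4))
#' @export
normalize_signals <- function(signals) {
  values <- if (is.numeric(signals)) signals else signals$signal
  cmax <- max(values)
  if (!is.finite(cmax) || cmax <= 0) {
    abort("cannot normalize: no positive signal")
  }
  out <- new_shot_signals(values / cmax,
                          sigma = (if (is.numeric(signals)) 0 else attr(signals, "sigma")) / cmax,
                          noiseless = if (is.numeric(signals)) TRUE else attr(signals, "noiseless"),
                          seed = if (is.numeric(signals)) NULL else attr(signals, "seed"))
  list(signals = out, constant = cmax)
}
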