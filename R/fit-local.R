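# Fast slice-wise local fit. For every high-resolution position, all shots
# covering it are gathered; each is assigned the shot's b-value and
# slice-averaged TR, and the signal is divided by the slice-profile row sum
# to reach sub-voxel scale. The scalar model is then fitted per position,
# which supplies the starting point for the full super-resolution fit (and
# the "no SRR" thick-slice reconstruction of the brain demo).

scalar_residuals <- function(theta, y, trbar, b, t1_frozen, t1_value) {
  T1 <- if (t1_frozen) t1_value else theta[4]
  predict_signal_scalar(theta[1], theta[2], theta[3], T1, trbar, b) - y
}

scalar_jacobian <- function(theta, y, trbar, b, t1_frozen, t1_value) {
  S0 <- theta[1]; D <- theta[2]; V <- theta[3]
  T1 <- if (t1_frozen) t1_value else theta[4]
  inf_tr <- is.na(trbar) | is.infinite(trbar)
  ex <- ifelse(inf_tr, 0, exp(-trbar / T1))
  sat <- 1 - ex
  att <- exp(-b * D + b^2 * V / 2)
  f <- S0 * sat * att
  J <- cbind(sat * att, -b * f, (b^2 / 2) * f)
  if (!t1_frozen) {
    dsat <- ifelse(inf_tr, 0, -ex * trbar / T1^2)
    J <- cbind(J, S0 * att * dsat)
  }
  J
}

#' Local (slice-wise) initialization fit
#'
#' Fits the scalar signal model independently at every high-resolution
#' position using the shots that cover it, each assigned its b-value and
#' slice-averaged TR, with signals divided by the slice-profile row sum.
#' Positions covered by fewer than 4 analysis shots or fewer than 3 distinct
#' b-values fall back to the bounds' midpoints and are flagged in the
#' `fallback` attribute. Results are clamped 1% inside the bounds so the main
#' fit never starts on the boundary.
#'
#' @param signals `shot_signals` tibble or numeric vector (one per shot).
#' @param scheme A `sero_scheme`.
#' @param bounds Per-parameter box bounds (see [default_fit_bounds()]).
#' @param config A [fit_config()] (controls single-TR T1 freezing).
#' @param norm_const Optional fixed normalization constant; default is the
#'   global maximum of the analysis signals.
#' @return Parameter-column tibble (S0 in input signal units), with
#'   attributes `fallback` (logical per position) and `t1_frozen`.
#' @export
local_fit_init <- function(signals, scheme, bounds = default_fit_bounds(),
                           config = fit_config(), norm_const = NULL) {
  cfg <- scheme_config_of(scheme)
  n <- cfg$n
  values <- if (is.numeric(signals)) signals else signals$signal
  mats <- scheme_matrices(scheme)
  am <- analysis_mats(mats, config$drop_first_coverage_shots)
  v <- values[am$keep]
  const <- norm_const %||% max(v)
  if (!is.finite(const) || const <= 0) abort("cannot normalize: no positive signal")
  v <- v / const

  rowsum_w <- rowSums(am$W)
  # slice-averaged TR per shot: mean of finite local TRs over covered
  # positions; all-first-coverage shots count as fully relaxed (Inf)
  trbar <- apply(am$TR, 1L, function(row) {
    fin <- row[!is.na(row)]
    if (length(fin)) mean(fin) else Inf
  })
  tr_fin <- trbar[is.finite(trbar)]
  t1_frozen <- length(tr_fin) == 0L ||
    diff(range(tr_fin)) < config$single_tr_tol

  mid <- vapply(bounds, mean, numeric(1))
  est <- matrix(rep(mid[param_names], each = n), n, 4L,
                dimnames = list(NULL, param_names))
  fallback <- rep(TRUE, n)
  lower <- vapply(bounds[param_names], `[`, numeric(1), 1L)
  upper <- vapply(bounds[param_names], `[`, numeric(1), 2L)
  nb <- if (t1_frozen) 3L else 4L
  for (i in seq_len(n)) {
    cov <- which(am$W[, i] > 0)
    if (length(cov) < 4L || length(unique(am$b[cov])) < 3L) next
    y_i <- v[cov] / rowsum_w[cov]
    start <- mid[param_names[seq_len(nb)]]
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, lower = lower[seq_len(nb)], upper = upper[seq_len(nb)],
        fn = scalar_residuals, jac = scalar_jacobian,
        y = y_i, trbar = trbar[cov], b = am$b[cov],
        t1_frozen = t1_frozen, t1_value = config$t1_fixed_value,
        control = minpack.lm::nls.lm.control(maxiter = 100L))),
      error = function(e) NULL)
    if (is.null(res)) next
    est[i, seq_len(nb)] <- res$par
    if (t1_frozen) est[i, 4L] <- config$t1_fixed_value
    fallback[i] <- FALSE
  }
  for (j in seq_len(4L)) {
    est[, j] <- clamp_interior(est[, j], lower[j], upper[j])
  }
  out <- param_column(S0 = est[, "S0"] * const, D = est[, "D"],
                      V = est[, "V"], T1 = est[, "T1"])
  attr(out, "fallback") <- fallback
  attr(out, "t1_frozen") <- t1_frozen
  out
}
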