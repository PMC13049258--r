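# Regularized bound-constrained nonlinear least squares for one
# through-slice column: minimize ||f(x, W, TR, b) - S||^2 + lambda ||Dx||^2
# over the 4n parameters within box bounds, where D takes first spatial
# differences of each parameter vector. Solved with Levenberg-Marquardt
# (minpack.lm::nls.lm) using an analytic Jacobian.

pack_params <- function(params) {
  list(S0 = params$S0, D = params$D, V = params$V, T1 = params$T1)
}

param_names <- c("S0", "D", "V", "T1")

# theta layout: c(S0, D, V[, T1]) blocks of length n; T1 absent when frozen.
theta_to_params <- function(theta, n, t1_frozen, t1_value) {
  p <- list(S0 = theta[seq_len(n)],
            D = theta[n + seq_len(n)],
            V = theta[2L * n + seq_len(n)])
  p$T1 <- if (t1_frozen) rep(t1_value, n) else theta[3L * n + seq_len(n)]
  p
}

#' Smoothness-penalty residuals
#'
#' Returns `sqrt(lambda)` times the stacked first spatial differences of the
#' four parameter vectors (`4 * (n - 1)` residuals), the rows appended to the
#' data residuals so the least-squares solver minimizes
#' `||f(x) - S||^2 + lambda * ||diff||^2`. Optional per-parameter weights
#' multiply individual blocks (all 1 by default).
#'
#' @param params Parameter column (tibble with `S0`, `D`, `V`, `T1`).
#' @param lambda Non-negative penalty weight.
#' @param penalty_weights Named per-parameter multipliers.
#' @return Numeric vector of penalty residuals.
#' @examples
#' regularization_residuals(param_column(S0 = c(1, 1, 2), D = c(1, 1, 1),
#'                                       V = c(0, 0, 0), T1 = c(1, 1, 1)),
#'                          lambda = 0.01)
#' @export
regularization_residuals <- function(params, lambda,
                                     penalty_weights = c(S0 = 1, D = 1,
                                                         V = 1, T1 = 1)) {
  p <- pack_params(params)
  unlist(lapply(param_names, function(nm) {
    sqrt(lambda * penalty_weights[[nm]]) * diff(p[[nm]])
  }), use.names = FALSE)
}

# Residuals and analytic Jacobian used inside the solver --------------------

fit_residuals <- function(theta, n, mats, y, lambda, weights,
                          t1_frozen, t1_value) {
  p <- theta_to_params(theta, n, t1_frozen, t1_value)
  r_data <- forward_signal(p, mats) - y
  blocks <- if (t1_frozen) param_names[1:3] else param_names
  r_pen <- unlist(lapply(blocks, function(nm) {
    sqrt(lambda * weights[[nm]]) * diff(p[[nm]])
  }), use.names = FALSE)
  c(r_data, r_pen)
}

fit_jacobian <- function(theta, n, mats, y, lambda, weights,
                         t1_frozen, t1_value) {
  p <- theta_to_params(theta, n, t1_frozen, t1_value)
  m <- nrow(mats$TR)
  ratio <- mats$TR * rep(1 / p$T1, each = m)
  ex <- exp(-ratio)
  sat <- 1 - ex
  sat[is.na(mats$TR)] <- 1
  att <- exp(outer(-mats$b, p$D) + outer(mats$b^2 / 2, p$V))
  E <- mats$W * sat * att
  J_S0 <- E
  ES0 <- E * rep(p$S0, each = m)
  J_D <- -mats$b * ES0
  J_V <- (mats$b^2 / 2) * ES0
  J <- cbind(J_S0, J_D, J_V)
  if (!t1_frozen) {
    dsat <- -ex * ratio * rep(1 / p$T1, each = m)   # d sat / d T1
    dsat[is.na(mats$TR)] <- 0
    J_T1 <- mats$W * att * dsat * rep(p$S0, each = m)
    J <- cbind(J, J_T1)
  }
  # penalty rows: sqrt(lambda * w) * first-difference operator per block
  nb <- if (t1_frozen) 3L else 4L
  if (n >= 2L) {
    D1 <- diff(diag(n))
    blocks <- param_names[seq_len(nb)]
    Jp <- matrix(0, nb * (n - 1L), nb * n)
    for (bi in seq_len(nb)) {
      rows <- (bi - 1L) * (n - 1L) + seq_len(n - 1L)
      cols <- (bi - 1L) * n + seq_len(n)
      Jp[rows, cols] <- sqrt(lambda * weights[[blocks[bi]]]) * D1
    }
    J <- rbind(J, Jp)
  }
  J
}

clamp_interior <- function(x, lo, hi, frac = 0.01) {
  span <- hi - lo
  pmin(pmax(x, lo + frac * span), hi - frac * span)
}

# Restrict scheme matrices to the shots entering the data term.
analysis_mats <- function(mats, drop_first_coverage_shots = FALSE) {
  keep <- mats$analysis_mask
  if (drop_first_coverage_shots) {
    keep <- keep & !apply(mats$first_coverage, 1L, any)
  }
  list(W = mats$W[keep, , drop = FALSE],
       TR = mats$TR[keep, , drop = FALSE],
       first_coverage = mats$first_coverage[keep, , drop = FALSE],
       b = mats$b[keep], keep = keep)
}

#' Fit one through-slice column by regularized super-resolution
#'
#' Estimates the four high-resolution parameter vectors from a column's
#' thick-slice shot signals by minimizing the regularized least-squares
#' objective within box bounds, starting from the fast local fit (or a
#' supplied initialization). Schemes whose TR spread is below
#' `config$single_tr_tol` (a single fixed TR, e.g. direct sampling) have T1
#' frozen at `config$t1_fixed_value` and excluded from the fit. Signals are
#' normalized by their global maximum before fitting; reported S0 is
#' denormalized back to input units.
#'
#' @param signals `shot_signals` for every shot of the scheme.
#' @param scheme The `sero_scheme` that produced the signals.
#' @param config A [fit_config()].
#' @param init Optional parameter-column initialization (input signal units).
#' @param norm_const Optional externally fixed normalization constant (used
#'   by [fit_volume()] so all columns share one global maximum).
#' @return A `sero_fit` object; see [tidy.sero_fit()] and
#'   [glance.sero_fit()].
#' @examples
#' cfg <- scheme_config(n = 12, k = 2, m = 120, seed = 5)
#' sch <- sero_scheme(cfg)
#' truth <- line_phantom(line_phantom_config(n = 12, seed = 2))
#' fit <- fit_column(predict_signal(truth, sch), sch,
#'                   fit_config(lambda = 0))
#' glance(fit)
#' @export
fit_column <- function(signals, scheme, config = fit_config(),
                       init = NULL, norm_const = NULL) {
  stop_if_not(inherits(config, "fit_config"), "`config` must be a fit_config")
  cfg <- scheme_config_of(scheme)
  n <- cfg$n
  values <- if (is.numeric(signals)) signals else signals$signal
  stop_if_not(length(values) == nrow(scheme),
              "signals length does not match the scheme's shot count")
  mats <- scheme_matrices(scheme)
  am <- analysis_mats(mats, config$drop_first_coverage_shots)
  if (is.null(norm_const)) {
    norm <- normalize_signals(values[am$keep])
    const <- norm$constant
  } else {
    const <- norm_const
  }
  y <- values[am$keep] / const

  tr_pool <- am$TR[!is.na(am$TR)]
  t1_frozen <- length(tr_pool) == 0L ||
    diff(range(tr_pool)) < config$single_tr_tol

  b <- config$bounds
  if (is.null(init)) {
    init_pc <- local_fit_init(values, scheme, bounds = b, config = config,
                              norm_const = const)
    init_used <- "local_fit"
  } else {
    check_param_column(init)
    init_pc <- init
    init_used <- "user"
  }
  init_pc$S0 <- init_pc$S0 / const   # fit S0 on the normalized scale
  theta0 <- c(clamp_interior(init_pc$S0, b$S0[1], b$S0[2]),
              clamp_interior(init_pc$D, b$D[1], b$D[2]),
              clamp_interior(init_pc$V, b$V[1], b$V[2]))
  lower <- c(rep(b$S0[1], n), rep(b$D[1], n), rep(b$V[1], n))
  upper <- c(rep(b$S0[2], n), rep(b$D[2], n), rep(b$V[2], n))
  if (!t1_frozen) {
    theta0 <- c(theta0, clamp_interior(init_pc$T1, b$T1[1], b$T1[2]))
    lower <- c(lower, rep(b$T1[1], n))
    upper <- c(upper, rep(b$T1[2], n))
  }

  jac_fun <- if (config$jacobian == "analytic") fit_jacobian else NULL
  res <- suppressWarnings(minpack.lm::nls.lm(
    par = theta0, lower = lower, upper = upper,
    fn = fit_residuals, jac = jac_fun,
    n = n, mats = am, y = y, lambda = config$lambda,
    weights = config$penalty_weights,
    t1_frozen = t1_frozen, t1_value = config$t1_fixed_value,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iter, ftol = config$ftol, ptol = config$ptol,
      gtol = config$gtol))
  )
  p_hat <- theta_to_params(res$par, n, t1_frozen, config$t1_fixed_value)
  est <- param_column(S0 = p_hat$S0 * const, D = p_hat$D, V = p_hat$V,
                      T1 = p_hat$T1)
  r_data <- forward_signal(p_hat, am) - y
  pen <- fit_residuals(res$par, n, am, y, config$lambda,
                       config$penalty_weights, t1_frozen,
                       config$t1_fixed_value)
  pen <- pen[-seq_along(r_data)]
  converged <- res$info %in% 1:4 && res$niter < config$max_iter
  structure(
    list(estimates = est,
         residual_norm = sqrt(sum(r_data^2)),
         penalty_norm = if (length(pen)) sqrt(sum(pen^2)) else 0,
         objective = sum(r_data^2) + sum(pen^2),
         iterations = res$niter,
         converged = converged,
         message = res$message,
         t1_frozen = t1_frozen,
         init = init_used,
         norm_constant = const,
         config = config,
         method = attr(scheme, "method"),
         n_shots_used = length(y)),
    class = "sero_fit"
  )
}

#' @export
print.sero_fit <- function(x, ...) {
  cat("<sero_fit>", x$method, "scheme;", nrow(x$estimates), "positions;",
      x$n_shots_used, "shots\n")
  cat(sprintf("  residual norm %.4g  penalty norm %.4g  iterations %d  %s\n",
              x$residual_norm, x$penalty_norm, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (x$t1_frozen) cat("  T1 frozen (single-TR scheme)\n")
  invisible(x)
}

#' Data-term Jacobian of the forward model at given parameters
#'
#' Linearizes the thick-slice forward model at `params` and returns the
#' Jacobian of the data residuals (analysis-masked shots) with respect to the
#' stacked `(S0, D, V, T1)` parameters. Used to assess the conditioning of
#' the super-resolution inverse problem for a sampling scheme.
#'
#' @param params Parameter column (truth or estimate).
#' @param scheme A `sero_scheme`.
#' @return Matrix of size (analysis shots) x 4n.
#' @export
forward_jacobian <- function(params, scheme) {
  check_param_column(params)
  cfg <- scheme_config_of(scheme)
  am <- analysis_mats(scheme_matrices(scheme))
  theta <- c(params$S0, params$D, params$V, params$T1)
  J <- fit_jacobian(theta, cfg$n, am, NULL, lambda = 0,
                    weights = c(S0 = 1, D = 1, V = 1, T1 = 1),
                    t1_frozen = FALSE, t1_value = 1)
  J
}

#' Conditioning of the linearized super-resolution problem
#'
#' Ratio of the largest singular value of the data-term Jacobian at `params`
#' to the smallest singular value among identifiable directions (singular
#' values above `tol` times the largest). Smaller is better conditioned.
#'
#' @inheritParams forward_jacobian
#' @param tol Relative threshold separating identifiable directions.
#' @return List with `condition` and the vector of singular values.
#' @export
scheme_conditioning <- function(params, scheme, tol = 1e-12) {
  sv <- svd(forward_jacobian(params, scheme), nu = 0, nv = 0)$d
  keep <- sv > tol * sv[1]
  list(condition = sv[1] / min(sv[keep]), singular_values = sv)
}
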