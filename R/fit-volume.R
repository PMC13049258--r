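#' Fit every through-slice column of a signal stack
#'
#' Applies [fit_column()] independently to each in-plane location of a
#' thick-slice signal stack (dimensions `nx x ny x m`, shots along the third
#' axis) and assembles the column solutions into 3D parameter maps. Columns
#' are independent, so results do not depend on execution order. One global
#' normalization constant (the stack maximum) is shared by all columns.
#'
#' @param stack 3D numeric array, in-plane grid x shots.
#' @param scheme The `sero_scheme` common to all columns.
#' @param config A [fit_config()].
#' @param support Optional `nx x ny` logical matrix restricting which columns
#'   are fitted (others are filled with `NA`); default fits columns with any
#'   positive signal.
#' @return List with `maps` (named list of `nx x ny x n` arrays), and `qc`
#'   (tibble of per-column diagnostics: convergence flag, iterations,
#'   residual norm).
#' @export
fit_volume <- function(stack, scheme, config = fit_config(), support = NULL) {
  stop_if_not(length(dim(stack)) == 3L, "`stack` must be a 3D array")
  cfg <- scheme_config_of(scheme)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  stop_if_not(dim(stack)[3] == nrow(scheme),
              "stack's third dimension must equal the scheme's shot count")
  if (is.null(support)) {
    support <- apply(stack, c(1, 2), function(s) any(s > 0))
  }
  const <- max(stack)
  maps <- lapply(param_names, function(p) array(NA_real_, c(nx, ny, cfg$n)))
  names(maps) <- param_names
  qc <- list()
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      if (!support[ix, iy]) next
      fit <- fit_column(stack[ix, iy, ], scheme, config, norm_const = const)
      for (p in param_names) maps[[p]][ix, iy, ] <- fit$estimates[[p]]
      qc[[length(qc) + 1L]] <- tibble::tibble(
        x = ix, y = iy, converged = fit$converged,
        iterations = fit$iterations, residual_norm = fit$residual_norm)
    }
  }
  list(maps = maps, qc = dplyr::bind_rows(qc),
       norm_constant = const, t1_frozen = NULL)
}

#' Tidy per-position estimates of a column fit
#'
#' @param x A `sero_fit`.
#' @param truth Optional parameter column of ground truth to join in as
#'   `*_true` columns.
#' @param ... Unused.
#' @return Long tibble with `position`, `parameter`, `estimate` (and `truth`
#'   when supplied).
#' @method tidy sero_fit
#' @export
tidy.sero_fit <- function(x, truth = NULL, ...) {
  est <- tidyr::pivot_longer(x$estimates, cols = dplyr::all_of(param_names),
                             names_to = "parameter", values_to = "estimate")
  if (!is.null(truth)) {
    tr <- tidyr::pivot_longer(truth, cols = dplyr::all_of(param_names),
                              names_to = "parameter", values_to = "truth")
    est <- dplyr::left_join(est, tr, by = c("position", "parameter"))
  }
  est
}

#' One-row fit diagnostics
#'
#' @param x A `sero_fit`.
#' @param ... Unused.
#' @return One-row tibble: residual/penalty norms, objective, iterations,
#'   convergence, T1-frozen flag, normalization constant, initialization.
#' @method glance sero_fit
#' @export
glance.sero_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 penalty_norm = x$penalty_norm,
                 objective = x$objective,
                 iterations = x$iterations,
                 converged = x$converged,
                 t1_frozen = x$t1_frozen,
                 norm_constant = x$norm_constant,
                 init = x$init,
                 method = x$method,
                 n_shots = x$n_shots_used)
}

#' Plot a fitted column against optional truth
#'
#' @param object A `sero_fit`.
#' @param truth Optional ground-truth parameter column.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter.
#' @method autoplot sero_fit
#' @export
autoplot.sero_fit <- function(object, truth = NULL, ...) {
  df <- tidy(object, truth = truth)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                         y = .data$estimate)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "through-slice position", y = "estimate") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    gg <- gg + ggplot2::geom_line(ggplot2::aes(y = .data$truth),
                                  linetype = "dashed", color = "grey40")
  }
  gg
}
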