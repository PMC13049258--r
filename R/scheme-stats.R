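#' Summary statistics of a sampling scheme
#'
#' Pools the defined (non-first-coverage) per-sub-voxel TR entries of the
#' analysis-masked shots and reports their order-statistic quantiles, the
#' fraction below a threshold, and per-position coverage counts (all shots,
#' in-FOV sub-voxels only). Mean coverage is total coverages divided by `n`.
#'
#' @param scheme A `sero_scheme`.
#' @param tr_threshold TR threshold (seconds) for the short-TR tail fraction.
#' @return A `scheme_stats` list: `coverage` tibble (`position`, `count`),
#'   `tr_quantiles` (named: min, q1, median, q3, max), `frac_below`,
#'   `tr_threshold`, `mean_coverage`, `n_tr`.
#' @examples
#' scheme_statistics(direct_scheme(scheme_config(n = 10, k = 1, m = 40)))
#' @export
scheme_statistics <- function(scheme, tr_threshold = 0.3) {
  cfg <- scheme_config_of(scheme)
  mats <- scheme_matrices(scheme)
  counts <- colSums(mats$W > 0)
  pool <- mats$TR[mats$analysis_mask, , drop = FALSE]
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0L) {
    abort("degenerate scheme: no defined TR entries (every coverage is a first coverage)")
  }
  q <- quantile(pool, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  structure(
    list(coverage = tibble::tibble(position = seq_len(cfg$n) - 1L,
                                   count = as.integer(counts)),
         tr_quantiles = setNames(q, c("min", "q1", "median", "q3", "max")),
         frac_below = mean(pool < tr_threshold),
         tr_threshold = tr_threshold,
         mean_coverage = sum(counts) / cfg$n,
         n_tr = length(pool)),
    class = "scheme_stats"
  )
}

#' @export
print.scheme_stats <- function(x, ...) {
  cat("<scheme_stats>\n")
  cat("  TR quantiles (s):",
      paste(sprintf("%s=%.3g", names(x$tr_quantiles), x$tr_quantiles),
            collapse = "  "), "\n")
  cat(sprintf("  fraction TR < %.3g s: %.3f   mean coverage: %.2f/position\n",
              x$tr_threshold, x$frac_below, x$mean_coverage))
  invisible(x)
}

#' Plot a sampling scheme
#'
#' Shows the early shots as horizontal slice segments colored by local TR
#' (left-panel style) plus the per-position sampling density.
#'
#' @param object A `sero_scheme`.
#' @param shots Which shots to draw in the slice panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sero_scheme
#' @export
autoplot.sero_scheme <- function(object, shots = 1:min(150L, nrow(object)), ...) {
  cfg <- scheme_config_of(object)
  mats <- scheme_matrices(object)
  sub <- mats$TR[shots, , drop = FALSE]
  df <- tibble::tibble(
    shot = rep(shots, times = cfg$n),
    position = rep(seq_len(cfg$n) - 1L, each = length(shots)),
    tr = as.vector(sub),
    covered = as.vector(mats$W[shots, , drop = FALSE] > 0)
  )
  df <- dplyr::filter(df, .data$covered)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$shot,
                                   fill = .data$tr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "local TR (s)", na.value = "grey80") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "through-slice position (sub-voxels)", y = "shot",
                  title = paste0("Sampling scheme (", attr(object, "method"), ")"),
                  subtitle = "grey tiles: first coverage (no finite TR)") +
    ggplot2::theme_minimal()
}
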