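#' Sampling-scheme configuration
#'
#' Bundles the geometry and timing of a through-slice sampling experiment:
#' the high-resolution grid (`n` sub-voxels of `voxel_size` mm), the excited
#' slice thickness in sub-voxels (`k`, the aspect ratio), the number of shots
#' `m` and their spacing in seconds, the diffusion-weighting levels, and the
#' knobs specific to each scheme family (rejection threshold for
#' random-overlap schemes, fixed TR and FOV shifting for the references).
#'
#' Defaults reproduce the reference protocol used throughout: a 75 mm FOV at
#' 1.5 mm resolution (`n = 50`), 6 mm slices (`k = 4`), 1000 shots separated
#' by 150 ms, b-values {0.1, 0.5, 0.9, 1.4} ms/um^2, and a 1.5 s
#' slice-averaged-TR rejection threshold.
#'
#' @param n Number of high-resolution through-slice positions.
#' @param k Slice thickness in sub-voxels (aspect ratio), `1 <= k <= n`.
#' @param m Number of shots.
#' @param shot_spacing Time between consecutive shots, seconds.
#' @param voxel_size High-resolution sub-voxel size, mm.
#' @param b_levels Strictly increasing non-negative b-values, ms/um^2.
#' @param min_mean_tr Slice-averaged TR rejection threshold for random-overlap
#'   schemes, seconds.
#' @param fixed_tr Informational fixed TR for the reference schemes, seconds
#'   (the realized TR falls out of the tiling and timing; see the vignette).
#' @param n_shifts Number of shifted FOV positions (slice shifting).
#' @param discard_per_fov Shots discarded from analysis at the start of each
#'   shifted FOV block (steady-state settling).
#' @param seed Integer seed driving slice-position and b-value draws.
#' @param profile Optional length-`k` non-negative slice-profile weights;
#'   default is a perfectly rectangular profile (all ones).
#' @return A `scheme_config` list.
#' @examples
#' scheme_config(seed = 1)
#' @export
scheme_config <- function(n = 50L, k = 4L, m = 1000L,
                          shot_spacing = 0.15, voxel_size = 1.5,
                          b_levels = c(0.1, 0.5, 0.9, 1.4),
                          min_mean_tr = 1.5, fixed_tr = NULL,
                          n_shifts = 4L, discard_per_fov = 2L,
                          seed = 1L, profile = NULL) {
  stop_if_not(is_count(n), "`n` must be a positive integer")
  stop_if_not(is_count(k) && k <= n, "`k` must be an integer in [1, n]")
  stop_if_not(is_count(m), "`m` must be a positive integer")
  stop_if_not(is.numeric(shot_spacing) && shot_spacing > 0,
              "`shot_spacing` must be > 0")
  stop_if_not(length(b_levels) >= 1 && all(b_levels >= 0) &&
                all(diff(b_levels) > 0),
              "`b_levels` must be non-empty, non-negative, strictly increasing")
  stop_if_not(is.numeric(min_mean_tr) && min_mean_tr >= 0,
              "`min_mean_tr` must be >= 0")
  stop_if_not(is_count(n_shifts), "`n_shifts` must be a positive integer")
  stop_if_not(is_count(discard_per_fov, min = 0L),
              "`discard_per_fov` must be a non-negative integer")
  if (!is.null(profile)) {
    stop_if_not(length(profile) == k && all(profile >= 0) && any(profile > 0),
                "`profile` must be length k, non-negative, not all zero")
  }
  structure(
    list(n = as.integer(n), k = as.integer(k), m = as.integer(m),
         shot_spacing = shot_spacing, voxel_size = voxel_size,
         b_levels = b_levels, min_mean_tr = min_mean_tr,
         fixed_tr = fixed_tr, n_shifts = as.integer(n_shifts),
         discard_per_fov = as.integer(discard_per_fov),
         seed = as.integer(seed), profile = profile),
    class = "scheme_config"
  )
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("<scheme_config> n =", x$n, " k =", x$k, " m =", x$m,
      " spacing =", x$shot_spacing, "s\n")
  cat("  b-levels:", paste(x$b_levels, collapse = ", "), "ms/um^2",
      " seed:", x$seed, "\n")
  invisible(x)
}
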