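# Ground-truth parameter containers and the randomized piecewise-smooth
# line phantoms used for the accuracy/precision study.

#' Construct a high-resolution parameter column
#'
#' A parameter column holds the four tissue parameters on the
#' high-resolution through-slice grid: baseline signal `S0` (a.u.),
#' diffusivity `D` (um^2/ms), diffusional variance `V` (um^4/ms^2) and
#' longitudinal relaxation time `T1` (s).
#'
#' @param S0,D,V,T1 Equal-length numeric vectors, one value per position.
#' @return A tibble with columns `position` (0-based), `S0`, `D`, `V`, `T1`.
#' @examples
#' param_column(S0 = c(1, 2), D = c(1, 1), V = c(0, 0), T1 = c(1, 2))
#' @export
param_column <- function(S0, D, V, T1) {
  out <- tibble::tibble(position = seq_along(S0) - 1L,
                        S0 = as.numeric(S0), D = as.numeric(D),
                        V = as.numeric(V), T1 = as.numeric(T1))
  check_param_column(out)
  out
}

check_param_column <- function(x) {
  stop_if_not(is.data.frame(x) && all(c("S0", "D", "V", "T1") %in% names(x)),
              "expected a parameter column with columns S0, D, V, T1")
  vals <- unlist(x[c("S0", "D", "V", "T1")], use.names = FALSE)
  stop_if_not(all(is.finite(vals)), "parameter values must be finite")
  stop_if_not(all(x$T1 > 0), "T1 must be > 0")
  stop_if_not(all(x$D > 0), "D must be > 0")
  stop_if_not(all(x$S0 >= 0) && all(x$V >= 0), "S0 and V must be >= 0")
  invisible(x)
}

#' Line-phantom configuration
#'
#' Controls the randomized piecewise-smooth through-plane profiles: the grid
#' length, how many plateaus to draw, the per-parameter value ranges, and the
#' edge-softening moving average. Values are always drawn strictly inside the
#' fit bounds so noiseless recovery is never bound-limited.
#'
#' @param n Number of through-slice positions.
#' @param segments Length-2 integer range for the plateau count (inclusive).
#' @param ranges Named list of length-2 ranges for `S0`, `D`, `V`, `T1`.
#'   Defaults are plausible human-brain tissue spans bracketing white matter,
#'   grey matter and CSF (S0 0.5-3.5 a.u., D 0.5-3.0 um^2/ms, V 0.05-1.5
#'   um^4/ms^2, T1 0.5-4.5 s), strictly inside the fit bounds; they keep the
#'   simulated diffusion signal physically sensible (predominantly decaying
#'   over the sampled b-range) while spanning a wide condition space.
#' @param smooth_width Moving-average radius (sub-voxels) used to soften a
#'   random subset of edges; 0 keeps every edge an exact step.
#' @param smooth_prob Probability that any given interior edge is softened.
#' @param seed Integer seed.
#' @return A `line_phantom_config` list.
#' @export
line_phantom_config <- function(n = 50L, segments = c(2L, 8L),
                                ranges = NULL, smooth_width = 2L,
                                smooth_prob = 0.5, seed = 1L) {
  stop_if_not(is_count(n), "`n` must be a positive integer")
  stop_if_not(length(segments) == 2L && segments[1] >= 1L &&
                segments[2] >= segments[1],
              "`segments` must be an increasing integer pair with min >= 1")
  if (is.null(ranges)) {
    ranges <- list(S0 = c(0.5, 3.5), D = c(0.5, 3.0),
                   V = c(0.05, 1.5), T1 = c(0.5, 4.5))
  }
  stop_if_not(all(c("S0", "D", "V", "T1") %in% names(ranges)),
              "`ranges` needs S0, D, V, T1 entries")
  b <- default_fit_bounds()
  for (p in names(b)) {
    stop_if_not(ranges[[p]][1] >= b[[p]][1] && ranges[[p]][2] <= b[[p]][2],
                paste0("range for ", p, " must lie within the fit bounds"))
  }
  structure(list(n = as.integer(n), segments = as.integer(segments),
                 ranges = ranges[c("S0", "D", "V", "T1")],
                 smooth_width = as.integer(smooth_width),
                 smooth_prob = smooth_prob, seed = as.integer(seed)),
            class = "line_phantom_config")
}

# Partition n positions into nseg plateaus with geometric-ish lengths.
draw_plateau_lengths <- function(n, nseg) {
  if (nseg == 1L) return(n)
  raw <- 1 + rgeom(nseg, prob = min(1, nseg / n))
  len <- pmax(1L, as.integer(round(raw * n / sum(raw))))
  # repair rounding so lengths sum to n, keeping every plateau >= 1
  excess <- sum(len) - n
  while (excess != 0L) {
    if (excess > 0L) {
      i <- which.max(len)
      take <- min(excess, len[i] - 1L)
      if (take == 0L) break
      len[i] <- len[i] - take
      excess <- excess - take
    } else {
      i <- which.min(len)
      len[i] <- len[i] - excess
      excess <- 0L
    }
  }
  len
}

#' Generate a randomized piecewise-smooth line phantom
#'
#' Draws a random segmentation of the grid into plateaus, assigns each
#' plateau independent uniform values per parameter from the configured
#' ranges, and softens a random subset of the edges with a short local moving
#' average. Deterministic for a fixed seed.
#'
#' @param config A [line_phantom_config()].
#' @return A parameter-column tibble (see [param_column()]).
#' @examples
#' line_phantom(line_phantom_config(n = 50, seed = 3))
#' @export
line_phantom <- function(config) {
  stop_if_not(inherits(config, "line_phantom_config"),
              "`config` must be a line_phantom_config")
  n <- config$n
  with_seed(config$seed, {
    nseg <- if (config$segments[1] == config$segments[2]) config$segments[1] else
      sample(seq(config$segments[1], config$segments[2]), 1L)
    nseg <- min(nseg, n)
    len <- draw_plateau_lengths(n, nseg)
    seg_id <- rep(seq_len(nseg), times = len)
    vals <- lapply(config$ranges, function(r) {
      runif(nseg, r[1], r[2])[seg_id]
    })
    if (nseg > 1L && config$smooth_width > 0L) {
      edges <- cumsum(len)[-nseg]                      # last index of each plateau
      soften <- edges[runif(length(edges)) < config$smooth_prob]
      r <- config$smooth_width
      for (e in soften) {
        span <- max(1L, e - r + 1L):min(n, e + r)
        for (p in names(vals)) {
          sm <- vapply(span, function(i) {
            mean(vals[[p]][max(1L, i - r):min(n, i + r)])
          }, numeric(1))
          vals[[p]][span] <- sm
        }
      }
    }
    param_column(S0 = vals$S0, D = vals$D, V = vals$V, T1 = vals$T1)
  })
}
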