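# File I/O: schemes as per-shot CSV + JSON config sidecar (dense W/TR are
# re-derived on load, never stored), parameter columns as CSV, parameter
# volumes as one NIfTI per map, plus a provenance record for reproducible
# runs.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a sampling scheme to CSV (+ JSON sidecar)
#'
#' One row per shot (`shot`, `time_s`, `start_index`, `k`, `b_ms_per_um2`,
#' `analysis_mask`) with the scheme configuration in a JSON sidecar next to
#' the CSV. Dense W/TR matrices are derived quantities and are not stored; a
#' checksum of the TR matrix is recorded so re-derivation can be validated.
#'
#' @param scheme A `sero_scheme`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  cfg <- scheme_config_of(scheme)
  # nanosecond rounding keeps repeated write/read/write cycles byte-stable
  df <- tibble::tibble(shot = scheme$shot, time_s = round(scheme$time_s, 9),
                       start_index = scheme$start_index, k = scheme$k,
                       b_ms_per_um2 = scheme$b,
                       analysis_mask = scheme$analysis_mask)
  readr::write_csv(df, path)
  sidecar <- list(config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                  method = attr(scheme, "method"),
                  tr_checksum = tr_checksum(scheme))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

tr_checksum <- function(scheme) {
  cfg <- scheme_config_of(scheme)
  tr <- compute_tr_matrix(scheme$start_index, scheme$time_s, cfg$k, cfg$n)$TR
  round(sum(tr, na.rm = TRUE), 6)
}

#' Read a sampling scheme written by [write_scheme()]
#'
#' Re-derives W and TR from the per-shot table and validates the TR checksum
#' recorded in the sidecar. A file lacking `analysis_mask` defaults to
#' all-`TRUE` with a warning. Start indices outside the FOV are rejected
#' with a position-specific error.
#'
#' @param path CSV path (sidecar expected alongside).
#' @return A `sero_scheme`.
#' @export
read_scheme <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  cfgl <- side$config
  cfg <- scheme_config(n = cfgl$n, k = cfgl$k, m = cfgl$m,
                       shot_spacing = cfgl$shot_spacing,
                       voxel_size = cfgl$voxel_size,
                       b_levels = cfgl$b_levels,
                       min_mean_tr = cfgl$min_mean_tr,
                       fixed_tr = cfgl$fixed_tr,
                       n_shifts = cfgl$n_shifts,
                       discard_per_fov = cfgl$discard_per_fov,
                       seed = cfgl$seed)
  required <- c("shot", "time_s", "start_index", "k", "b_ms_per_um2")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("scheme file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(df$start_index < 0 | df$start_index > cfg$n - 1L)
  if (length(bad)) {
    abort(sprintf("invalid start_index at row %d: %d (allowed 0..%d)",
                  bad[1], df$start_index[bad[1]], cfg$n - 1L))
  }
  if (!"analysis_mask" %in% names(df)) {
    warn("scheme file has no analysis_mask column; defaulting to all TRUE")
    df$analysis_mask <- TRUE
  }
  scheme <- new_scheme(
    tibble::tibble(shot = as.integer(df$shot), time_s = df$time_s,
                   start_index = as.integer(df$start_index),
                   k = as.integer(df$k), b = df$b_ms_per_um2,
                   analysis_mask = as.logical(df$analysis_mask)),
    cfg, side$method %||% "unknown")
  if (!is.null(side$tr_checksum) &&
      abs(tr_checksum(scheme) - side$tr_checksum) > 1e-4) {
    abort("TR re-derivation does not match the stored checksum")
  }
  scheme
}

#' Write/read signals as CSV with a JSON sidecar
#'
#' @param signals A `shot_signals` tibble.
#' @param path Output CSV path.
#' @param scheme_ref Optional scheme file reference recorded in the sidecar.
#' @return `path` invisibly; `read_signals()` returns a `shot_signals`.
#' @export
write_signals <- function(signals, path, scheme_ref = NULL) {
  readr::write_csv(tibble::tibble(shot = signals$shot,
                                  signal = signals$signal), path)
  jsonlite::write_json(
    list(sigma = attr(signals, "sigma"),
         noiseless = attr(signals, "noiseless"),
         seed = attr(signals, "seed"), scheme = scheme_ref),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  new_shot_signals(df$signal, sigma = side$sigma %||% 0,
                   noiseless = isTRUE(side$noiseless), seed = side$seed)
}

#' Write/read a parameter column as CSV
#'
#' Columns `position`, `S0`, `D`, `V`, `T1`.
#'
#' @param params Parameter-column tibble.
#' @param path CSV path.
#' @return `path` invisibly; `read_param_column()` returns the tibble.
#' @export
write_param_column <- function(params, path) {
  check_param_column(params)
  readr::write_csv(params, path)
  invisible(path)
}

#' @rdname write_param_column
#' @export
read_param_column <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- param_column(S0 = df$S0, D = df$D, V = df$V, T1 = df$T1)
  if ("position" %in% names(df)) out$position <- as.integer(df$position)
  out
}

#' Write/read parameter maps as NIfTI (one file per parameter)
#'
#' Voxel size is stored in the NIfTI header (mm); the through-slice axis is
#' axis 3 and is declared in an accompanying JSON sidecar.
#'
#' @param maps Named list of 3D arrays (e.g. `volume$maps` or
#'   `fit_volume()$maps`).
#' @param dir Output directory (created if needed).
#' @param voxel_size Isotropic voxel size in mm.
#' @return The directory, invisibly; `read_param_maps()` returns a named
#'   list of arrays with a `voxel_size` attribute.
#' @export
write_param_maps <- function(maps, dir, voxel_size = 1.5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in names(maps)) {
    img <- RNifti::asNifti(maps[[p]])
    RNifti::pixdim(img) <- rep(voxel_size, 3)
    RNifti::writeNifti(img, file.path(dir, paste0(p, ".nii.gz")))
  }
  jsonlite::write_json(list(voxel_size_mm = voxel_size, through_slice_axis = 3,
                            parameters = names(maps)),
                       file.path(dir, "maps.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_param_maps
#' @export
read_param_maps <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  maps <- lapply(side$parameters, function(p) {
    img <- RNifti::readNifti(file.path(dir, paste0(p, ".nii.gz")))
    arr <- array(as.numeric(img), dim = dim(img))
    arr
  })
  names(maps) <- side$parameters
  attr(maps, "voxel_size") <- side$voxel_size_mm
  maps
}

#' Provenance record for a reproducible run
#'
#' Records package version, R version, the global seed, named substream
#' seeds, the configuration echo and a wall-clock stamp (informational
#' only), as JSON.
#'
#' @param config Named list echoed verbatim into the record.
#' @param seed Global seed of the run.
#' @param substreams Character vector of substream names to record derived
#'   seeds for.
#' @param path Optional JSON output path.
#' @return The provenance list, invisibly if written to `path`.
#' @export
provenance_record <- function(config, seed, substreams = character(), path = NULL) {
  rec <- list(
    package = "serosrr",
    version = as.character(utils::packageVersion("serosrr")),
    r_version = R.version.string,
    seed = seed,
    substream_seeds = setNames(
      lapply(substreams, function(s) derive_seed(seed, s, 0L)), substreams),
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rec))
  }
  rec
}
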