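# Procedural brain-like labelled phantom: nested smoothly-deformed
# ellipsoids (background / CSF / cortical ribbon / WM core) with a
# user-editable per-tissue parameter table, plus block-letter inscription
# for legibility scoring. The geometry is synthetic and serves only to
# provide realistic nested tissue contrast, not anatomy.

#' Default per-tissue parameter table
#'
#' Plausible tissue values declared as configuration (not ground truth):
#' edit freely and pass to [brain_phantom()]. All values lie inside the fit
#' bounds.
#'
#' @return Tibble with columns `tissue`, `label`, `S0`, `D`, `V`, `T1`.
#' @export
default_tissue_params <- function() {
  tibble::tribble(
    ~tissue, ~label, ~S0,  ~D,   ~V,   ~T1,
    "csf",   1L,     3.2,  2.9,  0.2,  3.9,
    "gm",    2L,     2.6,  0.9,  0.9,  1.4,
    "wm",    3L,     2.2,  0.75, 0.5,  0.8
  )
}

# Smoothly perturbed ellipsoid membership: returns an array of "radial"
# coordinates (<= 1 inside). Perturbation is a low-order angular cosine
# field, seeded once per phantom so nested shells share the deformation.
ellipsoid_rho <- function(shape, center, radii, wobble) {
  ax <- lapply(1:3, function(d) (seq_len(shape[d]) - center[d]) / radii[d])
  x <- array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape)
  y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape)
  z <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  rho <- sqrt(x^2 + y^2 + z^2)
  theta <- atan2(y, x)
  phi <- atan2(sqrt(x^2 + y^2), z)
  bump <- wobble$a1 * cos(2 * theta + wobble$p1) +
    wobble$a2 * cos(3 * phi + wobble$p2) +
    wobble$a3 * cos(2 * phi + theta + wobble$p3)
  rho / (1 + bump)
}

#' Generate a procedural labelled brain-like phantom
#'
#' Builds nested smooth regions (background, CSF shell, cortical grey-matter
#' ribbon, white-matter core) from randomly deformed ellipsoids on a regular
#' grid and fills each tissue with the values from `tissue_params`.
#' Background voxels have `S0 = 0` (and nominal positive `D`/`T1` so the
#' container invariants hold; they carry no signal).
#'
#' @param shape Length-3 integer grid size; axis 3 is the through-slice axis.
#' @param voxel_size Isotropic voxel size, mm.
#' @param tissue_params Per-tissue parameter table, see
#'   [default_tissue_params()].
#' @param seed Integer seed for the shape deformation.
#' @return A `param_volume`: list with `maps` (3D arrays `S0`, `D`, `V`,
#'   `T1`), integer `labels` (0 = background), `voxel_size`, `tissue_params`,
#'   and `letter_masks` (filled by [inscribe_letters()]).
#' @examples
#' vol <- brain_phantom(shape = c(16, 16, 12), seed = 1)
#' table(vol$labels)
#' @export
brain_phantom <- function(shape = c(32L, 32L, 50L), voxel_size = 1.5,
                          tissue_params = default_tissue_params(),
                          seed = 1L) {
  stop_if_not(length(shape) == 3L && all(shape >= 4L),
              "`shape` must be three dimensions of at least 4 voxels")
  stop_if_not(all(c("tissue", "label", "S0", "D", "V", "T1") %in%
                    names(tissue_params)),
              "`tissue_params` needs tissue, label, S0, D, V, T1 columns")
  shape <- as.integer(shape)
  center <- (shape + 1) / 2
  radii <- shape / 2 * 0.92
  wobble <- with_seed(seed, list(
    a1 = runif(1, 0.02, 0.06), a2 = runif(1, 0.02, 0.06),
    a3 = runif(1, 0.01, 0.04),
    p1 = runif(1, 0, 2 * pi), p2 = runif(1, 0, 2 * pi),
    p3 = runif(1, 0, 2 * pi)
  ))
  rho <- ellipsoid_rho(shape, center, radii, wobble)
  labels <- array(0L, dim = shape)
  labels[rho <= 1.00] <- tissue_params$label[tissue_params$tissue == "csf"]
  labels[rho <= 0.90] <- tissue_params$label[tissue_params$tissue == "gm"]
  labels[rho <= 0.68] <- tissue_params$label[tissue_params$tissue == "wm"]
  maps <- list(
    S0 = array(0, dim = shape),
    D = array(1, dim = shape),      # nominal in background; S0 = 0 there
    V = array(0, dim = shape),
    T1 = array(1, dim = shape)
  )
  for (i in seq_len(nrow(tissue_params))) {
    sel <- labels == tissue_params$label[i]
    for (p in c("S0", "D", "V", "T1")) {
      maps[[p]][sel] <- tissue_params[[p]][i]
    }
  }
  structure(list(maps = maps, labels = labels, voxel_size = voxel_size,
                 tissue_params = tissue_params, letter_masks = list()),
            class = "param_volume")
}

#' @export
print.param_volume <- function(x, ...) {
  cat("<param_volume>", paste(dim(x$labels), collapse = " x "),
      "voxels @", x$voxel_size, "mm;",
      sum(x$labels != 0L), "support voxels;",
      length(x$letter_masks), "letter mask(s)\n")
  invisible(x)
}

# Fixed built-in 5x7 block font (subset). Rows are top-to-bottom.
block_font <- function() {
  list(
    L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    U = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
    R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    I = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####")
  )
}

# Rasterize text at integer scale: logical matrix, rows = vertical (7*scale),
# cols = horizontal (letters * 6*scale - scale).
rasterize_text <- function(text, scale = 1L) {
  font <- block_font()
  chars <- strsplit(toupper(text), "")[[1]]
  stop_if_not(all(chars %in% names(font)),
              paste0("unsupported character(s): only ",
                     paste(names(font), collapse = ""), " are in the font"))
  glyphs <- lapply(chars, function(ch) {
    g <- font[[ch]]
    m <- do.call(rbind, lapply(g, function(row) strsplit(row, "")[[1]] == "#"))
    m
  })
  spacer <- matrix(FALSE, 7L, 1L)
  full <- glyphs[[1]]
  for (g in glyphs[-1]) full <- cbind(full, spacer, g)
  full[rep(seq_len(nrow(full)), each = scale),
       rep(seq_len(ncol(full)), each = scale), drop = FALSE]
}

#' Inscribe block letters into a parameter volume
#'
#' Rasterizes `text` with the built-in 5x7 block font at each
#' (location, size) pair and perturbs the parameter maps inside the letter
#' masks by a multiplicative contrast rule (default: D and T1). Letters lie
#' in the x-z plane (strokes vary along the through-slice axis, so
#' through-slice blurring degrades their legibility) and are extruded over
#' `thickness` voxels in y. Masks are retained on the volume for downstream
#' legibility scoring and must fit inside the volume and not overlap.
#'
#' @param volume A `param_volume`.
#' @param text Character string (supported letters: see [brain_phantom()]
#'   source font).
#' @param locations List of length-3 integer voxel coordinates, one per
#'   inscription: the (x, y, z) corner where the raster starts.
#' @param sizes Integer scale factors (sub-voxels per font pixel), one per
#'   location.
#' @param contrast_rule Named multiplicative offsets applied inside the mask
#'   (subset of S0, D, V, T1).
#' @param thickness Extrusion depth in y, voxels.
#' @return The modified `param_volume` with `letter_masks` filled.
#' @export
inscribe_letters <- function(volume, text, locations, sizes,
                             contrast_rule = c(D = 1.6, T1 = 1.5),
                             thickness = 3L) {
  stop_if_not(inherits(volume, "param_volume"), "`volume` must be a param_volume")
  if (!nzchar(text)) return(volume)
  stop_if_not(length(locations) == length(sizes),
              "`locations` and `sizes` must have equal length")
  shape <- dim(volume$labels)
  masks <- list()
  for (i in seq_along(locations)) {
    ras <- rasterize_text(text, as.integer(sizes[i]))
    loc <- as.integer(locations[[i]])
    nx <- ncol(ras); nz <- nrow(ras)
    xs <- loc[1] + seq_len(nx) - 1L
    ys <- loc[2] + seq_len(thickness) - 1L
    zs <- loc[3] + seq_len(nz) - 1L
    if (min(xs) < 1L || max(xs) > shape[1] || min(ys) < 1L ||
        max(ys) > shape[2] || min(zs) < 1L || max(zs) > shape[3]) {
      abort(sprintf("letter mask %d exceeds volume bounds", i))
    }
    mask <- array(FALSE, dim = shape)
    # raster rows (top of glyph) map to increasing z
    for (r in seq_len(nz)) {
      cols <- which(ras[r, ])
      if (length(cols)) mask[xs[cols], ys, zs[r]] <- TRUE
    }
    masks[[i]] <- mask
  }
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]])) {
        abort("letter masks overlap; choose disjoint locations/sizes")
      }
    }
  }
  for (mask in masks) {
    for (p in names(contrast_rule)) {
      volume$maps[[p]][mask] <- volume$maps[[p]][mask] * contrast_rule[[p]]
    }
  }
  # keep every parameter inside the fit bounds after perturbation
  b <- default_fit_bounds()
  for (p in names(contrast_rule)) {
    volume$maps[[p]] <- pmin(pmax(volume$maps[[p]], b[[p]][1]), b[[p]][2])
  }
  volume$letter_masks <- c(volume$letter_masks, masks)
  volume
}

#' Letter-legibility contrast statistic
#'
#' Mean absolute difference between in-mask values and the mean of nearby
#' out-of-mask support values, per parameter map. Positive contrast means the
#' inscription is distinguishable from its surroundings.
#'
#' @param maps Named list of 3D parameter arrays.
#' @param masks List of logical letter masks (e.g. `volume$letter_masks`).
#' @param support Logical array of object support (non-background voxels).
#' @return Tibble with columns `parameter`, `contrast`.
#' @export
letter_contrast <- function(maps, masks, support) {
  all_mask <- Reduce(`|`, masks)
  out_mask <- support & !all_mask
  purrr::map_dfr(names(maps), function(p) {
    tibble::tibble(
      parameter = p,
      contrast = abs(mean(maps[[p]][all_mask], na.rm = TRUE) -
                       mean(maps[[p]][out_mask], na.rm = TRUE))
    )
  })
}
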