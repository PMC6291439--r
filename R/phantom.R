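#' Digital renal phantom specification
#'
#' Describes a 3D digital phantom with two ellipsoidal kidneys, each split
#' into a cortical shell and a medullary core, on a regular voxel grid. The
#' default grid (16 coronal sections of 32 x 64 voxels at 4 x 4.7 x 4.7 mm)
#' matches a 64 x 150 x 300 mm abdominal field of view; the first array axis
#' is the slice (coronal) axis. Default tissue values are typical healthy
#' renal parameters: cortical perfusion 190 and medullary 170 ml/min/100 g,
#' bolus arrival times 290/185 ms and tissue T1 790/805 ms.
#'
#' Each kidney is an ellipsoid given by its `center` and `semi_axes` in
#' (fractional) voxel coordinates. The medulla is obtained either by eroding
#' the whole-kidney mask in-plane by `cortex_depth` voxels (the default,
#' mirroring an outer-shell cortex definition) or, if a kidney descriptor
#' carries a `medulla_semi_axes` entry, as an inner ellipsoid around the
#' same center.
#'
#' @param grid_shape integer vector of voxels per axis (slice, x, y).
#' @param voxel_size_mm physical voxel size per axis, mm.
#' @param kidneys list of two kidney descriptors, each a list with `center`,
#'   `semi_axes` and optionally `medulla_semi_axes` (voxel units).
#' @param cortex_depth cortical shell thickness in voxels (in-plane
#'   erosion depth used when `medulla_semi_axes` is absent).
#' @param tissue data.frame with one row per compartment (`cortex`,
#'   `medulla`, `background`) and columns `f` (ml/min/100 g), `bat` (ms),
#'   `t1` (ms), `m0` (arbitrary signal units).
#' @param noise_sd standard deviation of the additive Gaussian noise applied
#'   to each control and label image, as a fraction of the cortical `m0`.
#' @param n_averages number of control/label repeats per TI.
#' @param seed integer seed driving all randomness of the simulator.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' spec$tissue
#' @export
phantom_spec <- function(grid_shape = c(16, 32, 64),
                         voxel_size_mm = c(4, 4.7, 4.7),
                         kidneys = default_kidneys(grid_shape),
                         cortex_depth = 3,
                         tissue = default_tissue(),
                         noise_sd = 0.005,
                         n_averages = 4,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape <= 0)) {
    stop("'grid_shape' must be three positive integers")
  }
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    stop("'voxel_size_mm' must be three positive sizes")
  }
  if (length(kidneys) != 2) stop("exactly two kidney descriptors required")
  for (k in kidneys) {
    if (is.null(k$center) || is.null(k$semi_axes) ||
        length(k$center) != 3 || length(k$semi_axes) != 3) {
      stop("each kidney needs 3-vector 'center' and 'semi_axes'")
    }
    if (any(k$semi_axes < 0)) stop("kidney semi-axes must be >= 0")
    if (!is.null(k$medulla_semi_axes) &&
        (length(k$medulla_semi_axes) != 3 || any(k$medulla_semi_axes < 0))) {
      stop("'medulla_semi_axes' must be three values >= 0")
    }
  }
  req <- c("cortex", "medulla", "background")
  if (!all(req %in% tissue$compartment)) {
    stop("'tissue' must contain rows for cortex, medulla and background")
  }
  if (any(tissue$f < 0) || any(tissue$bat < 0) || any(tissue$t1 <= 0)) {
    stop("tissue parameters must satisfy f >= 0, bat >= 0, t1 > 0")
  }
  if (cortex_depth < 0) stop("'cortex_depth' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_averages < 1) stop("'n_averages' must be >= 1")
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         kidneys = kidneys, cortex_depth = as.integer(cortex_depth),
         tissue = tissue, noise_sd = noise_sd,
         n_averages = as.integer(n_averages), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default two-kidney geometry for a given grid
#'
#' Places two non-overlapping ellipsoids (roughly 11 x 6 x 5 cm kidneys)
#' symmetrically about the head-foot midline of the grid.
#'
#' @param grid_shape voxels per axis (slice, x, y).
#' @return List of two kidney descriptors.
#' @export
default_kidneys <- function(grid_shape = c(16, 32, 64)) {
  g <- grid_shape
  semi <- c(0.30 * g[1], 0.19 * g[2], 0.18 * g[3])
  list(
    list(center = c(g[1] / 2 + 0.5, g[2] / 2 + 0.5, g[3] * 0.30),
         semi_axes = semi),
    list(center = c(g[1] / 2 + 0.5, g[2] / 2 + 0.5, g[3] * 0.70),
         semi_axes = semi)
  )
}

#' Default phantom tissue parameters
#'
#' Typical healthy renal values: cortex f = 190, medulla f = 170
#' ml/min/100 g; BAT 290/185 ms; T1 790/805 ms; non-perfused background
#' with T1 = 900 ms.
#'
#' @return data.frame with columns compartment, f, bat, t1, m0.
#' @export
default_tissue <- function() {
  data.frame(
    compartment = c("cortex", "medulla", "background"),
    f = c(190, 170, 0),
    bat = c(290, 185, 0),
    t1 = c(790, 805, 900),
    m0 = c(1, 1, 0.8),
    stringsAsFactors = FALSE
  )
}

# logical ellipsoid mask on the voxel grid (1-based voxel centers)
.ellipsoid_mask <- function(grid_shape, center, semi_axes) {
  if (any(semi_axes == 0)) return(array(FALSE, dim = grid_shape))
  i <- (seq_len(grid_shape[1]) - center[1]) / semi_axes[1]
  j <- (seq_len(grid_shape[2]) - center[2]) / semi_axes[2]
  k <- (seq_len(grid_shape[3]) - center[3]) / semi_axes[3]
  d2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(d2 <= 1, dim = grid_shape)
}

#' Build the ground-truth phantom volumes
#'
#' Deterministically constructs the per-voxel true parameter maps and the
#' whole-kidney / cortex / medulla masks from a [phantom_spec()]. Cortex and
#' medulla are disjoint and their union is the whole-kidney mask.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ground_truth`: list with `f_map`, `bat_map`,
#'   `t1_map`, `m0_map` (3D arrays) and `masks` (logical arrays `whole`,
#'   `cortex`, `medulla`), plus the generating `spec`.
#' @examples
#' gt <- make_phantom(phantom_spec(grid_shape = c(8, 16, 32)))
#' sum(gt$masks$whole)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  wholes <- lapply(spec$kidneys, function(k)
    .ellipsoid_mask(g, k$center, k$semi_axes))
  if (any(wholes[[1]] & wholes[[2]])) {
    stop("invalid phantom spec: kidney ellipsoids overlap")
  }
  medullas <- mapply(function(k, w) {
    if (!is.null(k$medulla_semi_axes)) {
      m <- .ellipsoid_mask(g, k$center, k$medulla_semi_axes)
      m & w
    } else {
      .erode_inplane(w, spec$cortex_depth)
    }
  }, spec$kidneys, wholes, SIMPLIFY = FALSE)
  whole <- wholes[[1]] | wholes[[2]]
  medulla <- medullas[[1]] | medullas[[2]]
  cortex <- whole & !medulla

  tt <- spec$tissue
  row <- function(comp) tt[tt$compartment == comp, , drop = FALSE]
  fill <- function(col) {
    v <- array(row("background")[[col]], dim = g)
    v[cortex] <- row("cortex")[[col]]
    v[medulla] <- row("medulla")[[col]]
    v
  }
  structure(
    list(f_map = fill("f"), bat_map = fill("bat"), t1_map = fill("t1"),
         m0_map = fill("m0"),
         masks = list(whole = whole, cortex = cortex, medulla = medulla),
         spec = spec),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("digital renal phantom: grid %s, %d kidney voxels (%d cortex, %d medulla)\n",
              paste(dim(x$f_map), collapse = " x "),
              sum(x$masks$whole), sum(x$masks$cortex), sum(x$masks$medulla)))
  invisible(x)
}

# deterministic child seed for independent random streams
.derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 11 * stream) %% 2147483647)
}

#' Simulate a multi-TI ASL acquisition of a phantom
#'
#' For every inversion time and signal average, generates a control and a
#' label image. The noise-free control is the tissue M0 map; the noise-free
#' label is M0 minus the GKM difference signal \eqn{\Delta M(TI)} computed
#' voxel-wise from the true (f, BAT, T1), so that the expectation of
#' control - label equals the kinetic forward model. Independent zero-mean
#' Gaussian noise of sd `noise_sd * cortical m0` is added to every control,
#' label and the M0 calibration volume.
#'
#' @param truth a [make_phantom()] result.
#' @param spec the generating [phantom_spec()] (noise, averages, seed).
#' @param protocol an [asl_protocol()].
#' @param seed optional override of `spec$seed`.
#' @return An object of class `asl_acquisition`: list with `controls` and
#'   `labels` (5D arrays: x, y, z, TI, average), `m0` (3D), `protocol`,
#'   `voxel_size_mm`.
#' @export
simulate_acquisition <- function(truth, spec, protocol, seed = spec$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "phantom_spec"),
            inherits(protocol, "asl_protocol"))
  g <- spec$grid_shape
  nti <- length(protocol$ti)
  nav <- spec$n_averages
  dm_true <- forward_model_volume(truth, protocol)

  sd_abs <- spec$noise_sd *
    spec$tissue$m0[spec$tissue$compartment == "cortex"]
  nvox <- prod(g)
  controls <- array(0, dim = c(g, nti, nav))
  labels <- array(0, dim = c(g, nti, nav))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  for (a in seq_len(nav)) {
    for (ti_i in seq_len(nti)) {
      controls[, , , ti_i, a] <- truth$m0_map +
        array(stats::rnorm(nvox, 0, sd_abs), dim = g)
      labels[, , , ti_i, a] <- truth$m0_map - dm_true[, , , ti_i] +
        array(stats::rnorm(nvox, 0, sd_abs), dim = g)
    }
  }
  m0 <- truth$m0_map + array(stats::rnorm(nvox, 0, sd_abs), dim = g)
  structure(
    list(controls = controls, labels = labels, m0 = m0,
         protocol = protocol, voxel_size_mm = spec$voxel_size_mm),
    class = "asl_acquisition"
  )
}

#' Noise-free forward-model difference signal of a phantom
#'
#' Evaluates the closed-form GKM signal at every voxel and TI from the true
#' parameter maps. Exploits the piecewise-constant phantom: the model is
#' evaluated once per distinct (f, bat, t1, m0) combination.
#'
#' @param truth a [make_phantom()] result.
#' @param protocol an [asl_protocol()].
#' @return 4D array (x, y, z, TI) of \eqn{\Delta M}.
#' @export
forward_model_volume <- function(truth, protocol) {
  g <- dim(truth$f_map)
  nti <- length(protocol$ti)
  key <- paste(truth$f_map, truth$bat_map, truth$t1_map, truth$m0_map)
  groups <- split(seq_along(key), key)
  dm <- array(0, dim = c(g, nti))
  flat <- matrix(dm, nrow = prod(g), ncol = nti)
  for (idx in groups) {
    v <- idx[1]
    f <- truth$f_map[v]
    if (f == 0) next
    sig <- gkm_signal(protocol$ti,
                      tissue_params(f, truth$bat_map[v], truth$t1_map[v]),
                      protocol,
                      m0b = m0_blood(truth$m0_map[v], protocol))
    flat[idx, ] <- matrix(sig, nrow = length(idx), ncol = nti, byrow = TRUE)
  }
  array(flat, dim = c(g, nti))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
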