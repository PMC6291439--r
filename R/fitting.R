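#' Build a perfusion-weighted series from control/label stacks
#'
#' The perfusion-weighted image (PWI) at each inversion time is the mean
#' over signal averages of control - label. Co-registration of control,
#' label and M0 volumes is assumed to have been done upstream.
#'
#' @param controls,labels 5D arrays (x, y, z, TI, average) or 4D arrays for
#'   a single average; equal numbers of control and label repeats per TI.
#' @param m0 3D calibration volume of tissue equilibrium magnetization.
#' @param protocol an [asl_protocol()]; its TI count must match the 4th
#'   dimension.
#' @param voxel_size_mm physical voxel size, carried as geometry metadata.
#' @return An object of class `pwi_series`: list with `dm` (4D), `m0`,
#'   `protocol`, `voxel_size_mm`.
#' @export
build_pwi <- function(controls, labels, m0, protocol,
                      voxel_size_mm = c(4, 4.7, 4.7)) {
  if (length(dim(controls)) == 4) dim(controls) <- c(dim(controls), 1)
  if (length(dim(labels)) == 4) dim(labels) <- c(dim(labels), 1)
  if (!identical(dim(controls), dim(labels))) {
    stop("control and label stacks must have identical shape")
  }
  d <- dim(controls)
  if (!identical(d[1:3], dim(m0))) {
    stop("M0 volume shape does not match the control/label stacks")
  }
  if (d[4] != length(protocol$ti)) {
    stop(sprintf("stack has %d TI frames but the protocol lists %d TIs",
                 d[4], length(protocol$ti)))
  }
  diff <- controls - labels
  dm <- apply(diff, 1:4, mean)
  structure(list(dm = dm, m0 = m0, protocol = protocol,
                 voxel_size_mm = voxel_size_mm),
            class = "pwi_series")
}

#' Convert a simulated acquisition to a PWI series
#'
#' @param acq an `asl_acquisition` from [simulate_acquisition()].
#' @return A [build_pwi()] result.
#' @export
as_pwi <- function(acq) {
  stopifnot(inherits(acq, "asl_acquisition"))
  build_pwi(acq$controls, acq$labels, acq$m0, acq$protocol,
            acq$voxel_size_mm)
}

#' @export
print.pwi_series <- function(x, ...) {
  d <- dim(x$dm)
  cat(sprintf("PWI series: %s voxels x %d TIs (%g-%g ms)\n",
              paste(d[1:3], collapse = " x "), d[4],
              min(x$protocol$ti), max(x$protocol$ti)))
  invisible(x)
}

#' Fit settings for voxel-wise kinetic-model fitting
#'
#' Bounds are generous physiological envelopes around healthy renal values.
#' Voxels whose M0 falls below `m0_floor_frac` of the 99th percentile of
#' the in-mask M0 are skipped to avoid calibration blow-ups from
#' near-signal-free voxels.
#'
#' @param f_bounds perfusion bounds, ml/min/100 g.
#' @param bat_bounds bolus-arrival-time bounds, ms.
#' @param t1_bounds tissue T1 bounds, ms.
#' @param ftol relative residual-sum-of-squares convergence tolerance.
#' @param max_iter maximum optimizer iterations.
#' @param m0_floor_frac M0 floor as a fraction of the robust (99th
#'   percentile) in-mask maximum.
#' @param n_starts 1 (default) or 3; with 3 the fit is restarted from the
#'   initial BAT shifted by one TI step either way and the lowest-residual
#'   solution is kept (useful for noisy voxels).
#' @param t1_init initial tissue T1, ms.
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(f_bounds = c(0, 1000),
                         bat_bounds = c(0, 1500),
                         t1_bounds = c(200, 3000),
                         ftol = 1e-10,
                         max_iter = 200,
                         m0_floor_frac = 0.05,
                         n_starts = 1,
                         t1_init = 800) {
  for (b in list(f_bounds, bat_bounds, t1_bounds)) {
    if (length(b) != 2 || b[1] >= b[2]) stop("bounds must satisfy lower < upper")
  }
  if (ftol <= 0) stop("'ftol' must be > 0")
  if (!n_starts %in% c(1, 3)) stop("'n_starts' must be 1 or 3")
  structure(list(f_bounds = f_bounds, bat_bounds = bat_bounds,
                 t1_bounds = t1_bounds, ftol = ftol,
                 max_iter = as.integer(max_iter),
                 m0_floor_frac = m0_floor_frac,
                 n_starts = as.integer(n_starts), t1_init = t1_init),
            class = "fit_settings")
}

#' Initial parameter guess for a voxel curve
#'
#' Heuristic start for the nonlinear fit: the initial BAT is the largest TI,
#' before the curve maximum, at which the signal is still below 20% of that
#' maximum (0 if the curve is maximal at the first TI); the initial
#' perfusion comes from the single-TI estimator at the TI nearest the
#' protocol's single TI; the initial T1 is `t1_init`. A curve that is
#' everywhere non-positive is flagged unfittable.
#'
#' @param dm_curve numeric vector of \eqn{\Delta M} per TI (>= 4 points).
#' @param m0_value tissue M0 at the voxel.
#' @param protocol an [asl_protocol()].
#' @param t1_init initial T1 (ms).
#' @return List with `f`, `bat`, `t1` and logical `fittable`.
#' @export
init_params <- function(dm_curve, m0_value, protocol, t1_init = 800) {
  ti <- protocol$ti
  if (length(dm_curve) != length(ti)) stop("curve/TI length mismatch")
  if (length(dm_curve) < 4) stop("need at least 4 points")
  mx <- max(dm_curve)
  if (!is.finite(mx) || mx <= 0) {
    return(list(f = NA_real_, bat = NA_real_, t1 = NA_real_,
                fittable = FALSE))
  }
  i_max <- which.max(dm_curve)
  low <- which(dm_curve[seq_len(i_max)] < 0.2 * mx)
  bat0 <- if (length(low)) ti[max(low)] else 0
  i_sti <- which.min(abs(ti - protocol$single_ti))
  f0 <- single_ti_perfusion(dm_curve[i_sti] / m0_value, ti[i_sti], protocol)
  list(f = f0, bat = bat0, t1 = t1_init, fittable = TRUE)
}

# residual vector for the bounded least-squares fit; par = (f, bat, t1)
.gkm_residuals <- function(par, dm_curve, ti, protocol, m0b) {
  sig <- gkm_signal(ti, tissue_params(par[1], par[2], par[3]),
                    protocol, m0b)
  dm_curve - sig
}

#' Fit the kinetic model to a single voxel curve
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()])
#' of the closed-form GKM signal to a measured \eqn{\Delta M(TI)} curve,
#' over (f, BAT, T1), started from [init_params()].
#'
#' @param dm_curve \eqn{\Delta M} per TI.
#' @param m0_value tissue M0 at the voxel (above the floor).
#' @param protocol an [asl_protocol()].
#' @param settings a [fit_settings()].
#' @return List with `params` ([tissue_params()] or `NULL`), `rss`,
#'   `converged`, `fittable`.
#' @export
fit_voxel <- function(dm_curve, m0_value, protocol,
                      settings = fit_settings()) {
  ini <- init_params(dm_curve, m0_value, protocol, settings$t1_init)
  if (!ini$fittable) {
    return(list(params = NULL, rss = NA_real_, converged = FALSE,
                fittable = FALSE))
  }
  m0b <- m0_blood(m0_value, protocol)
  lower <- c(settings$f_bounds[1], settings$bat_bounds[1],
             settings$t1_bounds[1])
  upper <- c(settings$f_bounds[2], settings$bat_bounds[2],
             settings$t1_bounds[2])
  clamp <- function(p) pmin(pmax(p, lower), upper)
  ti_step <- if (length(protocol$ti) > 1) diff(protocol$ti[1:2]) else 0
  starts <- list(clamp(c(ini$f, ini$bat, ini$t1)))
  if (settings$n_starts == 3) {
    starts <- c(starts,
                list(clamp(c(ini$f, ini$bat - ti_step, ini$t1)),
                     clamp(c(ini$f, ini$bat + ti_step, ini$t1))))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper,
        fn = .gkm_residuals, dm_curve = dm_curve, ti = protocol$ti,
        protocol = protocol, m0b = m0b,
        control = minpack.lm::nls.lm.control(
          ftol = settings$ftol, ptol = settings$ftol,
          maxiter = settings$max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(params = NULL, rss = NA_real_, converged = FALSE,
                fittable = TRUE))
  }
  p <- best$fit$par
  list(params = tissue_params(max(p[1], 0), max(p[2], 0), p[3]),
       rss = best$rss,
       converged = best$fit$info %in% 1:4,
       fittable = TRUE)
}

#' Single-curve GKM model fit
#'
#' Convenience modelling interface around [fit_voxel()] for one measured
#' \eqn{\Delta M(TI)} curve, returning a classed model object with the
#' usual methods (`print`, `summary`, `coef`, `predict`, `residuals`,
#' `plot`, `simulate`).
#'
#' @param dm \eqn{\Delta M} per TI.
#' @param m0 tissue M0 (scalar).
#' @param protocol an [asl_protocol()].
#' @param settings a [fit_settings()].
#' @return An object of class `gkm_fit`.
#' @examples
#' p <- asl_protocol()
#' truth <- tissue_params(190, 290, 790)
#' dm <- gkm_signal(p$ti, truth, p, m0b = m0_blood(1, p))
#' fit <- gkm_fit(dm, m0 = 1, protocol = p)
#' coef(fit)
#' @export
gkm_fit <- function(dm, m0, protocol = asl_protocol(),
                    settings = fit_settings()) {
  res <- fit_voxel(dm, m0, protocol, settings)
  if (!res$fittable || is.null(res$params)) {
    stop("curve is unfittable (non-positive or optimizer failure)")
  }
  structure(list(params = res$params, rss = res$rss,
                 converged = res$converged, dm = dm, m0 = m0,
                 protocol = protocol, settings = settings),
            class = "gkm_fit")
}

#' @export
coef.gkm_fit <- function(object, ...) {
  c(f = object$params$f, bat = object$params$bat, t1 = object$params$t1)
}

#' @export
print.gkm_fit <- function(x, ...) {
  cat("general-kinetic-model fit\n")
  cat(sprintf("  f   = %8.2f ml/min/100 g\n", x$params$f))
  cat(sprintf("  BAT = %8.2f ms\n", x$params$bat))
  cat(sprintf("  T1  = %8.2f ms\n", x$params$t1))
  cat(sprintf("  RSS = %.3e  (%s)\n", x$rss,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.gkm_fit <- function(object, ...) {
  out <- c(coef(object),
           rss = object$rss,
           sigma = sqrt(object$rss / max(1, length(object$dm) - 3)),
           single_ti_f = single_ti_perfusion(
             object$dm[which.min(abs(object$protocol$ti -
                                       object$protocol$single_ti))] /
               object$m0,
             object$protocol$ti[which.min(abs(object$protocol$ti -
                                                object$protocol$single_ti))],
             object$protocol))
  class(out) <- "summary.gkm_fit"
  out
}

#' @export
print.summary.gkm_fit <- function(x, ...) {
  y <- unclass(x)
  cat("GKM curve fit summary\n")
  for (nm in names(y)) cat(sprintf("  %-12s %g\n", nm, y[[nm]]))
  invisible(x)
}

#' @export
predict.gkm_fit <- function(object, t = object$protocol$ti, ...) {
  gkm_signal(t, object$params, object$protocol,
             m0_blood(object$m0, object$protocol))
}

#' @export
residuals.gkm_fit <- function(object, ...) {
  object$dm - predict(object)
}

#' @export
simulate.gkm_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  mu <- predict(object)
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(object$rss / max(1, length(object$dm) - 3))
  }
  out <- replicate(nsim, mu + stats::rnorm(length(mu), 0, noise_sd))
  as.data.frame(out)
}

#' @export
plot.gkm_fit <- function(x, ...) {
  tt <- seq(0, max(x$protocol$ti), length.out = 200)
  graphics::plot(x$protocol$ti, x$dm, xlab = "inversion time (ms)",
                 ylab = expression(Delta * M), ...)
  graphics::lines(tt, predict(x, tt), col = "red")
  invisible(x)
}

#' Voxel-wise kinetic-model fitting of a PWI series
#'
#' Applies [fit_voxel()] to every in-mask voxel whose M0 exceeds the floor,
#' producing parametric maps of perfusion, bolus arrival time and tissue T1
#' together with fit diagnostics, and a single-TI perfusion map from the TI
#' frame nearest the protocol's single TI. Out-of-mask, sub-floor and
#' failed voxels carry `NA` in all maps. The fit is deterministic given its
#' inputs and invariant to joint rescaling of `dm` and `m0`.
#'
#' @param pwi a [build_pwi()] series.
#' @param mask logical 3D array of voxels to fit.
#' @param settings a [fit_settings()].
#' @return An object of class `asl_fit` with elements `f_map`, `bat_map`,
#'   `t1_map`, `rss_map`, `converged_mask` (integer; 1 converged,
#'   0 attempted but not converged, `NA` not attempted), `single_ti_f_map`,
#'   `single_ti_frame`, counts, and the inputs needed by its methods.
#' @examples
#' \donttest{
#' spec <- phantom_spec(grid_shape = c(4, 8, 16), noise_sd = 0)
#' gt <- make_phantom(spec)
#' pwi <- as_pwi(simulate_acquisition(gt, spec, asl_protocol()))
#' fit <- fit_gkm_volume(pwi, gt$masks$whole)
#' fit
#' }
#' @export
fit_gkm_volume <- function(pwi, mask, settings = fit_settings()) {
  stopifnot(inherits(pwi, "pwi_series"))
  g <- dim(pwi$dm)[1:3]
  if (!identical(dim(mask), g)) stop("mask shape does not match the PWI")
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty")
  protocol <- pwi$protocol
  m0_in <- pwi$m0[mask]
  floor_val <- settings$m0_floor_frac *
    stats::quantile(m0_in, 0.99, names = FALSE)
  nti <- length(protocol$ti)
  dm_flat <- matrix(pwi$dm, nrow = prod(g), ncol = nti)

  f_map <- bat_map <- t1_map <- rss_map <- array(NA_real_, dim = g)
  conv <- array(NA_integer_, dim = g)
  idx <- which(mask)
  skipped_floor <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (v in idx) {
    m0v <- pwi$m0[v]
    if (!is.finite(m0v) || m0v < floor_val) {
      skipped_floor <- skipped_floor + 1L
      next
    }
    res <- fit_voxel(dm_flat[v, ], m0v, protocol, settings)
    if (!res$fittable || is.null(res$params)) {
      conv[v] <- 0L
      next
    }
    conv[v] <- as.integer(res$converged)
    if (res$converged) {
      f_map[v] <- res$params$f
      bat_map[v] <- res$params$bat
      t1_map[v] <- res$params$t1
      rss_map[v] <- res$rss
    }
  }
  runtime <- proc.time()[["elapsed"]] - t0

  i_sti <- which.min(abs(protocol$ti - protocol$single_ti))
  sti_map <- array(NA_real_, dim = g)
  fit_idx <- idx[pwi$m0[idx] >= floor_val & is.finite(pwi$m0[idx])]
  sti_map[fit_idx] <- single_ti_perfusion(
    dm_flat[fit_idx, i_sti] / pwi$m0[fit_idx], protocol$ti[i_sti], protocol)

  structure(
    list(f_map = f_map, bat_map = bat_map, t1_map = t1_map,
         rss_map = rss_map, converged_mask = conv,
         single_ti_f_map = sti_map, single_ti_frame = i_sti,
         mask = mask, n_masked = length(idx),
         n_skipped_floor = skipped_floor,
         n_converged = sum(conv == 1L, na.rm = TRUE),
         runtime_s = runtime,
         protocol = protocol, settings = settings, pwi = pwi),
    class = "asl_fit"
  )
}

#' @export
print.asl_fit <- function(x, ...) {
  cat("voxel-wise GKM parametric maps\n")
  cat(sprintf("  grid: %s\n", paste(dim(x$f_map), collapse = " x ")))
  cat(sprintf("  voxels in mask: %d (skipped below M0 floor: %d)\n",
              x$n_masked, x$n_skipped_floor))
  att <- x$n_masked - x$n_skipped_floor
  cat(sprintf("  converged: %d / %d (%.1f%%)\n", x$n_converged, att,
              100 * x$n_converged / max(1, att)))
  cat(sprintf("  runtime: %.1f s\n", x$runtime_s))
  if (x$n_converged > 0) {
    cat(sprintf("  median f = %.1f ml/min/100 g, BAT = %.0f ms, T1 = %.0f ms\n",
                stats::median(x$f_map, na.rm = TRUE),
                stats::median(x$bat_map, na.rm = TRUE),
                stats::median(x$t1_map, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
coef.asl_fit <- function(object, ...) {
  list(f = object$f_map, bat = object$bat_map, t1 = object$t1_map)
}

#' Region summaries of a fitted volume
#'
#' @param object an [fit_gkm_volume()] result.
#' @param seg optional [kidney_segmentation()]; if supplied the summary is
#'   computed per region via [summarize_regions()], otherwise over all
#'   fitted voxels.
#' @param ... unused.
#' @export
summary.asl_fit <- function(object, seg = NULL, ...) {
  if (!is.null(seg)) return(summarize_regions(object, seg))
  v <- !is.na(object$f_map)
  data.frame(
    region = "fitted",
    method = c("multi_ti", "single_ti"),
    mean_f = c(mean(object$f_map[v]),
               mean(object$single_ti_f_map[is.finite(object$single_ti_f_map)])),
    mean_bat = c(mean(object$bat_map[v]), NA),
    mean_t1 = c(mean(object$t1_map[v]), NA),
    n_vox = c(sum(v), sum(is.finite(object$single_ti_f_map))),
    stringsAsFactors = FALSE
  )
}

#' @export
predict.asl_fit <- function(object, t = object$protocol$ti, ...) {
  v <- which(!is.na(object$f_map))
  out <- matrix(NA_real_, nrow = length(v), ncol = length(t))
  for (i in seq_along(v)) {
    out[i, ] <- gkm_signal(
      t, tissue_params(object$f_map[v[i]], object$bat_map[v[i]],
                       object$t1_map[v[i]]),
      object$protocol, m0_blood(object$pwi$m0[v[i]], object$protocol))
  }
  rownames(out) <- as.character(v)
  out
}

#' @export
residuals.asl_fit <- function(object, ...) {
  fitted <- predict(object)
  v <- as.integer(rownames(fitted))
  dm_flat <- matrix(object$pwi$dm, nrow = prod(dim(object$f_map)))
  dm_flat[v, , drop = FALSE] - fitted
}

#' @export
plot.asl_fit <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(x$f_map)[1] / 2)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, title) {
    graphics::image(t(m[slice, , ]), axes = FALSE, main = title,
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  show(x$f_map, "f (ml/min/100 g)")
  show(x$bat_map, "BAT (ms)")
  show(x$t1_map, "T1 (ms)")
  invisible(x)
}
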