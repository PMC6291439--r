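#' Delivery function of the pulsed-ASL kinetic model
#'
#' Arterial delivery of labelled blood water: zero before the bolus arrives,
#' `alpha * exp(-t / T1b)` while the bolus (of length `tau`) is passing, and
#' zero afterwards. The support is closed at the lower edge,
#' `[bat, bat + tau)`; the model signal is continuous so the convention has
#' no measurable effect.
#'
#' @param t time since labelling (ms); vectorised.
#' @param params a [tissue_params()] object (uses `bat`).
#' @param protocol an [asl_protocol()] object (uses `alpha`, `t1b`, `tau`).
#' @return Dimensionless delivery, same length as `t`.
#' @export
delivery <- function(t, params, protocol) {
  stopifnot(all(t >= 0))
  inside <- t >= params$bat & t < params$bat + protocol$tau
  ifelse(inside, protocol$alpha * exp(-t / protocol$t1b), 0)
}

#' Residue (venous clearance) function
#'
#' Fraction of delivered label still in the voxel a time `t` after arrival,
#' `exp(-f t / lambda)`, with perfusion converted to ml/g/ms.
#'
#' @inheritParams delivery
#' @return Dimensionless residue, same length as `t`.
#' @export
residue <- function(t, params, protocol) {
  stopifnot(all(t >= 0))
  exp(-.f_per_ms(params$f) * t / protocol$lambda)
}

#' Longitudinal relaxation function
#'
#' Decay of the label with the tissue T1: `exp(-t / T1)`.
#'
#' @inheritParams delivery
#' @return Dimensionless relaxation factor, same length as `t`.
#' @export
relaxation <- function(t, params) {
  stopifnot(all(t >= 0))
  exp(-t / params$t1)
}

# Stable evaluation of (exp(dr * b) - exp(dr * a)) / dr, elementwise.
# For |dr| below tol the two-term Taylor expansion
# (b - a) * (1 + dr * (a + b) / 2) avoids catastrophic cancellation.
.eint <- function(a, b, dr, tol = 1e-9) {
  if (abs(dr) < tol) {
    (b - a) * (1 + dr * (a + b) / 2)
  } else {
    exp(dr * a) * expm1(dr * (b - a)) / dr
  }
}

#' Closed-form general-kinetic-model difference signal
#'
#' The pulsed-ASL difference signal \eqn{\Delta M(t) = 2 M_{0b} f \int_0^t
#' c(t') r(t - t') m(t - t') dt'} evaluated analytically. With clearance
#' rate \eqn{k = f/\lambda + 1/T_1} and \eqn{\delta R = k - 1/T_{1b}} the
#' integral over the exponential integrand reduces to
#' \deqn{\Delta M(t) = 2 M_{0b} f \alpha e^{-kt}
#'   \frac{e^{\delta R \min(t, \Delta t + \tau)} - e^{\delta R \Delta t}}
#'        {\delta R}}
#' for \eqn{t > \Delta t} and zero before. The degenerate case
#' \eqn{\delta R \to 0} is handled by a series limit, so the function is
#' continuous in both `t` and the parameters.
#'
#' @param t inversion time(s), ms; vectorised.
#' @param params a [tissue_params()] object.
#' @param protocol an [asl_protocol()] object.
#' @param m0b equilibrium magnetization of arterial blood (tissue M0
#'   divided by `lambda`, see [m0_blood()]).
#' @return \eqn{\Delta M(t)}, same length as `t`, in the units of `m0b`.
#' @seealso [gkm_signal_quadrature()] for the numerical-quadrature oracle.
#' @examples
#' p <- asl_protocol()
#' tp <- tissue_params(f = 190, bat = 270, t1 = 790)
#' gkm_signal(p$ti, tp, p, m0b = 1 / p$lambda)
#' @export
gkm_signal <- function(t, params, protocol, m0b = 1) {
  stopifnot(all(t >= 0))
  f_int <- .f_per_ms(params$f)
  k <- f_int / protocol$lambda + 1 / params$t1
  dr <- k - 1 / protocol$t1b
  upper <- pmin(t, params$bat + protocol$tau)
  out <- numeric(length(t))
  on_ <- t > params$bat
  if (any(on_)) {
    integral <- vapply(upper[on_], function(b) .eint(params$bat, b, dr),
                       numeric(1))
    out[on_] <- 2 * m0b * f_int * protocol$alpha * exp(-k * t[on_]) * integral
  }
  out
}

#' Numerical-quadrature evaluation of the kinetic model
#'
#' Computes \eqn{2 M_{0b} f \int_0^t c(t') r(t-t') m(t-t') dt'} by adaptive
#' quadrature of the delivery/residue/relaxation product over the dummy
#' variable \eqn{t'}. This is the brute-force oracle against which the
#' closed form [gkm_signal()] is verified; it is not used in fitting.
#'
#' @inheritParams gkm_signal
#' @param rel_tol relative accuracy requested from the quadrature.
#' @return \eqn{\Delta M(t)}, same length as `t`.
#' @export
gkm_signal_quadrature <- function(t, params, protocol, m0b = 1,
                                  rel_tol = 1e-12) {
  stopifnot(all(t >= 0))
  f_int <- .f_per_ms(params$f)
  vapply(t, function(ti) {
    if (ti <= params$bat || f_int == 0) return(0)
    # integrand support is [bat, min(ti, bat + tau)]
    hi <- min(ti, params$bat + protocol$tau)
    integrand <- function(tp) {
      delivery(tp, params, protocol) *
        residue(ti - tp, params, protocol) *
        relaxation(ti - tp, params)
    }
    q <- stats::integrate(integrand, lower = params$bat, upper = hi,
                          rel.tol = rel_tol, abs.tol = 0)
    2 * m0b * f_int * q$value
  }, numeric(1))
}

#' Blood equilibrium magnetization from the tissue M0
#'
#' The proton-density calibration volume measures tissue equilibrium
#' magnetization; the kinetic model is written in terms of arterial blood
#' magnetization, obtained by dividing by the partition coefficient:
#' `M0b = M0 / lambda`. This convention makes the single-TI estimator and
#' the GKM mutually consistent in the fast-exchange limit.
#'
#' @param m0 tissue equilibrium magnetization (scalar or array).
#' @param protocol an [asl_protocol()] object.
#' @return `m0 / lambda`, same shape as `m0`.
#' @export
m0_blood <- function(m0, protocol) m0 / protocol$lambda

#' Single-TI perfusion estimator
#'
#' The simplified perfusion formula used for single-inversion-time ASL,
#' \deqn{f = \frac{\lambda}{2 TI} \frac{\Delta M(TI)}{M_{0}} e^{TI/T_{1b}},}
#' converted to ml/min/100 g. The calibration term is the measured tissue
#' proton-density signal \eqn{M_0}: the partition coefficient
#' \eqn{\lambda} in the prefactor is exactly the conversion
#' \eqn{M_{0b} = M_0/\lambda} to blood magnetization, which makes this
#' estimator invert the general kinetic model to first order in `f` in the
#' no-delay, matched-T1, uncut-bolus limit. No inversion-efficiency factor
#' is included (the multi-TI model does include `alpha`), and negative
#' difference signals yield negative perfusion estimates without clipping —
#' clipping would bias downstream agreement statistics.
#'
#' @param dm_over_m0 ratio of the difference signal to the measured tissue
#'   M0, \eqn{\Delta M(TI) / M_0} (dimensionless); vectorised.
#' @param ti inversion time, ms.
#' @param protocol an [asl_protocol()] object.
#' @return Perfusion in ml/min/100 g, same length as `dm_over_m0`.
#' @examples
#' single_ti_perfusion(0.01, ti = 1250, asl_protocol())
#' @export
single_ti_perfusion <- function(dm_over_m0, ti, protocol) {
  if (!is.numeric(ti) || ti <= 0) stop("'ti' must be > 0")
  f_int <- protocol$lambda / (2 * ti) * dm_over_m0 * exp(ti / protocol$t1b)
  .f_reported(f_int)
}
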