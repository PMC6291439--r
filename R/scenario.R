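#' Simulated study scenarios: repeatability and vasodilator challenge
#'
#' Generates a series of phantom acquisitions emulating two study designs:
#'
#' * `"repeatability"` — two same-day scans of the same subject. The true
#'   per-compartment perfusion is perturbed multiplicatively and
#'   independently per scan by `N(1, between_scan_sd)`, emulating
#'   physiological between-scan variation.
#' * `"gtn_challenge"` — six timepoints (two baselines plus four
#'   post-vasodilator measurements). True perfusion is held constant across
#'   timepoints (renal autoregulation maintains blood flow), while an
#'   accompanying table of synthetic systolic/diastolic blood pressures
#'   drops at the third timepoint and recovers linearly — the positive
#'   control for the challenge analysis.
#'
#' @param spec a [phantom_spec()].
#' @param scenario `"repeatability"` or `"gtn_challenge"`.
#' @param between_scan_sd sd of the multiplicative between-scan perfusion
#'   perturbation (fraction; default 0.05).
#' @param protocol an [asl_protocol()].
#' @param simulate if `TRUE` (default) a full noisy acquisition is generated
#'   per timepoint; if `FALSE` only the truths (fast, for summary-level
#'   studies).
#' @param seed optional override of `spec$seed`.
#' @return An object of class `study_scenario`: list with `timepoints` (each
#'   a list with `truth` and, if simulated, `acquisition`), `bp` (blood
#'   pressure table for the challenge scenario, else `NULL`), `scenario`.
#' @examples
#' sc <- make_study_scenario(phantom_spec(grid_shape = c(4, 8, 16)),
#'                           "repeatability", simulate = FALSE)
#' length(sc$timepoints)
#' @export
make_study_scenario <- function(spec,
                                scenario = c("repeatability", "gtn_challenge"),
                                between_scan_sd = 0.05,
                                protocol = asl_protocol(),
                                simulate = TRUE,
                                seed = spec$seed) {
  scenario <- match.arg(scenario)
  n_tp <- if (scenario == "repeatability") 2L else 6L
  old <- .save_rng()
  on.exit(.restore_rng(old))

  bp <- NULL
  if (scenario == "gtn_challenge") bp <- gtn_bp_profile()

  timepoints <- vector("list", n_tp)
  for (tp in seq_len(n_tp)) {
    spec_tp <- spec
    if (scenario == "repeatability" && between_scan_sd > 0) {
      set.seed(.derive_seed(seed, tp))
      scale <- stats::rnorm(2, mean = 1, sd = between_scan_sd)
      tt <- spec_tp$tissue
      tt$f[tt$compartment == "cortex"] <- tt$f[tt$compartment == "cortex"] * scale[1]
      tt$f[tt$compartment == "medulla"] <- tt$f[tt$compartment == "medulla"] * scale[2]
      tt$f <- pmax(tt$f, 0)
      spec_tp$tissue <- tt
    }
    truth <- make_phantom(spec_tp)
    entry <- list(truth = truth)
    if (simulate) {
      entry$acquisition <- simulate_acquisition(
        truth, spec_tp, protocol, seed = .derive_seed(seed, 1000 + tp))
    }
    timepoints[[tp]] <- entry
  }
  structure(list(timepoints = timepoints, bp = bp, scenario = scenario,
                 spec = spec, protocol = protocol, seed = seed),
            class = "study_scenario")
}

#' Synthetic blood-pressure profile for the vasodilator challenge
#'
#' Noise-free design values: 120/70 mmHg at the two baselines, a nadir of
#' 105/60 mmHg at timepoint 3 (5 min after sublingual vasodilator) and
#' linear recovery to baseline by timepoint 6.
#'
#' @return data.frame with columns `timepoint`, `systolic`, `diastolic`.
#' @export
gtn_bp_profile <- function() {
  data.frame(
    timepoint = 1:6,
    systolic = c(120, 120, 105, 110, 115, 120),
    diastolic = c(70, 70, 60, 70 - 10 * 2 / 3, 70 - 10 / 3, 70)
  )
}

#' Summary-level challenge cohort simulator
#'
#' Generates per-subject, per-timepoint regional measurements for the
#' vasodilator-challenge design without simulating images: each subject's
#' true cortical perfusion is constant over time (drawn from a
#' between-subject distribution) and the measured value at each timepoint is
#' the truth times `N(1, between_scan_sd)`; blood pressures follow
#' [gtn_bp_profile()] plus a subject offset and measurement noise.
#'
#' @param n_subjects number of subjects (default 6).
#' @param rbf_mean,rbf_between_subject_sd cortical perfusion population mean
#'   and between-subject sd, ml/min/100 g.
#' @param between_scan_sd fractional within-subject measurement variability.
#' @param bp_sd blood-pressure measurement sd, mmHg.
#' @param bp_between_subject_sd sd of the per-subject BP offset, mmHg.
#' @param seed integer seed.
#' @return Long data.frame: `subject`, `timepoint`, `rbf`, `systolic`,
#'   `diastolic`.
#' @export
simulate_challenge_cohort <- function(n_subjects = 6,
                                      rbf_mean = 190,
                                      rbf_between_subject_sd = 30,
                                      between_scan_sd = 0.05,
                                      bp_sd = 6,
                                      bp_between_subject_sd = 10,
                                      seed = 1L) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  bp <- gtn_bp_profile()
  n_tp <- nrow(bp)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    rbf_true <- stats::rnorm(1, rbf_mean, rbf_between_subject_sd)
    sys_off <- stats::rnorm(1, 0, bp_between_subject_sd)
    dia_off <- stats::rnorm(1, 0, bp_between_subject_sd)
    out[[s]] <- data.frame(
      subject = sprintf("s%02d", s),
      timepoint = bp$timepoint,
      rbf = rbf_true * stats::rnorm(n_tp, 1, between_scan_sd),
      systolic = bp$systolic + sys_off + stats::rnorm(n_tp, 0, bp_sd),
      diastolic = bp$diastolic + dia_off + stats::rnorm(n_tp, 0, bp_sd)
    )
  }
  do.call(rbind, out)
}

#' Monte-Carlo rejection rates for the challenge analysis
#'
#' Repeats the summary-level challenge simulation over many seeds and runs
#' the repeated-measures ANOVA on systolic blood pressure (true time effect
#' injected) and on cortical perfusion (true effect null). Returns the
#' fraction of replicates rejecting at level `alpha`: the BP rate estimates
#' the power of the positive control, the perfusion rate the type-I error.
#'
#' @param n_seeds number of Monte-Carlo replicates.
#' @param alpha significance level.
#' @param seed base seed; replicate `i` uses a derived child seed.
#' @param ... passed to [simulate_challenge_cohort()].
#' @return List with `bp_rejection_rate`, `rbf_rejection_rate`, `n_seeds`.
#' @export
challenge_rejection_rates <- function(n_seeds = 200, alpha = 0.05,
                                      seed = 1L, ...) {
  rej_bp <- logical(n_seeds)
  rej_rbf <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    d <- simulate_challenge_cohort(seed = .derive_seed(seed, i), ...)
    rej_bp[i] <- rm_anova(d, "systolic", "subject", "timepoint")$p_value < alpha
    rej_rbf[i] <- rm_anova(d, "rbf", "subject", "timepoint")$p_value < alpha
  }
  list(bp_rejection_rate = mean(rej_bp),
       rbf_rejection_rate = mean(rej_rbf),
       n_seeds = n_seeds)
}

#' Summary-level repeatability cohort simulator
#'
#' Generates paired same-day scan measurements of cortical perfusion for a
#' cohort: each subject's true value is drawn from a between-subject
#' distribution and each scan observes it with independent multiplicative
#' `N(1, between_scan_sd)` measurement variation, mirroring the
#' repeatability scenario of [make_study_scenario()] at region-summary
#' level.
#'
#' @inheritParams simulate_challenge_cohort
#' @param n_subjects number of subjects (default 12).
#' @return data.frame with columns `subject`, `scan1`, `scan2`.
#' @export
simulate_repeatability_cohort <- function(n_subjects = 12,
                                          rbf_mean = 190,
                                          rbf_between_subject_sd = 30,
                                          between_scan_sd = 0.05,
                                          seed = 1L) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  truth <- stats::rnorm(n_subjects, rbf_mean, rbf_between_subject_sd)
  data.frame(
    subject = sprintf("s%02d", seq_len(n_subjects)),
    scan1 = truth * stats::rnorm(n_subjects, 1, between_scan_sd),
    scan2 = truth * stats::rnorm(n_subjects, 1, between_scan_sd)
  )
}
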