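---
title: "Quantifying renal perfusion from multi-TI pulsed ASL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal perfusion from multi-TI pulsed ASL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalasl)
```

## The measurement problem

Arterial spin labelling (ASL) measures tissue perfusion by magnetically
inverting arterial blood water upstream and imaging the small difference
between labelled and control acquisitions; the labelled blood acts as an
endogenous, freely diffusible tracer. In the kidney this is attractive
because it avoids gadolinium contrast, but quantification is harder than in
the brain: renal bolus arrival times and tissue T1 differ between cortex
and medulla, and a single-delay measurement confounds perfusion with
arrival time and relaxation.

`renalasl` implements the quantification chain for a pulsed (FAIR-type)
renal ASL protocol sampled at many inversion times (TIs): a closed-form
kinetic forward model, voxel-wise nonlinear fitting of perfusion $f$, bolus
arrival time $\Delta t$ and tissue $T_1$, the simplified single-TI
estimator for comparison, cortex/medulla segmentation, and the statistical
battery used in reproducibility and pharmacological-challenge studies. A
digital renal phantom supplies synthetic acquisitions with known ground
truth so every stage is testable without scanner data.

## The kinetic model

The difference signal follows the general kinetic model for pulsed ASL: a
convolution of arterial delivery, venous clearance and longitudinal
relaxation,

$$
\Delta M(t) \;=\; 2\,M_{0b}\, f \int_0^{t} c(t')\,
r(t-t')\, m(t-t') \, \mathrm{d}t',
$$

with

$$
c(t) = \begin{cases}
0 & t < \Delta t\\
\alpha\, e^{-t/T_{1b}} & \Delta t \le t < \Delta t + \tau\\
0 & t \ge \Delta t + \tau
\end{cases}
\qquad
r(t) = e^{-f t/\lambda},
\qquad
m(t) = e^{-t/T_1}.
$$

Because the integrand is a single exponential on the support
$[\Delta t, \min(t, \Delta t + \tau)]$, the convolution has a closed form.
With clearance rate $k = f/\lambda + 1/T_1$ and
$\delta R = k - 1/T_{1b}$,

$$
\Delta M(t) = 2\,M_{0b} f \alpha\, e^{-k t}\,
\frac{e^{\delta R\, b} - e^{\delta R\, \Delta t}}{\delta R},
\qquad b = \min(t, \Delta t + \tau),
$$

for $t > \Delta t$ and zero before. `gkm_signal()` implements this;
`gkm_signal_quadrature()` evaluates the convolution by adaptive quadrature
and serves purely as an independent oracle — the two agree to better than
$10^{-8}$ relative error across the physiological parameter range (the test
suite checks a $10^4$-point grid). When $\delta R \to 0$ (apparent tissue
relaxation equal to blood relaxation) the ratio is evaluated by a two-term
series expansion; the switch-over at $|\delta R| < 10^{-9}\,$ms$^{-1}$
avoids catastrophic cancellation and keeps the function continuous in both
$t$ and the parameters. The bolus window is closed at its lower edge,
$[\Delta t, \Delta t + \tau)$; since the signal is continuous this
convention has no measurable consequence.

### Units

All times are milliseconds. Perfusion is carried in the field's reporting
unit, ml/min/100 g, and converted internally to ml g$^{-1}$ ms$^{-1}$
(divide by $6 \times 10^6$) wherever it enters an exponent. The
calibration volume measures *tissue* equilibrium magnetization $M_0$; the
model's blood magnetization is $M_{0b} = M_0/\lambda$ with
$\lambda = 0.9$ ml/g the blood–tissue water partition coefficient.

### Protocol constants

`asl_protocol()` defaults to the study conditions the package emulates: 14
TIs from 200 ms in steps of 175 ms (to 2475 ms), bolus length
$\tau = 800$ ms (limited by saturation pulses), $T_{1b} = 1250$ ms,
inversion efficiency $\alpha = 0.98$, and a single-TI comparison delay of
1250 ms.

## The single-TI estimator

For single-delay data the package provides the conventional simplified
estimator

$$
f = \frac{\lambda}{2\,TI}\, \frac{\Delta M(TI)}{M_0}\, e^{TI/T_{1b}},
$$

which assumes no arrival delay, tissue relaxation at the blood rate, and a
bolus covering the whole TI. The $\lambda$ prefactor is exactly the
$M_{0b} = M_0/\lambda$ conversion, so the formula inverts the kinetic
model to first order in $f$ in that limit — a property the test suite
verifies analytically. Two deliberate conventions:

* No inversion-efficiency factor is applied, matching the simplified
  formula as conventionally printed; the multi-TI model does include
  $\alpha$.
* Negative difference signals produce negative perfusion estimates. They
  are **not** clipped at zero: clipping would bias the Bland–Altman
  agreement statistics downstream. Non-finite and failed voxels are
  excluded at the region-summary stage instead.

With a saturation-limited 800 ms bolus and renal $T_1$ shorter than blood
$T_1$, this estimator applied to the *same* multi-TI signal necessarily
reads lower than the full kinetic fit (the label accumulates for at most
$\tau$, not $TI$, and decays faster than assumed). Published
single-vs-multi-TI comparisons that acquire the two protocols separately
can and do find the opposite ordering; that between-acquisition bias is an
empirical property of the acquisitions, not of the shared forward model,
and the package reproduces it from the bundled published summary table
(`reference_method_comparison()`, bias $+29.27$ ml/min/100 g for the
whole kidney) rather than from simulation.

## Voxel-wise fitting

`fit_gkm_volume()` fits $(f, \Delta t, T_1)$ per voxel by bounded
Levenberg–Marquardt least squares on the closed-form model. Choices that
matter:

* **Bounds**: $f \in [0, 1000]$ ml/min/100 g, $\Delta t \in [0, 1500]$ ms,
  $T_1 \in [200, 3000]$ ms — generous physiological envelopes around
  healthy renal values.
* **Initialization**: $\Delta t_0$ is the largest TI before the curve
  maximum at which the signal is still below 20 % of that maximum (0 if
  the curve peaks immediately); $f_0$ comes from the single-TI estimator
  at the TI nearest 1250 ms; $T_{1,0} = 800$ ms. On noiseless curves this
  start is good enough that the optimizer recovers the generating
  parameters to machine precision.
* **Tolerances**: relative function/parameter tolerance $10^{-10}$, at
  most 200 iterations. An optional 3-start mode perturbs $\Delta t_0$ by
  one TI step either way for noisy voxels.
* **M0 floor**: voxels with $M_0$ below 5 % of the 99th-percentile
  in-mask $M_0$ are skipped; dividing by a near-zero calibration value
  would otherwise produce unbounded perfusion estimates.
* **Degenerate curves**: all-non-positive curves are flagged unfittable;
  failed voxels carry `NA` in every map and are excluded from summaries.

The fit is deterministic and invariant to joint rescaling of the
difference signal and $M_0$.

## Segmentation conventions

Three region tools mirror common renal ASL practice:

* `central_slices()` keeps the central sections of the imaging slab (8 of
  16 by default, sections 5–12), avoiding slab-edge partial-volume
  effects.
* `cortex_by_erosion()` defines cortex as the outer 3 voxels of the
  whole-kidney mask. The erosion is **2D, per coronal section, with a
  4-connected (city-block) element**: kidneys are segmented slice by
  slice and the through-slice voxel size (4 mm) differs from in-plane
  (4.7 mm), so a 3D erosion would mix anisotropic depths. This is a
  documented convention, not the only defensible one.
* `cortex_by_t1_threshold()` splits cortex from medulla on the fitted
  $T_1$ map: cortical $T_1$ is shorter, so sub-threshold voxels are
  cortex (a polarity flag covers data where the relation inverts). In
  interactive practice an observer chooses the threshold on the histogram;
  for reproducibility the default is Otsu's two-class criterion on the
  in-mask histogram with 128 bins, with an explicit numeric override.

## Statistics

Region summaries are means over finite in-region voxels pooled across both
kidneys; between-method and between-scan analyses operate on subject-scan
region means, not voxels. The battery comprises:

* `ma_regression()` — squared Pearson correlation with **major-axis**
  regression (first principal axis of the covariance; not standardized
  major axis — the slopes differ, $r^2$ does not).
* `bland_altman()` — bias, conventional $\pm 1.96\,$SD limits of
  agreement, $t$-based CI for the bias, and the standard
  $\mathrm{SD}\sqrt{3/n}$ approximation for the LoA standard errors.
* `wilcoxon_signed_rank()` — exact distribution for $n \le 25$ non-zero
  differences, normal approximation with continuity correction beyond;
  zero differences are dropped (Wilcoxon's original treatment).
* `rm_anova()` — one-way repeated-measures F with subject blocking,
  reported uncorrected and with a Greenhouse–Geisser correction (the
  epsilon uses the standard trace formula on the doubly centred
  covariance). Both region summaries report mean and median $T_1$, since
  either may feed a paired test.
* Significance is read at $\alpha = 0.05$ with no multiple-testing
  correction, mirroring how such studies are conventionally analysed;
  users comparing many regions should correct accordingly.

## The digital phantom

`phantom_spec()` describes two ellipsoidal kidneys (cortex shell, medulla
core) on a 16 × 32 × 64 grid at 4 × 4.7 × 4.7 mm — a 64 × 150 × 300 mm
abdominal field of view. Default tissue values are typical healthy renal
parameters: cortex $f = 190$, medulla $f = 170$ ml/min/100 g; arrival
times 290/185 ms; $T_1$ 790/805 ms; non-perfused background with
$T_1 = 900$ ms. The simulator generates control/label pairs per TI and
average (4 averages by default): control = $M_0$, label =
$M_0 - \Delta M(TI)$, each with independent zero-mean Gaussian noise.

What the phantom does *not* emulate — and therefore what passing tests do
not establish about scanner data: respiratory motion and registration
error, background-suppression imperfections, Rician magnitude statistics
at low SNR, coil sensitivity profiles, partial-volume mixing at tissue
interfaces, and intravascular signal. The Gaussian control/label noise
model is appropriate for high-SNR difference imaging where the
magnitude-image statistics are approximately Gaussian.

### Calibration choices

Values the study conditions do not pin down were chosen once, on
physiological or statistical grounds, and are documented here rather than
tuned:

* `noise_sd = 0.005` (noise SD as a fraction of cortical $M_0$ per
  control/label image). The peak difference signal at default tissue
  values is about 1.5 % of $M_0$, so after 4 averages this gives
  per-voxel PWI SNR of roughly 4 — and the per-voxel spread of fitted
  perfusion (≈ 50 ml/min/100 g) is of the same order as the SDs reported
  in regional summary tables for this kind of protocol. This is a
  calibration choice, not a measured quantity.
* `between_scan_sd = 0.05`: 5 % multiplicative physiological variation of
  regional perfusion between same-day scans.
* The challenge scenario's blood-pressure series (baseline 120/70 mmHg,
  nadir −15/−10 at the third timepoint, linear recovery) with 6 mmHg
  measurement noise: arbitrary but designed so the repeated-measures
  ANOVA detects the pressure dip with power well above 0.8 at $n = 6$
  subjects, while perfusion is held flat — the expected physiology under
  renal autoregulation, and the null against which the type-I error is
  checked.

### Study scenarios and problem sizes

`make_study_scenario()` builds two-scan repeatability series (perfusion
perturbed per scan) and six-timepoint vasodilator-challenge series
(perfusion flat, blood pressure dipping). Monte-Carlo checks of the
statistical battery run at region-summary level via
`simulate_challenge_cohort()` / `simulate_repeatability_cohort()`: the
quantities entering the repeated-measures ANOVA are subject-level region
means, so simulating them directly (truth plus between-scan measurement
variation) exercises the identical analysis path at a fraction of the cost
of fitting hundreds of full volumes, and makes a 200-replicate power study
routine. The test suite validates the image-level and summary-level routes
against each other where they overlap: the full noiseless
simulate → fit → summarize chain reproduces the phantom's regional truth
exactly, and the noisy image-level chain at 4 vs 64 averages shows the
region-mean bias shrinking as averages grow.

## Known limitations

* The fitted $T_1$ is a plain longitudinal relaxation time; with
  background suppression and multi-shot read-outs, the effective
  $T_1^{*}$ seen by the acquisition can differ, so fitted values should
  be compared across protocols with care.
* The delivery model is the plug-flow pulsed-ASL form; no dispersion of
  the bolus front, continuous/pseudo-continuous labelling, or
  two-compartment exchange is modelled.
* Motion correction is assumed done upstream; the package does not
  register volumes.
* Automatic whole-kidney segmentation is out of scope: masks come from
  the phantom or from upstream manual segmentation.
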