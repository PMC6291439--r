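# renalasl

Quantification of renal perfusion from multi-inversion-time (multi-TI)
pulsed arterial spin labelling (ASL) MRI.

ASL labels arterial blood water magnetically and images the difference
between control and label acquisitions, giving a perfusion-weighted signal
without contrast agents. A single-delay measurement confounds perfusion
with bolus arrival time and relaxation; sampling the inflow curve at many
inversion times and fitting a kinetic model separates them. `renalasl`
implements that pipeline for the kidney:

- **Kinetic model** — the general kinetic model for pulsed ASL,
  ΔM(t) = 2 M₀ᵦ f ∫₀ᵗ c(t′) r(t−t′) m(t−t′) dt′, with plug-flow delivery
  c(t) = α e^(−t/T₁ᵦ) on [Δt, Δt+τ), clearance r(t) = e^(−f t/λ) and
  relaxation m(t) = e^(−t/T₁), evaluated in closed form
  (`gkm_signal()`) and verified against adaptive quadrature
  (`gkm_signal_quadrature()`).
- **Voxel-wise fitting** — bounded Levenberg–Marquardt estimation of
  renal blood flow f (ml/min/100 g), bolus arrival time Δt (ms) and
  tissue T₁ (ms) per voxel (`fit_gkm_volume()`, `gkm_fit()`), plus the
  simplified single-TI estimator
  f = (λ / 2TI) (ΔM/M₀) e^(TI/T₁ᵦ) (`single_ti_perfusion()`).
- **Segmentation** — central-slice restriction, outer-3-voxel cortex by
  in-plane erosion, and a reproducible T1-histogram (Otsu) cortex/medulla
  split (`central_slices()`, `cortex_by_erosion()`,
  `cortex_by_t1_threshold()`).
- **Statistics** — region summaries, major-axis regression with Pearson
  r², Bland–Altman agreement with CIs, Wilcoxon signed-rank (exact for
  small n), and repeated-measures ANOVA with Greenhouse–Geisser
  correction (`summarize_regions()`, `ma_regression()`, `bland_altman()`,
  `wilcoxon_signed_rank()`, `rm_anova()`).
- **Digital renal phantom** — two-kidney cortex/medulla phantoms with
  known ground truth and simulated multi-TI acquisitions, including
  repeated-scan and vasodilator-challenge scenarios (`phantom_spec()`,
  `make_phantom()`, `simulate_acquisition()`, `make_study_scenario()`),
  so the full chain is testable without scanner data.

Volumes are read and written as NIfTI (via RNifti), configurations as
YAML, tables as CSV. A thin CLI (`exec/renalasl`) exposes `simulate`,
`fit`, `segment`, `stats` and `run` subcommands over the same functions;
`run_pipeline()` orchestrates the whole chain with a provenance log.

Conventions: voxel arrays are (slice, x, y) with the coronal slice axis
first; all times in ms; perfusion reported in ml/min/100 g; the
calibration volume is tissue M₀ and the model's blood magnetization is
M₀ᵦ = M₀/λ.

## Worked example

Simulate the default phantom (16 × 32 × 64 voxels at 4 × 4.7 × 4.7 mm,
14 TIs from 200 to 2475 ms, 4 averages), fit every kidney voxel, segment,
and summarize:

```r
library(renalasl)

protocol <- asl_protocol()
spec     <- phantom_spec(seed = 42)
truth    <- make_phantom(spec)
acq      <- simulate_acquisition(truth, spec, protocol)
pwi      <- as_pwi(acq)

fit <- fit_gkm_volume(pwi, truth$masks$whole)
fit
#> voxel-wise GKM parametric maps
#>   grid: 16 x 32 x 64
#>   voxels in mask: 2856 (skipped below M0 floor: 0)
#>   converged: 2855 / 2856 (100.0%)
#>   runtime: 9.1 s
#>   median f = 185.4 ml/min/100 g, BAT = 257 ms, T1 = 787 ms

seg <- cortex_by_erosion(central_slices(truth$masks$whole, 8), depth = 3)
summarize_regions(fit, seg)[, c("region", "method", "mean_f", "mean_bat", "mean_t1", "n_vox")]
#>    region    method mean_f mean_bat mean_t1 n_vox
#> 1   whole  multi_ti 192.59    254.6   832.7  2743
#> 2   whole single_ti  87.50       NA      NA  2744
#> 3  cortex  multi_ti 198.73    285.5   834.7  1864
#> 4  cortex single_ti  92.02       NA      NA  1864
#> 5 medulla  multi_ti 179.56    188.9   828.3   879
#> 6 medulla single_ti  77.93       NA      NA   880
```

The multi-TI fit recovers the phantom's regional truth (cortex 190,
medulla 170 ml/min/100 g) within the simulated noise, with arrival times
near the true 290/185 ms. The single-TI estimator applied to the same
signal reads far lower because the 800 ms saturation-limited bolus covers
only part of the 1250 ms delay — see the vignette for why separately
acquired single-TI protocols can nonetheless read higher.

Between-method agreement on the bundled published reference summaries:

```r
reference_method_comparison()$bias
#>    region   bias
#> 1  cortex 30.900
#> 2 medulla  8.205
#> 3   whole 29.270
```

i.e. a single-TI minus multi-TI bias of +29.27 ml/min/100 g for the whole
kidney and +30.90 for the cortex.

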