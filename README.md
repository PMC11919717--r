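# timsom

Time-shared optical tweezer microrheology in R: simulate, correct and fit
the frequency-dependent viscoelasticity of soft and living matter measured
with a single time-shared laser trap.

## The problem

Active optical-tweezer microrheology drives a trapped micrometre bead with
an oscillating optical force and reads the complex shear modulus
G\*(ω) = G′(ω) + iG″(ω) of the surrounding material — cytoplasm,
biomolecular condensates, hydrogels — from millipascals to kilopascals over
five decades of frequency. Measuring force and displacement simultaneously
normally requires two lasers; the time-shared scheme alternates *one*
laser at 25 kHz between a driving trap (x₁(t) = A sin ωt) and a static
detection trap, so a single detector and a single calibration serve both
roles. The price is a discontinuous stress/strain record: the equivalent
trap follows a trapezoidal waveform (10 µs acousto-optic ramps, 30 µs
dwells, 80 µs cycle) and each trap is sampled once per cycle, 33 µs after
its rising edge. From the interleaved fundamental amplitudes V̂₁, V̂₂ the
*deviated* response function of the probe (radius a, total stiffness k) is

    χ̂ₜ(ω) = −2 V̂₂ / (k (V̂₁ + V̂₂)),      Ĝₜ(ω) = 1 / (6 π a χ̂ₜ(ω))

which departs from the true χ̂(ω) at high frequency because the bead
relaxes between the two slots. This package provides, in pN–µm–s units:

* **Fractional viscoelastic models** — springpot (σ = C_α D_t^α ε),
  fractional Kelvin–Voigt and Maxwell, plus the classic limits — with
  complex moduli, creep/relaxation kernels (two-parameter Mittag-Leffler
  function included) and derived quantities (τ, crossover frequency,
  plateau): `visco_model()`, `model_G()`, `model_creep()`,
  `derived_params()`.
* **A forward simulator** of the probe trajectory under the time-shared
  waveform — Grünwald–Letnikov fractional-derivative and hereditary
  creep-integral solvers in compiled code, plus an exact frequency-domain
  harmonic summation as an independent cross-check: `simulate_probe()`,
  `run_sweep()`, `harmonic_chi_t()`.
* **Extraction and compensation** — leakage-free single-bin projection of
  the interleaved streams, the first-harmonic approximation (FHA) forward
  map χ → χₜ, and its model-assisted fixed-point inversion with passivity
  quality flags: `extract_fundamental()`, `chi_t_from_signals()`,
  `fha_forward()`, `fha_compensate()`, `peak_snr()`.
* **Model fitting** with multi-start Levenberg–Marquardt on relative
  residuals, negative-point exclusion, robust 95% confidence intervals:
  `fit_model()`, `crossover_from_fit()`, `viscosity_from_loss()`.
* **Non-oscillatory estimators** — creep compliance and its conversion to
  G\*(ω), Jeffrey's-model indentation fits, Stokes-drag viscosity, trap
  stiffness and particle radius from force scans: `creep_to_G()`,
  `fit_jeffrey()`, `stokes_viscosity()`, `trap_stiffness_from_scan()`.

## Worked example

Simulate the full time-shared measurement of water with the standard
instrument settings (A = 100 nm, k = 50 pN/µm, a = 0.5 µm), extract the
deviated response at each drive frequency, compensate it, and recover the
viscosity from the loss-modulus slope:

```r
library(timsom)

cfg <- ts_config(k = 50, a = 0.5, A = 0.1)
water <- visco_model("newtonian", eta = 1e-3)
traces <- run_sweep(water, default_frequency_grid(10, 6250, 5), cfg)
dev <- deviated_spectrum(traces)
comp <- fha_compensate(dev, "springpot")
print(comp)
#> <response_spectrum> 15 frequencies ( 10 - 6250 Hz ), stage: compensated ; 2 flagged
vl <- viscosity_from_loss(comp)
cat(sprintf("eta = %.4g +/- %.2g Pa s (n = %d)\n", vl$eta, vl$se, vl$n_used))
#> eta = 0.0009941 +/- 2.2e-06 Pa s (n = 13)
```

The recovered viscosity is within 0.6% of the 10⁻³ Pa s ground truth.
The two flagged frequencies (3.8 and 6.25 kHz) violate passivity after
compensation — the first-harmonic approximation breaks down near the
Nyquist frequency — and are excluded from the fit automatically.

Compensating a cytoplasm-like viscoelastic solid (fractional
Kelvin–Voigt, C_α = 5 Pa s^α, α = 0.2, C_β = 0.01 Pa s^β, β = 0.9)
through the first-harmonic map and re-fitting recovers the model and its
crossover frequency:

```r
cyto <- visco_model("fractional_kv", C_alpha = 5, alpha = 0.2,
                    C_beta = 0.01, beta = 0.9)
omega <- 2 * pi * default_frequency_grid(0.1, 6250, 5)
omega_t <- 2 * pi * cfg$per_trap_rate
chi_t <- fha_forward(function(w) model_chi(cyto, w, cfg$a), omega, omega_t, cfg$k)
deviated <- response_spectrum(omega, chi_t, a = cfg$a, stage = "deviated",
                              k = cfg$k, omega_t = omega_t)
fit <- fit_model(fha_compensate(deviated, "viscoelastic_solid"), "fractional_kv")
print(fit)
#> <visco_fit> family: fractional_kv
#>   C_alpha             5 +/- 1.004e-07 (95% CI)
#>   C_beta     0.00999999 +/- 8.3e-09 (95% CI)
#>   alpha             0.2 +/- 1.041e-08 (95% CI)
#>   beta              0.9 +/- 8.289e-08 (95% CI)
#>   points used: 25 ( excluded: 0 ); RMS relative residual: 4.003e-08
print(derived_params(fit$model))
#> <derived_params> tau = 0.00020164 s; omega_c = 4959.4 rad/s ( 789.31 Hz ); plateau = NA Pa
```

The methods vignette (`vignettes/timsom-methods.Rmd`) documents the
models, the solvers, the accuracy limits of the first-harmonic
compensation and the design choices behind the estimators.

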