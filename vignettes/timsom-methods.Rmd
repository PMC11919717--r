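---
title: "Time-shared optical tweezer microrheology: models, simulation and compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-shared optical tweezer microrheology: models, simulation and compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timsom)
```

## The measurement and its artefact

Active microrheology with optical tweezers extracts the complex shear
modulus $G^*(\omega) = G'(\omega) + i G''(\omega)$ of a soft material from
the motion of an embedded micrometre-sized probe under an oscillating
optical force. Measuring stress and strain simultaneously normally needs
two lasers; time-shared microrheology instead alternates a *single* laser
at 25 kHz between a driving trap, which oscillates as
$x_1(t) = A \sin(\omega t)$, and a static detection trap at $x_2 = 0$.
Both traps then share one detector and one calibration, at the price of a
*discontinuous* stress/strain record.

Within the linear range of the trap the alternating pair is equivalent to
a single trap of full stiffness $k$ moving along a trapezoidal
trajectory: every 80 µs cycle ramps from $x_2$ to the current drive
sample $x_{1,n}$ in 10 µs (the acousto-optic transition), holds for
30 µs, ramps back, and holds at $x_2$. The drive sequence
$x_{1,n} = A\sin(\omega n/f_t)$ is updated once per cycle at the per-trap
rate $f_t = 12.5$ kHz, so the drive sweep is bounded by the Nyquist
frequency $f_t/2 = 6.25$ kHz. One force sample per trap per cycle is
taken 33 µs after that trap's rising edge (inside the dwell). From the
interleaved fundamental amplitudes $\hat V_1$, $\hat V_2$ the *deviated*
response function is

$$\hat\chi_t(\omega) = \frac{-2 \hat V_2}{k(\hat V_1 + \hat V_2)},
\qquad
\hat G_t(\omega) = \frac{1}{6\pi a\,\hat\chi_t(\omega)},$$

with $a$ the probe radius (generalized Stokes–Einstein relation). Because
the probe relaxes between the two slots, $\hat\chi_t$ deviates from the
true $\hat\chi$ at high frequency — most severely for materials with a
dominant elastic contribution, where the bead jumps quasi-instantaneously
between the traps and the static-slot signal is suppressed.

**Units.** Everything is expressed in pN–µm–s, so pN/µm² is identical to
Pa and no conversion constants appear. The complex convention is
$e^{+i\omega t}$ with $G'' \ge 0$; a physical response function then has
$\mathrm{Re}\,\chi \ge 0$ and $\mathrm{Im}\,\chi \le 0$.

## Viscoelastic model families

`visco_model()` provides six linear families built from springs, dashpots
and springpots (stress $\sigma = C_\alpha D_t^\alpha \epsilon$,
interpolating spring at $\alpha = 0$ and dashpot at $\alpha = 1$):

| family               | $G^*(\omega)$                                            | archetype            |
|----------------------|----------------------------------------------------------|----------------------|
| `newtonian`          | $i\omega\eta$                                            | simple fluid         |
| `springpot`          | $C_\alpha (i\omega)^\alpha$                              | power-law gel        |
| `fractional_kv`      | $C_\alpha (i\omega)^\alpha + C_\beta (i\omega)^\beta$    | viscoelastic solid (cytoplasm) |
| `fractional_maxwell` | $G_a G_b / (G_a + G_b)$                                  | viscoelastic liquid (condensates) |
| `maxwell`            | $E\,i\omega\tau/(1 + i\omega\tau)$, $\tau = \eta/E$      | classic liquid       |
| `kelvin_voigt`       | $E + i\omega\eta$                                        | classic solid        |

The fractional Maxwell modulus is the series (harmonic) combination of
its two springpots; its creep compliance is the sum of the springpot
creeps. The fractional Kelvin–Voigt creep is
$J(t) = (t^\beta/C_\beta)\,
E_{\beta-\alpha,\,1+\beta}\!\left(-(C_\alpha/C_\beta)t^{\beta-\alpha}\right)$
with the two-parameter Mittag-Leffler function (`mittag_leffler()`):
adaptive power series, an algebraic asymptotic expansion for large
negative arguments, and exponential closed forms at $a = 1$. In the
series/asymptotic handoff zone the achievable double-precision accuracy
bottoms out near $10^{-5}$ relative — far below the 0.5 % tolerance the
creep pipeline needs. At exponents 0 and 1 every fractional family
reproduces its classic counterpart to $10^{-12}$, which the tests assert.

Derived quantities (`derived_params()`, `crossover_from_fit()`): the
crossover frequency $\omega_c$ solves $G' = G''$ (for a Maxwell liquid
exactly $1/\tau = E/\eta$) and is reported as absent, not an error, when
no crossing exists in $(10^{-6}, 10^9)$ rad/s; equal-exponent families
have a frequency-independent $G''/G'$ and hence no crossover (at
$\alpha = \beta = 1/2$ the ratio is identically 1 — a degenerate case we
also report as absent).

## Simulating the probe

`simulate_probe()` integrates the inertialess force balance
$6\pi a\,[\text{material}](x) = k(x_l(t) - x(t))$ with $x(0) = 0$ and
zero pre-history, on a uniform grid with default `dt` = 0.5 µs (20 points
per AOD ramp; halving `dt` moves extracted fundamentals by < 0.2 %).
Two independent solver routes are implemented:

* **Grünwald–Letnikov** for stress-additive families (springpot,
  fractional/classic Kelvin–Voigt): the fractional derivative becomes a
  discrete memory kernel, combined across terms so each step is a single
  dot product (compiled code; $O(N^2)$ overall). For integer exponents
  the kernel support collapses to two samples and the solver is $O(N)$.
  Below 10 Hz drive a short-memory window is used when the dropped tail
  holds less than $10^{-3}$ of the kernel mass; for small $\alpha$ that
  rule is unattainable and the full memory is kept.
* **Hereditary creep integral (Volterra)** for compliance-described
  families (fractional Maxwell), using midpoint samples of $J(t)$.

Both routes apply to the springpot and agree to $\le 0.5$ % maximum
trajectory error over 20 ms — a mutual oracle asserted in the tests.
Newtonian and Maxwell media use $O(N)$ Crank–Nicolson steppers.

Sweeps (`run_sweep()`) snap each requested frequency to the nearest value
giving an integer number of drive periods in an integer number of sharing
cycles, so the rectangular-window single-bin projection
(`extract_fundamental()`) at the stream's true timestamps is
leakage-free; the snapped frequency is recorded in the trace. One
start-up drive period is simulated in addition to the evaluation window
and flagged as transient (slow power-law materials keep a $t^{-\alpha}$
start-up tail; the convergence of the extracted fundamental with longer
discards is verified in the tests). A drive landing exactly on the
Nyquist frequency uses a 90° phase, because the zero-phase discrete sine
$A\sin(\pi n)$ vanishes identically.

A third, fully independent route, `harmonic_chi_t()`, computes the exact
steady-state $\hat\chi_t$ in the frequency domain: the equivalent-trap
waveform is expanded as the product of the trapezoid's analytic Fourier
series and the zero-order-hold images of the discrete drive; the bead
responds through the active–passive response
$\chi_a = \chi/(1 + k\chi)$ at every image frequency
$\omega + s\,\omega_t$; and the interleaved samples pick up image $s$
with phase $e^{i s \omega_t \delta}$ ($\delta$ the sampling delay, times
$(-1)^s$ for the static stream). The time-domain simulator matches this
solution to 0.01–0.4 % once transients are shed.

## The first-harmonic map and its inversion

Truncating the sharing modulation at its first harmonic,
$x_l(t) = \tfrac{x_1}{2} e^{i\omega t}\left[1 + \sin(\omega_t t)\right]$,
gives a closed-form *forward map* from the true response to the deviated
one (`fha_forward()`):

$$\hat\chi_t =
\frac{\hat\chi - \hat\chi_1 + k(\hat\chi\hat\chi_1 - \hat\chi_+\hat\chi_-^*)}
     {1 + 2k\hat\chi_1 + k^2 \hat\chi_+\hat\chi_-^*},$$

with $\hat\chi_\pm$ the response at the shifted frequencies
$\omega_t \pm \omega$ (negative frequencies via Hermitian symmetry
$\chi(-\nu) = \chi^*(\nu)$) and
$\hat\chi_1 = (\hat\chi_+ + \hat\chi_-^*)/2$. A constant real $\chi$
(ideal elastic solid) gives $\hat\chi_t \equiv 0$: the map degenerates
exactly as the instrument does.

**Compensation.** The shifted frequencies lie beyond the drive Nyquist,
so they cannot be read off the data; recovering $\chi$ from $\chi_t$
therefore *requires an assumption about the material class*.
`fha_compensate()` iterates: fit the hinted family
(`viscoelastic_solid` → fractional Kelvin–Voigt, `viscoelastic_liquid` →
fractional Maxwell, or any concrete family) to the current estimate;
evaluate $\hat\chi_\pm$ from the fit; solve the forward map algebraically
for $\chi$; repeat to a $10^{-6}$ fixed point. The plain iteration
converges slowly (geometric rate approaching 1) for strongly deviated
liquids, so every third step applies Aitken $\Delta^2$ extrapolation;
round trips on forward-map data then recover $\chi$ to machine precision
within ~25 iterations for both hints. The inner fit works on the complex
$\chi$ itself with no sign exclusion — the small negative real part of a
deviated liquid spectrum *is* the artefact being removed, and discarding
those points would leave nothing to compensate.

Two deliberate semantics:

* **Stage guard.** Compensation is defined on deviated spectra; passing
  an already-compensated spectrum returns it unchanged with a warning
  (the inversion applied twice would re-remove an artefact that is gone).
* **Passivity QC.** Compensated frequencies violating passivity beyond a
  relative tolerance of $10^{-3}$
  ($\mathrm{Re}\,\chi < -10^{-3}|\chi|$ or
  $\mathrm{Im}\,\chi > 10^{-3}|\chi|$) are flagged, not dropped;
  downstream fits exclude flagged points, alongside the usual exclusion
  of negative spectral points. A strict sign rule would be useless here:
  a pure liquid's compensated $G'$ is numerically zero and falls on
  either side of it.

### Accuracy of the first-harmonic approximation

Comparing the exact harmonic solution with the first-harmonic map
quantifies the approximation itself, independent of any solver:

* for liquid-like materials (water, high-exponent springpots) the map is
  accurate to better than 1 % of $|\chi|$ across the drive band;
* for elastic-dominated materials (low-$\alpha$ springpots, cytoplasm-like
  fractional Kelvin–Voigt, plateau-forming fractional Maxwell) the map
  carries a systematic 5–9 % of $|\chi|$ even at $\omega \le \omega_t/10$
  when sampling at the instrument's 33 µs delay. The discrepancy is a
  property of the truncation, not of the simulator: re-running the same
  materials with the sample taken at the dwell centre (25 µs) — where the
  first-harmonic reconstruction and the trapezoid coincide — shrinks it
  to 0.2–2 %. The probe keeps relaxing inside the dwell, and only the
  dwell centre is phase-consistent with the single-harmonic model.
* because compensation divides by the (suppressed) deviated response,
  these forward-map errors are *amplified* in the recovered $\chi$ of
  strongly suppressed materials. Practical guidance follows the method's
  own rule: keep the trap softer than the material response at the
  Nyquist frequency, and treat flagged high-frequency points with
  suspicion. For the water benchmark the passivity flag marks exactly
  the two top frequencies where the truncation error concentrates, and
  the recovered viscosity is then within 0.6 % of truth (vs 3 % with the
  flagged points kept).

## Fitting

`fit_model()` performs Levenberg–Marquardt least squares on the stacked
relative residuals $(G'_{\rm model} - G')/|G|$ and
$(G''_{\rm model} - G'')/|G|$ — measured spectra span five decades, so
absolute residuals would be meaningless. Points with non-positive $G'$
or $G''$ or a set QC flag are excluded before fitting (negative points in
a rheological spectrum are measurement artefacts); the fit errors out,
naming counts, if fewer than $\max(4, 2\times\#\text{parameters})$ points
survive. Moduli are fitted on a log scale, exponents box-constrained to
$[0, 1]$ (boundary-pinned exponents are reported with a flag), and the
optimizer is started from a fixed grid of exponent pairs with moduli read
off the spectrum's ends — low end for the dominant element, which is the
stiffer springpot in a parallel pair and the softer one in a series pair.
The two springpots of a fractional pair commute, so estimates are
canonicalized to $\alpha \le \beta$.

95 % confidence half-widths use a heteroscedasticity-robust (sandwich,
HC1) covariance at the optimum: under component-wise noise the $1/|G|$
weighting leaves the stacked residuals with unequal variances, and the
naive $\sigma^2 (J^\top J)^{-1}$ covariance under-covers the
low-frequency-identified modulus (86 % observed vs 91 % with the
sandwich, at the nominal 95 %, over 500 simulated spectra). For a
Maxwell fit the relaxation time $\tau = \eta/E$ carries a delta-method
interval including the $\eta$–$E$ covariance.

`viscosity_from_loss()` fits $G'' = \eta\omega$ through the origin by
relative-weighted least squares, the standard reduction for simple
liquids.

## Non-oscillatory estimators

* **Creep compliance** (`creep_compliance()`):
  $J(t) = 6\pi a\, x_{\rm bead}(t)/F_0$ with
  $x_{\rm bead} = x_{\rm trap} - F/k$; samples where the clamp force
  leaves a ±5 % band around $F_0$ are flagged (the tolerance is this
  package's choice; the clamp setpoint itself, 40 pN by default, follows
  the force-clamp protocol for soft gels).
* **Creep → modulus** (`creep_to_G()`): piecewise-linear discrete
  transform $G^*(\omega) = 1/(i\omega \hat J(\omega))$ with $J(0^+)$ from
  linear extrapolation of the first two samples (clamped at ≥ 0) and the
  terminal slope from a power-law fit over the last decade of the record
  (a flat tail contributes nothing). Against Maxwell and Newtonian
  closed forms the conversion is accurate to ≤ 3 % over the two interior
  decades of the frequency window $[1/t_{\max},\, 1/(2\Delta t_{\min})]$;
  the endpoints carry the usual truncation bias and should be discarded.
* **Jeffrey's model** (`fit_jeffrey()`): nonlinear least squares of
  $x(t)/f_{\rm FC} = (1/\kappa)(1 - e^{-\kappa t/\gamma_1}) + t/\gamma_2$,
  initialized from the closed-form slope relations (initial slope
  $f_{\rm FC}(1/\gamma_1 + 1/\gamma_2)$, late slope
  $f_{\rm FC}/\gamma_2$, late-asymptote intercept $f_{\rm FC}/\kappa$);
  the initializer lands in the convergence basin across the tested
  recovery grid. Non-monotonicity is detected by maximum drawdown
  (robust to pointwise noise) rather than single-step decreases.
* **Stokes drag** (`stokes_viscosity()`): zero-intercept regression of
  plateau force on trap velocity, slope divided by $6\pi R$.
* **Trap stiffness** (`trap_stiffness_from_scan()`): linear fit of force
  against trap–bead offset restricted to ±200 nm around the force zero
  crossing, with an RMS-residual linearity diagnostic.
* **Particle radius** (`radius_from_scan()`): half the distance between
  the force extrema of a whole-particle scan. This is a documented
  heuristic: in a harmonic-trap/finite-sphere toy model
  (`synth_droplet_scan()`) the extrema sit inside the geometric edge, so
  the estimate carries a negative bias equal to the edge fraction; the
  calibration ships in the tests.

## Synthetic data: what it does and does not emulate

All fixtures are generated by code (`generate_fixture()`,
`synth_creep_trace()`, `synth_drag_series()`, `synth_trap_scan()`), with
the instrument timing above as the fixed study conditions: 25 kHz
sharing, 10 µs ramps, 30 µs dwells, 33 µs sampling delay, k = 50 pN/µm,
a = 0.5 µm, A = 100 nm (2 % of trap linearity headroom below the 200 nm
bound). Noise, when enabled, is additive Gaussian *detector* noise on
the sampled signals, seeded and scaled to the drive-stream RMS. It is
not thermodynamically consistent Brownian motion: passing tests
demonstrate correctness of the deterministic mechanics, the spectral
pipeline and the estimators' noise robustness, but say nothing about
fluctuation–dissipation consistency, low-signal passive microrheology,
hydrodynamic wall effects or probe–material boundary artefacts in real
samples.

Problem sizes used by the test suite and the acceptance script (chosen
to exercise every code path at meaningful accuracy): sweeps of 9–15
frequencies with 2–4 evaluation periods each; 20 ms dual-solver
comparisons; 200-point creep and indentation records; 200-seed Jeffrey
and 500-seed confidence-interval calibrations; a 27-truth fractional
Kelvin–Voigt recovery grid at 2 % noise.

## Known limitations

* The first-harmonic compensation inherits the truncation error
  described above; for elastic-dominated materials the recovered
  response beyond $\omega_t/10$ should be treated as semi-quantitative,
  and the passivity flags should be respected.
* The fixed-point compensation assumes the hinted family can represent
  the material over $[\omega_{\min}, \omega_t + \omega_{\max}]$; a wrong
  hint biases the beyond-Nyquist extrapolation silently.
* Creep conversion accuracy is limited by sampling: frequencies within a
  decade of either end of the record are biased.
* The simulator is one-dimensional, ignores optical-force nonlinearity
  beyond the linear-range bound, bead rotation and wall corrections.
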