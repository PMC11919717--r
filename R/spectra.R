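#' Response spectrum container
#'
#' Per-frequency complex response chi (um/pN) and complex shear modulus
#' G (Pa), linked by the generalized Stokes-Einstein relation
#' G = 1/(6 pi a chi).  \code{stage} records whether the spectrum is the
#' raw deviated time-sharing measurement, the FHA-compensated result or an
#' ideal (model) spectrum.
#'
#' @param omega angular frequencies, rad/s, strictly increasing.
#' @param chi complex compliance, um/pN.
#' @param a bead radius, um.
#' @param stage one of \code{"deviated"}, \code{"compensated"},
#'   \code{"ideal"}.
#' @param k trap stiffness used in the measurement, pN/um (provenance).
#' @param omega_t time-sharing angular frequency 2 pi f_t, rad/s
#'   (provenance).
#' @param qc logical quality flags (TRUE = suspect point), default all
#'   FALSE.
#' @return object of class \code{response_spectrum}.
#' @export
response_spectrum <- function(omega, chi, a,
                              stage = c("deviated", "compensated", "ideal"),
                              k = NA_real_, omega_t = NA_real_, qc = NULL) {
  stage <- match.arg(stage)
  stopifnot(length(omega) == length(chi), a > 0)
  if (is.unsorted(omega, strictly = TRUE)) {
    stop("omega must be strictly increasing")
  }
  if (is.null(qc)) qc <- rep(FALSE, length(omega))
  qc <- qc | !is.finite(chi)
  G <- 1 / (gse_prefactor(a) * chi)
  structure(list(omega = omega, chi = chi, G = G, stage = stage,
                 k = k, a = a, omega_t = omega_t, qc = qc),
            class = "response_spectrum")
}

#' @export
print.response_spectrum <- function(x, ...) {
  cat("<response_spectrum>", length(x$omega), "frequencies (",
      signif(min(x$omega) / 2 / pi, 4), "-", signif(max(x$omega) / 2 / pi, 4),
      "Hz ), stage:", x$stage, ";", sum(x$qc), "flagged\n")
  invisible(x)
}

#' @export
as.data.frame.response_spectrum <- function(x, ...) {
  data.frame(omega_rad_s = x$omega, freq_hz = x$omega / (2 * pi),
             chi_re = Re(x$chi), chi_im = Im(x$chi),
             G_prime_pa = Re(x$G), G_dprime_pa = Im(x$G),
             stage = x$stage, qc_flag = x$qc)
}

#' Single-bin Fourier amplitude of the interleaved streams
#'
#' Projects each stream onto the drive frequency with a rectangular window
#' over an integer number of drive periods, evaluated at the stream's true
#' sample timestamps (the two streams are offset by half a sharing cycle):
#' Vhat = (2/N) sum_i V_i exp(-i w t_i).  Samples flagged as start-up
#' transient are discarded first.
#'
#' @param trace an \code{\link{interleaved_trace}}.
#' @return list with complex \code{V1hat}, \code{V2hat}, \code{omega}
#'   (rad/s) and \code{n_used} (samples per stream).
#' @export
extract_fundamental <- function(trace) {
  stopifnot(inherits(trace, "interleaved_trace"))
  skip <- trace$n_transient_cycles
  idx <- seq_along(trace$t1) > skip
  n <- sum(idx)
  if (n < 2) stop("trace too short after transient removal")
  cy <- trace$config$cycle
  periods <- n * cy * trace$drive_freq
  if (abs(periods - round(periods)) > 1e-6) {
    stop("evaluation window covers ", signif(periods, 8),
         " drive periods; trim the trace to an integer period count")
  }
  w <- 2 * pi * trace$drive_freq
  proj <- function(t, V) 2 * sum(V * exp(-1i * w * t)) / length(t)
  list(V1hat = proj(trace$t1[idx], trace$V1[idx]),
       V2hat = proj(trace$t2[idx], trace$V2[idx]),
       omega = w, n_used = n)
}

#' Deviated response function from interleaved signal amplitudes
#'
#' chi_t = -2 Vhat2 / (k (Vhat1 + Vhat2)): the time-sharing response
#' function of the probe, in um/pN when the signals are forces in pN.  The
#' companion deviated modulus is G_t = 1/(6 pi a chi_t).
#'
#' @param V1hat,V2hat complex fundamental amplitudes of the driving- and
#'   static-trap streams.
#' @param k total trap stiffness, pN/um.
#' @return complex chi_t, um/pN.
#' @export
chi_t_from_signals <- function(V1hat, V2hat, k) {
  stopifnot(k > 0)
  den <- V1hat + V2hat
  if (any(abs(den) == 0)) stop("singular measurement: Vhat1 + Vhat2 = 0")
  -2 * V2hat / (k * den)
}

#' Deviated spectrum from a list of interleaved traces
#'
#' Applies \code{\link{extract_fundamental}} and
#' \code{\link{chi_t_from_signals}} to every trace of a sweep and collects
#' the result into a \code{\link{response_spectrum}} (stage "deviated"),
#' ordered by frequency.
#'
#' @param traces list of \code{interleaved_trace} (e.g. from
#'   \code{\link{run_sweep}}).
#' @return a \code{response_spectrum}.
#' @export
deviated_spectrum <- function(traces) {
  stopifnot(length(traces) > 0)
  cfg <- traces[[1]]$config
  omega <- vapply(traces, function(tr) 2 * pi * tr$drive_freq, numeric(1))
  ord <- order(omega)
  chi <- vapply(traces[ord], function(tr) {
    f <- extract_fundamental(tr)
    chi_t_from_signals(f$V1hat, f$V2hat, cfg$k)
  }, complex(1))
  response_spectrum(omega[ord], chi, a = cfg$a, stage = "deviated",
                    k = cfg$k, omega_t = 2 * pi * cfg$per_trap_rate)
}

#' Response function of the active-passive trap-material system
#'
#' chi_a = chi / (1 + k chi): the response of the bead held by a trap of
#' stiffness k in a material of response chi.
#'
#' @param chi complex material response, um/pN.
#' @param k trap stiffness, pN/um (k = 0 returns chi unchanged).
#' @return complex chi_a, um/pN.
#' @export
chi_active_passive <- function(chi, k) {
  den <- 1 + k * chi
  if (any(abs(den) < 1e-14)) stop("resonant denominator 1 + k chi = 0")
  chi / den
}

#' First-harmonic approximation of the time-sharing measurement
#'
#' The forward map from the ideal material response chi(w) to the deviated
#' response chi_t(w) measured by the time-shared trap, truncating the
#' sharing waveform at its first harmonic:
#' \deqn{\chi_t = \frac{\chi - \chi_1 + k(\chi \chi_1 - \chi_+ \chi_-^*)}
#'                     {1 + 2 k \chi_1 + k^2 \chi_+ \chi_-^*}}
#' with chi_+ = chi(w_t + w), chi_-^* = chi^*(w_t - w) (negative
#' frequencies via the Hermitian symmetry chi(-v) = chi^*(v)) and
#' chi_1 = (chi_+ + chi_-^*)/2.  A constant real chi (ideal elastic solid)
#' gives chi_t = 0 identically.
#'
#' @param chi_fn function of angular frequency (rad/s, positive) returning
#'   the complex material response, um/pN; must be evaluable at w, and at
#'   the shifted frequencies w_t +/- w.
#' @param omega drive angular frequencies, rad/s (0 < w < w_t).
#' @param omega_t time-sharing angular frequency 2 pi f_t, rad/s.
#' @param k total trap stiffness, pN/um.
#' @return complex chi_t, um/pN; frequencies with a vanishing denominator
#'   are returned as NA (flagged, not an error).
#' @export
fha_forward <- function(chi_fn, omega, omega_t, k) {
  stopifnot(is.function(chi_fn), all(omega > 0), all(omega < omega_t), k >= 0)
  chi <- chi_fn(omega)
  chip <- chi_fn(omega_t + omega)
  chim <- Conj(chi_fn(omega_t - omega))
  chi1 <- (chip + chim) / 2
  P <- chip * chim
  num <- chi - chi1 + k * (chi * chi1 - P)
  den <- 1 + 2 * k * chi1 + k^2 * P
  out <- num / den
  out[abs(den) < 1e-14 * (1 + abs(k * chi1))] <- NA_complex_
  out
}

# model fit on the complex response itself (stacked relative residuals of
# Re chi and Im chi).  Used inside the compensation loop, where the
# current chi estimate legitimately carries a small negative real part
# (the very artefact being removed), so the negative-point exclusion rule
# of the reported G-spectrum fit must not apply.
fit_chi <- function(omega, chi, a, family) {
  keep <- is.finite(chi)
  w <- omega[keep]
  chid <- chi[keep]
  wt <- 1 / Mod(chid)
  G_pseudo <- 1 / (gse_prefactor(a) * chid)
  resid_fn <- function(p) {
    chim <- model_chi(fit_par_to_model(p, family), w, a)
    c((Re(chim) - Re(chid)) * wt, (Im(chim) - Im(chid)) * wt)
  }
  bounds <- fit_bounds(family)
  best <- NULL
  for (p0 in fit_starts(family, w, G_pseudo)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all fit starts failed for family ", family)
  fit_par_to_model(best$par, family)
}

# resolve a compensation family hint to a concrete model family
resolve_family_hint <- function(hint) {
  switch(hint,
         viscoelastic_solid = "fractional_kv",
         viscoelastic_liquid = "fractional_maxwell",
         kv = "fractional_kv",
         maxwell_type = "fractional_maxwell",
         hint)
}

#' Compensate the time-sharing deviation of a measured spectrum
#'
#' Inverts the first-harmonic forward map to retrieve the artefact-free
#' response chi(w) from the deviated measurement chi_t(w).  The shifted
#' frequencies w_t +/- w lie beyond the drive Nyquist, so they cannot be
#' read off the data; they are evaluated from a viscoelastic model of the
#' assumed material class fitted to the current estimate.  The scheme
#' iterates to a fixed point: (i) start from chi = chi_t; (ii) fit the
#' hinted family; (iii) evaluate chi_+, chi_-^*, chi_1 from the fit;
#' (iv) solve the forward map algebraically,
#' chi = [chi_t (1 + 2 k chi_1 + k^2 P) + chi_1 + k P] / (1 + k chi_1)
#' with P = chi_+ chi_-^*; (v) repeat until the relative change is below
#' \code{tol} (or \code{max_iter}).
#'
#' @param spectrum a deviated \code{\link{response_spectrum}}.
#' @param family_hint assumed material class:
#'   \code{"viscoelastic_solid"} (fractional Kelvin-Voigt),
#'   \code{"viscoelastic_liquid"} (fractional Maxwell),
#'   \code{"springpot"}, or any concrete \code{\link{visco_model}} family.
#' @param k trap stiffness, pN/um; defaults to the spectrum's provenance.
#' @param omega_t sharing angular frequency, rad/s; ditto.
#' @param tol relative fixed-point tolerance.
#' @param max_iter iteration cap.
#' @param passivity_tol relative tolerance of the passivity QC flag: a
#'   physical response function has Re chi >= 0 and Im chi <= 0 (in the
#'   exp(+i w t) convention), so compensated frequencies with
#'   Re chi < -passivity_tol |chi| or Im chi > passivity_tol |chi| are
#'   sign-violating - the first-harmonic inversion has broken down there
#'   (typically near the Nyquist frequency) - and are flagged, not
#'   dropped; downstream fits apply the exclusion rule.
#' @return a compensated \code{response_spectrum} with attributes
#'   \code{iterations}, \code{converged}, \code{delta} (relative-change
#'   trace) and \code{fit} (the final inner \code{\link{visco_model}} used
#'   for the beyond-Nyquist extrapolation).  Non-convergence flags the
#'   result rather than failing.
#' @export
fha_compensate <- function(spectrum, family_hint, k = spectrum$k,
                           omega_t = spectrum$omega_t,
                           tol = 1e-6, max_iter = 50L,
                           passivity_tol = 1e-3) {
  stopifnot(inherits(spectrum, "response_spectrum"),
            is.finite(k), is.finite(omega_t))
  if (spectrum$stage == "compensated") {
    # the inversion is defined on deviated measurements; applying it twice
    # would re-remove an artefact that is no longer there
    warning("spectrum is already compensated; returning it unchanged")
    return(spectrum)
  }
  family <- resolve_family_hint(family_hint)
  omega <- spectrum$omega
  a <- spectrum$a
  chi_t <- spectrum$chi
  ok <- !spectrum$qc & is.finite(chi_t)
  chi_est <- chi_t
  delta <- Inf
  iter <- 0L
  fit <- NULL
  trace_delta <- numeric(0)
  hist <- list()  # last iterates, for Aitken delta-squared acceleration
  while (iter < max_iter && delta > tol) {
    iter <- iter + 1L
    fit <- tryCatch(fit_chi(omega[ok], chi_est[ok], a, family),
                    error = function(e) {
                      stop("compensation fit for family '", family,
                           "' failed: ", conditionMessage(e))
                    })
    chip <- model_chi(fit, omega_t + omega, a)
    chim <- Conj(model_chi(fit, omega_t - omega, a))
    chi1 <- (chip + chim) / 2
    P <- chip * chim
    chi_new <- (chi_t * (1 + 2 * k * chi1 + k^2 * P) + chi1 + k * P) /
      (1 + k * chi1)
    delta <- max(abs(chi_new[ok] - chi_est[ok]) /
                   pmax(abs(chi_est[ok]), 1e-300))
    trace_delta <- c(trace_delta, delta)
    chi_est <- chi_new
    hist <- c(hist, list(chi_new))
    if (length(hist) == 3L) {
      # Aitken extrapolation: the slow mode of the fixed point is nearly
      # geometric, so x2 - (x2-x1)^2 / ((x2-x1) - (x1-x0)) jumps ahead
      d1 <- hist[[2]] - hist[[1]]
      d2 <- hist[[3]] - hist[[2]]
      den <- d2 - d1
      safe <- abs(den) > 1e-12 * pmax(abs(d2), 1e-300)
      acc <- hist[[3]]
      acc[safe] <- hist[[3]][safe] - d2[safe]^2 / den[safe]
      chi_est <- acc
      hist <- list()
    }
  }
  sign_violating <- Re(chi_est) < -passivity_tol * Mod(chi_est) |
    Im(chi_est) > passivity_tol * Mod(chi_est)
  out <- response_spectrum(omega, chi_est, a = a, stage = "compensated",
                           k = k, omega_t = omega_t,
                           qc = spectrum$qc | sign_violating)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- delta <= tol
  attr(out, "delta") <- trace_delta
  attr(out, "fit") <- fit
  out
}

#' Exact deviated response by harmonic summation
#'
#' Frequency-domain steady-state solution of the time-shared measurement,
#' independent of the time-domain simulator: the equivalent-trap waveform
#' is expanded as the product of the trapezoid modulation (analytic
#' Fourier coefficients m_q) and the zero-order-hold images of the
#' discrete drive, the bead responds through the active-passive response
#' chi_a at every image frequency w + s w_t, and the interleaved samples
#' pick up each image with phase exp(i s w_t delay) (times (-1)^s for the
#' static stream).  The returned chi_t is exact up to harmonic truncation
#' at |s| <= n_harmonics, whereas \code{\link{fha_forward}} keeps only the
#' first harmonic; the difference between the two is the intrinsic error
#' of the first-harmonic approximation.
#'
#' @param model a \code{\link{visco_model}}.
#' @param freq drive frequency, Hz (scalar, 0 < freq < per-trap rate).
#' @param config a \code{\link{ts_config}}.
#' @param n_harmonics truncation order of the image sum.
#' @return complex chi_t, um/pN.
#' @export
harmonic_chi_t <- function(model, freq, config, n_harmonics = 300L) {
  stopifnot(inherits(model, "visco_model"), inherits(config, "ts_config"),
            length(freq) == 1L, freq > 0, freq < config$per_trap_rate)
  Tcy <- config$cycle
  wt <- 2 * pi / Tcy
  w <- 2 * pi * freq
  k <- config$k
  delta <- config$sample_delay
  r <- config$ramp
  h <- config$dwell
  # trapezoid = rect[0, r+h] convolved with rect[0, r]/r; m_q is the product
  # of the two rect transforms
  Q <- ceiling(n_harmonics / 2)
  qs <- -Q:Q
  wq <- qs * wt
  Frect <- function(L, v) ifelse(v == 0, L, (1 - exp(-1i * v * L)) / (1i * v))
  mq <- Frect(r + h, wq) * Frect(r, wq) / (r * Tcy)
  # zero-order-hold image amplitudes of exp(i w t) sampled at 1/Tcy
  cr <- function(nu) ifelse(abs(nu) < 1e-9,
                            1 + 0i,
                            (1 - exp(-1i * nu * Tcy)) / (1i * nu * Tcy))
  chi_a_signed <- function(nu) {
    out <- complex(length(nu))
    pos <- nu > 0
    ca <- function(x) chi_active_passive(model_chi(model, x, config$a), k)
    out[pos] <- ca(nu[pos])
    out[!pos] <- Conj(ca(-nu[!pos]))
    out
  }
  ss <- -n_harmonics:n_harmonics
  ds <- vapply(ss, function(s) sum(mq * cr(w + (s - qs) * wt)), complex(1))
  amp <- ds * (1 - k * chi_a_signed(w + ss * wt))
  ph <- exp(1i * ss * wt * delta)
  V1 <- sum(amp * ph)
  V2 <- sum(amp * (-1)^ss * ph)
  chi_t_from_signals(V1, V2, k)
}

#' Active-peak signal-to-noise ratio of a trace
#'
#' Quality control of the static-trap (passive) stream: the amplitude of
#' the DFT bin at the drive frequency divided by mean + 1 SD of the
#' neighbouring-bin amplitudes (the drive bin and its two immediate
#' neighbours excluded).  A measurement passes QC when the ratio exceeds
#' 1, i.e. the passive peak stands at least one standard deviation above
#' the noise baseline.
#'
#' @param trace an \code{\link{interleaved_trace}}.
#' @param n_neighbours half-width of the baseline window, in bins.
#' @return list with \code{ratio} and logical \code{pass}.
#' @export
peak_snr <- function(trace, n_neighbours = 10L) {
  stopifnot(inherits(trace, "interleaved_trace"))
  skip <- trace$n_transient_cycles
  V <- trace$V2[seq_along(trace$V2) > skip]
  N <- length(V)
  if (N < 16) stop("trace too short for SNR estimation (need >= 16 samples)")
  amp <- Mod(fft(V))
  ft <- trace$config$per_trap_rate
  ib <- round(trace$drive_freq * N / ft) + 1L
  lo <- max(2L, ib - n_neighbours)
  hi <- min(N %/% 2 + 1L, ib + n_neighbours)  # stay below the stream Nyquist
  cand <- setdiff(lo:hi, (ib - 1L):(ib + 1L))
  if (length(cand) < 8) stop("fewer than 8 baseline bins around the drive bin")
  base <- amp[cand]
  ratio <- amp[ib] / (mean(base) + sd(base))
  list(ratio = ratio, pass = ratio > 1)
}
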