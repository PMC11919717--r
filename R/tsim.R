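#' Time-sharing instrument configuration
#'
#' Timing and trap parameters of the time-shared dual-trap setup.  The
#' acousto-optic deflectors alternate the laser between the driving and
#' the static trap every half-cycle; each transition takes \code{ramp}
#' seconds (power transfer through the AOD crystal) followed by a
#' \code{dwell} hold, so the full sharing cycle is
#' \code{2 * (ramp + dwell)} (80 us: 12.5 kHz per trap, 25 kHz sharing).
#' Each trap's force signal is sampled once per cycle, \code{sample_delay}
#' seconds after that trap's rising edge, which places the sample inside
#' the dwell.
#'
#' @param k total trap stiffness (sum of both traps), pN/um.
#' @param a bead radius, um.
#' @param A drive amplitude, um; must lie in the trap's linear range
#'   (bound \code{linear_range}).
#' @param ramp AOD transition time, s.
#' @param dwell per-trap hold time, s.
#' @param sample_delay delay of the force sample after the slot's rising
#'   edge, s; must satisfy \code{ramp < sample_delay < ramp + dwell}.
#' @param dt integration step of the simulator, s; at most \code{ramp/10}.
#' @param volt_per_pn detector conversion factor; the default 1 means
#'   signals are forces in pN.
#' @param linear_range bound on \code{A}, um.
#' @return object of class \code{ts_config} with derived fields
#'   \code{cycle} (s) and \code{per_trap_rate} (Hz).
#' @examples
#' cfg <- ts_config(k = 50, a = 0.5, A = 0.1)
#' @export
ts_config <- function(k = 50, a = 0.5, A = 0.1,
                      ramp = 10e-6, dwell = 30e-6, sample_delay = 33e-6,
                      dt = 0.5e-6, volt_per_pn = 1, linear_range = 0.2) {
  stopifnot(k > 0, a > 0, A >= 0, ramp > 0, dwell > 0, dt > 0,
            volt_per_pn > 0)
  if (A > linear_range) {
    stop("drive amplitude A = ", A, " um exceeds the trap linear range (",
         linear_range, " um)")
  }
  if (sample_delay <= ramp || sample_delay >= ramp + dwell) {
    stop("sample_delay must fall inside the dwell: ramp < delay < ramp + dwell")
  }
  if (dt > ramp / 10) stop("dt must be at most ramp/10 to resolve the ramps")
  cycle <- 2 * (ramp + dwell)
  structure(list(k = k, a = a, A = A, ramp = ramp, dwell = dwell,
                 sample_delay = sample_delay, dt = dt,
                 volt_per_pn = volt_per_pn, linear_range = linear_range,
                 cycle = cycle, per_trap_rate = 1 / cycle),
            class = "ts_config")
}

#' @export
print.ts_config <- function(x, ...) {
  cat("<ts_config> k =", x$k, "pN/um; a =", x$a, "um; A =", x$A, "um\n",
      " cycle =", x$cycle * 1e6, "us (ramp", x$ramp * 1e6, "us, dwell",
      x$dwell * 1e6, "us); sample delay =", x$sample_delay * 1e6,
      "us; per-trap rate =", x$per_trap_rate, "Hz; dt =", x$dt * 1e6, "us\n")
  invisible(x)
}

#' Nyquist frequency of the drive
#'
#' Half the per-trap sampling rate: the upper bound of the oscillatory
#' sweep (6.25 kHz for the default 25 kHz two-slot sharing).
#'
#' @param config a \code{\link{ts_config}}.
#' @return frequency in Hz.
#' @export
nyquist_frequency <- function(config) {
  stopifnot(inherits(config, "ts_config"))
  config$per_trap_rate / 2
}

#' Discrete drive positions of the oscillating trap
#'
#' The driving trap follows x1(t) = A sin(w t + phase) sampled once per
#' sharing cycle at the per-trap rate f_t, giving the discrete sequence
#' x_{1,n} = A sin(w n / f_t + phase); the static trap stays at
#' x_{2,n} = 0.
#'
#' @param omega drive angular frequency, rad/s; at most the drive Nyquist
#'   2 pi f_t / 2.
#' @param A drive amplitude, um.
#' @param config a \code{\link{ts_config}}.
#' @param n_cycles number of sharing cycles.
#' @param phase drive phase offset, rad (default 0).
#' @return numeric vector of length \code{n_cycles}, um.
#' @export
drive_positions <- function(omega, A, config, n_cycles, phase = 0) {
  stopifnot(inherits(config, "ts_config"), omega > 0, n_cycles >= 1)
  ft <- config$per_trap_rate
  if (omega / (2 * pi) > ft / 2 + 1e-9) {
    stop("drive frequency ", omega / (2 * pi),
         " Hz exceeds the Nyquist bound ", ft / 2, " Hz")
  }
  n <- seq_len(n_cycles) - 1
  A * sin(omega * n / ft + phase)
}

#' Equivalent single-trap trajectory of the time-shared pair
#'
#' Within the linear range the two alternating traps act like one trap of
#' full stiffness k moving along a trapezoid: per 80 us cycle n, a linear
#' ramp from x_{2,n} to x_{1,n} during the first \code{ramp} seconds, a
#' hold at x_{1,n} for \code{dwell}, a ramp back to x_{2,n}, and a hold at
#' x_{2,n}.  Ramp interpolation uses local time since the segment start,
#' which makes the trajectory continuous.
#'
#' @param t times, s (>= 0); values beyond the last cycle are an error.
#' @param x1_seq per-cycle drive positions (from
#'   \code{\link{drive_positions}}), um.
#' @param config a \code{\link{ts_config}}.
#' @param x2_seq per-cycle static-trap positions; default all zero.
#' @return numeric vector x_l(t), um.
#' @export
trap_trajectory <- function(t, x1_seq, config, x2_seq = NULL) {
  stopifnot(inherits(config, "ts_config"), all(t >= -1e-15))
  cy <- config$cycle; rp <- config$ramp; dw <- config$dwell
  n <- pmin(floor(t / cy + 1e-12), length(x1_seq) - 1)
  if (any(n < 0) || any(t > length(x1_seq) * cy + 1e-12)) {
    stop("t outside the simulated cycles")
  }
  x1 <- x1_seq[n + 1]
  x2 <- if (is.null(x2_seq)) rep(0, length(x1)) else x2_seq[n + 1]
  tl <- t - n * cy
  out <- numeric(length(t))
  s1 <- tl < rp                       # ramp x2 -> x1
  s2 <- tl >= rp & tl < rp + dw       # hold x1
  s3 <- tl >= rp + dw & tl < 2 * rp + dw  # ramp x1 -> x2
  s4 <- tl >= 2 * rp + dw             # hold x2
  out[s1] <- x2[s1] + (tl[s1] / rp) * (x1[s1] - x2[s1])
  out[s2] <- x1[s2]
  out[s3] <- x1[s3] - ((tl[s3] - rp - dw) / rp) * (x1[s3] - x2[s3])
  out[s4] <- x2[s4]
  out
}

# short-memory window (steps) such that the dropped Gruenwald-Letnikov
# tail mass is below `frac` of the total kernel mass (= 2); unusable
# (returns 0 = full memory) when the required window exceeds n
gl_memory_window <- function(alphas, n, frac = 1e-3) {
  a <- min(alphas[alphas > 0])
  if (!length(a) || !is.finite(a)) return(0L)
  L <- ceiling((recip_gamma(1 - a) / (2 * frac))^(1 / a))
  if (!is.finite(L) || L >= n) 0L else as.integer(L)
}

#' Simulate the trapped probe in a viscoelastic medium
#'
#' Solves the inertialess force balance
#' 6 pi a [material operator](x) = k (x_l(t) - x(t)), x(0) = 0 with zero
#' pre-history, where x_l is the trapezoidal equivalent-trap trajectory.
#' Stress-additive families (springpot, fractional and classic
#' Kelvin-Voigt) use the Gruenwald-Letnikov fractional-derivative solver;
#' compliance-described families (fractional Maxwell) use the hereditary
#' creep-integral (Volterra) solver; Newtonian and Maxwell media use O(N)
#' Crank-Nicolson steppers.  The springpot supports both solver routes
#' (\code{method}), which agree and serve as mutual oracles.  The
#' simulation is deterministic (no thermal noise).
#'
#' @param model a \code{\link{visco_model}}.
#' @param omega drive angular frequency, rad/s.
#' @param config a \code{\link{ts_config}}.
#' @param n_cycles number of 80 us sharing cycles to simulate; must cover
#'   at least 2 drive periods.
#' @param method \code{"auto"} (family default), \code{"gl"}
#'   (Gruenwald-Letnikov) or \code{"volterra"} (creep integral).
#' @param phase drive phase, rad.
#' @param A drive amplitude, um; defaults to \code{config$A}.  \code{A = 0}
#'   gives the null trajectory.
#' @return object of class \code{probe_trajectory}: fields \code{t},
#'   \code{x} (probe, um), \code{x_l} (equivalent trap, um), \code{F}
#'   (instantaneous trap force k (x_l - x), pN), \code{x1_seq},
#'   \code{drive_freq} (Hz), \code{config}.
#' @export
simulate_probe <- function(model, omega, config, n_cycles,
                           method = c("auto", "gl", "volterra"),
                           phase = 0, A = config$A) {
  stopifnot(inherits(model, "visco_model"), inherits(config, "ts_config"))
  method <- match.arg(method)
  f <- omega / (2 * pi)
  if (n_cycles * config$cycle < 2 / f) {
    stop("n_cycles must cover at least 2 drive periods")
  }
  x1 <- drive_positions(omega, A, config, n_cycles, phase)
  nsteps <- round(n_cycles * config$cycle / config$dt)
  t <- seq(0, nsteps) * config$dt
  xl <- trap_trajectory(t, c(x1, 0), config)
  spa <- gse_prefactor(config$a)
  k <- config$k
  dt <- config$dt
  m <- model
  gl_terms <- switch(m$family,
                     springpot = list(C = m$C_alpha, a = m$alpha),
                     fractional_kv = list(C = c(m$C_alpha, m$C_beta),
                                          a = c(m$alpha, m$beta)),
                     kelvin_voigt = list(C = c(m$E, m$eta), a = c(0, 1)),
                     NULL)
  use_gl <- switch(method,
                   gl = TRUE,
                   volterra = FALSE,
                   auto = !is.null(gl_terms) || m$family %in%
                     c("newtonian", "maxwell"))
  x <- if (m$family == "newtonian" && method == "auto") {
    .newtonian_solve(xl, dt, k, spa, m$eta)
  } else if (m$family == "maxwell" && method == "auto") {
    .maxwell_solve(xl, dt, k, spa, m$eta, m$E)
  } else if (use_gl) {
    if (is.null(gl_terms)) {
      stop("Gruenwald-Letnikov solver needs a stress-additive family ",
           "(springpot, fractional_kv, kelvin_voigt), not ", m$family)
    }
    mem <- if (all(gl_terms$a %in% c(0, 1))) {
      2L  # spring/dashpot terms: the GL kernel has support 2, solver is O(N)
    } else if (f < 10) {
      gl_memory_window(gl_terms$a, length(xl))
    } else 0L
    .gl_solve(xl, dt, k, spa, gl_terms$C, gl_terms$a, mem)
  } else {
    kern <- model_creep(m, (seq_along(xl) - 0.5) * dt) / spa
    .volterra_solve(xl, k, kern)
  }
  structure(list(t = t, x = x, x_l = xl, F = k * (xl - x),
                 x1_seq = x1, drive_freq = f, phase = phase,
                 config = config),
            class = "probe_trajectory")
}

#' @export
print.probe_trajectory <- function(x, ...) {
  cat("<probe_trajectory>", length(x$t), "steps,",
      round(max(x$t) / x$config$cycle), "sharing cycles; drive",
      signif(x$drive_freq, 5), "Hz\n")
  invisible(x)
}

#' Sample interleaved detector signals from a trajectory
#'
#' Emulates the instrument's acquisition: one sample per trap per sharing
#' cycle, taken \code{sample_delay} seconds after that trap's rising edge
#' (trap 1 at the cycle start, trap 2 half a cycle later).  The sampled
#' value is the instantaneous full-stiffness trap force k (x_l - x)
#' divided by \code{volt_per_pn}.
#'
#' @param traj a \code{\link{simulate_probe}} result covering an integer
#'   number of sharing cycles.
#' @param n_transient_cycles cycles flagged as start-up transient (kept in
#'   the trace, skipped later by spectral extraction).
#' @return object of class \code{interleaved_trace}: \code{t1, V1, t2, V2},
#'   \code{drive_freq}, \code{n_transient_cycles}, \code{config}.
#' @export
sample_voltages <- function(traj, n_transient_cycles = 0L) {
  stopifnot(inherits(traj, "probe_trajectory"))
  cfg <- traj$config
  M <- round(max(traj$t) / cfg$cycle)
  if (abs(M * cfg$cycle - max(traj$t)) > cfg$dt / 2) {
    stop("trajectory does not cover an integer number of sharing cycles")
  }
  t1 <- (seq_len(M) - 1) * cfg$cycle + cfg$sample_delay
  t2 <- t1 + cfg$cycle / 2
  if (max(t2) > max(traj$t) + 1e-15) stop("sample time outside trajectory")
  Fs <- function(ts) approx(traj$t, traj$F, xout = ts)$y / cfg$volt_per_pn
  structure(list(t1 = t1, V1 = Fs(t1), t2 = t2, V2 = Fs(t2),
                 drive_freq = traj$drive_freq, phase = traj$phase,
                 n_transient_cycles = as.integer(n_transient_cycles),
                 config = cfg),
            class = "interleaved_trace")
}

#' @export
print.interleaved_trace <- function(x, ...) {
  cat("<interleaved_trace> drive", signif(x$drive_freq, 6), "Hz;",
      length(x$t1), "samples/stream (", x$n_transient_cycles,
      "transient cycles )\n")
  invisible(x)
}

#' Simulate a frequency sweep
#'
#' Runs \code{\link{simulate_probe}} and \code{\link{sample_voltages}} for
#' each requested drive frequency.  Each frequency is snapped to the
#' nearest value giving an integer number of drive periods in an integer
#' number of sharing cycles (f = n_periods * f_t / M), so the
#' rectangular-window projection at the drive frequency is leakage-free;
#' the snapped frequency is stored in the trace.  One extra block of
#' transient cycles (about \code{n_transient_periods} periods) is
#' simulated and flagged for removal.  A drive that lands exactly on the
#' Nyquist frequency uses a 90-degree phase so the discrete sine is not
#' identically zero.
#'
#' @param model a \code{\link{visco_model}}.
#' @param freqs drive frequencies, Hz; all at most the Nyquist bound.
#' @param config a \code{\link{ts_config}}.
#' @param n_periods drive periods in the evaluation window (>= 2).
#' @param n_transient_periods start-up periods to flag (default 1).
#' @param method solver choice, as in \code{\link{simulate_probe}}.
#' @return list of \code{interleaved_trace}, one per frequency, in input
#'   order (duplicates preserved).
#' @export
run_sweep <- function(model, freqs, config, n_periods = 4,
                      n_transient_periods = 1, method = "auto") {
  stopifnot(inherits(config, "ts_config"), n_periods >= 2)
  ft <- config$per_trap_rate
  if (any(freqs > ft / 2 + 1e-9)) {
    stop("frequencies above the Nyquist bound ", ft / 2, " Hz")
  }
  lapply(freqs, function(f) {
    M_eval <- max(n_periods, round(n_periods * ft / f))
    f_eff <- n_periods * ft / M_eval
    M_trans <- ceiling(n_transient_periods * ft / f_eff)
    phase <- if (abs(f_eff - ft / 2) < 1e-9) pi / 2 else 0
    traj <- simulate_probe(model, 2 * pi * f_eff, config,
                           n_cycles = M_trans + M_eval,
                           method = method, phase = phase)
    sample_voltages(traj, n_transient_cycles = M_trans)
  })
}
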