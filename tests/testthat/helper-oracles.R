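# Independent oracles and shared fixtures for the test suite.

# default instrument configuration used throughout the tests (25 kHz
# sharing, 10/30 us ramp/dwell, 33 us sampling delay, k = 50 pN/um,
# a = 0.5 um, A = 100 nm)
test_config <- function(...) ts_config(k = 50, a = 0.5, A = 0.1, ...)

# Gaver-Stehfest numerical inverse Laplace transform (independent of the
# package's Mittag-Leffler route); fine for smooth monotone originals
gaver_stehfest <- function(Fs, t, N = 14L) {
  stopifnot(N %% 2 == 0)
  V <- numeric(N)
  for (k in seq_len(N)) {
    j <- seq(floor((k + 1) / 2), min(k, N / 2))
    V[k] <- (-1)^(k + N / 2) *
      sum(j^(N / 2) * factorial(2 * j) /
            (factorial(N / 2 - j) * factorial(j) * factorial(j - 1) *
               factorial(k - j) * factorial(2 * j - k)))
  }
  vapply(t, function(tt) {
    s <- seq_len(N) * log(2) / tt
    log(2) / tt * sum(V * Fs(s))
  }, numeric(1))
}

# Laplace transform of the relaxation modulus, written from the
# constitutive laws directly (not via model_G)
Ghat_laplace <- function(model, s) {
  m <- model
  switch(m$family,
         newtonian = rep(m$eta, length(s)),
         springpot = m$C_alpha * s^(m$alpha - 1),
         fractional_kv = m$C_alpha * s^(m$alpha - 1) +
           m$C_beta * s^(m$beta - 1),
         fractional_maxwell = (m$C_alpha * s^m$alpha * m$C_beta * s^m$beta) /
           ((m$C_alpha * s^m$alpha + m$C_beta * s^m$beta) * s),
         maxwell = m$E * (m$eta / m$E) / (1 + s * m$eta / m$E),
         kelvin_voigt = m$E / s + m$eta)
}

# creep compliance by numerical Laplace inversion of 1/(s^2 Ghat(s))
creep_laplace_oracle <- function(model, t) {
  gaver_stehfest(function(s) 1 / (s^2 * Ghat_laplace(model, s)), t)
}

# run one simulated time-shared measurement and extract chi_t
simulate_chi_t <- function(model, f, cfg = test_config(), n_periods = 2,
                           n_transient_periods = 1, method = "auto") {
  tr <- run_sweep(model, f, cfg, n_periods = n_periods,
                  n_transient_periods = n_transient_periods,
                  method = method)[[1]]
  ex <- extract_fundamental(tr)
  list(chi_t = chi_t_from_signals(ex$V1hat, ex$V2hat, cfg$k),
       f = tr$drive_freq, trace = tr)
}

# ideal-spectrum builder for fitting tests
model_spectrum <- function(model, freqs, a = 0.5, stage = "ideal") {
  omega <- 2 * pi * freqs
  response_spectrum(omega, model_chi(model, omega, a), a = a, stage = stage)
}

# seeded multiplicative noise on a spectrum's moduli
noisy_spectrum <- function(model, freqs, noise, seed, a = 0.5) {
  omega <- 2 * pi * freqs
  G <- model_G(model, omega)
  set.seed(seed)
  Gn <- complex(real = Re(G) * (1 + rnorm(length(G), sd = noise)),
                imaginary = Im(G) * (1 + rnorm(length(G), sd = noise)))
  response_spectrum(omega, 1 / (6 * pi * a * Gn), a = a, stage = "compensated")
}

# brute-force grid-scan crossover oracle, Hz
crossover_grid_oracle <- function(model, lo = 1e-6, hi = 1e9, n = 4e5) {
  w <- exp(seq(log(lo), log(hi), length.out = n))
  G <- model_G(model, w)
  d <- Re(G) - Im(G)
  i <- which(d[-1] * d[-n] < 0)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  # linear interpolation in log-omega
  lw <- log(w[i]) - d[i] * (log(w[i + 1]) - log(w[i])) / (d[i + 1] - d[i])
  exp(lw) / (2 * pi)
}
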