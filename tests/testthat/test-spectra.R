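# Spectral extraction, the first-harmonic forward map and its inversion.

make_trace <- function(V1, V2, f, cfg = test_config(), skip = 0L) {
  n <- length(V1)
  t1 <- (seq_len(n) - 1) * cfg$cycle + cfg$sample_delay
  structure(list(t1 = t1, V1 = V1, t2 = t1 + cfg$cycle / 2, V2 = V2,
                 drive_freq = f, phase = 0, n_transient_cycles = skip,
                 config = cfg),
            class = "interleaved_trace")
}

test_that("single-bin projection recovers amplitude and phase", {
  cfg <- test_config()
  f <- 625; w <- 2 * pi * f
  n <- 40  # 2 drive periods
  t1 <- (seq_len(n) - 1) * cfg$cycle + cfg$sample_delay
  tr <- make_trace(cos(w * t1), rep(0, n), f, cfg)
  ex <- extract_fundamental(tr)
  expect_equal(ex$V1hat, 1 + 0i, tolerance = 1e-12)
  expect_equal(ex$V2hat, 0 + 0i)

  # a pure phase shift of a stream rotates its projection by the same angle
  phi <- 0.7
  tr2 <- make_trace(cos(w * t1 - phi), rep(0, n), f, cfg)
  expect_equal(extract_fundamental(tr2)$V1hat, exp(-1i * phi),
               tolerance = 1e-12)

  # non-integer period count is rejected with advice
  tr3 <- make_trace(cos(w * t1[1:37]), rep(0, 37), f, cfg)
  expect_error(extract_fundamental(tr3), "integer period")

  # immobile bead: Vhat2 / Vhat1 = 0
  x1 <- drive_positions(w, 0.1, cfg, n)
  tr4 <- make_trace(cfg$k * x1, rep(0, n), f, cfg)
  ex <- extract_fundamental(tr4)
  expect_equal(abs(ex$V2hat / ex$V1hat), 0)
})

test_that("chi_t from signal amplitudes follows the interleaved-force ratio", {
  k <- 50
  expect_equal(chi_t_from_signals(3 + 2i, 0i, k), 0 + 0i)      # rigid limit
  V2 <- 1 + 1i
  expect_equal(chi_t_from_signals(-2 * V2, V2, k), 2 / k + 0i,
               tolerance = 1e-14)
  expect_error(chi_t_from_signals(1 + 0i, -1 + 0i, k), "singular")
})

test_that("active-passive response has the closed form chi/(1 + k chi)", {
  chi <- 0.3 - 0.1i
  expect_equal(chi_active_passive(chi, 0), chi)
  k <- 50
  expect_equal(chi_active_passive((1 - 1i) / k, k), (1 - 1i) / (k * (2 - 1i)),
               tolerance = 1e-14)
  # stiff-material limit: k chi >> 1 gives 1/k
  expect_equal(chi_active_passive(1e9 + 0i, k), 1 / k + 0i, tolerance = 1e-8)
})

test_that("first-harmonic forward map: elastic degeneracy and weak-trap limit", {
  cfg <- test_config()
  omega_t <- 2 * pi * cfg$per_trap_rate
  omega <- 2 * pi * c(1, 50, 1000, 6000)
  # constant real chi (ideal elastic solid): chi_t vanishes identically
  chi_const <- function(w) rep(0.02 + 0i, length(w))
  chit <- fha_forward(chi_const, omega, omega_t, k = 50)
  expect_lt(max(abs(chit)), 1e-10 * 0.02)
  # k -> 0 with a decaying chi: chi_t ~ chi - chi1 ~ chi
  water <- visco_model("newtonian", eta = 1e-3)
  chi_fn <- function(w) model_chi(water, w, cfg$a)
  w_lo <- 2 * pi * c(1, 5, 20)
  expect_equal(fha_forward(chi_fn, w_lo, omega_t, k = 0), chi_fn(w_lo),
               tolerance = 2e-3)
  # matches the FDE simulation for water at 625 Hz
  r <- simulate_chi_t(water, 625, cfg)
  fha <- fha_forward(chi_fn, 2 * pi * r$f, omega_t, cfg$k)
  expect_lt(abs(r$chi_t - fha) / abs(chi_fn(2 * pi * r$f)), 0.02)
})

test_that("compensation inverts the forward map and is idempotent", {
  cfg <- test_config()
  omega_t <- 2 * pi * cfg$per_trap_rate
  fkv <- visco_model("fractional_kv", C_alpha = 5, alpha = 0.2,
                     C_beta = 0.01, beta = 0.9)
  freqs <- default_frequency_grid(0.1, 1250, 5)   # up to omega_t/10
  omega <- 2 * pi * freqs
  chi_fn <- function(w) model_chi(fkv, w, cfg$a)
  chit <- fha_forward(chi_fn, omega, omega_t, cfg$k)
  dev <- response_spectrum(omega, chit, a = cfg$a, stage = "deviated",
                           k = cfg$k, omega_t = omega_t)
  comp <- fha_compensate(dev, "viscoelastic_solid")
  expect_true(attr(comp, "converged"))
  expect_lt(max(abs(comp$chi - chi_fn(omega)) / abs(chi_fn(omega))), 0.01)

  # idempotence: compensating a compensated spectrum changes it by <1e-4
  # (the stage field prevents re-removing an artefact that is gone)
  comp2 <- suppressWarnings(fha_compensate(comp, "viscoelastic_solid"))
  expect_lt(max(abs(comp2$chi - comp$chi) / abs(comp$chi)), 1e-4)

  # weak trap and decaying response: compensation is a near-identity
  # (low frequencies of a liquid, where chi(omega) >> chi(omega_t))
  water <- visco_model("newtonian", eta = 1e-3)
  chi_w <- function(w) model_chi(water, w, cfg$a)
  om_lo <- 2 * pi * default_frequency_grid(0.1, 10, 5)
  devw <- response_spectrum(om_lo, fha_forward(chi_w, om_lo, omega_t, 0.001),
                            a = cfg$a, stage = "deviated", k = 0.001,
                            omega_t = omega_t)
  compw <- fha_compensate(devw, "springpot")
  expect_lt(max(abs(compw$chi - devw$chi) / abs(devw$chi)), 1e-3)
})

test_that("elastic-dominated materials underestimate |chi| at high frequency", {
  # the deviated response falls below the true response, monotonically
  # over the upper decade, when the elastic contribution dominates
  cfg <- test_config()
  omega_t <- 2 * pi * cfg$per_trap_rate
  fkv <- visco_model("fractional_kv", C_alpha = 50, alpha = 0.05,
                     C_beta = 0.01, beta = 0.9)
  chi_fn <- function(w) model_chi(fkv, w, cfg$a)
  # upper decade of the first-harmonic validity band (<= omega_t/10)
  omega <- 2 * pi * 10^seq(log10(125), log10(1250), length.out = 8)
  chit <- fha_forward(chi_fn, omega, omega_t, cfg$k)
  ratio <- abs(chit) / abs(chi_fn(omega))
  expect_true(all(ratio < 1))
  expect_true(all(diff(ratio) < 0))
})

test_that("harmonic summation agrees with the first-harmonic map for liquids", {
  cfg <- test_config()
  water <- visco_model("newtonian", eta = 1e-3)
  for (f in c(100, 625, 1250)) {
    ex <- harmonic_chi_t(water, f, cfg)
    fha <- fha_forward(function(w) model_chi(water, w, cfg$a),
                       2 * pi * f, 2 * pi * cfg$per_trap_rate, cfg$k)
    expect_lt(abs(ex - fha) / abs(model_chi(water, 2 * pi * f, cfg$a)), 0.01)
  }
})

test_that("active-peak SNR separates signal from noise", {
  cfg <- test_config()
  f <- 625
  n <- 400
  t1 <- (seq_len(n) - 1) * cfg$cycle + cfg$sample_delay
  t2 <- t1 + cfg$cycle / 2
  # noiseless drive: ratio far above 1
  tr <- make_trace(rep(0, n), sin(2 * pi * f * t2), f, cfg)
  expect_gt(peak_snr(tr)$ratio, 100)
  expect_true(peak_snr(tr)$pass)

  # pure white noise, no drive: ratio about 1 distributionally
  ratios <- vapply(1:100, function(s) {
    set.seed(s)
    trn <- make_trace(rnorm(n), rnorm(n), f, cfg)
    peak_snr(trn)$ratio
  }, numeric(1))
  expect_gt(median(ratios), 0.5)
  expect_lt(median(ratios), 2)

  # scaling the drive by 10 scales the ratio by 10 over fixed noise
  set.seed(42)
  noise <- rnorm(n, sd = 0.05)
  r1 <- peak_snr(make_trace(rep(0, n), sin(2 * pi * f * t2) + noise, f, cfg))
  r10 <- peak_snr(make_trace(rep(0, n), 10 * sin(2 * pi * f * t2) + noise,
                             f, cfg))
  expect_equal(r10$ratio / r1$ratio, 10, tolerance = 0.02)

  expect_error(peak_snr(make_trace(rep(0, 8), rep(0, 8), f, cfg)), "short")
})
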