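# Time-shared trap simulator: drive sequence, trapezoid, probe dynamics,
# interleaved sampling.

test_that("configuration invariants are enforced", {
  cfg <- test_config()
  expect_equal(cfg$cycle, 80e-6)
  expect_equal(cfg$per_trap_rate, 12500)
  expect_equal(nyquist_frequency(cfg), 6250)
  expect_error(ts_config(A = 0.5), "linear range")
  expect_error(ts_config(sample_delay = 5e-6), "dwell")
  expect_error(ts_config(sample_delay = 45e-6), "dwell")
  expect_error(ts_config(dt = 2e-6), "ramp/10")
})

test_that("drive positions follow the sampled sine", {
  cfg <- test_config()
  # vanishing frequency: all positions 0
  expect_equal(drive_positions(1e-9, 0.1, cfg, 10), rep(0, 10),
               tolerance = 1e-10)
  # quarter-rate sine cycles {0, A, 0, -A}
  x <- drive_positions(2 * pi * cfg$per_trap_rate / 4, 0.1, cfg, 8)
  expect_equal(x, rep(c(0, 0.1, 0, -0.1), 2), tolerance = 1e-12)
  # Fig-style drive: 625 Hz, A = 100 nm
  x <- drive_positions(2 * pi * 625, 0.1, cfg, 20)
  expect_equal(x, 0.1 * sin(2 * pi * 625 * (0:19) / 12500), tolerance = 1e-12)
  expect_error(drive_positions(2 * pi * 7000, 0.1, cfg, 4), "Nyquist")
})

test_that("trapezoidal trap trajectory interpolates the slots", {
  cfg <- test_config()
  x1 <- c(0.08, -0.05, 0.02)
  # hold at x1 during the dwell (25 us into the cycle)
  expect_equal(trap_trajectory(25e-6 + (0:2) * 80e-6, x1, cfg), x1)
  # ramp midpoint at 5 us: (x2 + x1)/2 with x2 = 0
  expect_equal(trap_trajectory(5e-6 + (0:2) * 80e-6, x1, cfg), x1 / 2)
  # second hold at x2 = 0
  expect_equal(trap_trajectory(60e-6 + (0:2) * 80e-6, x1, cfg), rep(0, 3))
  # zero drive: identically zero
  expect_equal(trap_trajectory(seq(0, 240e-6, by = 1e-6), rep(0, 4), cfg),
               rep(0, 241))
  # continuity across every segment boundary
  eps <- 1e-12
  for (tb in c(10e-6, 40e-6, 50e-6, 80e-6, 90e-6)) {
    expect_equal(trap_trajectory(tb - eps, x1, cfg),
                 trap_trajectory(tb + eps, x1, cfg), tolerance = 1e-6)
  }
})

test_that("probe simulation: null drive, static balance, linearity", {
  cfg <- test_config()
  sp <- visco_model("springpot", C_alpha = 2, alpha = 0.5)
  # A = 0: bead never moves, no force
  traj <- simulate_probe(sp, 2 * pi * 625, cfg, n_cycles = 40, A = 0)
  expect_equal(max(abs(traj$x)), 0)
  expect_equal(max(abs(traj$F)), 0)

  # pure spring: instantaneous balance x = k x1 / (k + 6 pi a G0) during
  # the driving dwell and x = 0 during the static dwell
  G0 <- 30
  spring <- visco_model("springpot", C_alpha = G0, alpha = 0)
  traj <- simulate_probe(spring, 2 * pi * 625, cfg, n_cycles = 40)
  i_hold1 <- which(abs((traj$t * 1e6) %% 80 - 25) < 1e-9)
  i_hold2 <- which(abs((traj$t * 1e6) %% 80 - 60) < 1e-9)
  expect_equal(traj$x[i_hold1],
               cfg$k * traj$x_l[i_hold1] / (cfg$k + 6 * pi * cfg$a * G0),
               tolerance = 1e-12)
  expect_equal(max(abs(traj$x[i_hold2])), 0)

  # linearity: doubling A doubles x pointwise
  t1 <- simulate_probe(sp, 2 * pi * 625, cfg, n_cycles = 40, A = 0.05)
  t2 <- simulate_probe(sp, 2 * pi * 625, cfg, n_cycles = 40, A = 0.1)
  expect_equal(t2$x, 2 * t1$x, tolerance = 1e-10)

  # causality: a longer simulation agrees with a shorter one on the
  # common prefix (future drive samples cannot act backwards)
  t3 <- simulate_probe(sp, 2 * pi * 625, cfg, n_cycles = 80)
  n <- length(t1$t)
  expect_equal(t3$x[seq_len(n)], simulate_probe(sp, 2 * pi * 625, cfg,
                                                n_cycles = 40)$x,
               tolerance = 1e-14)
})

test_that("solver order: halving dt moves the extracted fundamentals by <0.2%", {
  water <- visco_model("newtonian", eta = 1e-3)
  ex <- lapply(c(1e-6, 0.5e-6), function(dtv) {
    cfg <- test_config(dt = dtv)
    extract_fundamental(run_sweep(water, 625, cfg)[[1]])
  })
  expect_lt(abs(ex[[2]]$V1hat / ex[[1]]$V1hat - 1), 0.002)
  expect_lt(abs(ex[[2]]$V2hat / ex[[1]]$V2hat - 1), 0.002)
})

test_that("Gruenwald-Letnikov and Volterra solvers agree on a springpot", {
  cfg <- test_config()
  sp <- visco_model("springpot", C_alpha = 1, alpha = 0.5)
  # 20 ms = 250 sharing cycles
  gl <- simulate_probe(sp, 2 * pi * 150, cfg, n_cycles = 250, method = "gl")
  vo <- simulate_probe(sp, 2 * pi * 150, cfg, n_cycles = 250,
                       method = "volterra")
  expect_lt(max(abs(gl$x - vo$x)) / max(abs(gl$x)), 0.005)
})

test_that("time-domain simulation matches the harmonic-summation solution", {
  cfg <- test_config()
  fkv <- visco_model("fractional_kv", C_alpha = 5, alpha = 0.2,
                     C_beta = 0.01, beta = 0.9)
  r <- simulate_chi_t(fkv, 450, cfg, n_periods = 2, n_transient_periods = 2)
  exact <- harmonic_chi_t(fkv, r$f, cfg)
  expect_lt(abs(r$chi_t - exact) / abs(exact), 0.01)
  # Newtonian too, through the O(N) path
  water <- visco_model("newtonian", eta = 1e-3)
  r <- simulate_chi_t(water, 625, cfg)
  exact <- harmonic_chi_t(water, r$f, cfg)
  expect_lt(abs(r$chi_t - exact) / abs(exact), 0.005)
})

test_that("interleaved sampling picks the instantaneous force at the delay", {
  cfg <- test_config()
  # immobile bead: build the trajectory by hand with x = 0
  n_cycles <- 16
  x1 <- drive_positions(2 * pi * 625, 0.1, cfg, n_cycles)
  nst <- round(n_cycles * cfg$cycle / cfg$dt)
  t <- seq(0, nst) * cfg$dt
  xl <- trap_trajectory(t, c(x1, 0), cfg)
  traj <- structure(list(t = t, x = rep(0, length(t)), x_l = xl,
                         F = cfg$k * xl, x1_seq = x1, drive_freq = 625,
                         phase = 0, config = cfg),
                    class = "probe_trajectory")
  tr <- sample_voltages(traj)
  expect_length(tr$V1, n_cycles)   # one sample per stream per cycle
  expect_length(tr$V2, n_cycles)
  expect_equal(tr$V1, cfg$k * x1, tolerance = 1e-12)  # dwell value at 33 us
  expect_equal(max(abs(tr$V2)), 0)
  # stream 2 offset by half a cycle
  expect_equal(tr$t2 - tr$t1, rep(cfg$cycle / 2, n_cycles))

  # pure-spring material: the bead relaxes fully in the static slot,
  # so every V2 sample vanishes
  spring <- visco_model("springpot", C_alpha = 30, alpha = 0)
  tr <- sample_voltages(simulate_probe(spring, 2 * pi * 625, cfg,
                                       n_cycles = 40))
  expect_equal(max(abs(tr$V2)), 0, tolerance = 1e-14)
})

test_that("sweeps snap to commensurate frequencies and keep order", {
  cfg <- test_config()
  water <- visco_model("newtonian", eta = 1e-3)
  expect_length(run_sweep(water, numeric(0), cfg), 0)
  trs <- run_sweep(water, c(625, 625, 1000), cfg)
  expect_equal(vapply(trs, function(x) x$drive_freq, numeric(1))[1:2],
               c(625, 625))
  # snapped frequency gives an integer period count in the evaluation window
  tr <- trs[[3]]
  n_eval <- length(tr$t1) - tr$n_transient_cycles
  periods <- n_eval * cfg$cycle * tr$drive_freq
  expect_equal(periods, round(periods), tolerance = 1e-9)
  expect_error(run_sweep(water, 1e4, cfg), "Nyquist")
})
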