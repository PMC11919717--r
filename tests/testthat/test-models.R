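# Viscoelastic model library: complex moduli, creep/relaxation kernels,
# derived parameters.

test_that("complex moduli match closed forms and stay passive", {
  # water at 625 Hz: purely viscous, G'' = eta * omega
  w <- 2 * pi * 625
  G <- model_G(visco_model("newtonian", eta = 1e-3), w)
  expect_equal(Re(G), 0)
  expect_equal(Im(G), 1e-3 * w, tolerance = 1e-12)

  # exponent-0 springpot is a pure spring at every frequency
  sp0 <- visco_model("springpot", C_alpha = 7.5, alpha = 0)
  expect_equal(model_G(sp0, c(0.01, 1, 1e4)), rep(7.5 + 0i, 3))

  # fractional Maxwell at the classic limit equals the Maxwell closed form
  eta <- 0.2; E <- 4
  fm <- visco_model("fractional_maxwell", C_alpha = E, alpha = 0,
                    C_beta = eta, beta = 1)
  tau <- eta / E
  w <- 1 / tau
  expect_equal(model_G(fm, w), complex(real = E / 2, imaginary = E / 2),
               tolerance = 1e-12)
  # at general frequencies too, against E i w tau / (1 + i w tau)
  ws <- 10^seq(-2, 5)
  expect_equal(model_G(fm, ws), E * 1i * ws * tau / (1 + 1i * ws * tau),
               tolerance = 1e-12)
  # and matches the maxwell family itself
  expect_equal(model_G(fm, ws),
               model_G(visco_model("maxwell", eta = eta, E = E), ws),
               tolerance = 1e-12)

  # kelvin_voigt is the same limit of fractional_kv
  fkv <- visco_model("fractional_kv", C_alpha = E, alpha = 0,
                     C_beta = eta, beta = 1)
  expect_equal(model_G(fkv, ws),
               model_G(visco_model("kelvin_voigt", eta = eta, E = E), ws),
               tolerance = 1e-12)

  # passivity: G' >= 0 and G'' >= 0 for every family
  models <- list(
    visco_model("newtonian", eta = 2),
    visco_model("springpot", C_alpha = 3, alpha = 0.4),
    visco_model("fractional_kv", C_alpha = 5, alpha = 0.2,
                C_beta = 0.01, beta = 0.9),
    visco_model("fractional_maxwell", C_alpha = 50, alpha = 0.1,
                C_beta = 5, beta = 0.9),
    visco_model("maxwell", eta = 1, E = 10),
    visco_model("kelvin_voigt", eta = 1, E = 10))
  for (m in models) {
    G <- model_G(m, 10^seq(-4, 6, length.out = 41))
    expect_true(all(Re(G) >= -1e-15) && all(Im(G) >= -1e-15))
  }
  expect_error(model_G(models[[1]], -1), "positive")
})

test_that("response function obeys the generalized Stokes-Einstein relation", {
  # G = 1 Pa, a = 0.5 um -> chi = 1/(3 pi)
  solid <- visco_model("springpot", C_alpha = 1, alpha = 0)
  expect_equal(model_chi(solid, 123, a = 0.5), complex(real = 1 / (3 * pi)),
               tolerance = 1e-12)
  # chi * G * 6 pi a = 1 for random models and frequencies
  set.seed(7)
  for (i in 1:20) {
    m <- visco_model("fractional_kv", C_alpha = runif(1, 0.1, 100),
                     alpha = runif(1), C_beta = runif(1, 0.01, 10),
                     beta = runif(1))
    w <- 10^runif(1, -2, 4)
    a <- runif(1, 0.2, 2)
    expect_equal(model_chi(m, w, a) * model_G(m, w) * 6 * pi * a, 1 + 0i,
                 tolerance = 1e-12)
  }
  # newtonian closed form chi = -i/(6 pi a eta w)
  eta <- 1e-3; w <- 100; a <- 0.5
  expect_equal(model_chi(visco_model("newtonian", eta = eta), w, a),
               -1i / (6 * pi * a * eta * w), tolerance = 1e-12)
})

test_that("creep and relaxation kernels match closed forms and Laplace duality", {
  # springpot: J(1 s) = 1/Gamma(1.5); G(t) J(t) = 1/(Gamma(1+a)Gamma(1-a))
  sp <- visco_model("springpot", C_alpha = 1, alpha = 0.5)
  expect_equal(model_creep(sp, 1), 1 / gamma(1.5), tolerance = 1e-12)
  tt <- 10^seq(-3, 2, length.out = 11)
  expect_equal(model_relaxation(sp, tt) * model_creep(sp, tt),
               rep(1 / (gamma(1.5) * gamma(0.5)), 11), tolerance = 1e-12)

  # newtonian J = t/eta; maxwell and kelvin-voigt closed forms
  expect_equal(model_creep(visco_model("newtonian", eta = 2), tt), tt / 2)
  mx <- visco_model("maxwell", eta = 1.5, E = 3)
  expect_equal(model_creep(mx, tt), 1 / 3 + tt / 1.5)
  kv <- visco_model("kelvin_voigt", eta = 1.5, E = 3)
  expect_equal(model_creep(kv, tt), (1 - exp(-3 * tt / 1.5)) / 3)

  # fractional Maxwell creep is the sum of its springpots' creeps
  fm <- visco_model("fractional_maxwell", C_alpha = 4, alpha = 0.2,
                    C_beta = 0.6, beta = 0.7)
  expect_equal(model_creep(fm, tt),
               tt^0.2 / (4 * gamma(1.2)) + tt^0.7 / (0.6 * gamma(1.7)),
               tolerance = 1e-12)

  # fractional KV creep against numerical Laplace inversion, 20 points
  fkv <- visco_model("fractional_kv", C_alpha = 5, alpha = 0.2,
                     C_beta = 0.5, beta = 0.9)
  t20 <- 10^seq(-2, 1.5, length.out = 20)
  expect_lt(max(abs(model_creep(fkv, t20) / creep_laplace_oracle(fkv, t20) - 1)),
            0.005)
  # same duality for the fractional Maxwell family
  expect_lt(max(abs(model_creep(fm, t20) / creep_laplace_oracle(fm, t20) - 1)),
            0.005)
  # relaxation duality: G(t) from inversion of Ghat(s)
  g_or <- gaver_stehfest(function(s) Ghat_laplace(fkv, s), t20)
  expect_lt(max(abs(model_relaxation(fkv, t20) / g_or - 1)), 0.005)

  expect_error(model_creep(sp, 0), "positive")
  expect_error(model_relaxation(sp, -1), "positive")
})

test_that("Mittag-Leffler function matches its exponential special cases", {
  x <- seq(0.1, 30, length.out = 12)
  expect_equal(mittag_leffler(-x, 1, 1), exp(-x), tolerance = 1e-10)
  expect_equal(mittag_leffler(-x, 1, 2), (1 - exp(-x)) / x, tolerance = 1e-10)
  # E_{1/2,1}(-x) = exp(x^2) erfc(x)
  erfc <- function(z) 2 * pnorm(-z * sqrt(2))
  # accuracy bottoms out around 1e-5 in the series/asymptotic handoff zone
  x2 <- seq(0.2, 5, by = 0.4)
  expect_equal(mittag_leffler(-x2, 0.5, 1), exp(x2^2) * erfc(x2),
               tolerance = 1e-4)
  expect_equal(mittag_leffler(-seq(0.2, 2, by = 0.2), 0.5, 1),
               exp(seq(0.2, 2, by = 0.2)^2) * erfc(seq(0.2, 2, by = 0.2)),
               tolerance = 1e-10)
  # large-argument asymptotic branch, against overflow-safe exp(x^2) erfc(x)
  xl <- c(50, 200, 1000)
  erfcx <- exp(xl^2 + pnorm(-xl * sqrt(2), log.p = TRUE) + log(2))
  expect_equal(mittag_leffler(-xl, 0.5, 1), erfcx, tolerance = 1e-6)
})

test_that("derived parameters: crossover, relaxation time, plateau", {
  mx <- visco_model("maxwell", eta = 1, E = 10)
  d <- derived_params(mx)
  expect_equal(d$tau, 0.1)
  expect_equal(d$omega_c, 10)
  expect_equal(d$plateau, 10)

  # equal exponents: no crossover, reported absent (not an error)
  flat <- visco_model("fractional_kv", C_alpha = 1, alpha = 0.3,
                      C_beta = 2, beta = 0.3)
  expect_true(is.na(derived_params(flat)$omega_c))

  # fractional Maxwell crossover equals the brute-force grid scan
  fm <- visco_model("fractional_maxwell", C_alpha = 1, alpha = 0.2,
                    C_beta = 1, beta = 0.8)
  d <- derived_params(fm)
  expect_equal(d$f_c, crossover_grid_oracle(fm), tolerance = 1e-6)
})

test_that("model JSON serialization round-trips", {
  m <- visco_model("fractional_maxwell", C_alpha = 24.3, alpha = 0.12,
                   C_beta = 3.7, beta = 0.95)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2, m)
})

test_that("model constructor validates parameters", {
  expect_error(visco_model("springpot", C_alpha = 1), "alpha")
  expect_error(visco_model("springpot", C_alpha = -1, alpha = 0.5),
               "positive")
  expect_error(visco_model("springpot", C_alpha = 1, alpha = 1.5), "0, 1")
  # two-springpot families canonicalize alpha <= beta
  m <- visco_model("fractional_kv", C_alpha = 2, alpha = 0.9,
                   C_beta = 5, beta = 0.1)
  expect_lte(m$alpha, m$beta)
  expect_equal(m$C_alpha, 5)
})
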