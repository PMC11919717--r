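#' Parametric viscoelastic model
#'
#' Constructs a linear viscoelastic model from one of six families built
#' from springs (elastic modulus E, Pa), dashpots (viscosity eta, Pa s)
#' and springpots.  A springpot is the fractional element with stress
#' sigma(t) = C_alpha D_t^alpha epsilon(t): a spring at alpha = 0, a
#' dashpot at alpha = 1, a power-law material in between.
#'
#' Families and their active parameters:
#' \describe{
#'   \item{newtonian}{\code{eta}; G = i w eta.}
#'   \item{springpot}{\code{C_alpha}, \code{alpha}; G = C_alpha (i w)^alpha.}
#'   \item{fractional_kv}{two springpots in parallel (viscoelastic solid
#'     archetype): G = C_alpha (i w)^alpha + C_beta (i w)^beta.}
#'   \item{fractional_maxwell}{two springpots in series (viscoelastic
#'     liquid archetype): G = Ga Gb / (Ga + Gb).}
#'   \item{maxwell}{\code{eta}, \code{E}; spring and dashpot in series,
#'     the (alpha = 0, beta = 1) limit of fractional_maxwell.}
#'   \item{kelvin_voigt}{\code{eta}, \code{E}; spring and dashpot in
#'     parallel, the same limit of fractional_kv.}
#' }
#'
#' Units are pN-um-s so that pN/um^2 is identical to Pa: \code{C_alpha} in
#' Pa s^alpha, \code{C_beta} in Pa s^beta, \code{eta} in Pa s, \code{E} in
#' Pa.  For the two-springpot families 0 <= alpha <= beta <= 1 is required
#' (the constructor canonicalizes the order).
#'
#' @param family one of \code{"newtonian"}, \code{"springpot"},
#'   \code{"fractional_kv"}, \code{"fractional_maxwell"},
#'   \code{"maxwell"}, \code{"kelvin_voigt"}.
#' @param C_alpha,alpha,C_beta,beta,eta,E family-dependent parameters.
#' @return an object of class \code{visco_model}.
#' @examples
#' water <- visco_model("newtonian", eta = 1e-3)
#' cell  <- visco_model("fractional_kv", C_alpha = 5, alpha = 0.2,
#'                      C_beta = 0.01, beta = 0.9)
#' @export
visco_model <- function(family = c("newtonian", "springpot", "fractional_kv",
                                   "fractional_maxwell", "maxwell",
                                   "kelvin_voigt"),
                        C_alpha = NULL, alpha = NULL,
                        C_beta = NULL, beta = NULL,
                        eta = NULL, E = NULL) {
  family <- match.arg(family)
  need <- switch(family,
                 newtonian = "eta",
                 springpot = c("C_alpha", "alpha"),
                 fractional_kv = c("C_alpha", "alpha", "C_beta", "beta"),
                 fractional_maxwell = c("C_alpha", "alpha", "C_beta", "beta"),
                 maxwell = c("eta", "E"),
                 kelvin_voigt = c("eta", "E"))
  given <- list(C_alpha = C_alpha, alpha = alpha, C_beta = C_beta,
                beta = beta, eta = eta, E = E)
  miss <- setdiff(need, names(Filter(Negate(is.null), given)))
  if (length(miss)) {
    stop("visco_model('", family, "') requires: ", paste(miss, collapse = ", "))
  }
  p <- given[need]
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite scalar")
    }
    if (nm %in% c("alpha", "beta")) {
      if (v < 0 || v > 1) stop("exponent '", nm, "' must lie in [0, 1]")
    } else if (v <= 0) {
      stop("parameter '", nm, "' must be strictly positive")
    }
  }
  if (family %in% c("fractional_kv", "fractional_maxwell") &&
      p$alpha > p$beta) {
    # the two springpots commute; store with alpha <= beta
    p <- list(C_alpha = p$C_beta, alpha = p$beta,
              C_beta = p$C_alpha, beta = p$alpha)
  }
  structure(c(list(family = family), p), class = "visco_model")
}

#' @export
print.visco_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<visco_model> family:", x$family, "\n  ",
      paste(names(pars), signif(unlist(pars), 5), sep = " = ",
            collapse = ", "),
      "  [pN-um-s units]\n", sep = "")
  invisible(x)
}

# springpot complex modulus; alpha = 0 gives a pure spring, 1 a dashpot
springpot_G <- function(C, alpha, omega) C * (1i * omega)^alpha

#' Complex shear modulus of a viscoelastic model
#'
#' Evaluates G*(w) = G'(w) + i G''(w) in Pa.  Convention exp(+i w t);
#' both G' and G'' are non-negative for every supported family
#' (passivity).
#'
#' @param model a \code{\link{visco_model}}.
#' @param omega angular frequency, rad/s; vector, all > 0.
#' @return complex vector of moduli, Pa.
#' @examples
#' model_G(visco_model("newtonian", eta = 1e-3), 2 * pi * 625)
#' @export
model_G <- function(model, omega) {
  stopifnot(inherits(model, "visco_model"))
  if (!is.numeric(omega) || any(omega <= 0)) {
    stop("omega must be positive (rad/s)")
  }
  m <- model
  switch(m$family,
         newtonian = 1i * omega * m$eta,
         springpot = springpot_G(m$C_alpha, m$alpha, omega),
         fractional_kv = springpot_G(m$C_alpha, m$alpha, omega) +
           springpot_G(m$C_beta, m$beta, omega),
         fractional_maxwell = {
           ga <- springpot_G(m$C_alpha, m$alpha, omega)
           gb <- springpot_G(m$C_beta, m$beta, omega)
           ga * gb / (ga + gb)
         },
         maxwell = {
           tau <- m$eta / m$E
           m$E * 1i * omega * tau / (1 + 1i * omega * tau)
         },
         kelvin_voigt = m$E + 1i * omega * m$eta)
}

#' Complex response function of a trapped bead via the generalized
#' Stokes-Einstein relation
#'
#' chi(w) = 1 / (6 pi a G*(w)), the complex compliance of a sphere of
#' radius \code{a} embedded in the material, in um/pN.
#'
#' @inheritParams model_G
#' @param a bead radius, um.
#' @return complex vector, um/pN.
#' @export
model_chi <- function(model, omega, a) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  G <- model_G(model, omega)
  if (any(abs(G) == 0)) stop("singular material: |G| = 0")
  1 / (gse_prefactor(a) * G)
}

#' Relaxation modulus G(t)
#'
#' Stress per unit step strain, Pa.  For a springpot
#' G(t) = C_alpha t^(-alpha) / Gamma(1 - alpha); the fractional
#' Kelvin-Voigt modulus is the sum of its springpots' relaxations, and the
#' fractional Maxwell modulus is
#' C_alpha t^(-alpha) E_{beta-alpha, 1-alpha}(-(C_alpha/C_beta)
#' t^(beta-alpha)).  Ideal dashpot contributions (a delta function at
#' t = 0) are zero for t > 0.
#'
#' @inheritParams model_G
#' @param t time, s; vector, all > 0.
#' @return numeric vector, Pa.
#' @export
model_relaxation <- function(model, t) {
  stopifnot(inherits(model, "visco_model"))
  if (!is.numeric(t) || any(t <= 0)) stop("t must be positive (s)")
  m <- model
  sp_relax <- function(C, alpha, t) {
    if (alpha == 1) return(rep(0, length(t)))  # dashpot: eta * delta(t)
    C * t^(-alpha) * recip_gamma(1 - alpha)
  }
  switch(m$family,
         newtonian = rep(0, length(t)),
         springpot = sp_relax(m$C_alpha, m$alpha, t),
         fractional_kv = sp_relax(m$C_alpha, m$alpha, t) +
           sp_relax(m$C_beta, m$beta, t),
         fractional_maxwell = {
           if (m$alpha == m$beta) {
             sp_relax(1 / (1 / m$C_alpha + 1 / m$C_beta), m$alpha, t)
           } else {
             m$C_alpha * t^(-m$alpha) *
               mittag_leffler(-(m$C_alpha / m$C_beta) * t^(m$beta - m$alpha),
                              m$beta - m$alpha, 1 - m$alpha)
           }
         },
         maxwell = m$E * exp(-m$E * t / m$eta),
         kelvin_voigt = rep(m$E, length(t)))
}

#' Creep compliance J(t)
#'
#' Strain per unit step stress, 1/Pa.  For a springpot
#' J(t) = t^alpha / (C_alpha Gamma(1 + alpha)); the fractional Maxwell
#' creep is the sum of its springpots' creeps, and the fractional
#' Kelvin-Voigt creep is
#' (t^beta / C_beta) E_{beta-alpha, 1+beta}(-(C_alpha/C_beta)
#' t^(beta-alpha)) (two-parameter Mittag-Leffler function).
#'
#' @inheritParams model_relaxation
#' @return numeric vector, 1/Pa.
#' @export
model_creep <- function(model, t) {
  stopifnot(inherits(model, "visco_model"))
  if (!is.numeric(t) || any(t <= 0)) stop("t must be positive (s)")
  m <- model
  sp_creep <- function(C, alpha, t) t^alpha / (C * gamma(1 + alpha))
  switch(m$family,
         newtonian = t / m$eta,
         springpot = sp_creep(m$C_alpha, m$alpha, t),
         fractional_maxwell = sp_creep(m$C_alpha, m$alpha, t) +
           sp_creep(m$C_beta, m$beta, t),
         fractional_kv = {
           if (m$alpha == m$beta) {
             sp_creep(m$C_alpha + m$C_beta, m$alpha, t)
           } else {
             (t^m$beta / m$C_beta) *
               mittag_leffler(-(m$C_alpha / m$C_beta) * t^(m$beta - m$alpha),
                              m$beta - m$alpha, 1 + m$beta)
           }
         },
         maxwell = 1 / m$E + t / m$eta,
         kelvin_voigt = (1 - exp(-m$E * t / m$eta)) / m$E)
}

#' Derived rheological parameters
#'
#' Relaxation time tau (s), crossover frequency omega_c (rad/s, where
#' G'(w) = G''(w), reported also in Hz) and the plateau modulus (Pa) where
#' the family has one.  For the Maxwell model tau = eta/E and
#' omega_c = 1/tau exactly; for other families the crossover is the
#' numeric root of G' = G'' on (1e-6, 1e9) rad/s and is reported as
#' absent (\code{NA}) when no crossing exists in that window.
#'
#' @inheritParams model_G
#' @return a list of class \code{derived_params} with fields \code{tau},
#'   \code{omega_c} (rad/s), \code{f_c} (Hz) and \code{plateau} (Pa);
#'   \code{NA} fields mean "absent".
#' @export
derived_params <- function(model) {
  stopifnot(inherits(model, "visco_model"))
  m <- model
  omega_c <- if (m$family == "maxwell") {
    m$E / m$eta
  } else {
    crossover_omega(function(w) model_G(m, w))
  }
  tau <- if (is.na(omega_c)) NA_real_ else 1 / omega_c
  if (m$family == "maxwell") tau <- m$eta / m$E
  plateau <- switch(m$family,
                    kelvin_voigt = m$E,            # low-frequency plateau
                    maxwell = m$E,                 # high-frequency plateau
                    newtonian = NA_real_,
                    springpot = if (m$alpha == 0) m$C_alpha else NA_real_,
                    fractional_kv = if (m$alpha == 0) m$C_alpha else NA_real_,
                    fractional_maxwell =
                      if (m$alpha == 0) m$C_alpha else NA_real_)
  structure(list(tau = tau, omega_c = omega_c,
                 f_c = omega_c / (2 * pi), plateau = plateau),
            class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat("<derived_params> tau =", signif(x$tau, 5), "s; omega_c =",
      signif(x$omega_c, 5), "rad/s (", signif(x$f_c, 5), "Hz ); plateau =",
      signif(x$plateau, 5), "Pa\n")
  invisible(x)
}

# root of G'(w) = G''(w) on a log grid; NA when absent
crossover_omega <- function(Gfun, lower = 1e-6, upper = 1e9) {
  h <- function(lw) {
    G <- Gfun(exp(lw))
    log(Re(G)) - log(Im(G))
  }
  lw <- log(c(lower, upper))
  hl <- h(lw[1]); hu <- h(lw[2])
  if (!is.finite(hl) || !is.finite(hu) || hl * hu > 0) return(NA_real_)
  exp(uniroot(h, lw, tol = 1e-12)$root)
}

#' Serialize / deserialize a viscoelastic model as JSON
#'
#' @param model a \code{\link{visco_model}}.
#' @param path file path; for \code{read_model} the file to read.
#' @return \code{write_model} returns \code{path} invisibly;
#'   \code{read_model} returns a \code{visco_model}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "visco_model"))
  pars <- model[setdiff(names(model), "family")]
  jsonlite::write_json(list(family = model$family, params = pars,
                            units = "pN-um-s"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(visco_model, c(list(family = x$family), as.list(x$params)))
}
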