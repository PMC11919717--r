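# Non-oscillatory estimators: creep compliance and its conversion to the
# frequency domain, Jeffrey's-model indentation fits, Stokes-drag
# viscosity and trap calibration from force scans.

#' Bead position from trap position and force
#'
#' x_bead = x_trap - F/k: the probe sits behind the trap centre by the
#' force divided by the trap stiffness.
#'
#' @param x_trap trap positions, um.
#' @param F trap forces, pN.
#' @param k trap stiffness, pN/um.
#' @return bead positions, um.
#' @export
bead_position <- function(x_trap, F, k) {
  stopifnot(k > 0, length(x_trap) == length(F))
  x_trap - F / k
}

#' Force-clamp creep trace
#'
#' Container for a force-clamp (creep) record: the trap holds a constant
#' force \code{F0} on the bead and the position is followed in time.
#'
#' @param t times, s, strictly increasing from > 0.
#' @param x_trap trap positions, um.
#' @param F measured forces, pN.
#' @param k trap stiffness, pN/um.
#' @param F0 clamp setpoint, pN (> 0).
#' @param a bead radius, um.
#' @return object of class \code{creep_trace}.
#' @export
creep_trace <- function(t, x_trap, F, k, F0, a) {
  stopifnot(F0 > 0, k > 0, a > 0, length(t) == length(x_trap),
            length(t) == length(F))
  if (t[1] <= 0 || is.unsorted(t, strictly = TRUE)) {
    stop("t must be strictly increasing and positive")
  }
  structure(list(t = t, x_trap = x_trap, F = F, k = k, F0 = F0, a = a),
            class = "creep_trace")
}

#' Creep compliance from a force-clamp trace
#'
#' J(t) = 6 pi a x_bead(t) / F0 with x_bead = x_trap - F/k, in 1/Pa under
#' the pN-um-s convention.  Samples where the measured force leaves the
#' clamp band |F - F0| > tol_frac * F0 are flagged, not dropped.
#'
#' @param trace a \code{\link{creep_trace}}.
#' @param tol_frac clamp tolerance band, fraction of F0 (default 0.05).
#' @return data.frame with columns \code{t}, \code{J} (1/Pa) and logical
#'   \code{clamped} (FALSE = clamp violated at that sample).
#' @export
creep_compliance <- function(trace, tol_frac = 0.05) {
  stopifnot(inherits(trace, "creep_trace"))
  xb <- bead_position(trace$x_trap, trace$F, trace$k)
  J <- gse_prefactor(trace$a) * xb / trace$F0
  clamped <- abs(trace$F - trace$F0) <= tol_frac * trace$F0
  data.frame(t = trace$t, J = J, clamped = clamped)
}

#' Complex shear modulus from a creep compliance record
#'
#' Converts J(t) sampled in the time domain to G*(w) on a log-spaced
#' frequency grid, using the piecewise-linear discrete transform
#' G*(w) = 1 / (i w Jhat(w)) with
#' i w Jhat = J(0+) + sum_k Jdot_k (e^(-i w t_[k-1]) - e^(-i w t_k))/(i w)
#' + Jdot_inf e^(-i w t_N)/(i w).  J(0+) is linearly extrapolated from the
#' first two samples (clamped at >= 0) and the terminal slope Jdot_inf
#' comes from a power-law fit over the last decade of the record
#' (J ~ c t^p, so Jdot_inf = c p t_N^(p-1)); a flat tail contributes
#' nothing.  The frequency grid spans [1/t_max, 1/(2 dt_min)] rad/s.
#'
#' @param t sample times, s, strictly increasing.
#' @param J creep compliance samples, 1/Pa (>= 8 samples).
#' @param a bead radius used only to carry the chi/G duality in the
#'   returned spectrum, um (default 0.5).
#' @param n_freq number of frequencies on the log grid.
#' @return a \code{\link{response_spectrum}} (stage "ideal") with the
#'   transformed modulus.
#' @export
creep_to_G <- function(t, J, a = 0.5, n_freq = 40L) {
  stopifnot(length(t) == length(J))
  if (length(t) < 8) stop("need at least 8 creep samples")
  if (is.unsorted(t, strictly = TRUE) || t[1] <= 0) {
    stop("t must be strictly increasing and positive")
  }
  if (!is.finite(J[1])) stop("J(0+) not finite")
  N <- length(t)
  J0 <- max(0, J[1] - t[1] * (J[2] - J[1]) / (t[2] - t[1]))
  # terminal slope from a power-law fit over the last decade
  tail_idx <- which(t >= t[N] / 10)
  if (length(tail_idx) < 3) tail_idx <- seq(max(1, N - 3), N)
  pl <- lm(log(pmax(J[tail_idx], 1e-300)) ~ log(t[tail_idx]))
  p_exp <- unname(coef(pl)[2])
  Jdot_inf <- if (is.finite(p_exp) && p_exp > 1e-6) {
    exp(unname(coef(pl)[1])) * p_exp * t[N]^(p_exp - 1)
  } else 0
  omega <- exp(seq(log(1 / t[N]), log(1 / (2 * min(diff(t)))),
                   length.out = n_freq))
  tfull <- c(0, t)
  Jfull <- c(J0, J)
  Jdot <- diff(Jfull) / diff(tfull)
  G <- vapply(omega, function(w) {
    e <- exp(-1i * w * tfull)
    iwJ <- J0 + sum(Jdot * (e[-length(e)] - e[-1])) / (1i * w) +
      Jdot_inf * e[length(e)] / (1i * w)
    1 / iwJ
  }, complex(1))
  response_spectrum(omega, 1 / (gse_prefactor(a) * G), a = a, stage = "ideal")
}

#' Fit a Jeffrey's model to a normalized indentation record
#'
#' The spring-dashpot-dashpot creep model
#' x(t)/f_FC = (1/kappa)(1 - exp(-kappa t / gamma1)) + t/gamma2
#' describes force-clamp indentation: restoring stiffness kappa (pN/um)
#' and viscoelastic drags gamma1, gamma2 (pN s/um).  Nonlinear least
#' squares, initialized from the closed-form slope relations (initial
#' slope f_FC (1/gamma1 + 1/gamma2), late slope f_FC/gamma2, late-asymptote
#' intercept f_FC/kappa).
#'
#' @param t times, s.
#' @param x displacements, um.
#' @param f_FC clamp force, pN.
#' @param tol_nonmono tolerated non-monotonicity of x(t)/f_FC, as a
#'   fraction of its range.
#' @return object of class \code{jeffrey_fit}: \code{kappa},
#'   \code{gamma1}, \code{gamma2}, \code{f_FC}, \code{ci95}, \code{residual}.
#' @export
fit_jeffrey <- function(t, x, f_FC, tol_nonmono = 0.05) {
  stopifnot(length(t) == length(x), f_FC > 0, length(t) >= 6)
  y <- x / f_FC   # um/pN
  rng <- diff(range(y))
  # maximum drawdown: robust to pointwise noise, catches real decreases
  if (max(cummax(y) - y) > tol_nonmono * rng) {
    stop("normalized displacement decreases beyond tolerance; ",
         "not a creep record")
  }
  # closed-form initializer from the early and late slopes
  n <- length(t)
  i_late <- max(2, ceiling(0.7 * n)):n
  late <- lm(y[i_late] ~ t[i_late])
  g2 <- 1 / max(unname(coef(late)[2]), 1e-12)
  kap <- 1 / max(unname(coef(late)[1]), 1e-12)
  s0 <- (y[2] - y[1]) / (t[2] - t[1])
  g1 <- 1 / max(s0 - 1 / g2, 1 / (10 * g2))
  p0 <- log(c(kappa = kap, gamma1 = g1, gamma2 = g2))
  resid_fn <- function(lp) {
    p <- exp(lp)
    ym <- (1 - exp(-p[1] * t / p[2])) / p[1] + t / p[3]
    (ym - y) / rng
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12))
  p <- exp(fit$par)
  J <- num_jacobian(resid_fn, fit$par)
  dof <- max(length(y) - 3L, 1L)
  sigma2 <- fit$deviance / dof
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, 3, 3))
  ci95 <- qt(0.975, dof) * sqrt(pmax(diag(cov_log), 0)) * p
  names(ci95) <- c("kappa", "gamma1", "gamma2")
  structure(list(kappa = unname(p[1]), gamma1 = unname(p[2]),
                 gamma2 = unname(p[3]), f_FC = f_FC, ci95 = ci95,
                 residual = sqrt(fit$deviance / length(y))),
            class = "jeffrey_fit")
}

#' @export
print.jeffrey_fit <- function(x, ...) {
  cat("<jeffrey_fit> kappa =", signif(x$kappa, 5), "pN/um; gamma1 =",
      signif(x$gamma1, 5), "pN s/um; gamma2 =", signif(x$gamma2, 5),
      "pN s/um (f_FC =", x$f_FC, "pN )\n")
  invisible(x)
}

#' Viscosity from Stokes-drag plateau forces
#'
#' Fits F_drag(v_trap) = 6 pi eta R v_trap through the origin; the slope
#' divided by 6 pi R is the viscosity.
#'
#' @param v trap velocities, um/s (> 0, >= 3 values).
#' @param F_plateau plateau drag forces, pN.
#' @param R bead radius, um.
#' @return list with \code{eta} (Pa s), \code{se} and \code{n_used}.
#' @export
stokes_viscosity <- function(v, F_plateau, R) {
  stopifnot(length(v) == length(F_plateau), R > 0, all(v > 0))
  if (length(v) < 3) stop("need at least 3 velocities")
  fit <- lm(F_plateau ~ 0 + v)
  se <- suppressWarnings(unname(sqrt(diag(vcov(fit)))[1]))
  list(eta = unname(coef(fit)[1]) / (6 * pi * R),
       se = se / (6 * pi * R),
       n_used = length(v))
}

#' Trap stiffness from a force scan
#'
#' The trap is scanned across the probe and the force is recorded; within
#' the linear range the force is F = k x.  A linear fit restricted to
#' |offset| <= \code{window} um around the force zero-crossing gives k.
#'
#' @param position trap-bead offsets, um.
#' @param force measured forces, pN.
#' @param window half-width of the linear fit window, um (default 0.2,
#'   i.e. +/- 200 nm).
#' @return list with \code{k} (pN/um), \code{se}, \code{n_used},
#'   \code{rms_residual} (pN, linear-range diagnostic) and \code{x0}
#'   (zero-crossing position, um).
#' @export
trap_stiffness_from_scan <- function(position, force, window = 0.2) {
  stopifnot(length(position) == length(force), window > 0)
  ord <- order(position)
  x <- position[ord]; F <- force[ord]
  x0 <- if (any(diff(sign(F)) != 0)) {
    i <- which(diff(sign(F)) != 0)[1]
    x[i] - F[i] * (x[i + 1] - x[i]) / (F[i + 1] - F[i])
  } else x[which.min(abs(F))]
  keep <- abs(x - x0) <= window
  if (sum(keep) < 3) stop("scan does not cover the linear window around ", x0)
  fit <- lm(F[keep] ~ I(x[keep] - x0))
  k <- unname(coef(fit)[2])
  se <- suppressWarnings(unname(sqrt(diag(vcov(fit)))[2]))
  list(k = k, se = se, n_used = sum(keep),
       rms_residual = sqrt(mean(fit$residuals^2)), x0 = x0)
}

#' Particle radius from a trans-particle force scan
#'
#' Heuristic: as the trap is scanned across the whole particle the force
#' profile is antisymmetric with extrema near the particle edges; the
#' radius is estimated as half the distance between the force minimum and
#' maximum.  The estimate carries a size-dependent bias (the extrema sit
#' inside the geometric edge for small particles); calibrate against
#' \code{\link{synth_droplet_scan}} when absolute sizes matter.
#'
#' @param position scan positions, um (covering the whole particle).
#' @param force measured forces, pN.
#' @return list with \code{radius} (um) and the extrema positions.
#' @export
radius_from_scan <- function(position, force) {
  stopifnot(length(position) == length(force))
  imin <- which.min(force); imax <- which.max(force)
  if (imin == imax || min(force) >= 0 || max(force) <= 0) {
    stop("force extrema not found; scan must cross the whole particle")
  }
  list(radius = abs(position[imax] - position[imin]) / 2,
       x_min = position[imin], x_max = position[imax])
}
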