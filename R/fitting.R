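# Nonlinear least-squares fitting of viscoelastic model families to
# response spectra.  Residuals are the stacked relative errors of G' and
# G'' (each point weighted by 1/|G|), because measured spectra span
# several decades of modulus.  Moduli are fitted on a log scale; power-law
# exponents are box-constrained to [0, 1].

# parameter layout per family: transformed vector <-> visco_model
fit_param_info <- function(family) {
  switch(family,
         newtonian = list(log = "eta", exp = character(0)),
         springpot = list(log = "C_alpha", exp = "alpha"),
         maxwell = list(log = c("eta", "E"), exp = character(0)),
         kelvin_voigt = list(log = c("eta", "E"), exp = character(0)),
         fractional_kv = list(log = c("C_alpha", "C_beta"),
                              exp = c("alpha", "beta")),
         fractional_maxwell = list(log = c("C_alpha", "C_beta"),
                                   exp = c("alpha", "beta")),
         stop("unknown family: ", family))
}

fit_par_to_model <- function(p, family) {
  info <- fit_param_info(family)
  args <- as.list(c(exp(p[info$log]), pmin(pmax(p[info$exp], 0), 1)))
  names(args) <- c(info$log, info$exp)
  do.call(visco_model, c(list(family = family), args))
}

fit_model_to_par <- function(model) {
  info <- fit_param_info(model$family)
  p <- c(log(unlist(model[info$log])), unlist(model[info$exp]))
  names(p) <- c(info$log, info$exp)
  p
}

# multi-start initial guesses: exponents on a coarse grid, moduli
# bracketing the spectrum's extremes (fractional fits are multi-modal)
fit_starts <- function(family, omega, G) {
  absG <- Mod(G)
  n <- length(omega)
  lo <- which.min(omega); hi <- which.max(omega)
  mk <- function(...) {
    m <- do.call(visco_model, c(list(family = family), list(...)))
    fit_model_to_par(m)
  }
  eta0 <- max(median(Im(G) / omega), 1e-12)
  switch(family,
         newtonian = list(mk(eta = eta0)),
         springpot = lapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(al) {
           mk(C_alpha = max(median(absG / omega^al), 1e-12), alpha = al)
         }),
         maxwell = list(
           mk(eta = eta0, E = max(absG)),
           mk(eta = eta0, E = max(Re(G), absG[hi] / 2)),
           mk(eta = max(Im(G)[lo] / omega[lo], 1e-12), E = absG[hi])),
         kelvin_voigt = list(
           mk(eta = eta0, E = max(Re(G)[lo], absG[lo] / 2, 1e-12)),
           mk(eta = max(Im(G)[hi] / omega[hi], 1e-12),
              E = max(Re(G)[lo], 1e-12))),
         fractional_kv = {
           # parallel springpots: the stiffer element dominates, so the
           # low-frequency end estimates the alpha term, the high end beta
           grid <- list(c(0.1, 0.5), c(0.1, 0.9), c(0.3, 0.7), c(0.5, 0.9),
                        c(0.2, 0.5), c(0.8, 0.9))
           lapply(grid, function(ab) {
             mk(C_alpha = max(absG[lo] / omega[lo]^ab[1], 1e-12),
                alpha = ab[1],
                C_beta = max(absG[hi] / omega[hi]^ab[2], 1e-12),
                beta = ab[2])
           })
         },
         fractional_maxwell = {
           # series springpots: the softer element dominates, so the ends
           # inform the opposite exponents
           grid <- list(c(0.1, 0.5), c(0.1, 0.9), c(0.3, 0.7), c(0.5, 0.9),
                        c(0.2, 0.5), c(0.8, 0.9))
           lapply(grid, function(ab) {
             mk(C_alpha = max(absG[hi] / omega[hi]^ab[1], 1e-12),
                alpha = ab[1],
                C_beta = max(absG[lo] / omega[lo]^ab[2], 1e-12),
                beta = ab[2])
           })
         })
}

fit_bounds <- function(family) {
  info <- fit_param_info(family)
  nlog <- length(info$log); nexp <- length(info$exp)
  list(lower = c(rep(log(1e-12), nlog), rep(0, nexp)),
       upper = c(rep(log(1e12), nlog), rep(1, nexp)))
}

#' Fit a viscoelastic model family to a response spectrum
#'
#' Least squares on the stacked relative residuals of the storage and loss
#' moduli, (G'_model - G')/|G| and (G''_model - G'')/|G|.  Points with
#' non-positive G' or G'', a set QC flag, or non-finite values are
#' excluded before fitting (negative points in a rheological spectrum are
#' measurement artefacts).  Optimization is Levenberg-Marquardt from a
#' fixed multi-start grid (deterministic), moduli on a log scale and
#' exponents box-constrained to [0, 1]; the best final residual wins.
#' 95\% confidence half-widths come from the Jacobian covariance at the
#' optimum scaled by the residual variance.
#'
#' @param spectrum a \code{\link{response_spectrum}}.
#' @param family model family to fit (see \code{\link{visco_model}}).
#' @return object of class \code{visco_fit}: \code{model} (the fitted
#'   \code{visco_model}), \code{ci95} (named 95\% half-widths, natural
#'   scale), \code{n_used}, \code{n_excluded}, \code{residual} (RMS
#'   relative error), \code{derived} (\code{\link{derived_params}} of the
#'   fit), \code{boundary} (exponents pinned at 0 or 1), \code{cov_log}
#'   (covariance on the transformed scale).
#' @export
fit_model <- function(spectrum, family) {
  stopifnot(inherits(spectrum, "response_spectrum"))
  G <- spectrum$G
  omega <- spectrum$omega
  keep <- is.finite(G) & Re(G) > 0 & Im(G) > 0 & !spectrum$qc
  n_used <- sum(keep)
  n_excluded <- length(keep) - n_used
  info <- fit_param_info(family)
  npar <- length(info$log) + length(info$exp)
  if (n_used < max(4L, 2L * npar)) {
    stop("under-determined fit: ", n_used, " usable points (",
         n_excluded, " excluded) for ", npar, " parameters")
  }
  w <- omega[keep]
  Gd <- G[keep]
  wt <- 1 / Mod(Gd)
  resid_fn <- function(p) {
    Gm <- model_G(fit_par_to_model(p, family), w)
    c((Re(Gm) - Re(Gd)) * wt, (Im(Gm) - Im(Gd)) * wt)
  }
  bounds <- fit_bounds(family)
  best <- NULL
  for (p0 in fit_starts(family, w, Gd)) {
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
  p <- best$par
  if (length(info$exp) == 2 && p["alpha"] > p["beta"]) {
    # the two springpots commute: canonicalize to alpha <= beta
    p <- c(C_alpha = unname(p["C_beta"]), C_beta = unname(p["C_alpha"]),
           alpha = unname(p["beta"]), beta = unname(p["alpha"]))
  }
  model <- fit_par_to_model(p, family)
  # covariance from the Jacobian at the optimum; heteroscedasticity-robust
  # (sandwich, HC1) because the 1/|G| weighting leaves the stacked G'/G''
  # residuals with unequal variances under component-wise noise
  J <- num_jacobian(resid_fn, p)
  r0 <- resid_fn(p)
  nres <- length(r0)
  dof <- max(nres - npar, 1L)
  cov_log <- tryCatch({
    A <- solve(crossprod(J))
    A %*% crossprod(J * r0) %*% A * nres / dof
  }, error = function(e) matrix(NA_real_, npar, npar))
  se_t <- sqrt(pmax(diag(cov_log), 0))
  # delta method back to the natural scale for log-fitted moduli
  scale <- c(exp(p[info$log]), rep(1, length(info$exp)))
  ci95 <- qt(0.975, dof) * se_t * scale
  names(ci95) <- names(p)
  boundary <- names(p[info$exp])[p[info$exp] < 1e-6 | p[info$exp] > 1 - 1e-6]
  derived <- derived_params(model)
  if (model$family == "maxwell" && all(is.finite(se_t))) {
    # tau = eta/E: propagate on the log scale including covariance
    v <- cov_log[1, 1] + cov_log[2, 2] - 2 * cov_log[1, 2]
    attr(derived, "tau_ci95") <- qt(0.975, dof) * sqrt(max(v, 0)) * derived$tau
  }
  structure(list(model = model, ci95 = ci95, n_used = n_used,
                 n_excluded = n_excluded,
                 residual = sqrt(best$deviance / (2 * n_used)),
                 derived = derived, boundary = boundary, cov_log = cov_log,
                 dof = dof, family = family),
            class = "visco_fit")
}

num_jacobian <- function(fn, p, h = 1e-6) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    hj <- h * max(abs(p[j]), 1)
    pp <- p; pp[j] <- pp[j] + hj
    pm <- p; pm[j] <- pm[j] - hj
    J[, j] <- (fn(pp) - fn(pm)) / (2 * hj)
  }
  J
}

#' @export
print.visco_fit <- function(x, ...) {
  cat("<visco_fit> family:", x$family, "\n")
  pars <- fit_model_to_par(x$model)
  info <- fit_param_info(x$family)
  nat <- c(exp(pars[info$log]), pars[info$exp])
  names(nat) <- names(pars)
  for (nm in names(nat)) {
    cat(sprintf("  %-8s %12.6g +/- %.4g (95%% CI)\n", nm, nat[[nm]],
                x$ci95[[nm]]))
  }
  cat("  points used:", x$n_used, "( excluded:", x$n_excluded,
      "); RMS relative residual:", signif(x$residual, 4), "\n")
  if (length(x$boundary)) {
    cat("  NOTE: exponent(s) at the [0,1] boundary:",
        paste(x$boundary, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Crossover frequency of a fitted model
#'
#' The frequency at which G' = G'', in Hz.  For a Maxwell fit this is
#' E/(2 pi eta) exactly; otherwise the numeric root of G'(w) = G''(w) on
#' the fitted model.  Absence of a crossover is reported as \code{NA},
#' not an error.
#'
#' @param fit a \code{\link{fit_model}} result.
#' @return crossover frequency, Hz (NA if absent).
#' @export
crossover_from_fit <- function(fit) {
  stopifnot(inherits(fit, "visco_fit"))
  m <- fit$model
  if (m$family == "maxwell") return(m$E / (2 * pi * m$eta))
  wc <- crossover_omega(function(w) model_G(m, w))
  if (is.na(wc)) NA_real_ else wc / (2 * pi)
}

#' Viscosity from the slope of the loss modulus
#'
#' Fits G''(w) = eta w through the origin by weighted least squares
#' (relative weighting, appropriate for data spanning decades); points
#' with non-positive or non-finite G'' are excluded.
#'
#' @param spectrum a \code{\link{response_spectrum}}.
#' @return list with \code{eta} (Pa s), \code{se} (standard error of the
#'   slope) and \code{n_used}.
#' @export
viscosity_from_loss <- function(spectrum) {
  stopifnot(inherits(spectrum, "response_spectrum"))
  Gpp <- Im(spectrum$G)
  keep <- is.finite(Gpp) & Gpp > 0 & !spectrum$qc
  if (sum(keep) < 3) stop("need at least 3 positive loss-modulus points")
  w <- spectrum$omega[keep]
  y <- Gpp[keep]
  fit <- lm(y ~ 0 + w, weights = 1 / y^2)
  # suppress the "essentially perfect fit" note on noiseless input
  se <- suppressWarnings(unname(sqrt(diag(vcov(fit)))[1]))
  list(eta = unname(coef(fit)[1]), se = se, n_used = sum(keep))
}
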