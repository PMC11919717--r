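# Readers/writers, the default sweep grid, synthetic fixture generators
# and the 4-step measurement workflow.  All files are plain text: traces
# as TSV with a commented YAML header, spectra as CSV, fits and ground
# truth as JSON.

#' Default microrheology frequency grid
#'
#' Log-spaced drive frequencies from \code{fmin} to \code{fmax} Hz at
#' \code{points_per_decade}, inclusive of both endpoints (the sweep upper
#' bound is the drive Nyquist frequency, 6.25 kHz for 25 kHz sharing).
#'
#' @param fmin lowest frequency, Hz.
#' @param fmax highest frequency, Hz.
#' @param points_per_decade grid density.
#' @return increasing numeric vector of frequencies, Hz.
#' @examples
#' default_frequency_grid()           # 0.1 Hz ... 6250 Hz, 5/decade
#' @export
default_frequency_grid <- function(fmin = 0.1, fmax = 6250,
                                   points_per_decade = 5) {
  stopifnot(fmin > 0, fmax > fmin, points_per_decade >= 1)
  kmax <- floor(log10(fmax / fmin) * points_per_decade + 1e-9)
  f <- fmin * 10^(seq(0, kmax) / points_per_decade)
  if (tail(f, 1) < fmax * (1 - 1e-12)) f <- c(f, fmax)
  f
}

# run a function with a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Add seeded Gaussian detector noise to an interleaved trace
#'
#' Additive white noise on the sampled signals only (detector noise, not
#' thermodynamically consistent Brownian motion).  The noise SD is
#' \code{noise} times the RMS of the driving-trap stream after transient
#' removal, applied to both streams.
#'
#' @param trace an \code{\link{interleaved_trace}}.
#' @param noise relative noise level (0 = return unchanged).
#' @param seed integer seed (global RNG state is restored afterwards).
#' @return the trace with noisy \code{V1}, \code{V2}.
#' @export
add_detector_noise <- function(trace, noise, seed) {
  stopifnot(inherits(trace, "interleaved_trace"), noise >= 0)
  if (noise == 0) return(trace)
  idx <- seq_along(trace$V1) > trace$n_transient_cycles
  sd0 <- noise * sqrt(mean(trace$V1[idx]^2))
  with_seed(seed, {
    trace$V1 <- trace$V1 + rnorm(length(trace$V1), sd = sd0)
    trace$V2 <- trace$V2 + rnorm(length(trace$V2), sd = sd0)
  })
  trace
}

trace_header <- function(trace) {
  cfg <- trace$config
  list(drive_freq_hz = trace$drive_freq, phase_rad = trace$phase,
       n_transient_cycles = trace$n_transient_cycles,
       k_pn_um = cfg$k, a_um = cfg$a, A_um = cfg$A,
       ramp_s = cfg$ramp, dwell_s = cfg$dwell,
       sample_delay_s = cfg$sample_delay, dt_s = cfg$dt,
       volt_per_pn = cfg$volt_per_pn, linear_range_um = cfg$linear_range)
}

#' Write / read an interleaved trace as TSV
#'
#' Tab-separated columns \code{time_s}, \code{slot} (1|2), \code{signal},
#' time-ordered, preceded by a commented YAML header echoing the
#' configuration.  \code{read_trace} reconstructs the
#' \code{interleaved_trace} exactly (numeric fields at full precision).
#'
#' @param trace an \code{\link{interleaved_trace}}.
#' @param path file path.
#' @return \code{write_trace}: \code{path}, invisibly; \code{read_trace}:
#'   an \code{interleaved_trace}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "interleaved_trace"))
  hdr <- paste0("# ", strsplit(yaml::as.yaml(trace_header(trace)),
                               "\n")[[1]])
  df <- data.frame(
    time_s = c(trace$t1, trace$t2),
    slot = rep(c(1L, 2L), c(length(trace$t1), length(trace$t2))),
    signal = c(trace$V1, trace$V2))
  df <- df[order(df$time_s), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\tslot\tsignal", con)
  writeLines(sprintf("%.17g\t%d\t%.17g", df$time_s, df$slot, df$signal), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- yaml::yaml.load(paste(sub("^# ?", "", hdr_lines), collapse = "\n"))
  df <- read.delim(text = lines[!grepl("^#", lines)])
  cfg <- ts_config(k = hdr$k_pn_um, a = hdr$a_um, A = hdr$A_um,
                   ramp = hdr$ramp_s, dwell = hdr$dwell_s,
                   sample_delay = hdr$sample_delay_s, dt = hdr$dt_s,
                   volt_per_pn = hdr$volt_per_pn,
                   linear_range = hdr$linear_range_um)
  s1 <- df$slot == 1L
  structure(list(t1 = df$time_s[s1], V1 = df$signal[s1],
                 t2 = df$time_s[!s1], V2 = df$signal[!s1],
                 drive_freq = hdr$drive_freq_hz, phase = hdr$phase_rad,
                 n_transient_cycles = as.integer(hdr$n_transient_cycles),
                 config = cfg),
            class = "interleaved_trace")
}

#' Write / read a response spectrum as CSV
#'
#' Columns \code{omega_rad_s, freq_hz, chi_re, chi_im, G_prime_pa,
#' G_dprime_pa, stage, qc_flag}, with a commented YAML header holding the
#' provenance scalars (k, a, omega_t).
#'
#' @param spectrum a \code{\link{response_spectrum}}.
#' @param path file path.
#' @return \code{write_spectrum}: \code{path}, invisibly;
#'   \code{read_spectrum}: a \code{response_spectrum}.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "response_spectrum"))
  hdr <- paste0("# ", strsplit(yaml::as.yaml(list(
    k_pn_um = spectrum$k, a_um = spectrum$a,
    omega_t_rad_s = spectrum$omega_t)), "\n")[[1]])
  df <- as.data.frame(spectrum)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%s,%s",
                     df$omega_rad_s, df$freq_hz, df$chi_re, df$chi_im,
                     df$G_prime_pa, df$G_dprime_pa, df$stage, df$qc_flag),
             con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- yaml::yaml.load(paste(sub("^# ?", "", hdr_lines), collapse = "\n"))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  response_spectrum(df$omega_rad_s, complex(real = df$chi_re,
                                            imaginary = df$chi_im),
                    a = hdr$a_um, stage = df$stage[1],
                    k = if (is.null(hdr$k_pn_um)) NA_real_ else hdr$k_pn_um,
                    omega_t = if (is.null(hdr$omega_t_rad_s)) NA_real_
                              else hdr$omega_t_rad_s,
                    qc = as.logical(df$qc_flag))
}

#' Write a model fit as JSON
#'
#' @param fit a \code{\link{fit_model}} result.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "visco_fit"))
  m <- fit$model
  jsonlite::write_json(list(
    model = list(family = m$family,
                 params = m[setdiff(names(m), "family")],
                 units = "pN-um-s"),
    ci95 = as.list(fit$ci95),
    diagnostics = list(n_used = fit$n_used, n_excluded = fit$n_excluded,
                       residual = fit$residual, dof = fit$dof,
                       boundary = fit$boundary),
    derived = list(tau_s = fit$derived$tau,
                   omega_c_rad_s = fit$derived$omega_c,
                   f_c_hz = fit$derived$f_c,
                   plateau_pa = fit$derived$plateau)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Generate a synthetic sweep fixture on disk
#'
#' Simulates the full time-shared sweep for a ground-truth model, adds
#' optional seeded detector noise, and writes one trace file per frequency
#' plus a ground-truth sidecar JSON (the model, the ideal response, and
#' the FHA-predicted deviated response at each snapped frequency).
#' Byte-stable for a fixed seed.
#'
#' @param model ground-truth \code{\link{visco_model}}.
#' @param dir output directory (created if needed).
#' @param config a \code{\link{ts_config}}.
#' @param freqs drive frequencies, Hz.
#' @param noise relative detector noise level (0 = noiseless).
#' @param seed integer seed for the noise.
#' @param n_periods evaluation periods per frequency.
#' @return invisibly, a list with the trace paths and the sidecar path.
#' @export
generate_fixture <- function(model, dir, config = ts_config(),
                             freqs = default_frequency_grid(),
                             noise = 0, seed = 0L, n_periods = 4) {
  stopifnot(inherits(model, "visco_model"), inherits(config, "ts_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- run_sweep(model, freqs, config, n_periods = n_periods)
  paths <- character(length(traces))
  for (i in seq_along(traces)) {
    tr <- add_detector_noise(traces[[i]], noise, seed + i)
    paths[i] <- file.path(dir, sprintf("trace_%03d.tsv", i))
    write_trace(tr, paths[i])
  }
  f_eff <- vapply(traces, function(tr) tr$drive_freq, numeric(1))
  omega <- 2 * pi * f_eff
  omega_t <- 2 * pi * config$per_trap_rate
  chi_fn <- function(w) model_chi(model, w, config$a)
  chi_ideal <- chi_fn(omega)
  chi_dev <- fha_forward(chi_fn, omega, omega_t, config$k)
  sidecar <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    model = list(family = model$family,
                 params = model[setdiff(names(model), "family")],
                 units = "pN-um-s"),
    k_pn_um = config$k, a_um = config$a, noise = noise, seed = seed,
    freq_hz = f_eff,
    chi_ideal_re = Re(chi_ideal), chi_ideal_im = Im(chi_ideal),
    chi_deviated_fha_re = Re(chi_dev), chi_deviated_fha_im = Im(chi_dev)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(traces = paths, ground_truth = sidecar))
}

#' Run the 4-step active-microrheology workflow
#'
#' Executes the measurement pipeline on file inputs: (1) probe/trap
#' centring (assumed done upstream; logged as a no-op), (2) trap-stiffness
#' advisory - after fitting, warn when the trap is stiffer than the
#' material response at the Nyquist frequency (k |chi(w_Nyq)| >= 1, the
#' regime where a time-shared trap cannot resolve a viscoelastic liquid),
#' (3) trap stiffness from a force scan, (4) sweep extraction,
#' FHA compensation and model fitting.
#'
#' @param trace_files paths of interleaved-trace TSV files (one sweep).
#' @param family_hint material-class assumption for the compensation (see
#'   \code{\link{fha_compensate}}).
#' @param scan_file optional path to a position/force scan (TSV/CSV with
#'   columns position, force) for step 3; if \code{NULL}, \code{k} from
#'   the trace headers is used and step 3 is marked skipped.
#' @param out optional path for a JSON report.
#' @return a report list: stage log, trap stiffness, the deviated and
#'   compensated spectra (data frames), the fit parameters, derived
#'   quantities and the stiffness advisory.
#' @export
workflow_run <- function(trace_files, family_hint, scan_file = NULL,
                         out = NULL) {
  stages <- character(0)
  log_stage <- function(s) {
    stages <<- c(stages, s)
    message("[workflow] ", s)
  }
  log_stage("stage 1 (centring): assumed done upstream (no-op)")
  log_stage("stage 2 (stiffness choice): advisory evaluated after fitting")
  # stage 3: trap stiffness
  if (!is.null(scan_file)) {
    if (!file.exists(scan_file)) {
      stop("stage 3 (trap calibration): scan file not found: ", scan_file)
    }
    scan <- read.delim(scan_file, sep = "", comment.char = "#")
    cal <- trap_stiffness_from_scan(scan[[1]], scan[[2]])
    k <- cal$k
    log_stage(sprintf("stage 3 (trap calibration): k = %.4g pN/um", k))
  } else {
    cal <- NULL
    k <- NULL
    log_stage("stage 3 (trap calibration): skipped, using trace header k")
  }
  # stage 4: sweep -> extract -> compensate -> fit
  missing <- trace_files[!file.exists(trace_files)]
  if (length(missing)) {
    stop("stage 4 (sweep): trace files not found: ",
         paste(missing, collapse = ", "))
  }
  traces <- lapply(trace_files, read_trace)
  dev <- deviated_spectrum(traces)
  if (is.null(k)) k <- dev$k
  comp <- fha_compensate(dev, family_hint, k = k)
  fit <- fit_model(comp, resolve_family_hint(family_hint))
  log_stage(sprintf(
    "stage 4 (sweep): %d frequencies extracted, compensated (%s, %d iter), fitted",
    length(dev$omega), family_hint, attr(comp, "iterations")))
  # drive Nyquist: omega = 2 pi f_t / 2
  chi_nyq <- model_chi(fit$model, pi * traces[[1]]$config$per_trap_rate,
                       dev$a)
  advisory <- list(k_chi_nyquist = abs(k * chi_nyq),
                   trap_too_stiff = abs(k * chi_nyq) >= 1)
  if (advisory$trap_too_stiff) {
    warning("trap stiffer than the material response at Nyquist ",
            "(k|chi| = ", signif(advisory$k_chi_nyquist, 3),
            " >= 1): high-frequency response may be unresolvable")
  }
  info <- fit_param_info(fit$family)
  report <- list(stages = stages, k = k, calibration = cal,
                 deviated = as.data.frame(dev),
                 compensated = as.data.frame(comp),
                 fit = list(family = fit$family,
                            params = fit$model[setdiff(names(fit$model),
                                                       "family")],
                            ci95 = as.list(fit$ci95),
                            n_used = fit$n_used,
                            n_excluded = fit$n_excluded,
                            residual = fit$residual),
                 derived = list(tau_s = fit$derived$tau,
                                f_c_hz = fit$derived$f_c,
                                plateau_pa = fit$derived$plateau),
                 advisory = advisory,
                 converged = attr(comp, "converged"))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "columns")
  }
  report
}

#' Synthetic force-clamp creep trace
#'
#' Generates the record a force clamp would produce on a bead in the given
#' material: x_bead(t) = J(t) F0 / (6 pi a), x_trap = x_bead + F/k, with
#' optional seeded relative noise on the clamp force.
#'
#' @param model ground-truth \code{\link{visco_model}}.
#' @param t sample times, s.
#' @param F0 clamp force, pN.
#' @param k trap stiffness, pN/um.
#' @param a bead radius, um.
#' @param noise relative force noise SD.
#' @param seed integer seed.
#' @return a \code{\link{creep_trace}}.
#' @export
synth_creep_trace <- function(model, t, F0 = 40, k = 220, a = 0.5,
                              noise = 0, seed = 0L) {
  xb <- model_creep(model, t) * F0 / gse_prefactor(a)
  F <- if (noise > 0) {
    with_seed(seed, F0 * (1 + rnorm(length(t), sd = noise)))
  } else rep(F0, length(t))
  creep_trace(t, x_trap = xb + F / k, F = F, k = k, F0 = F0, a = a)
}

#' Synthetic Stokes-drag series
#'
#' Plateau drag forces F = 6 pi eta R v with optional seeded relative
#' noise.
#'
#' @param eta viscosity, Pa s.
#' @param v trap velocities, um/s.
#' @param R bead radius, um.
#' @param noise relative noise SD.
#' @param seed integer seed.
#' @return data.frame with \code{v} and \code{F_plateau}.
#' @export
synth_drag_series <- function(eta, v, R = 0.5, noise = 0, seed = 0L) {
  F <- 6 * pi * eta * R * v
  if (noise > 0) F <- with_seed(seed, F * (1 + rnorm(length(v), sd = noise)))
  data.frame(v = v, F_plateau = F)
}

#' Synthetic trap force scan
#'
#' Force profile F = k x - c x^3 across the linear range and saturating
#' wings, for calibration tests.
#'
#' @param k trap stiffness, pN/um.
#' @param cubic coefficient of the saturating cubic term, pN/um^3.
#' @param range scan half-width, um.
#' @param n number of scan points.
#' @param noise absolute force noise SD, pN.
#' @param seed integer seed.
#' @return data.frame with \code{position} and \code{force}.
#' @export
synth_trap_scan <- function(k, cubic = 0, range = 0.6, n = 121L,
                            noise = 0, seed = 0L) {
  x <- seq(-range, range, length.out = n)
  F <- k * x - cubic * x^3
  if (noise > 0) F <- with_seed(seed, F + rnorm(n, sd = noise))
  data.frame(position = x, force = F)
}

#' Synthetic trans-droplet force scan
#'
#' Harmonic-trap/finite-sphere toy model of a scan across a whole
#' particle: restoring force F(d) = k d exp(-d^2 / (2 sigma^2)) with
#' sigma = \code{edge_frac} * R, so the force extrema sit at +/- sigma,
#' inside the geometric radius.  Used to calibrate the bias of
#' \code{\link{radius_from_scan}}.
#'
#' @param R true particle radius, um.
#' @param k central stiffness, pN/um.
#' @param edge_frac extremum position as a fraction of R.
#' @param n scan points.
#' @return data.frame with \code{position}, \code{force} and attribute
#'   \code{true_radius}.
#' @export
synth_droplet_scan <- function(R, k = 100, edge_frac = 0.8, n = 201L) {
  x <- seq(-2 * R, 2 * R, length.out = n)
  s <- edge_frac * R
  df <- data.frame(position = x, force = k * x * exp(-x^2 / (2 * s^2)))
  attr(df, "true_radius") <- R
  df
}
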