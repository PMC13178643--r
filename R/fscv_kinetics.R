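#' Electrode calibration
#'
#' Electrodes are calibrated against a known dopamine standard (3 uM by
#' convention) in a flow-injection system; the factor converts recorded
#' current (nA) to concentration (uM).
#'
#' @param known_conc standard concentration, uM.
#' @param measured_current current produced by the standard, nA.
#' @return object of class `calibration` with `factor = measured_current /
#'   known_conc` (nA per uM).
#' @export
calibration <- function(known_conc = 3, measured_current) {
  factor <- measured_current / known_conc
  if (!is.finite(factor) || factor <= 0) stop("calibration factor must be > 0")
  structure(list(known_conc = known_conc, measured_current = measured_current,
                 factor = factor), class = "calibration")
}

#' Convert a current trace to concentration
#'
#' @param trace a [voltammetry_trace()] in nA.
#' @param cal a [calibration()].
#' @return the trace with `signal / cal$factor` and unit uM; metadata
#'   preserved. Calibrating an already-calibrated trace is an error.
#' @export
apply_calibration <- function(trace, cal) {
  stopifnot(inherits(trace, "voltammetry_trace"), inherits(cal, "calibration"))
  if (trace$unit == "uM") stop("trace already calibrated (unit uM)")
  out <- trace
  out$signal <- trace$signal / cal$factor
  out$unit <- "uM"
  out
}

#' Signal stability criterion
#'
#' Stimulations are repeated until the evoked signal stabilises, defined as
#' under 10% variability in peak height across the last three recordings.
#' Operationalised as: every peak within `tol` of the three-peak mean.
#'
#' @param peaks numeric vector of exactly 3 positive peak heights, uM.
#' @param tol relative tolerance, default 0.10.
#' @return `TRUE` iff `max(abs(peaks - mean)) / mean <= tol`.
#' @export
check_stability <- function(peaks, tol = 0.10) {
  if (length(peaks) != 3) stop("exactly 3 peak heights required")
  if (any(peaks <= 0)) stop("peak heights must be > 0")
  m <- mean(peaks)
  max(abs(peaks - m)) / m <= tol
}

#' Baseline-subtracted peak height of a transient
#'
#' Maximum signal in the window from stimulus onset to `window` seconds after
#' it, minus the mean of the 1 s immediately preceding the stimulus.
#'
#' @param trace a calibrated [voltammetry_trace()] (uM).
#' @param window search window after stimulus onset, s.
#' @param baseline_window pre-stimulus averaging window, s.
#' @return peak height, uM.
#' @export
peak_height <- function(trace, window = 5, baseline_window = 1) {
  stopifnot(inherits(trace, "voltammetry_trace"))
  if (trace$unit != "uM") stop("peak_height expects a calibrated (uM) trace")
  t0 <- trace$stim_onset
  if (t0 < min(trace$time) || t0 > max(trace$time))
    stop("stimulus onset not inside trace")
  pre <- trace$signal[trace$time >= t0 - baseline_window & trace$time < t0]
  base <- if (length(pre)) mean(pre) else 0
  win <- trace$signal[trace$time >= t0 & trace$time <= t0 + window]
  max(win) - base
}

#' Percent of baseline
#' @param values numeric vector, uM (or any common unit).
#' @param baseline positive scalar baseline in the same unit.
#' @return `100 * values / baseline`.
#' @export
percent_of_baseline <- function(values, baseline) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline must be > 0")
  100 * values / baseline
}

#' Fit the release/uptake kinetic model to one transient
#'
#' Nonlinear least squares of the pulsed-release + Michaelis-Menten forward
#' model (the same RK4 integrator used by [simulate_fscv_trace()]) against the
#' trace from stimulus onset to the end of the recording. Parameters are
#' bounded below at zero (L-BFGS-B); any subset can be held fixed. By default
#' all three of `[DA]p` (release per pulse), `Vmax` and `Km` float, matching
#' drug-free modelling practice; under a competitive inhibitor it is common to
#' fix `Vmax` at the slice's baseline value (see [apparent_km_series()]).
#'
#' @param trace calibrated [voltammetry_trace()] (uM) containing the
#'   stimulation epoch and at least 2 s of decay.
#' @param protocol [stim_protocol()]; defaults to the trace's own.
#' @param fixed named list of parameters to hold fixed, e.g.
#'   `list(vmax = 2.1)`; names among `da_per_pulse`, `vmax`, `km`.
#' @param init named list of starting values; defaults: `da_per_pulse` =
#'   observed peak, `vmax` = 2 uM/s, `km` = 0.16 uM.
#' @param maxit maximum optimizer iterations.
#' @return object of class `kinetic_fit`: `da_per_pulse`, `vmax`, `km`
#'   (apparent when drug present), `fixed_flags`, `sse` (uM^2), `converged`,
#'   `n_iter`.
#' @export
fit_transient <- function(trace, protocol = trace$protocol, fixed = list(),
                          init = list(), maxit = 500) {
  stopifnot(inherits(trace, "voltammetry_trace"))
  if (trace$unit != "uM") stop("fit_transient expects a calibrated (uM) trace")
  t0 <- trace$stim_onset
  sel <- trace$time >= t0 - 1e-9
  if (sum(sel) < 5) stop("fewer than 5 samples after stimulus onset")
  tt <- trace$time[sel]; yy <- trace$signal[sel]

  pk <- peak_height(trace)
  noise_est <- stats::sd(trace$signal[trace$time < t0])
  if (!is.finite(noise_est)) noise_est <- 0
  if (pk <= 0 || (noise_est > 0 && pk < 3 * noise_est))
    stop("unfittable trace: peak below 3x the pre-stimulus noise estimate")

  par_names <- c("da_per_pulse", "vmax", "km")
  bad <- setdiff(names(fixed), par_names)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  defaults <- list(da_per_pulse = max(pk / protocol$n_pulses, 1e-3),
                   vmax = 2, km = 0.16)
  start <- utils::modifyList(defaults, init)
  free <- setdiff(par_names, names(fixed))

  full <- function(theta) {
    p <- as.list(theta); names(p) <- free
    p <- utils::modifyList(p, fixed)
    p[par_names]
  }
  objective <- function(theta) {
    p <- full(theta)
    pred <- mm_forward(tt, t0, protocol, p$da_per_pulse, p$vmax, p$km)
    sum((yy - pred)^2)
  }

  if (length(free) == 0) {
    p <- fixed[par_names]
    sse <- objective(numeric(0))
    return(structure(list(da_per_pulse = p$da_per_pulse, vmax = p$vmax,
                          km = p$km, fixed_flags = par_names, sse = sse,
                          converged = TRUE, n_iter = 0L),
                     class = "kinetic_fit"))
  }

  theta0 <- unlist(start[free])
  lower <- stats::setNames(rep(1e-9, length(free)), free)
  lower["vmax"] <- 0  # vmax = 0 (no uptake) is admissible
  lower <- lower[free]
  opt <- tryCatch(
    stats::optim(theta0, objective, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = maxit, factr = 10)),
    error = function(e) NULL)
  if (is.null(opt)) {
    p <- full(theta0)
    return(structure(list(da_per_pulse = p$da_per_pulse, vmax = p$vmax,
                          km = p$km, fixed_flags = names(fixed),
                          sse = objective(theta0), converged = FALSE,
                          n_iter = 0L),
                     class = "kinetic_fit"))
  }
  p <- full(opt$par)
  structure(list(da_per_pulse = p$da_per_pulse, vmax = p$vmax, km = p$km,
                 fixed_flags = names(fixed), sse = opt$value,
                 converged = opt$convergence == 0,
                 n_iter = as.integer(opt$counts[["function"]])),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> [DA]p=%.4g uM, Vmax=%.4g uM/s, Km=%.4g uM, sse=%.3g, %s\n",
              x$da_per_pulse, x$vmax, x$km, x$sse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Apparent-Km series across a drug concentration ladder
#'
#' For each drug trace the transient is refit with `Vmax` fixed at the slice's
#' baseline estimate while release and the (apparent) Michaelis constant
#' float — competitive inhibitors raise the apparent Km without changing
#' transporter number. Set `fix_vmax = FALSE` for a fully floating refit.
#'
#' @param traces list of calibrated drug traces, one per concentration; each
#'   must carry `condition$concentration` (uM) and share the baseline
#'   protocol.
#' @param baseline_fit converged [fit_transient()] result of the drug-free
#'   trace.
#' @param fix_vmax hold `Vmax` at `baseline_fit$vmax` (default TRUE).
#' @return data.frame of class `apparent_km_series` with columns
#'   `concentration`, `apparent_km`, sorted by ascending concentration;
#'   non-converged fits are dropped with a warning.
#' @export
apparent_km_series <- function(traces, baseline_fit, fix_vmax = TRUE) {
  stopifnot(inherits(baseline_fit, "kinetic_fit"))
  if (!baseline_fit$converged) stop("baseline fit did not converge")
  rows <- lapply(traces, function(tr) {
    conc <- tr$condition$concentration
    if (is.null(conc)) stop("trace missing condition$concentration")
    fixed <- if (fix_vmax) list(vmax = baseline_fit$vmax) else list()
    fit <- fit_transient(tr, fixed = fixed,
                         init = list(km = baseline_fit$km,
                                     da_per_pulse = baseline_fit$da_per_pulse))
    data.frame(concentration = conc, apparent_km = fit$km,
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  if (any(!out$converged)) {
    warning(sum(!out$converged), " non-converged drug fit(s) excluded")
    out <- out[out$converged, , drop = FALSE]
  }
  out <- out[order(out$concentration), c("concentration", "apparent_km")]
  rownames(out) <- NULL
  class(out) <- c("apparent_km_series", "data.frame")
  out
}

#' Estimate inhibitor potency (Ki) from an apparent-Km series
#'
#' Under competitive inhibition the apparent Km rises linearly with inhibitor
#' concentration: `Km_app = Km * (1 + C / Ki)`, so the slope of the
#' ordinary-least-squares line of apparent Km on concentration equals
#' `Km / Ki`, and `Ki = Km_baseline / slope`. The baseline Km is the dopamine
#' affinity of the transporter in drug-free conditions; when no slice-specific
#' baseline fit exists a literature value of 0.16 uM is conventional.
#'
#' @param points data.frame with columns `concentration`, `apparent_km`
#'   (e.g. an [apparent_km_series()] result); at least 3 points over at least
#'   2 distinct concentrations.
#' @param baseline_km drug-free Michaelis constant, uM.
#' @return object of class `potency_result`: `ki` (uM), `slope`, `intercept`,
#'   `r_squared`, `baseline_km`, `n_points`.
#' @export
estimate_ki <- function(points, baseline_km = 0.16) {
  if (!all(c("concentration", "apparent_km") %in% names(points)))
    stop("points must have columns concentration and apparent_km")
  if (nrow(points) < 3 || length(unique(points$concentration)) < 2)
    stop("need >= 3 points spanning >= 2 distinct concentrations")
  if (baseline_km <= 0) stop("baseline_km must be > 0")
  fit <- linear_fit(points$concentration, points$apparent_km)
  if (fit$slope <= 0)
    stop("potency undefined: apparent Km does not increase with concentration")
  structure(list(ki = baseline_km / fit$slope, slope = fit$slope,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 baseline_km = baseline_km, n_points = nrow(points)),
            class = "potency_result")
}

#' @export
print.potency_result <- function(x, ...) {
  cat(sprintf("<potency_result> Ki=%.4g uM (slope %.4g, r2=%.4f, n=%d, baseline Km %.3g uM)\n",
              x$ki, x$slope, x$r_squared, x$n_points, x$baseline_km))
  invisible(x)
}

#' Release change by stimulation protocol
#'
#' Contrasts drug-on peak release against pre-drug reference traces for each
#' stimulation protocol (tonic single pulse vs phasic bursts), as percent of
#' baseline. Amphetamine characteristically suppresses tonic release while
#' enhancing phasic release; reuptake blockers do neither.
#'
#' @param drug_traces named list (protocol label -> calibrated trace) under
#'   drug.
#' @param reference_traces named list with matching labels, pre-drug.
#' @return data.frame: `protocol`, `drug_peak`, `reference_peak`,
#'   `pct_of_baseline`.
#' @export
release_by_protocol <- function(drug_traces, reference_traces) {
  if (length(drug_traces) == 0) stop("empty protocol map")
  labs <- names(drug_traces)
  missing <- setdiff(labs, names(reference_traces))
  if (length(missing))
    stop("missing reference protocol(s): ", paste(missing, collapse = ", "))
  rows <- lapply(labs, function(l) {
    dp <- peak_height(drug_traces[[l]])
    rp <- peak_height(reference_traces[[l]])
    data.frame(protocol = l, drug_peak = dp, reference_peak = rp,
               pct_of_baseline = percent_of_baseline(dp, rp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a group-level modulation curve
#'
#' Generic ladder assembly for input-output, calcium-concentration or agonist
#' dose-response experiments: each slice's values are expressed as percent of
#' its own baseline, then levels are summarised across slices as mean and
#' standard error. Level order is preserved from the input.
#'
#' @param groups named list: level label -> numeric vector of per-slice values
#'   (uM), one entry per slice; every level needs at least one slice.
#' @param baselines numeric vector of per-slice baselines (uM), matched by
#'   position to each level's slices.
#' @return data.frame: `level`, `n`, `mean_pct`, `sem_pct`.
#' @export
assemble_modulation_curve <- function(groups, baselines) {
  if (length(groups) == 0) stop("no levels supplied")
  rows <- lapply(seq_along(groups), function(i) {
    vals <- groups[[i]]
    if (length(vals) == 0) stop("level '", names(groups)[i], "' has zero slices")
    if (length(baselines) != length(vals))
      stop("baselines must match the number of slices at each level")
    pct <- 100 * vals / baselines
    sem <- if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else 0
    data.frame(level = names(groups)[i], n = length(pct),
               mean_pct = mean(pct), sem_pct = sem)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
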