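#' Stimulation protocol descriptor
#'
#' Tonic stimulation is a single pulse; phasic stimulation is a short burst
#' (typically 5 pulses at 5-20 Hz). Amplitude and pulse width are carried as
#' metadata only: release is modelled as an instantaneous concentration jump
#' per pulse.
#'
#' @param n_pulses integer pulse count, >= 1.
#' @param frequency burst frequency in Hz; ignored (and may be NA) when
#'   `n_pulses == 1`.
#' @param amplitude stimulation current in uA (metadata).
#' @param pulse_width pulse width in ms (metadata).
#' @return object of class `stim_protocol`.
#' @export
stim_protocol <- function(n_pulses = 1, frequency = NA_real_,
                          amplitude = 350, pulse_width = 4) {
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (n_pulses > 1 && (!is.finite(frequency) || frequency <= 0))
    stop("frequency must be > 0 for multi-pulse protocols")
  structure(list(n_pulses = n_pulses, frequency = frequency,
                 amplitude = amplitude, pulse_width = pulse_width),
            class = "stim_protocol")
}

#' Tonic (single-pulse) and phasic (burst) protocol presets
#' @param frequency burst frequency in Hz for the phasic preset.
#' @rdname stim_protocol
#' @export
tonic_protocol <- function() stim_protocol(1, NA_real_, amplitude = 350)

#' @rdname stim_protocol
#' @export
phasic_protocol <- function(frequency = 20) {
  stim_protocol(5, frequency, amplitude = 500)
}

#' FSCV simulation parameters
#'
#' The generative model for an evoked dopamine transient: each stimulus pulse
#' adds `release_scale * da_per_pulse` uM of dopamine instantaneously, and the
#' transporter clears it with Michaelis-Menten kinetics
#' `dC/dt = -vmax * C / (km_app + C)` where the apparent Michaelis constant
#' under a competitive uptake inhibitor at bath concentration `inhibitor_conc`
#' is `km_app = km * (1 + inhibitor_conc / ki_true)`.
#'
#' @param da_per_pulse dopamine released per pulse, uM.
#' @param vmax maximal uptake rate, uM/s (>= 0).
#' @param km drug-free Michaelis constant, uM (> 0).
#' @param inhibitor_conc competitive inhibitor concentration, uM (>= 0).
#' @param ki_true true inhibition constant of the drug, uM (> 0).
#' @param release_scale multiplicative modifier of release under drug
#'   (e.g. amphetamine suppresses single-pulse release, enhances burst
#'   release); dimensionless, default 1.
#' @param noise_sd additive white Gaussian noise on the recorded current, nA.
#' @param calibration_factor electrode sensitivity, nA per uM.
#' @param scan_rate samples per second, Hz (default 10, the triangular
#'   waveform repetition rate).
#' @param duration trace length, s.
#' @param stim_onset time of the first pulse, s.
#' @param seed integer RNG seed for the noise draw.
#' @return object of class `fscv_params`.
#' @export
fscv_params <- function(da_per_pulse = 1, vmax = 2, km = 0.16,
                        inhibitor_conc = 0, ki_true = 2, release_scale = 1,
                        noise_sd = 0, calibration_factor = 5,
                        scan_rate = 10, duration = 15, stim_onset = 5,
                        seed = 1L) {
  p <- list(da_per_pulse = da_per_pulse, vmax = vmax, km = km,
            inhibitor_conc = inhibitor_conc, ki_true = ki_true,
            release_scale = release_scale, noise_sd = noise_sd,
            calibration_factor = calibration_factor, scan_rate = scan_rate,
            duration = duration, stim_onset = stim_onset,
            seed = as.integer(seed))
  if (p$vmax < 0) stop("vmax must be >= 0")
  if (p$km <= 0) stop("km must be > 0")
  if (p$ki_true <= 0) stop("ki_true must be > 0")
  if (p$inhibitor_conc < 0) stop("inhibitor_conc must be >= 0")
  if (p$scan_rate <= 0) stop("scan_rate must be > 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$calibration_factor <= 0) stop("calibration_factor must be > 0")
  if (p$stim_onset < 0 || p$stim_onset >= p$duration)
    stop("stim_onset must lie inside [0, duration)")
  structure(p, class = "fscv_params")
}

#' Apparent Michaelis constant under competitive inhibition
#' @param params an [fscv_params()] object.
#' @return `km * (1 + inhibitor_conc / ki_true)`, uM.
#' @export
apparent_km <- function(params) {
  params$km * (1 + params$inhibitor_conc / params$ki_true)
}

#' Construct a voltammetry trace object
#'
#' @param time sample times, s; strictly increasing and uniformly spaced.
#' @param signal recorded values, nA or uM.
#' @param unit `"uM"` or `"nA"`.
#' @param protocol the [stim_protocol()] used.
#' @param stim_onset time of the first pulse, s.
#' @param condition named list of labels (sex, cycle_stage, drug,
#'   concentration ...).
#' @return object of class `voltammetry_trace`.
#' @export
voltammetry_trace <- function(time, signal, unit = c("uM", "nA"),
                              protocol = tonic_protocol(), stim_onset = 5,
                              condition = list()) {
  unit <- match.arg(unit)
  time <- as.numeric(time); signal <- as.numeric(signal)
  if (length(time) != length(signal)) stop("time/signal length mismatch")
  if (length(time) < 2 || any(diff(time) <= 0)) stop("time must be strictly increasing")
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9) stop("time must be uniformly sampled")
  if (any(!is.finite(signal))) stop("signal must be finite")
  structure(list(time = time, signal = signal, unit = unit,
                 protocol = protocol, stim_onset = stim_onset,
                 condition = condition),
            class = "voltammetry_trace")
}

#' @export
print.voltammetry_trace <- function(x, ...) {
  cat(sprintf("<voltammetry_trace> %d samples @ %.3g Hz, unit %s, %d pulse(s) at t=%.3g s\n",
              length(x$time), 1 / diff(x$time[1:2]), x$unit,
              x$protocol$n_pulses, x$stim_onset))
  invisible(x)
}

pulse_times <- function(stim_onset, protocol) {
  if (protocol$n_pulses == 1) return(stim_onset)
  stim_onset + (seq_len(protocol$n_pulses) - 1) / protocol$frequency
}

# Forward Michaelis-Menten release/uptake model evaluated on a sample grid.
# Shared by the simulator and the transient fitter.
mm_forward <- function(time, stim_onset, protocol, da_per_pulse, vmax, km_app,
                       dt_internal = 1e-3) {
  mm_integrate_cpp(time, pulse_times(stim_onset, protocol),
                   da_per_pulse, vmax, km_app, dt_internal)
}

#' Simulate an evoked dopamine transient
#'
#' Integrates the pulsed-release + Michaelis-Menten-clearance model with a
#' fixed-step 4th-order Runge-Kutta scheme at 1 kHz internal resolution,
#' down-sampled to `scan_rate`. With `as_current = TRUE` the concentration is
#' converted to electrode current via `calibration_factor` and additive
#' Gaussian noise of sd `noise_sd` (nA) is applied; the noise draw is
#' deterministic given `params$seed`.
#'
#' @param params an [fscv_params()] object.
#' @param protocol a [stim_protocol()]; default tonic (single pulse).
#' @param as_current return current in nA (with noise) instead of a clean
#'   concentration trace in uM.
#' @param condition optional named list of condition labels stored on the
#'   trace.
#' @return a [voltammetry_trace()].
#' @export
simulate_fscv_trace <- function(params, protocol = tonic_protocol(),
                                as_current = FALSE, condition = list()) {
  stopifnot(inherits(params, "fscv_params"), inherits(protocol, "stim_protocol"))
  time <- seq(0, params$duration, by = 1 / params$scan_rate)
  conc <- mm_forward(time, params$stim_onset, protocol,
                     params$release_scale * params$da_per_pulse,
                     params$vmax, apparent_km(params))
  cond <- utils::modifyList(
    list(drug = if (params$inhibitor_conc > 0) "drug" else "none",
         concentration = params$inhibitor_conc), condition)
  if (!as_current) {
    return(voltammetry_trace(time, conc, "uM", protocol, params$stim_onset, cond))
  }
  current <- conc * params$calibration_factor
  if (params$noise_sd > 0) {
    current <- current + with_seed(params$seed,
                                   stats::rnorm(length(current), 0, params$noise_sd))
  }
  voltammetry_trace(time, current, "nA", protocol, params$stim_onset, cond)
}

#' Simulate a cumulative concentration-response series
#'
#' One trace per bath concentration of a competitive DAT inhibitor, sharing
#' all baseline parameters; a drug-free baseline trace (concentration 0) is
#' always prepended. This mirrors the cumulative bath-application design used
#' for amphetamine (0.1, 0.3, 1, 3, 10 uM) and methylphenidate (1, 3, 10,
#' 30 uM) ladders.
#'
#' @param params baseline [fscv_params()]; `inhibitor_conc` is overridden per
#'   trace.
#' @param concentrations strictly increasing drug concentrations, uM.
#' @param protocol a [stim_protocol()].
#' @param as_current simulate noisy current traces instead of clean uM traces.
#' @return list of [voltammetry_trace()] of length `length(concentrations)+1`,
#'   baseline first; each trace's `condition$concentration` records the dose.
#' @export
simulate_concentration_series <- function(params, concentrations,
                                          protocol = tonic_protocol(),
                                          as_current = FALSE) {
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(diff(concentrations) <= 0) && length(concentrations) > 1)
    stop("concentrations must be strictly increasing")
  doses <- c(0, concentrations)
  lapply(seq_along(doses), function(i) {
    p <- params
    p$inhibitor_conc <- doses[i]
    p$seed <- params$seed + i - 1L  # independent noise per trace
    simulate_fscv_trace(p, protocol, as_current = as_current)
  })
}

#' Hormone-state parameter presets
#'
#' Categorical hormone conditions map to FSCV parameter modifiers: high
#' estradiol states (pro/estrus) raise pulsatile release and maximal uptake
#' and increase drug potency (lower Ki); ovariectomy reverts to male-like
#' values and bath estradiol on ovariectomised tissue restores potency. The
#' magnitudes are configurable placeholders for directions reported in the
#' literature, not measured quantities.
#'
#' @param stage one of `"male"`, `"pro_estrus"`, `"met_diestrus"`, `"ovx"`,
#'   `"ovx_estradiol"`.
#' @param base [fscv_params()] to modify.
#' @param release_boost,vmax_boost,potency_boost multipliers applied under
#'   high-estradiol states.
#' @return modified [fscv_params()] with `condition` preset applied.
#' @export
hormone_preset <- function(stage = c("male", "pro_estrus", "met_diestrus",
                                     "ovx", "ovx_estradiol"),
                           base = fscv_params(),
                           release_boost = 1.3, vmax_boost = 1.2,
                           potency_boost = 1.5) {
  stage <- match.arg(stage)
  p <- base
  if (stage %in% c("pro_estrus", "ovx_estradiol")) {
    p$da_per_pulse <- base$da_per_pulse * release_boost
    p$vmax <- base$vmax * vmax_boost
    p$ki_true <- base$ki_true / potency_boost
  }
  attr(p, "cycle_stage") <- stage
  p
}

#' Write / read a trace as CSV with a JSON metadata sidecar
#'
#' CSV columns: `time_s`, `value`, `unit` (one of nA, uM). The sidecar
#' `<path>.json` stores the protocol, stimulus onset and condition labels.
#'
#' @param trace a [voltammetry_trace()].
#' @param path CSV file path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly (for `write_trace_csv`); a
#'   [voltammetry_trace()] for `read_trace_csv`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time, value = trace$signal,
                   unit = trace$unit)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(protocol = unclass(trace$protocol),
               stim_onset = trace$stim_onset,
               condition = trace$condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "value", "unit")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns time_s, value, unit")
  sidecar <- paste0(path, ".json")
  proto <- tonic_protocol(); onset <- 5; cond <- list()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    proto <- do.call(stim_protocol, meta$protocol[c("n_pulses", "frequency",
                                                    "amplitude", "pulse_width")])
    onset <- meta$stim_onset
    cond <- as.list(meta$condition)
  }
  voltammetry_trace(df$time_s, df$value, unique(df$unit)[1], proto, onset, cond)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
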