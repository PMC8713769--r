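# Parametric mechanical stimuli and the passive (nonreflexive) muscle model.
# All commands are displacements in mm from resting length L_o, on a uniform
# clock in seconds with t = 0 at record start; stimulus onsets are stored
# explicitly, never implied.

#' Construct a stretch stimulus object
#'
#' Internal constructor shared by the stimulus generators. A
#' `stretch_stimulus` carries the length command (mm from resting length
#' L_o), its uniform clock, and every generating parameter, so that any
#' waveform is exactly reproducible from its parameters alone.
#'
#' @param kind One of `"ramp_hold_release"`, `"ramp_release"`, `"vibration"`,
#'   `"skin_ramp_hold_release"`.
#' @param time Numeric vector of sample times (s).
#' @param command Numeric vector of length equal to `time`; displacement (mm).
#' @param onsets Numeric vector of command onset times (s), one per repeat.
#' @param sample_rate Samples per second (Hz).
#' @param ... Further generating parameters stored on the object
#'   (`amplitude`, `velocity`, `hold`, `vib_frequency`, `vib_peak_to_peak`,
#'   `baseline_offset`, `n_repeats`).
#' @return An object of class `stretch_stimulus`.
#' @keywords internal
new_stimulus <- function(kind, time, command, onsets, sample_rate, ...) {
  stopifnot(length(time) == length(command))
  structure(
    list(kind = kind, time = time, command = command, onsets = onsets,
         sample_rate = sample_rate, ...),
    class = "stretch_stimulus")
}

#' @export
print.stretch_stimulus <- function(x, ...) {
  cat(sprintf("<stretch_stimulus: %s, %d samples @ %g Hz, %d onset(s)>\n",
              x$kind, length(x$time), x$sample_rate, length(x$onsets)))
  invisible(x)
}

#' Ramp-hold-release stretch command
#'
#' Piecewise-linear length command: rise at constant `velocity` to
#' `amplitude`, hold for `hold` seconds, then release symmetrically (the
#' release velocity equals the rise velocity). With `hold = 0` this is a
#' ramp-release. Multiple repeats are separated by `inter_interval` seconds
#' at baseline.
#'
#' @param amplitude Peak displacement from resting length (mm), > 0.
#' @param velocity Ramp speed (mm/s), > 0. Ramp duration is
#'   `amplitude / velocity`.
#' @param hold Plateau duration (s), >= 0.
#' @param sample_rate Sampling rate (Hz).
#' @param onset Time of the first command onset (s); the record holds
#'   baseline before it.
#' @param tail Baseline duration appended after the last release (s).
#' @param n_repeats Number of identical stretches in the record.
#' @param inter_interval Baseline gap between repeats (s).
#' @param baseline_offset Constant background length offset (mm) added to the
#'   whole command; models increased background muscle length (L_o strain).
#' @param kind Stimulus kind label; `"skin_ramp_hold_release"` marks the same
#'   waveform applied as skin indentation.
#' @return A `stretch_stimulus`.
#' @examples
#' s <- make_ramp_hold_release(3, 20, hold = 1, sample_rate = 1000)
#' max(s$command)  # 3 mm plateau
#' @export
make_ramp_hold_release <- function(amplitude, velocity, hold = 0,
                                   sample_rate = 10000, onset = 0.25,
                                   tail = 1, n_repeats = 1,
                                   inter_interval = 1,
                                   baseline_offset = 0,
                                   kind = "ramp_hold_release") {
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  if (velocity <= 0) stop("`velocity` must be positive", call. = FALSE)
  if (hold < 0) stop("`hold` must be non-negative", call. = FALSE)
  ramp <- amplitude / velocity
  cycle <- ramp + hold + ramp
  onsets <- onset + (seq_len(n_repeats) - 1) * (cycle + inter_interval)
  total <- onsets[n_repeats] + cycle + tail
  time <- seq(0, total, by = 1 / sample_rate)
  command <- numeric(length(time))
  for (t0 in onsets) {
    rel <- time - t0
    seg <- pmax(0, pmin(rel, ramp)) * velocity -
      pmax(0, pmin(rel - ramp - hold, ramp)) * velocity
    seg[rel < 0] <- 0
    command <- command + seg
  }
  if (hold == 0) kind <- if (kind == "ramp_hold_release") "ramp_release" else kind
  new_stimulus(kind, time, command + baseline_offset, onsets, sample_rate,
               amplitude = amplitude, velocity = velocity, hold = hold,
               baseline_offset = baseline_offset, n_repeats = n_repeats)
}

#' Sinusoidal muscle vibration command
#'
#' Low-amplitude sinusoid superimposed on resting length; amplitude is half
#' the peak-to-peak excursion. Requires at least 10 samples per cycle.
#'
#' @param frequency Vibration frequency (Hz), > 0.
#' @param peak_to_peak Peak-to-peak excursion (micrometres).
#' @param duration Vibration epoch duration (s).
#' @param sample_rate Sampling rate (Hz); must be >= 10 * `frequency`.
#' @param onset Vibration onset time (s).
#' @param tail Baseline appended after the vibration (s).
#' @param baseline_offset Constant background length offset (mm).
#' @return A `stretch_stimulus` of kind `"vibration"`; command in mm.
#' @examples
#' v <- make_vibration(100, 80, duration = 1, sample_rate = 10000)
#' @export
make_vibration <- function(frequency, peak_to_peak, duration = 1,
                           sample_rate = 10000, onset = 0.25, tail = 0.25,
                           baseline_offset = 0) {
  if (frequency <= 0) stop("`frequency` must be positive", call. = FALSE)
  if (sample_rate < 10 * frequency)
    stop("`sample_rate` must be at least 10 x `frequency` (undersampled)",
         call. = FALSE)
  amp_mm <- (peak_to_peak / 2) / 1000
  time <- seq(0, onset + duration + tail, by = 1 / sample_rate)
  rel <- time - onset
  command <- ifelse(rel >= 0 & rel <= duration,
                    amp_mm * sin(2 * pi * frequency * rel), 0)
  new_stimulus("vibration", time, command + baseline_offset, onset,
               sample_rate, vib_frequency = frequency,
               vib_peak_to_peak = peak_to_peak, duration = duration,
               baseline_offset = baseline_offset, n_repeats = 1)
}

#' Skin ramp-hold-release indentation
#'
#' Convenience wrapper for the cutaneous stimulation protocol: a probe
#' indents the plantar skin with a ramp-hold-release displacement
#' (default 2 mm at 20 mm/s with a 10 s hold).
#'
#' @inheritParams make_ramp_hold_release
#' @return A `stretch_stimulus` of kind `"skin_ramp_hold_release"`.
#' @export
make_skin_ramp_hold_release <- function(amplitude = 2, velocity = 20,
                                        hold = 10, sample_rate = 2000,
                                        onset = 0.25, tail = 1) {
  make_ramp_hold_release(amplitude, velocity, hold, sample_rate,
                         onset = onset, tail = tail,
                         kind = "skin_ramp_hold_release")
}

#' Concatenate stimulus records on one clock
#'
#' Appends stimulus `b` after stimulus `a`, preserving each record's onsets
#' (shifted for `b`). Both must share the same sample rate. Used to build
#' mixed batteries such as two slow ramp-releases followed by two fast
#' ramp-hold-releases in one continuous record.
#'
#' @param a,b `stretch_stimulus` objects with equal `sample_rate`.
#' @return A `stretch_stimulus` of kind `"composite"` (velocity/hold fields
#'   are taken from segment `a`; per-onset parameters are stored in
#'   `segment_params`).
#' @export
concat_stimuli <- function(a, b) {
  stopifnot(inherits(a, "stretch_stimulus"), inherits(b, "stretch_stimulus"))
  if (a$sample_rate != b$sample_rate)
    stop("sample rates differ", call. = FALSE)
  shift <- a$time[length(a$time)] + 1 / a$sample_rate
  time <- c(a$time, b$time + shift)
  command <- c(a$command, b$command)
  seg <- function(s) data.frame(onset = s$onsets,
                                velocity = s$velocity %||% NA_real_,
                                hold = s$hold %||% NA_real_,
                                amplitude = s$amplitude %||% NA_real_)
  sp <- rbind(seg(a), transform(seg(b), onset = onset + shift))
  new_stimulus("composite", time, command, sp$onset, a$sample_rate,
               amplitude = a$amplitude, velocity = a$velocity,
               hold = a$hold, baseline_offset = a$baseline_offset %||% 0,
               n_repeats = length(sp$onset), segment_params = sp)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Default viscoelastic muscle parameters
#'
#' Linear elastic stiffness plus a viscous branch whose stress relaxes
#' through a two-exponential kernel. Force is in arbitrary units (au);
#' the model captures the passive restoring force of the nonreflexive
#' muscle: ramp overshoot scaling with stretch velocity and a static
#' plateau equal to stiffness times amplitude.
#'
#' @param stiffness Elastic constant k (au/mm).
#' @param viscosity Viscous constant c (au per mm/s).
#' @param relax_tau Relaxation time constants (s) of the viscous branch.
#' @param relax_frac Kernel weights, summing to 1.
#' @return A list of class `muscle_params`.
#' @export
default_muscle_params <- function(stiffness = 5, viscosity = 0.2,
                                  relax_tau = c(0.05, 0.5),
                                  relax_frac = c(0.7, 0.3)) {
  if (stiffness < 0 || viscosity < 0)
    stop("stiffness and viscosity must be non-negative", call. = FALSE)
  stopifnot(length(relax_tau) == length(relax_frac),
            abs(sum(relax_frac) - 1) < 1e-9)
  structure(list(stiffness = stiffness, viscosity = viscosity,
                 relax_tau = relax_tau, relax_frac = relax_frac),
            class = "muscle_params")
}

#' Simulate the passive muscle restoring force
#'
#' Force(t) = k x(t) + relaxed viscous response to c dx/dt, where the
#' viscous branch is the stretch-rate signal filtered through a unit-area
#' multi-exponential relaxation kernel (each exponential implemented as a
#' recursive first-order filter). Under a held constant length the viscous
#' contribution decays to zero, so force converges to k x amplitude; peak
#' ramp force grows with stretch velocity. Deterministic given parameters.
#'
#' @param stimulus A `stretch_stimulus`.
#' @param params A `muscle_params` list, see [default_muscle_params()].
#' @return A list of class `muscle_dynamics` with `time`, `force` (au) on
#'   the stimulus clock, and the parameters used.
#' @export
simulate_muscle_force <- function(stimulus, params = default_muscle_params()) {
  stopifnot(inherits(stimulus, "stretch_stimulus"))
  if (!inherits(params, "muscle_params")) params <- do.call(default_muscle_params, params)
  dt <- 1 / stimulus$sample_rate
  x <- stimulus$command - stimulus$command[1]
  rate <- c(0, diff(x)) / dt
  viscous <- numeric(length(x))
  for (i in seq_along(params$relax_tau)) {
    a <- exp(-dt / params$relax_tau[i])
    viscous <- viscous + params$relax_frac[i] *
      as.numeric(stats::filter((1 - a) * rate, a, method = "recursive"))
  }
  force <- params$stiffness * x + params$viscosity * viscous
  structure(list(time = stimulus$time, force = force, params = params,
                 stimulus_kind = stimulus$kind),
            class = "muscle_dynamics")
}

#' Dynamic and static analysis windows
#'
#' For each command onset returns the dynamic window (150 ms from stretch
#' command onset) and the static window (the following 1 s). The windows are
#' disjoint by construction; the static window is the half-open interval
#' (onset + 0.15, onset + 1.15].
#'
#' @param stimulus A ramp-kind `stretch_stimulus` (vibration has no
#'   dynamic/static phase structure and is rejected).
#' @param dynamic_duration Dynamic-phase duration (s).
#' @param static_duration Static-phase duration (s).
#' @return A data.frame of class `phase_windows` with one row per onset and
#'   columns `onset`, `dynamic_start`, `dynamic_end`, `static_start`,
#'   `static_end`.
#' @export
phase_windows <- function(stimulus, dynamic_duration = 0.150,
                          static_duration = 1.0) {
  stopifnot(inherits(stimulus, "stretch_stimulus"))
  if (stimulus$kind == "vibration")
    stop("phase windows are undefined for vibration stimuli", call. = FALSE)
  w <- data.frame(onset = stimulus$onsets,
                  dynamic_start = stimulus$onsets,
                  dynamic_end = stimulus$onsets + dynamic_duration,
                  static_start = stimulus$onsets + dynamic_duration,
                  static_end = stimulus$onsets + dynamic_duration + static_duration)
  class(w) <- c("phase_windows", "data.frame")
  w
}

#' Write a time-series trace to delimited text
#'
#' Two-column CSV `time_s,value` with a single header line; the format used
#' for stimulus commands, force traces, and synaptic traces.
#'
#' @param time,value Equal-length numeric vectors.
#' @param path Output file path.
#' @param value_name Header name for the value column.
#' @export
write_trace <- function(time, value, path, value_name = "value") {
  df <- data.frame(time_s = time, v = value)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column trace written by [write_trace()]
#'
#' @param path CSV path with columns `time_s` and one value column.
#' @return A data.frame with columns `time_s` and `value`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  names(df)[2] <- "value"
  df
}
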