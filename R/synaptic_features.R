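# Feature extraction from trial-averaged motoneuron synaptic potentials:
# detection classification (present / decaying / absent), detection delay,
# dynamic peak, static amplitude, and per-cycle vibration peaks.
# Detection uses k baseline-noise SDs (k = 3 default); the decaying class
# is an amplitude ratio rule (last third < 50% of first third of the
# stimulation epoch). Both constants are explicit arguments.

#' Average trial traces on stimulus onset
#'
#' Pointwise mean of onset-aligned trials, trimmed to the common support
#' when lengths differ (with a message), then baseline-subtracted using
#' the pre-onset mean.
#'
#' @param trial_traces List of numeric voltage vectors (mV), all sampled on
#'   the same clock starting at the same record time.
#' @param time Time vector (s) of the longest trial.
#' @param onset Stimulus onset (s) used for baseline subtraction.
#' @param baseline_mV Resting potential recorded for the cell.
#' @return A `synaptic_trace`.
#' @export
average_on_onset <- function(trial_traces, time, onset = 0,
                             baseline_mV = -70) {
  stopifnot(length(trial_traces) >= 1)
  lens <- lengths(trial_traces)
  n <- min(lens)
  if (any(lens != n))
    message(sprintf("trials trimmed to common support (%d samples)", n))
  mat <- vapply(trial_traces, function(v) v[seq_len(n)], numeric(n))
  avg <- rowMeans(mat)
  tt <- time[seq_len(n)]
  pre <- avg[tt < onset]
  if (length(pre)) avg <- avg - mean(pre)
  synaptic_trace(tt, avg, baseline_mV = baseline_mV,
                 n_trials = length(trial_traces))
}

#' Baseline noise SD of an averaged trace
#'
#' Estimated from the pre-onset baseline (default last 200 ms before
#' onset) of the averaged trace.
#'
#' @param trace A `synaptic_trace`.
#' @param onset Stimulus onset (s).
#' @param window Baseline window length (s).
#' @return Scalar SD (mV).
#' @export
baseline_noise_sd <- function(trace, onset, window = 0.2) {
  pre <- trace$voltage[trace$time >= onset - window & trace$time < onset]
  if (length(pre) < 2) return(NA_real_)
  stats::sd(pre)
}

#' Classify synaptic-potential detection
#'
#' `absent` when the peak depolarization within the stimulation epoch is
#' below `k * noise_sd`; otherwise `decaying` when the mean amplitude over
#' the last third of the epoch is below `decay_ratio` times the first
#' third; otherwise `present`.
#'
#' @param trace A `synaptic_trace`.
#' @param noise_sd Baseline noise SD (mV), > 0.
#' @param epoch `c(start, end)` (s) of the stimulation epoch; defaults to
#'   the whole trace.
#' @param k Detection threshold in noise SDs.
#' @param decay_ratio Last-third / first-third amplitude ratio below which
#'   a detected potential is classed `decaying`.
#' @return `"present"`, `"decaying"` or `"absent"`.
#' @export
detect_potential <- function(trace, noise_sd, epoch = range(trace$time),
                             k = 3, decay_ratio = 0.5) {
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be positive", call. = FALSE)
  w <- trace$time >= epoch[1] & trace$time <= epoch[2]
  v <- trace$voltage[w]
  if (max(v) < k * noise_sd) return("absent")
  third <- floor(length(v) / 3)
  first <- mean(v[seq_len(third)])
  last <- mean(v[(length(v) - third + 1):length(v)])
  if (first > 0 && last < decay_ratio * first) "decaying" else "present"
}

#' Synaptic-potential features
#'
#' Detection delay (first crossing of `k * noise_sd` after command onset),
#' dynamic peak (maximum depolarization inside the dynamic window, at the
#' maximum perturbation amplitude), and static amplitude (mean
#' depolarization over the last 100 ms of the hold phase). An absent trace
#' returns all-`NA` features (missing flags).
#'
#' @param trace A `synaptic_trace`.
#' @param windows [phase_windows()] of the driving stimulus.
#' @param noise_sd Baseline noise SD (mV).
#' @param hold_end End of the hold phase (s); defaults to the static
#'   window end.
#' @param k Detection threshold in noise SDs.
#' @return List: `detection_delay` (s), `dynamic_peak` (mV),
#'   `static_amplitude` (mV).
#' @export
synaptic_features <- function(trace, windows, noise_sd,
                              hold_end = windows$static_end[1], k = 3) {
  w <- windows[1, ]
  cls <- detect_potential(trace, noise_sd,
                          epoch = c(w$onset, hold_end), k = k)
  if (cls == "absent")
    return(list(detection_delay = NA_real_, dynamic_peak = NA_real_,
                static_amplitude = NA_real_))
  crossing <- trace$time[trace$time >= w$onset &
                           trace$voltage > k * noise_sd][1]
  dynw <- trace$time >= w$dynamic_start & trace$time <= w$dynamic_end
  statw <- trace$time > hold_end - 0.1 & trace$time <= hold_end
  list(detection_delay = if (is.na(crossing)) NA_real_ else crossing - w$onset,
       dynamic_peak = if (any(dynw)) max(trace$voltage[dynw]) else NA_real_,
       static_amplitude = if (any(statw)) mean(trace$voltage[statw]) else NA_real_)
}

#' Vibration-cycle synaptic peaks
#'
#' Peak depolarization within the first and third vibration cycle windows,
#' anchored at vibration onset.
#'
#' @param trace A `synaptic_trace`.
#' @param vib_stimulus A vibration `stretch_stimulus` with at least 3
#'   cycles.
#' @return List: `first_cycle_peak`, `third_cycle_peak` (mV).
#' @export
vibration_peaks <- function(trace, vib_stimulus) {
  stopifnot(vib_stimulus$kind == "vibration")
  f <- vib_stimulus$vib_frequency
  if (vib_stimulus$duration * f < 3)
    stop("need at least 3 vibration cycles", call. = FALSE)
  t0 <- vib_stimulus$onsets[1]
  peak_in <- function(cyc) {
    w <- trace$time >= t0 + (cyc - 1) / f & trace$time < t0 + cyc / f
    if (!any(w)) NA_real_ else max(trace$voltage[w])
  }
  list(first_cycle_peak = peak_in(1), third_cycle_peak = peak_in(3))
}

#' Detection counts per group
#'
#' Counts traces classified other than `absent`, per group -- the `k / n`
#' input to the Beta-binomial detection model.
#'
#' @param classifications Character vector of `detect_potential()` results.
#' @param groups Parallel group labels.
#' @return data.frame with columns `group`, `k_detected`, `n`.
#' @export
detection_counts <- function(classifications, groups) {
  stopifnot(length(classifications) == length(groups),
            length(groups) > 0)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    cl <- classifications[groups == g]
    data.frame(group = g, k_detected = sum(cl != "absent"), n = length(cl))
  }))
  rownames(out) <- NULL
  out
}
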