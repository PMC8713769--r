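# Per-neuron encoding parameter battery computed from spike trains aligned
# to ramp stimuli. Parameters are grouped into three clusters:
# threshold (4), dynamic (13), static (14) -- 31 in total. Silent neurons
# produce NA flags that propagate through trial averaging (pairwise
# exclusion), never NaN poisoning.

#' Instantaneous firing rate
#'
#' Rate of each interspike interval, 1/(t_i - t_{i-1}) in pulses per second,
#' assigned to the later spike of the pair (the plotting convention for
#' instantaneous-rate dots over a spike raster). Fewer than two spikes give
#' an empty series.
#'
#' @param train A `spike_train` or numeric vector of spike times.
#' @return data.frame with columns `time` (s) and `rate` (pps).
#' @export
instantaneous_rate <- function(train) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (length(times) < 2)
    return(data.frame(time = numeric(0), rate = numeric(0)))
  data.frame(time = times[-1], rate = 1 / diff(times))
}

encoded_series <- function(stimulus, dynamics, modality) {
  if (modality == "force") {
    if (is.null(dynamics)) stop("force modality needs `dynamics`", call. = FALSE)
    list(time = dynamics$time, value = dynamics$force)
  } else {
    list(time = stimulus$time,
         value = stimulus$command - stimulus$command[1])
  }
}

#' Detection threshold of a neuron
#'
#' Value of the encoded variable (muscle length in mm, or simulated force in
#' au for Ib neurons) at the time of the first spike after stretch command
#' onset, minus its pre-onset baseline. A neuron silent during the stretch
#' yields `NA` (a missing-value flag, excluded pairwise downstream).
#'
#' @param train A `spike_train`.
#' @param stimulus A ramp-kind `stretch_stimulus`.
#' @param dynamics `muscle_dynamics`, required when `modality = "force"`.
#' @param modality `"length"` or `"force"`.
#' @param onset Command onset to measure from (default: first onset).
#' @return Scalar threshold (mm or au), or `NA_real_`.
#' @export
detection_threshold <- function(train, stimulus, dynamics = NULL,
                                modality = c("length", "force"),
                                onset = stimulus$onsets[1]) {
  modality <- match.arg(modality)
  if (stimulus$kind == "vibration")
    stop("detection threshold is defined for ramp stimuli", call. = FALSE)
  enc <- encoded_series(stimulus, dynamics, modality)
  first <- train$times[train$times >= onset][1]
  if (is.na(first)) return(NA_real_)
  baseline <- enc$value[findInterval(onset, enc$time)]
  enc$value[findInterval(first, enc$time)] - baseline
}

rates_in <- function(ir, lo, hi) ir$rate[ir$time > lo & ir$time <= hi]

#' Dynamic-phase firing metrics
#'
#' Thirteen scalars describing firing inside the 150 ms dynamic window:
#' peak and mean instantaneous rate, dynamic index (peak dynamic rate minus
#' the rate 0.5 s into the static phase; 0 when the static phase is
#' silent), rate at ramp end, onset latency, time to peak rate, spike
#' count, rate slope/SD/range, ISI statistics, and peak rate per unit
#' stretch velocity. Silent windows give zero rates and `NA` latencies.
#'
#' @param train A `spike_train`.
#' @param windows One row of [phase_windows()] (or the full frame; first
#'   row used).
#' @param velocity Stretch velocity (mm/s) for the rate-per-velocity
#'   normalization; optional.
#' @return Named list of 13 scalars (see Details).
#' @export
dynamic_metrics <- function(train, windows, velocity = NA_real_) {
  w <- windows[1, ]
  ir <- instantaneous_rate(train)
  dyn <- ir[ir$time >= w$dynamic_start & ir$time <= w$dynamic_end, ]
  sp_dyn <- train$times[train$times >= w$dynamic_start &
                          train$times <= w$dynamic_end]
  first <- train$times[train$times >= w$onset][1]
  half_static <- rates_in(ir, w$static_start + 0.45, w$static_start + 0.55)
  rate_mid_static <- if (length(half_static)) mean(half_static) else 0
  peak <- if (nrow(dyn)) max(dyn$rate) else 0
  ramp_end_rate <- if (nrow(dyn)) dyn$rate[which.min(abs(dyn$time - w$dynamic_end))] else 0
  isi <- if (length(sp_dyn) > 1) diff(sp_dyn) else numeric(0)
  slope <- if (nrow(dyn) > 1) unname(stats::coef(stats::lm(rate ~ time, dyn))[2]) else NA_real_
  list(
    peak_dynamic_rate = peak,
    mean_dynamic_rate = if (nrow(dyn)) mean(dyn$rate) else 0,
    dynamic_index = peak - rate_mid_static,
    rate_at_ramp_end = ramp_end_rate,
    onset_latency = if (is.na(first)) NA_real_ else first - w$onset,
    time_to_peak_rate = if (nrow(dyn)) dyn$time[which.max(dyn$rate)] - w$onset else NA_real_,
    n_spikes_dynamic = length(sp_dyn),
    dynamic_rate_slope = slope,
    dynamic_rate_sd = if (nrow(dyn) > 1) stats::sd(dyn$rate) else 0,
    dynamic_rate_range = if (nrow(dyn)) diff(range(dyn$rate)) else 0,
    mean_isi_dynamic = if (length(isi)) mean(isi) else NA_real_,
    cv_isi_dynamic = if (length(isi) > 1) stats::sd(isi) / mean(isi) else NA_real_,
    peak_rate_per_velocity = if (is.na(velocity)) NA_real_ else peak / velocity)
}

#' Static-phase firing metrics
#'
#' Fourteen scalars describing firing through the 1 s static window: mean,
#' initial, final and midpoint rates; static duration (last spike in window
#' minus window start) and time to cessation (same endpoint measured from
#' stretch onset); least-squares accommodation slope of rate vs time and
#' the final/initial accommodation ratio; spike count, rate SD, static
#' index, ISI statistics, and the fraction of the window with spiking.
#'
#' @inheritParams dynamic_metrics
#' @return Named list of 14 scalars.
#' @export
static_metrics <- function(train, windows) {
  w <- windows[1, ]
  ir <- instantaneous_rate(train)
  st <- ir[ir$time > w$static_start & ir$time <= w$static_end, ]
  sp_st <- train$times[train$times > w$static_start &
                         train$times <= w$static_end]
  win_len <- w$static_end - w$static_start
  dur <- if (length(sp_st)) max(sp_st) - w$static_start else 0
  slope <- if (nrow(st) > 1) unname(stats::coef(stats::lm(rate ~ time, st))[2]) else NA_real_
  init <- if (nrow(st)) st$rate[1] else 0
  fin <- if (nrow(st)) st$rate[nrow(st)] else 0
  mid <- rates_in(ir, w$static_start + 0.45, w$static_start + 0.55)
  isi <- if (length(sp_st) > 1) diff(sp_st) else numeric(0)
  list(
    mean_static_rate = if (nrow(st)) mean(st$rate) else 0,
    initial_static_rate = init,
    final_static_rate = fin,
    rate_at_static_midpoint = if (length(mid)) mean(mid) else 0,
    static_duration = dur,
    time_to_cessation = if (length(sp_st)) max(sp_st) - w$onset else NA_real_,
    accommodation_slope = slope,
    accommodation_ratio = if (init > 0) fin / init else NA_real_,
    n_spikes_static = length(sp_st),
    static_rate_sd = if (nrow(st) > 1) stats::sd(st$rate) else 0,
    static_index = init - fin,
    mean_isi_static = if (length(isi)) mean(isi) else NA_real_,
    cv_isi_static = if (length(isi) > 1) stats::sd(isi) / mean(isi) else NA_real_,
    static_fraction_active = dur / win_len)
}

threshold_metrics <- function(train, stimulus, dynamics, modality, windows) {
  w <- windows[1, ]
  ir <- instantaneous_rate(train)
  first_two <- train$times[train$times >= w$onset]
  pre <- rates_in(ir, -Inf, w$onset)
  list(
    detection_threshold = detection_threshold(train, stimulus, dynamics,
                                              modality, onset = w$onset),
    onset_latency_threshold = if (length(first_two)) first_two[1] - w$onset else NA_real_,
    rate_at_threshold = if (length(first_two) >= 2)
      1 / (first_two[2] - first_two[1]) else NA_real_,
    baseline_rate = if (length(pre)) mean(pre) else 0)
}

#' Names of the 31-parameter encoding battery
#'
#' @return Character vector of 31 parameter names in cluster order
#'   (threshold 4, dynamic 13, static 14).
#' @export
encoding_parameter_names <- function() {
  c("detection_threshold", "onset_latency_threshold", "rate_at_threshold",
    "baseline_rate",
    "peak_dynamic_rate", "mean_dynamic_rate", "dynamic_index",
    "rate_at_ramp_end", "onset_latency", "time_to_peak_rate",
    "n_spikes_dynamic", "dynamic_rate_slope", "dynamic_rate_sd",
    "dynamic_rate_range", "mean_isi_dynamic", "cv_isi_dynamic",
    "peak_rate_per_velocity",
    "mean_static_rate", "initial_static_rate", "final_static_rate",
    "rate_at_static_midpoint", "static_duration", "time_to_cessation",
    "accommodation_slope", "accommodation_ratio", "n_spikes_static",
    "static_rate_sd", "static_index", "mean_isi_static", "cv_isi_static",
    "static_fraction_active")
}

#' Cluster membership of the encoding battery
#'
#' @return data.frame with columns `parameter` and `cluster`
#'   (threshold/dynamic/static).
#' @export
encoding_parameter_clusters <- function() {
  data.frame(parameter = encoding_parameter_names(),
             cluster = rep(c("threshold", "dynamic", "static"),
                           times = c(4, 13, 14)),
             stringsAsFactors = FALSE)
}

profile_one_trial <- function(train, stimulus, dynamics, modality, windows) {
  v <- c(unlist(threshold_metrics(train, stimulus, dynamics, modality, windows)),
         unlist(dynamic_metrics(train, windows, velocity = stimulus$velocity %||% NA_real_)),
         unlist(static_metrics(train, windows)))
  names(v) <- encoding_parameter_names()
  v
}

#' Encoding profile of one neuron
#'
#' Computes the 31-parameter battery for each trial and averages
#' element-wise, ignoring missing flags (a parameter missing in some trials
#' is averaged over the trials where it is defined). Profiles are computed
#' against the first phase-window pair of the stimulus.
#'
#' @param trains List of `spike_train` trials (>= 1) from one neuron.
#' @param stimulus The shared ramp `stretch_stimulus`.
#' @param dynamics `muscle_dynamics`; needed for force-modality neurons.
#' @param modality `"length"` or `"force"`; defaults by neuron class
#'   (`Ib` encodes force).
#' @return data.frame of class `encoding_profile`, one row, 31 parameter
#'   columns plus `neuron_class`, `treatment`, `n_trials_averaged`.
#' @export
compute_profile <- function(trains, stimulus, dynamics = NULL,
                            modality = NULL) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (length(trains) < 1) stop("need at least one trial", call. = FALSE)
  cls <- trains[[1]]$neuron_class
  if (is.null(modality))
    modality <- if (identical(cls, "Ib")) "force" else "length"
  windows <- phase_windows(stimulus)
  mat <- vapply(trains, profile_one_trial, numeric(31),
                stimulus = stimulus, dynamics = dynamics,
                modality = modality, windows = windows)
  means <- rowMeans(mat, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  out <- as.data.frame(as.list(means))
  out$neuron_class <- cls
  out$treatment <- trains[[1]]$treatment
  out$n_trials_averaged <- length(trains)
  class(out) <- c("encoding_profile", "data.frame")
  out
}

#' Vibration response fidelity
#'
#' Mean firing rate over the vibration epoch, spikes per vibration cycle,
#' and whether the neuron meets the 50 pps criterion used to score
#' high-frequency vibration responsiveness.
#'
#' @param train A `spike_train`.
#' @param vib_stimulus A `stretch_stimulus` of kind `"vibration"`.
#' @return List: `mean_rate_pps`, `spikes_per_cycle`, `meets_50pps`.
#' @export
vibration_fidelity <- function(train, vib_stimulus) {
  if (vib_stimulus$kind != "vibration")
    stop("vibration_fidelity needs a vibration stimulus", call. = FALSE)
  t0 <- vib_stimulus$onsets[1]
  t1 <- t0 + vib_stimulus$duration
  n <- sum(train$times >= t0 & train$times <= t1)
  rate <- n / (t1 - t0)
  list(mean_rate_pps = rate,
       spikes_per_cycle = n / (vib_stimulus$duration * vib_stimulus$vib_frequency),
       meets_50pps = rate >= 50)
}

#' Write encoding profiles to CSV
#'
#' One row per neuron: 31 parameter columns plus class/treatment/n_trials.
#'
#' @param profiles data.frame of stacked `encoding_profile` rows.
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
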