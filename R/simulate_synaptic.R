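# Synthetic trial-averaged motoneuron synaptic potentials: population-rate
# drive filtered through a double-exponential EPSP kernel, with the cOIN
# phenotype expressed as fold attenuation of the dynamic and static drive
# segments, an extra onset delay, and a vibration response pattern drawn
# from {absent, decaying, present}.

#' Construct a synaptic trace
#'
#' @param time Sample times (s).
#' @param voltage Membrane-potential deviation (mV, depolarization
#'   positive), baseline-subtracted.
#' @param baseline_mV Resting potential; traces recorded above -60 mV are
#'   flagged for exclusion.
#' @param n_trials Number of trials averaged.
#' @param stimulus Optional `stretch_stimulus`.
#' @param pattern Optional generator-side vibration pattern label.
#' @return Object of class `synaptic_trace` with an `included` flag
#'   (`baseline_mV <= -60`).
#' @export
synaptic_trace <- function(time, voltage, baseline_mV = -70, n_trials = 1L,
                           stimulus = NULL, pattern = NA_character_) {
  stopifnot(length(time) == length(voltage), n_trials >= 1)
  structure(list(time = time, voltage = voltage, baseline_mV = baseline_mV,
                 n_trials = as.integer(n_trials), stimulus = stimulus,
                 pattern = pattern, included = baseline_mV <= -60),
            class = "synaptic_trace")
}

#' @export
print.synaptic_trace <- function(x, ...) {
  cat(sprintf("<synaptic_trace: %d samples, %d trials, baseline %.0f mV%s>\n",
              length(x$time), x$n_trials, x$baseline_mV,
              if (x$included) "" else " (excluded)"))
  invisible(x)
}

# Unit-area double-exponential (difference of exponentials) EPSP kernel.
epsp_kernel <- function(dt, tau_rise, tau_decay, len = NULL) {
  if (is.null(len)) len <- ceiling(8 * tau_decay / dt)
  t <- (seq_len(len) - 1) * dt
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / sum(k * dt)
}

#' Simulate a trial-averaged motoneuron synaptic potential
#'
#' The drive (a population firing-rate series, pps) is segmented by the
#' stimulus phase windows: the dynamic-window segment is divided by
#' `dynamic_attenuation` and everything after it by `static_attenuation`
#' (for control both folds are 1). The attenuated drive is convolved with
#' a unit-area double-exponential EPSP kernel, scaled by `epsp_gain`
#' (mV/pps), delayed by `onset_delay_extra`, and averaged over `n_trials`
#' noisy trials. For vibration stimuli a response pattern is drawn from
#' `vibration_pattern_probs`: `absent` zeroes the response, `decaying`
#' multiplies it by a 0.2 s exponential decay from vibration onset,
#' `present` leaves it intact.
#'
#' @param population_drive data.frame with `time` and `rate` columns (or a
#'   `population_code`, whose `rate_mean` is used).
#' @param phenotype `default_phenotypes()$synaptic` list.
#' @param n_trials Trials to average (>= 1; typically 15-20).
#' @param seed Integer seed.
#' @param stimulus The `stretch_stimulus` behind the drive (for phase
#'   windows); taken from a `population_code` when available.
#' @return A `synaptic_trace`.
#' @export
simulate_synaptic_potential <- function(population_drive, phenotype,
                                        n_trials = 20L, seed = 1L,
                                        stimulus = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  if (inherits(population_drive, "population_code")) {
    if (is.null(stimulus)) stimulus <- population_drive$stimulus
    population_drive <- data.frame(time = population_drive$time,
                                   rate = population_drive$rate_mean)
  }
  time <- population_drive$time
  dt <- time[2] - time[1]
  drive <- population_drive$rate
  pattern <- NA_character_
  if (!is.null(stimulus) && stimulus$kind == "vibration") {
    p <- phenotype$vibration_pattern_probs
    pattern <- sample(names(p), 1, prob = p)
    rel <- time - stimulus$onsets[1]
    drive <- switch(pattern,
                    absent = drive * 0,
                    decaying = drive * ifelse(rel >= 0, exp(-rel / 0.2), 1),
                    present = drive)
  } else if (!is.null(stimulus)) {
    w <- phase_windows(stimulus)[1, ]
    dynw <- time >= w$dynamic_start & time <= w$dynamic_end
    postw <- time > w$dynamic_end
    drive[dynw] <- drive[dynw] / phenotype$dynamic_attenuation
    drive[postw] <- drive[postw] / phenotype$static_attenuation
  }
  k <- epsp_kernel(dt, phenotype$epsp_tau_rise, phenotype$epsp_tau_decay)
  clean <- phenotype$epsp_gain * dt *
    as.numeric(stats::convolve(drive, rev(k), type = "open"))[seq_along(drive)]
  if (phenotype$onset_delay_extra > 0) {
    s <- round(phenotype$onset_delay_extra / dt)
    clean <- c(numeric(s), clean[seq_len(length(clean) - s)])
  }
  noise_sd <- phenotype$noise_sd_mV %||% 0
  avg <- clean
  if (noise_sd > 0) {
    trials <- replicate(n_trials, clean + stats::rnorm(length(clean), 0, noise_sd))
    avg <- rowMeans(trials)
  }
  synaptic_trace(time, avg, baseline_mV = -70, n_trials = n_trials,
                 stimulus = stimulus, pattern = pattern)
}
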