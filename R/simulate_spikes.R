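# Synthetic spike trains from a rate model via time-rescaled renewal
# (gamma-interval) sampling. One seeded stream per call; identical
# seed + parameters give identical output.

#' Construct a spike train
#'
#' @param times Sorted, strictly increasing spike times (s).
#' @param neuron_class Class label (Ia, Iun, Ib, II, RAI, RAII, SAI, SAII).
#' @param treatment Group label.
#' @param trial_id Integer trial identifier.
#' @param stimulus Optional `stretch_stimulus` the train is locked to.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, neuron_class = NA_character_,
                        treatment = NA_character_, trial_id = 1L,
                        stimulus = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(times = times, neuron_class = neuron_class,
                 treatment = treatment, trial_id = trial_id,
                 stimulus = stimulus),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %s/%s, %d spikes>\n",
              x$neuron_class, x$treatment, length(x$times)))
  invisible(x)
}

# Draw spike times from a rate vector by time rescaling. A renewal process
# with gamma-distributed rescaled intervals (shape 1/cv^2, mean 1) gives
# interspike-interval CV ~= cv; cv = 0 degenerates to deterministic unit
# intervals. `reset_at` are times where the integrated rate restarts with
# an immediate spike (detection-threshold gate openings).
rescaled_renewal <- function(time, rate, cv, reset_at = numeric(0)) {
  dt <- time[2] - time[1]
  active <- rate > 0
  if (!any(active)) return(numeric(0))
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  spikes <- numeric(0)
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    lam <- cumsum(rate[idx]) * dt
    total <- lam[length(lam)]
    # spike at gate opening, then renewal through rescaled time
    seg_spikes <- time[idx[1]]
    pos <- 0
    repeat {
      xi <- if (cv <= 0) 1 else
        stats::rgamma(1, shape = 1 / cv^2, scale = cv^2)
      pos <- pos + xi
      if (pos > total) break
      j <- which.max(lam >= pos)
      seg_spikes <- c(seg_spikes, time[idx[j]])
    }
    spikes <- c(spikes, seg_spikes)
  }
  unique(spikes)
}

# Shared rate model. encoded: encoded-variable vector on the stimulus
# clock; phenotype: one row of default_phenotypes()$neurons;
# hold_onsets: plateau start per repeat (for adaptation + cessation).
rate_from_encoded <- function(time, encoded, phenotype, onsets, hold_onsets,
                              first_stretch_factor = 1) {
  dt <- time[2] - time[1]
  d_enc <- pmax(0, c(0, diff(encoded)) / dt)
  above <- pmax(0, encoded - phenotype$detection_threshold)
  r <- phenotype$dynamic_gain * d_enc + phenotype$static_gain * above
  # exponential adaptation of the static component from each hold onset
  if (is.finite(phenotype$adaptation_tau) && !is.na(phenotype$adaptation_tau)) {
    decay <- rep(1, length(time))
    for (h in hold_onsets) {
      rel <- time - h
      w <- rel >= 0
      decay[w] <- pmin(decay[w], exp(-rel[w] / phenotype$adaptation_tau))
    }
    r <- phenotype$dynamic_gain * d_enc + phenotype$static_gain * above * decay
  }
  # gate: silent below detection threshold and after static cessation
  r[encoded < phenotype$detection_threshold] <- 0
  if (!is.na(phenotype$static_cessation_time)) {
    for (i in seq_along(hold_onsets)) {
      h <- hold_onsets[i]
      nxt <- if (i < length(hold_onsets)) onsets[i + 1] else Inf
      r[time > h + phenotype$static_cessation_time & time < nxt] <- 0
    }
  }
  # history dependence: first stretch of the record scaled up
  if (first_stretch_factor != 1 && length(onsets) >= 1) {
    first_end <- if (length(onsets) > 1) onsets[2] else Inf
    w <- time >= onsets[1] & time < first_end
    r[w] <- r[w] * first_stretch_factor
  }
  # onset conduction/transduction delay
  if (phenotype$onset_delay > 0) {
    shift <- round(phenotype$onset_delay / dt)
    if (shift > 0) r <- c(numeric(shift), r[seq_len(length(r) - shift)])
  }
  r
}

hold_onsets_of <- function(stimulus) {
  if (!is.null(stimulus$segment_params)) {
    sp <- stimulus$segment_params
    sp$onset + ifelse(is.na(sp$amplitude / sp$velocity), 0,
                      sp$amplitude / sp$velocity)
  } else {
    ramp <- if (!is.null(stimulus$amplitude)) stimulus$amplitude / stimulus$velocity else 0
    stimulus$onsets + ramp
  }
}

#' Simulate a muscle propriosensor spike train
#'
#' Rate model: dynamic term proportional to the positive rate of change of
#' the encoded variable (muscle length for Ia/Iun/II, simulated force for
#' Ib) plus a static term proportional to the suprathreshold encoded value
#' with exponential adaptation from hold onset; the whole rate is gated to
#' zero below the detection threshold and after the class's static
#' cessation time, and the first stretch of a repeated sequence is scaled
#' by the history-dependence factor. Spikes are drawn by time-rescaled
#' gamma renewal sampling with interspike CV `noise_cv`; a spike is emitted
#' at each threshold crossing, so at zero noise the measured detection
#' threshold equals the generator's. Vibration stimuli are handled
#' per cycle with `vibration_entrainment_prob`.
#'
#' @param phenotype One row of `default_phenotypes()$neurons` (a muscle
#'   class).
#' @param stimulus A `stretch_stimulus`.
#' @param dynamics `muscle_dynamics` from [simulate_muscle_force()];
#'   required for Ib (force-encoding) neurons.
#' @param seed Integer seed; the call is deterministic given it.
#' @return A `spike_train`.
#' @export
simulate_propriosensor_spikes <- function(phenotype, stimulus,
                                          dynamics = NULL, seed = 1L) {
  stopifnot(inherits(stimulus, "stretch_stimulus"))
  if (!phenotype$neuron_class %in% MUSCLE_CLASSES)
    stop("phenotype is not a muscle propriosensor class", call. = FALSE)
  set.seed(as.integer(seed))
  if (stimulus$kind == "vibration")
    return(entrained_train(phenotype, stimulus))
  if (phenotype$neuron_class == "Ib") {
    if (is.null(dynamics))
      stop("Ib neurons encode force: supply `dynamics`", call. = FALSE)
    if (length(dynamics$time) != length(stimulus$time))
      stop("stimulus and dynamics are on different clocks", call. = FALSE)
    encoded <- dynamics$force
  } else {
    encoded <- stimulus$command - stimulus$command[1]
  }
  r <- rate_from_encoded(stimulus$time, encoded, phenotype,
                         stimulus$onsets, hold_onsets_of(stimulus),
                         phenotype$history_dependence_factor)
  spike_train(rescaled_renewal(stimulus$time, r, phenotype$noise_cv),
              phenotype$neuron_class, phenotype$treatment,
              stimulus = stimulus)
}

# Per-cycle Bernoulli entrainment at the cycle peak phase.
entrained_train <- function(phenotype, stimulus) {
  f <- stimulus$vib_frequency
  dur <- stimulus$duration
  n_cycles <- floor(dur * f)
  if (n_cycles < 1 || phenotype$vibration_entrainment_prob <= 0)
    return(spike_train(numeric(0), phenotype$neuron_class,
                       phenotype$treatment, stimulus = stimulus))
  t0 <- stimulus$onsets[1]
  cand <- t0 + (seq_len(n_cycles) - 1 + 0.25) / f
  keep <- stats::runif(n_cycles) < phenotype$vibration_entrainment_prob
  spike_train(cand[keep], phenotype$neuron_class, phenotype$treatment,
              stimulus = stimulus)
}

#' Simulate a cutaneous afferent spike train
#'
#' Skin indentation is converted to force through a linear compliance
#' (`g_per_mm`). Rapidly adapting classes (RAI, RAII) fire only during the
#' onset and offset ramps (rate proportional to |force rate|) plus
#' vibration entrainment; slowly adapting classes (SAI, SAII) fire through
#' the hold with the class's sustain time (static cessation measured from
#' hold onset). All classes are silent below their force threshold.
#'
#' @param phenotype One row of `default_phenotypes()$neurons` (a cutaneous
#'   class).
#' @param skin_stimulus A `stretch_stimulus` of kind
#'   `"skin_ramp_hold_release"` or `"vibration"`.
#' @param seed Integer seed.
#' @param g_per_mm Skin compliance: grams of force per mm of indentation.
#' @return A `spike_train`.
#' @export
simulate_cutaneous_spikes <- function(phenotype, skin_stimulus, seed = 1L,
                                      g_per_mm = 12.5) {
  if (!phenotype$neuron_class %in% CUTANEOUS_CLASSES)
    stop("phenotype is not a cutaneous class", call. = FALSE)
  if (!skin_stimulus$kind %in% c("skin_ramp_hold_release", "vibration"))
    stop("cutaneous simulation needs a skin indentation or vibration stimulus",
         call. = FALSE)
  set.seed(as.integer(seed))
  if (skin_stimulus$kind == "vibration")
    return(entrained_train(phenotype, skin_stimulus))
  time <- skin_stimulus$time
  dt <- 1 / skin_stimulus$sample_rate
  force_g <- g_per_mm * (skin_stimulus$command - skin_stimulus$command[1])
  ra <- phenotype$neuron_class %in% c("RAI", "RAII")
  if (ra) {
    d_abs <- abs(c(0, diff(force_g)) / dt)
    r <- phenotype$dynamic_gain * d_abs
    r[force_g < phenotype$detection_threshold] <- 0
  } else {
    r <- rate_from_encoded(time, force_g, phenotype, skin_stimulus$onsets,
                           hold_onsets_of(skin_stimulus))
  }
  spike_train(rescaled_renewal(time, r, phenotype$noise_cv),
              phenotype$neuron_class, phenotype$treatment,
              stimulus = skin_stimulus)
}
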