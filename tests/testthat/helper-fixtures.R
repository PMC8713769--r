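# Shared fixture builders. Simulations in unit tests run at reduced
# sampling rates where the property under test does not depend on them.

fast_ramp <- function(sample_rate = 5000, velocity = 20, hold = 1,
                      amplitude = 3, ...) {
  make_ramp_hold_release(amplitude, velocity, hold,
                         sample_rate = sample_rate, ...)
}

# A phenotype row with every stochastic/delay term switched off, so spike
# times are exact functions of the stimulus.
exact_phenotype <- function(neuron_class = "Ia", detection_threshold = 0.1,
                            dynamic_gain = 6, static_gain = 20,
                            adaptation_tau = 2, static_cessation_time = 5,
                            treatment = "control",
                            vibration_entrainment_prob = 1) {
  data.frame(neuron_class = neuron_class, treatment = treatment,
             modality = if (neuron_class == "Ib") "force" else "length",
             detection_threshold = detection_threshold,
             dynamic_gain = dynamic_gain, static_gain = static_gain,
             adaptation_tau = adaptation_tau,
             static_cessation_time = static_cessation_time,
             onset_delay = 0, history_dependence_factor = 1,
             vibration_entrainment_prob = vibration_entrainment_prob,
             noise_cv = 0, stringsAsFactors = FALSE)
}

# Regular spike train spanning [t0, t1] at a constant rate.
regular_train <- function(rate, t0, t1, ...) {
  spike_train(seq(t0, t1, by = 1 / rate), ...)
}

# Identity synaptic phenotype (no attenuation, no delay, no noise).
identity_synaptic <- function(noise_sd = 0) {
  list(detection_prob = 1, dynamic_attenuation = 1, static_attenuation = 1,
       onset_delay_extra = 0,
       vibration_pattern_probs = c(absent = 0, decaying = 0, present = 1),
       epsp_tau_rise = 0.005, epsp_tau_decay = 0.05, epsp_gain = 0.05,
       noise_sd_mV = noise_sd)
}

gait_with <- function(...) {
  g <- default_phenotypes("control")$gait
  utils::modifyList(g, list(...))
}

default_rungs <- function(n = 30, spacing = 4) seq(0, by = spacing,
                                                   length.out = n)
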