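test_that("instantaneous rate matches interval arithmetic and a brute-force oracle", {
  expect_equal(instantaneous_rate(c(0, 0.1, 0.2))$rate, c(10, 10))
  expect_equal(instantaneous_rate(c(0, 0.05, 0.15))$rate, c(20, 10))
  expect_equal(instantaneous_rate(c(0, 0.1, 0.2))$time, c(0.1, 0.2))
  expect_equal(nrow(instantaneous_rate(0.3)), 0)
  # oracle: explicit pairwise differences on random trains
  set.seed(42)
  for (i in 1:10) {
    times <- sort(stats::runif(sample(2:40, 1), 0, 5))
    times <- unique(times)
    got <- instantaneous_rate(times)
    oracle <- vapply(seq_along(times)[-1],
                     function(j) 1 / (times[j] - times[j - 1]), numeric(1))
    expect_equal(got$rate, oracle)
  }
})

test_that("detection threshold reads the encoded variable at the first spike", {
  s <- make_ramp_hold_release(3, 20, 1, 1000, onset = 0.25)
  tr <- spike_train(s$onsets[1] + c(0.05, 0.08, 0.12), "Ia", "control")
  expect_equal(detection_threshold(tr, s, modality = "length"), 1.0,
               tolerance = 1e-6)
  d <- simulate_muscle_force(s)
  thr_f <- detection_threshold(tr, s, d, modality = "force")
  i <- which.min(abs(s$time - (s$onsets[1] + 0.05)))
  expect_equal(thr_f, d$force[i] - d$force[s$time == s$onsets[1]],
               tolerance = 1e-6)
  silent <- spike_train(numeric(0), "Ia", "control")
  expect_true(is.na(detection_threshold(silent, s, modality = "length")))
})

test_that("dynamic metrics behave on constant, scaled, and silent trains", {
  s <- make_ramp_hold_release(3, 20, 1, 1000, onset = 0.25)
  w <- phase_windows(s)
  const <- regular_train(100, 0.05, 1.6)
  dm <- dynamic_metrics(const, w)
  expect_equal(dm$peak_dynamic_rate, 100, tolerance = 1e-6)
  expect_equal(dm$mean_dynamic_rate, 100, tolerance = 1e-6)
  expect_equal(dm$dynamic_index, 0, tolerance = 1e-6)
  # halving the generator dynamic gain halves the peak dynamic rate
  d <- simulate_muscle_force(s)
  peak_for <- function(gain) {
    p <- exact_phenotype("Ia", dynamic_gain = gain, static_gain = 0,
                         detection_threshold = 1e-6)
    dynamic_metrics(simulate_propriosensor_spikes(p, s, d, seed = 1), w)$peak_dynamic_rate
  }
  expect_equal(peak_for(3) / peak_for(6), 0.5, tolerance = 0.05)
  empty <- dynamic_metrics(spike_train(numeric(0)), w)
  expect_equal(empty$peak_dynamic_rate, 0)
  expect_true(is.na(empty$onset_latency))
})

test_that("static metrics capture duration, accommodation and cessation", {
  s <- make_ramp_hold_release(3, 20, 1, 1000, onset = 0.25)
  w <- phase_windows(s)
  spanning <- regular_train(80, 0.05, 1.6)
  sm <- static_metrics(spanning, w)
  expect_equal(sm$static_duration, 1, tolerance = 1 / 80 + 1e-9)
  expect_equal(sm$accommodation_slope, 0, tolerance = 1e-6)
  ceasing <- spike_train(seq(0.42, 0.9, by = 1 / 80))
  expect_lt(static_metrics(ceasing, w)$static_duration, 0.55)
  # exponentially decaying instantaneous rate: negative accommodation slope
  decay_times <- Reduce(function(t, i) t + 1 / (100 * exp(-(t - 0.4) / 0.5)),
                        1:25, accumulate = TRUE, init = 0.41)
  sm2 <- static_metrics(spike_train(decay_times), w)
  expect_lt(sm2$accommodation_slope, 0)
  expect_lt(sm2$accommodation_ratio, 1)
})

test_that("profiles average trials element-wise, skipping missing flags", {
  s <- make_ramp_hold_release(3, 20, 1, 1000, onset = 0.25)
  tr <- regular_train(100, 0.3, 1.6, neuron_class = "Ia", treatment = "control")
  prof1 <- compute_profile(list(tr), s)
  prof4 <- compute_profile(list(tr, tr, tr, tr), s)
  pars <- encoding_parameter_names()
  expect_equal(unlist(prof4[, pars]), unlist(prof1[, pars]))
  expect_equal(prof4$n_trials_averaged, 4)
  expect_length(pars, 31)
  expect_equal(table(encoding_parameter_clusters()$cluster)[c("threshold", "dynamic", "static")],
               table(factor(rep(c("threshold", "dynamic", "static"), c(4, 13, 14))))[c("threshold", "dynamic", "static")])
  # a silent trial contributes NA, averaged over the remaining trials
  silent <- spike_train(numeric(0), "Ia", "control")
  prof_mix <- compute_profile(list(tr, tr, tr, silent), s)
  expect_equal(prof_mix$detection_threshold, prof1$detection_threshold)
  expect_error(compute_profile(list(), s), "at least one")
})

test_that("full battery on a default control Ia neuron is finite", {
  s <- fast_ramp(5000)
  d <- simulate_muscle_force(s)
  p <- default_phenotypes("control")$neurons[1, ]
  trains <- lapply(1:4, function(i)
    simulate_propriosensor_spikes(p, s, d, seed = i))
  prof <- compute_profile(trains, s, d)
  vals <- unlist(prof[, encoding_parameter_names()])
  expect_length(vals, 31)
  expect_true(all(is.finite(vals)))
})

test_that("encoding parameters are invariant to a common time shift", {
  s1 <- make_ramp_hold_release(3, 20, 1, 1000, onset = 0.25)
  s2 <- make_ramp_hold_release(3, 20, 1, 1000, onset = 0.75)
  set.seed(3)
  isis <- stats::runif(80, 0.008, 0.02)     # irregular train: no rate ties
  base <- spike_train(0.27 + cumsum(c(0, isis)), "Ia")
  shifted <- spike_train(base$times + 0.5, "Ia")
  p1 <- compute_profile(list(base), s1)
  p2 <- compute_profile(list(shifted), s2)
  pars <- setdiff(encoding_parameter_names(), "time_to_cessation")
  expect_equal(unlist(p1[, pars]), unlist(p2[, pars]), tolerance = 1e-9)
  expect_equal(p2$time_to_cessation, p1$time_to_cessation, tolerance = 1e-9)
})

test_that("measured detection threshold is monotone in the generator threshold", {
  s <- fast_ramp(5000)
  d <- simulate_muscle_force(s)
  thr <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th) {
    p <- exact_phenotype("Ia", detection_threshold = th)
    detection_threshold(simulate_propriosensor_spikes(p, s, d, seed = 1), s,
                        modality = "length")
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("vibration fidelity reports rate and the 50 pps criterion", {
  v <- make_vibration(100, 80, 1, 2000)
  full <- spike_train(v$onsets[1] + (0:99 + 0.25) / 100)
  f <- vibration_fidelity(full, v)
  expect_equal(f$mean_rate_pps, 100)
  expect_true(f$meets_50pps)
  silent <- vibration_fidelity(spike_train(numeric(0)), v)
  expect_equal(silent$mean_rate_pps, 0)
  expect_false(silent$meets_50pps)
  expect_error(vibration_fidelity(full, fast_ramp(1000)), "vibration")
})
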