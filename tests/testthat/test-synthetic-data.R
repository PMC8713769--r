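test_that("generators are deterministic given seed and config", {
  s <- fast_ramp(2000)
  d <- simulate_muscle_force(s)
  p <- default_phenotypes("control")$neurons[1, ]
  a <- simulate_propriosensor_spikes(p, s, d, seed = 7)
  b <- simulate_propriosensor_spikes(p, s, d, seed = 7)
  expect_identical(a$times, b$times)
  g <- default_phenotypes("cOIN")$gait
  ta <- simulate_ladder_trial(g, default_rungs(), 10, seed = 3)
  tb <- simulate_ladder_trial(g, default_rungs(), 10, seed = 3)
  expect_identical(ta$frames, tb$frames)
})

test_that("default phenotype tables carry the anchored values", {
  ctrl <- default_phenotypes("control")
  coin <- default_phenotypes("cOIN")
  get <- function(ph, cls, col) ph$neurons[ph$neurons$neuron_class == cls, col]
  expect_equal(get(ctrl, "SAII", "detection_threshold"), 4.96)
  expect_equal(get(coin, "RAI", "detection_threshold"), 10.26)
  expect_equal(get(ctrl, "RAI", "detection_threshold"), 18.9)
  expect_equal(get(coin, "SAI", "static_cessation_time"), 6.02)
  expect_equal(ctrl$synaptic$detection_prob, 19 / 20)
  expect_equal(coin$synaptic$detection_prob, 7 / 26)
  # cOIN muscle threshold fold within the two- to fivefold range
  for (cls in c("Ia", "Iun", "Ib", "II")) {
    fold <- get(coin, cls, "detection_threshold") /
      get(ctrl, cls, "detection_threshold")
    expect_gte(fold, 2); expect_lte(fold, 5)
  }
  # Ia vibration entrainment preserved under treatment
  expect_equal(get(coin, "Ia", "vibration_entrainment_prob"),
               get(ctrl, "Ia", "vibration_entrainment_prob"))
  expect_error(default_phenotypes("sham"))
  expect_true(all(c("parameter", "anchor") %in% names(phenotype_provenance())))
})

test_that("forced 1:1 vibration entrainment fires once per cycle", {
  v <- make_vibration(100, 80, duration = 1, sample_rate = 2000)
  p <- exact_phenotype("Ia")
  tr <- simulate_propriosensor_spikes(p, v, seed = 1)
  expect_equal(length(tr$times), 100)
  fid <- vibration_fidelity(tr, v)
  expect_equal(fid$mean_rate_pps, 100)
  expect_equal(fid$spikes_per_cycle, 1)
})

test_that("tripling the generator threshold triples the stretch at first spike", {
  s <- fast_ramp(10000, velocity = 20)
  d <- simulate_muscle_force(s)
  first_stretch <- function(thr) {
    p <- exact_phenotype("Ia", detection_threshold = thr)
    tr <- simulate_propriosensor_spikes(p, s, d, seed = 1)
    (tr$times[1] - s$onsets[1]) * 20
  }
  expect_equal(first_stretch(0.3), 3 * first_stretch(0.1),
               tolerance = 20 / 10000 / 0.3)  # one sample of stretch
})

test_that("zero-amplitude stimulus with zero background yields no spikes", {
  z <- make_vibration(100, 0, duration = 0.5, sample_rate = 2000)
  p <- exact_phenotype("Ia", vibration_entrainment_prob = 0)
  expect_length(simulate_propriosensor_spikes(p, z, seed = 1)$times, 0)
})

test_that("cutaneous classes obey RA/SA phenomenology and thresholds", {
  skin <- make_skin_ramp_hold_release(2, 20, 10, sample_rate = 1000)
  phen <- default_phenotypes("cOIN")$neurons
  hold_on <- skin$onsets[1] + 2 / 20
  # SA: sustain limited to the class cessation time after hold onset
  sai <- phen[phen$neuron_class == "SAI", ]
  tr <- simulate_cutaneous_spikes(sai, skin, seed = 2)
  isi <- max(diff(tr$times))
  expect_lte(max(tr$times), hold_on + 6.02 + isi)
  expect_gt(max(tr$times), hold_on + 1)  # but does fire into the hold
  # RA: onset/offset only, silent during the hold
  rai <- default_phenotypes("control")$neurons
  rai <- rai[rai$neuron_class == "RAI", ]
  tra <- simulate_cutaneous_spikes(rai, skin, seed = 2)
  expect_gt(length(tra$times), 0)
  expect_length(tra$times[tra$times > hold_on + 0.5 &
                            tra$times < hold_on + 9.5], 0)
  # subthreshold ramp: no onset/offset spikes at all
  weak <- make_skin_ramp_hold_release(0.2, 20, 1, sample_rate = 1000)
  expect_length(simulate_cutaneous_spikes(rai, weak, seed = 2)$times, 0)
  # vibration responsiveness: control RAI entrainment clears 50 pps at 167 Hz
  vib <- make_vibration(167, 80, duration = 1, sample_rate = 2000)
  ent <- rai; ent$vibration_entrainment_prob <- 1
  fid <- vibration_fidelity(simulate_cutaneous_spikes(ent, vib, seed = 1), vib)
  expect_gte(fid$mean_rate_pps, 50)
  expect_equal(fid$mean_rate_pps, 167)
  expect_error(simulate_cutaneous_spikes(phen[phen$neuron_class == "Ia", ],
                                         skin), "cutaneous")
})

test_that("identity synaptic phenotype reproduces the kernel-filtered drive", {
  s <- fast_ramp(1000)
  code_time <- s$time
  drive <- data.frame(time = code_time,
                      rate = 100 * pmin(1, pmax(0, code_time - s$onsets[1]) / 0.15))
  tr <- simulate_synaptic_potential(drive, identity_synaptic(), n_trials = 1,
                                    seed = 1, stimulus = s)
  # plateau: unit-area kernel times gain maps 100 pps -> 5 mV
  late <- tr$voltage[code_time > s$onsets[1] + 0.8 & code_time < s$onsets[1] + 1]
  expect_equal(mean(late), 5, tolerance = 0.01)
  expect_equal(length(tr$voltage), length(drive$rate))
})

test_that("attenuation folds survive the generator/extractor round trip", {
  st <- fast_ramp(1000)
  w <- phase_windows(st)
  drive <- data.frame(time = st$time,
                      rate = 100 * pmin(1, pmax(0, st$time - st$onsets[1]) / 0.15))
  drive$rate[st$time > w$static_end[1]] <- 0
  coin_phen <- identity_synaptic()
  coin_phen$dynamic_attenuation <- 4.5
  coin_phen$static_attenuation <- 35
  ctrl <- simulate_synaptic_potential(drive, identity_synaptic(), 1, 1, st)
  coin <- simulate_synaptic_potential(drive, coin_phen, 1, 1, st)
  f_ctrl <- synaptic_features(ctrl, w, noise_sd = 1e-3)
  f_coin <- synaptic_features(coin, w, noise_sd = 1e-3)
  expect_equal(f_ctrl$dynamic_peak / f_coin$dynamic_peak, 4.5, tolerance = 0.1)
  expect_equal(f_ctrl$static_amplitude / f_coin$static_amplitude, 35,
               tolerance = 0.1)
})

test_that("degenerate vibration pattern probabilities force their class", {
  v <- make_vibration(100, 80, duration = 0.5, sample_rate = 2000)
  drive <- data.frame(time = v$time,
                      rate = ifelse(v$time >= v$onsets[1] &
                                      v$time <= v$onsets[1] + 0.5, 100, 0))
  ph <- identity_synaptic()
  ph$vibration_pattern_probs <- c(absent = 1, decaying = 0, present = 0)
  for (seed in 1:5) {
    tr <- simulate_synaptic_potential(drive, ph, 1, seed, v)
    expect_identical(tr$pattern, "absent")
    expect_true(all(tr$voltage == 0))
  }
})

test_that("ladder generator honours miss, undershoot and dropout settings", {
  rungs <- default_rungs()
  t_perfect <- simulate_ladder_trial(gait_with(miss_prob = 0,
                                               confidence_dropout_prob = 0),
                                     rungs, 15, seed = 1)
  expect_true(all(t_perfect$truth$error_cm == 0))
  t_exact <- simulate_ladder_trial(gait_with(miss_prob = 1, undershoot_sd = 1e-9,
                                             replacement_prob = 1),
                                   rungs, 15, seed = 1)
  expect_equal(t_exact$truth$error_cm, rep(-1.72, 15), tolerance = 1e-6)
  t_drop <- simulate_ladder_trial(gait_with(confidence_dropout_prob = 1),
                                  rungs, 5, seed = 1)
  expect_equal(filter_frames(t_drop)$exclusion_report$n_kept, 0)
  expect_error(simulate_ladder_trial(gait_with(), rungs[1], 5), "2 rungs")
})
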