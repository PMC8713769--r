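# Orchestration: one seeded config drives simulate -> encode -> population
# -> PCA -> circuit accuracy -> synaptic -> Bayes -> kinematics and writes
# per-stage CSV/JSON outputs. Every constant in force is echoed into the
# run log; outputs are regenerable from the config alone.

#' Default run configuration
#'
#' All knobs of the pipeline in one serializable list: the global seed
#' (children are derived per stage, so stage order does not perturb
#' streams), sampling rates, stimulus battery, ensemble composition,
#' analysis constants, and phenotype overrides.
#'
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sample_rate = 10000,
    population_sample_rate = 1000,
    stimulus = list(amplitude = 3, fast_velocity = 20, slow_velocity = 4,
                    hold = 1),
    composition = c(Ia = 10, Iun = 5, Ib = 14, II = 11),
    kernel_width = 0.020,
    max_lag = 0.3,
    hit_tolerance_cm = 0.5,
    replacement_tolerance_cm = 0.5,
    prior = c(a = 5, b = 1),
    hdi_level = 0.95,
    detection_k = 3,
    n_trials_encoding = 4,
    n_trials_synaptic = 20,
    rung_spacing_cm = 4,
    n_rungs = 30,
    n_gait_steps = 25), class = "run_config")
}

#' Read / write a run configuration
#'
#' YAML on disk (JSON also accepted on read, by extension).
#'
#' @param config A `run_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `read_config()` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  # named vectors survive YAML/JSON as maps, not bare sequences
  out$composition <- as.list(out$composition)
  out$prior <- as.list(out$prior)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), raw)
  cfg$composition <- unlist(cfg$composition)
  cfg$prior <- unlist(cfg$prior)
  class(cfg) <- "run_config"
  cfg
}

child_seed <- function(seed, stage) {
  # double arithmetic stays exact well past 2^31; fold into integer range
  as.integer((as.numeric(seed) %% 1e6 * 1009 + stage * 9973) %% 2147483647)
}

member_classes <- function(composition) {
  rep(names(composition), times = composition)
}

# Simulate one treatment's ensemble on a shared stimulus and build its
# population code, force trace and synaptic trace; the core of the
# circuit-accuracy comparison.
simulate_treatment_arm <- function(treatment, stimulus, config, seed) {
  phen <- default_phenotypes(treatment)$neurons
  dyn <- simulate_muscle_force(stimulus)
  classes <- member_classes(config$composition)
  trains <- lapply(seq_along(classes), function(i) {
    p <- phen[phen$neuron_class == classes[i], ]
    simulate_propriosensor_spikes(p, stimulus, dyn,
                                  seed = child_seed(seed, i))
  })
  code <- build_population(trains, composition = config$composition,
                           kernel_width = config$kernel_width,
                           sample_rate = config$population_sample_rate)
  syn_phen <- default_phenotypes(treatment)$synaptic
  trace <- simulate_synaptic_potential(code, syn_phen,
                                       n_trials = config$n_trials_synaptic,
                                       seed = child_seed(seed, 900),
                                       stimulus = stimulus)
  list(trains = trains, code = code, dynamics = dyn, trace = trace,
       stimulus = stimulus)
}

#' Stagewise and compounded circuit accuracy for one treatment
#'
#' Simulates the default ensemble (10 Ia + 5 Iun + 14 Ib + 11 II) on a
#' fast ramp-hold-release stretch, builds the population code and the
#' motoneuron synaptic trace, and computes peripheral accuracy
#' (population rate representing muscle force), central accuracy
#' (synaptic trace representing the population rate), and their product.
#' R^2 is computed over the stimulus epoch (onset to 1 s after release)
#' with a bounded best-lag search.
#'
#' @param treatment `"control"` or `"cOIN"`.
#' @param config A `run_config`.
#' @param seed Integer seed (defaults to the config seed).
#' @return List: `peripheral`, `central` (`accuracy_result`s), `compound`
#'   (`compound_accuracy`), `arm` (the simulated objects).
#' @export
circuit_stage_accuracies <- function(treatment, config = default_config(),
                                     seed = config$seed) {
  st <- make_ramp_hold_release(config$stimulus$amplitude,
                               config$stimulus$fast_velocity,
                               config$stimulus$hold,
                               sample_rate = config$sample_rate)
  arm <- simulate_treatment_arm(treatment, st, config, seed)
  ramp <- st$amplitude / st$velocity
  epoch <- c(st$onsets[1], st$onsets[1] + 2 * ramp + st$hold + 1)
  grid_force <- stats::approx(arm$dynamics$time, arm$dynamics$force,
                              xout = arm$code$time)$y
  peripheral <- vaf(arm$code$rate_mean, grid_force,
                    max_lag = config$max_lag,
                    sample_rate = config$population_sample_rate,
                    epoch = epoch, time = arm$code$time,
                    stage_name = "peripheral")
  central <- vaf(arm$trace$voltage, arm$code$rate_mean,
                 max_lag = config$max_lag,
                 sample_rate = config$population_sample_rate,
                 epoch = epoch, time = arm$code$time,
                 stage_name = "central")
  list(peripheral = peripheral, central = central,
       compound = compound(c(peripheral$r2_percent, central$r2_percent)),
       arm = arm)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic data under one config and writes a
#' report bundle to `out_dir`: encoding profiles (CSV), PCA scores and
#' explained variance (CSV), population codes (CSV), circuit accuracy and
#' posterior and kinematic summaries (JSON), and a run log listing every
#' analysis constant in force. Identical config + seed give identical
#' outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the in-memory report list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # encoding profiles per class x treatment on the fast stretch
  st <- make_ramp_hold_release(config$stimulus$amplitude,
                               config$stimulus$fast_velocity,
                               config$stimulus$hold,
                               sample_rate = config$sample_rate)
  dyn <- simulate_muscle_force(st)
  profiles <- stage("encode", {
    rows <- list()
    i <- 0
    for (treatment in c("control", "cOIN")) {
      phen <- default_phenotypes(treatment)$neurons
      for (cls in MUSCLE_CLASSES) {
        p <- phen[phen$neuron_class == cls, ]
        for (neuron in 1:5) {
          i <- i + 1
          trains <- lapply(seq_len(config$n_trials_encoding), function(tr)
            simulate_propriosensor_spikes(p, st, dyn,
                                          seed = child_seed(seed, 1000 + 10 * i + tr)))
          rows[[length(rows) + 1]] <- compute_profile(trains, st, dyn)
        }
      }
    }
    do.call(rbind, rows)
  })
  write_profiles(profiles, file.path(out_dir, "encoding_profiles.csv"))

  latent <- stage("pca", {
    space <- fit_pca(standardize_profiles(profiles))
    geom <- group_geometry(space)
    utils::write.csv(cbind(space$labels, as.data.frame(space$scores)),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(PC = seq_along(space$explained_variance),
                                explained_percent = space$explained_variance),
                     file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
    list(space = space, geometry = geom)
  })

  acc <- stage("accuracy", {
    lapply(c(control = "control", cOIN = "cOIN"), function(tr)
      circuit_stage_accuracies(tr, config, seed = child_seed(seed, 2000)))
  })
  for (tr in names(acc))
    write_population(scale_population(acc[[tr]]$arm$code),
                     file.path(out_dir, paste0("population_", tr, ".csv")))

  bayes <- stage("bayes", {
    prior <- beta_posterior(config$prior[["a"]], config$prior[["b"]])
    s_ctrl <- summarize_posterior(update_beta(prior, 19, 20), config$hdi_level)
    s_coin <- summarize_posterior(update_beta(prior, 7, 26), config$hdi_level)
    list(control = s_ctrl, cOIN = s_coin,
         overlap = hdi_overlap_test(s_ctrl, s_coin))
  })

  kin <- stage("kinematics", {
    rungs <- seq(0, by = config$rung_spacing_cm,
                 length.out = config$n_rungs)
    lapply(c(control = "control", cOIN = "cOIN"), function(tr) {
      trial <- simulate_ladder_trial(default_phenotypes(tr)$gait, rungs,
                                     n_steps = config$n_gait_steps,
                                     seed = child_seed(seed, 3000))
      ev <- classify_hits(detect_placements(filter_frames(trial)),
                          rungs, config$hit_tolerance_cm)
      kinematic_summary(replacement_and_error(ev,
                                              config$replacement_tolerance_cm))
    })
  })

  summary <- list(
    config = unclass(config),
    n_neurons_population = sum(config$composition),
    pc12_explained_percent = sum(latent$space$explained_variance[1:2]),
    accuracy = lapply(acc, function(a) list(
      peripheral = a$peripheral$r2_percent,
      central = a$central$r2_percent,
      compound = a$compound$overall_percent_int,
      lags = c(a$peripheral$lag_used, a$central$lag_used))),
    detection_posterior = lapply(bayes[c("control", "cOIN")], unclass),
    detection_significant = bayes$overlap$significant,
    kinematics = kin)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(summary)
}
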