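# Synthetic pose-tracker exports of ladder-rung walking. One hindlimb
# chain (hip, knee, ankle, toe tip, hindfoot) plus the ipsilateral
# forefoot, per-frame x/y (cm) with per-keypoint confidences, in the wide
# format common to markerless trackers. Forefoot placements land on rungs;
# the hindfoot targets the prior ipsilateral forefoot rung (replacement)
# and misses undershoot by a truncated normal.

kp_names <- function() c("hip", "knee", "ankle", "toe_tip", "forefoot",
                         "hindfoot")

# Piecewise foot trajectory through a sequence of (time, x) stances:
# constant during stance, sinusoidal-lift swing between stances.
foot_path <- function(t, stance_t0, stance_t1, stance_x, lift = 2) {
  x <- numeric(length(t)); y <- numeric(length(t))
  n <- length(stance_x)
  for (i in seq_len(n)) {
    w <- t >= stance_t0[i] & t <= stance_t1[i]
    x[w] <- stance_x[i]; y[w] <- 0
    if (i < n) {
      w2 <- t > stance_t1[i] & t < stance_t0[i + 1]
      ph <- (t[w2] - stance_t1[i]) / (stance_t0[i + 1] - stance_t1[i])
      x[w2] <- stance_x[i] + ph * (stance_x[i + 1] - stance_x[i])
      y[w2] <- lift * sin(pi * ph)
    }
  }
  x[t < stance_t0[1]] <- stance_x[1]
  x[t > stance_t1[n]] <- stance_x[n]
  list(x = x, y = y)
}

# Two-link planar IK: knee position given hip and ankle and segment
# lengths, knee bent forward (positive x side of the hip-ankle line).
knee_ik <- function(hip, ankle, l_thigh = 4, l_shank = 4) {
  d <- sqrt(sum((ankle - hip)^2))
  d <- min(d, l_thigh + l_shank - 1e-6)
  a <- (l_thigh^2 - l_shank^2 + d^2) / (2 * d)
  h <- sqrt(max(l_thigh^2 - a^2, 0))
  u <- (ankle - hip) / d
  mid <- hip + a * u
  mid + h * c(u[2], -u[1])
}

#' Simulate a tracked ladder-rung walking trial
#'
#' Generates per-frame keypoint coordinates with confidences for one limb
#' pair crossing a rung ladder. For each stride the forefoot lands on the
#' next rung; the hindfoot then targets the rung the ipsilateral forefoot
#' just vacated with probability `replacement_prob` (otherwise the rung
#' before it), lands exactly on its target with probability
#' `1 - miss_prob`, and otherwise undershoots it by
#' `Normal(undershoot_mean, undershoot_sd)` truncated at zero. Keypoint
#' coordinates get Gaussian noise (`keypoint_noise_sd`); each keypoint's
#' confidence drops below 0.8 with probability
#' `confidence_dropout_prob` per frame.
#'
#' @param gait `default_phenotypes()$gait` list.
#' @param rung_positions Rung x positions (cm), strictly increasing,
#'   length >= 2.
#' @param n_steps Number of hindfoot placements to generate.
#' @param seed Integer seed.
#' @return Object of class `tracked_trial`: `frames` (data.frame, one row
#'   per frame: `frame`, `time_s`, then `<kp>_x`, `<kp>_y`, `<kp>_conf`
#'   per keypoint), `frame_rate`, `rung_positions`, `slope_deg`, and the
#'   generator's per-step `truth` table (target rung, hit, replacement,
#'   error).
#' @export
simulate_ladder_trial <- function(gait, rung_positions, n_steps = 20,
                                  seed = 1L) {
  if (length(rung_positions) < 2)
    stop("need at least 2 rungs", call. = FALSE)
  stopifnot(!is.unsorted(rung_positions, strictly = TRUE))
  set.seed(as.integer(seed))
  fr <- gait$frame_rate
  step_dur <- 0.5            # s per stride: 0.3 stance + 0.2 swing
  stance_dur <- 0.3
  rungs <- rung_positions
  n_steps <- min(n_steps, length(rungs) - 1)
  # forefoot stance i is on rung i+1; hindfoot step i targets rung of
  # forefoot stance i (replacement) or the previous rung
  fore_rung <- seq_len(n_steps + 1)
  truth <- data.frame(step = seq_len(n_steps))
  truth$replacement <- stats::runif(n_steps) < gait$replacement_prob
  truth$target_rung <- ifelse(truth$replacement, fore_rung[truth$step + 1] - 1,
                              pmax(1, fore_rung[truth$step + 1] - 2))
  truth$miss <- stats::runif(n_steps) < gait$miss_prob
  under <- abs(stats::rnorm(n_steps, gait$undershoot_mean, gait$undershoot_sd))
  truth$error_cm <- ifelse(truth$miss, -under, 0)
  truth$hind_x <- rungs[truth$target_rung] + truth$error_cm
  t0_fore <- 0.2 + (seq_len(n_steps + 1) - 1) * step_dur
  t0_hind <- t0_fore[-1] - 0.25   # hindfoot lands mid-way through stride
  total <- t0_fore[n_steps + 1] + stance_dur + 0.2
  t <- seq(0, total, by = 1 / fr)
  fore <- foot_path(t, t0_fore, t0_fore + stance_dur, rungs[fore_rung])
  hind <- foot_path(t, t0_hind, t0_hind + stance_dur, truth$hind_x)
  nfr <- length(t)
  frames <- data.frame(frame = seq_len(nfr), time_s = t)
  ns <- gait$keypoint_noise_sd
  add_kp <- function(frames, name, x, y) {
    frames[[paste0(name, "_x")]] <- x + stats::rnorm(nfr, 0, ns)
    frames[[paste0(name, "_y")]] <- y + stats::rnorm(nfr, 0, ns)
    conf <- stats::runif(nfr, 0.9, 1)
    drop <- stats::runif(nfr) < gait$confidence_dropout_prob
    conf[drop] <- stats::runif(sum(drop), 0.2, 0.79)
    frames[[paste0(name, "_conf")]] <- conf
    frames
  }
  # hindlimb chain above the hindfoot
  ankle_x <- hind$x + 0.5; ankle_y <- hind$y + 1
  hip_x <- hind$x - 1.5; hip_y <- rep(7, nfr)
  knee <- vapply(seq_len(nfr), function(i)
    knee_ik(c(hip_x[i], hip_y[i]), c(ankle_x[i], ankle_y[i])),
    numeric(2))
  frames <- add_kp(frames, "hip", hip_x, hip_y)
  frames <- add_kp(frames, "knee", knee[1, ], knee[2, ])
  frames <- add_kp(frames, "ankle", ankle_x, ankle_y)
  frames <- add_kp(frames, "toe_tip", hind$x + 1, hind$y)
  frames <- add_kp(frames, "forefoot", fore$x, fore$y)
  frames <- add_kp(frames, "hindfoot", hind$x, hind$y)
  structure(list(frames = frames, frame_rate = fr,
                 rung_positions = rungs, slope_deg = 10, truth = truth),
            class = "tracked_trial")
}

#' @export
print.tracked_trial <- function(x, ...) {
  cat(sprintf("<tracked_trial: %d frames @ %g Hz, %d rungs>\n",
              nrow(x$frames), x$frame_rate, length(x$rung_positions)))
  invisible(x)
}

#' Write a tracked trial as a pose-export CSV
#'
#' Wide CSV, one row per frame, three columns (`_x`, `_y`, `_conf`) per
#' keypoint -- the layout of common markerless pose-tracker exports.
#'
#' @param trial A `tracked_trial`.
#' @param path Output path.
#' @export
write_tracked_trial <- function(trial, path) {
  utils::write.csv(trial$frames, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose-export CSV into a tracked trial
#'
#' @param path CSV written by [write_tracked_trial()] (or any wide export
#'   with `frame`, `time_s` and `<kp>_x/_y/_conf` columns).
#' @param frame_rate Frames per second; inferred from `time_s` if omitted.
#' @param rung_positions Rung x positions (cm).
#' @param slope_deg Ladder slope (degrees).
#' @return A `tracked_trial` (without generator truth).
#' @export
read_tracked_trial <- function(path, frame_rate = NULL, rung_positions = NULL,
                               slope_deg = 10) {
  frames <- utils::read.csv(path)
  if (is.null(frame_rate))
    frame_rate <- 1 / stats::median(diff(frames$time_s))
  structure(list(frames = frames, frame_rate = frame_rate,
                 rung_positions = rung_positions, slope_deg = slope_deg,
                 truth = NULL),
            class = "tracked_trial")
}
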