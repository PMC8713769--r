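# Ladder-rung walking analysis from pose-tracker exports: frame quality
# filters (keypoint confidence < 0.8; keypoint speed > 150 cm/s),
# stance-based placement detection, hit/miss classification against rung
# positions, the forefoot-reporter replacement rule with signed initial
# hindfoot error (negative = undershoot), and sagittal joint angles.

kp_cols <- function(frames, suffix) {
  grep(paste0("_", suffix, "$"), names(frames), value = TRUE)
}

#' Filter pose frames by confidence and speed
#'
#' Drops frames where any keypoint's confidence is below `min_confidence`,
#' or where any keypoint's frame-to-frame speed exceeds `max_speed_cm_s`
#' (tracking glitches faster than the animal's maximum locomotor speed).
#' The two rules are applied to the original frame set, so their order is
#' immaterial and the exclusion report partitions the dropped frames.
#'
#' @param trial A `tracked_trial`.
#' @param min_confidence Minimum per-keypoint detection confidence.
#' @param max_speed_cm_s Maximum plausible keypoint speed (cm/s).
#' @return The trial with filtered `frames` and an `exclusion_report`
#'   list: `n_input`, `n_confidence`, `n_speed`, `n_kept` (a frame failing
#'   both rules is counted under confidence).
#' @export
filter_frames <- function(trial, min_confidence = 0.8,
                          max_speed_cm_s = 150) {
  frames <- trial$frames
  if (!nrow(frames)) stop("empty trial", call. = FALSE)
  conf <- as.matrix(frames[, kp_cols(frames, "conf"), drop = FALSE])
  bad_conf <- apply(conf < min_confidence, 1, any)
  xs <- as.matrix(frames[, kp_cols(frames, "x"), drop = FALSE])
  ys <- as.matrix(frames[, kp_cols(frames, "y"), drop = FALSE])
  dt <- diff(frames$time_s)
  speed <- sqrt(diff(xs)^2 + diff(ys)^2) / dt
  bad_speed <- c(FALSE, rowSums(speed > max_speed_cm_s) > 0)
  keep <- !(bad_conf | bad_speed)
  trial$frames <- frames[keep, , drop = FALSE]
  trial$exclusion_report <- list(
    n_input = nrow(frames),
    n_confidence = sum(bad_conf),
    n_speed = sum(bad_speed & !bad_conf),
    n_kept = sum(keep))
  trial
}

# 3-point running mean, ends untouched.
smooth3 <- function(v) {
  if (length(v) < 3) return(v)
  out <- v
  out[2:(length(v) - 1)] <- (v[-c(1, 2)] + v[-c(1, length(v))] +
                               v[-c(length(v) - 1, length(v))]) / 3
  out
}

#' Detect foot placements (stances)
#'
#' A placement is a run of >= `min_frames` consecutive frames in which the
#' foot keypoint's smoothed vertical speed stays below
#' `max_vert_speed_cm_s` and its height is in the lower part of its range
#' (within `height_frac` of the trial minimum-to-maximum span). Runs
#' separated by fewer than `min_frames` lifted frames are merged. The
#' stance position is the mean x over the run.
#'
#' @param trial A (filtered) `tracked_trial`.
#' @param feet Foot keypoints to scan.
#' @param max_vert_speed_cm_s Vertical-speed threshold (cm/s).
#' @param min_frames Minimum stance duration in frames.
#' @param height_frac Fraction of the vertical span above the minimum
#'   still counted as "on the ground".
#' @return data.frame of step events ordered by time: `foot`, `t_start`,
#'   `t_end`, `placement_x`, `placement_y`; empty (with a warning) when no
#'   stance is found.
#' @export
detect_placements <- function(trial, feet = c("forefoot", "hindfoot"),
                              max_vert_speed_cm_s = 5, min_frames = 3,
                              height_frac = 0.25) {
  frames <- trial$frames
  events <- list()
  for (foot in feet) {
    x <- frames[[paste0(foot, "_x")]]
    y <- smooth3(frames[[paste0(foot, "_y")]])
    t <- frames$time_s
    if (length(t) < min_frames + 1) next
    vy <- c(0, diff(y) / diff(t))
    low <- y <= min(y) + height_frac * max(diff(range(y)), 1e-6)
    cand <- abs(vy) <= max_vert_speed_cm_s & low
    # break candidate runs across temporal gaps left by frame filtering
    gap <- c(FALSE, diff(t) > 2.5 / trial$frame_rate)
    run_id <- cumsum((!cand) | gap)
    for (g in split(seq_along(cand)[cand], run_id[cand])) {
      if (length(g) < min_frames) next
      events[[length(events) + 1]] <- data.frame(
        foot = foot, t_start = t[g[1]], t_end = t[g[length(g)]],
        placement_x = mean(x[g]), placement_y = mean(frames[[paste0(foot, "_y")]][g]))
    }
  }
  if (!length(events)) {
    warning("no placements detected", call. = FALSE)
    return(data.frame(foot = character(0), t_start = numeric(0),
                      t_end = numeric(0), placement_x = numeric(0),
                      placement_y = numeric(0)))
  }
  out <- do.call(rbind, events)
  out <- out[order(out$t_start), ]
  # merge same-foot stances separated by a sub-threshold lift
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    prev <- max(which(keep[seq_len(i - 1)] &
                        out$foot[seq_len(i - 1)] == out$foot[i]), -Inf)
    if (is.finite(prev) &&
        out$t_start[i] - out$t_end[prev] < min_frames / trial$frame_rate) {
      out$t_end[prev] <- out$t_end[i]
      out$placement_x[prev] <- (out$placement_x[prev] + out$placement_x[i]) / 2
      keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify placements as rung hits or misses
#'
#' A placement is a hit when its distance to the nearest rung is at most
#' `tolerance_cm`; the nearest rung is recorded either way.
#'
#' @param events Step events from [detect_placements()].
#' @param rung_positions Rung x positions (cm).
#' @param tolerance_cm Hit tolerance (cm).
#' @return `events` with `nearest_rung_x`, `dist_to_rung` and `hit`
#'   columns.
#' @export
classify_hits <- function(events, rung_positions, tolerance_cm = 0.5) {
  if (!nrow(events)) {
    events$nearest_rung_x <- numeric(0)
    events$dist_to_rung <- numeric(0)
    events$hit <- logical(0)
    return(events)
  }
  idx <- vapply(events$placement_x,
                function(x) which.min(abs(rung_positions - x)), integer(1))
  events$nearest_rung_x <- rung_positions[idx]
  events$dist_to_rung <- abs(events$placement_x - events$nearest_rung_x)
  events$hit <- events$dist_to_rung <= tolerance_cm
  events
}

#' Replacement rule and signed initial hindfoot error
#'
#' For each hindfoot placement the intended target is the most recent
#' preceding ipsilateral forefoot placement's rung (the forefoot-reporter
#' strategy); `replacement` is true when the hindfoot lands within
#' `tolerance_cm` of the forefoot position. The signed error is the
#' hindfoot position minus the target rung along the direction of travel
#' (inferred from the forefoot x trend), so negative errors are
#' undershoots. Only the first (initial) hindfoot placement per forefoot
#' target is retained -- subsequent corrective placements toward the same
#' target are excluded; hindfoot placements with no preceding forefoot
#' placement are skipped.
#'
#' @param events Step events with `hit` flags (see [classify_hits()]).
#' @param tolerance_cm Replacement distance tolerance (cm).
#' @return Hindfoot events with `target_x`, `replacement`, `error_cm`,
#'   `initial` columns; only initial placements are returned.
#' @export
replacement_and_error <- function(events, tolerance_cm = 0.5) {
  fore <- events[events$foot == "forefoot", ]
  hind <- events[events$foot == "hindfoot", ]
  if (!nrow(hind) || !nrow(fore))
    return(cbind(hind[0, ], target_x = numeric(0),
                 replacement = logical(0), error_cm = numeric(0)))
  travel <- sign(fore$placement_x[nrow(fore)] - fore$placement_x[1])
  if (travel == 0) travel <- 1
  out <- list()
  seen_targets <- numeric(0)
  for (i in seq_len(nrow(hind))) {
    prev <- fore[fore$t_start < hind$t_start[i], ]
    if (!nrow(prev)) next
    f <- prev[nrow(prev), ]
    target <- f$nearest_rung_x
    initial <- !any(abs(seen_targets - target) < 1e-9)
    seen_targets <- c(seen_targets, target)
    if (!initial) next
    e <- hind[i, ]
    e$target_x <- target
    e$replacement <- abs(e$placement_x - f$placement_x) <= tolerance_cm
    e$error_cm <- (e$placement_x - target) * travel
    out[[length(out) + 1]] <- e
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary rates for a set of hindfoot events
#'
#' @param hind_events Output of [replacement_and_error()].
#' @return List: `n_steps`, `hit_rate`, `miss_rate`,
#'   `replacement_rate` (among hits, the restriction under which
#'   replacement is scored), `mean_error_cm`, `mean_abs_miss_error_cm`.
#' @export
kinematic_summary <- function(hind_events) {
  hits <- hind_events$hit
  miss_err <- abs(hind_events$error_cm[!hits])
  list(n_steps = nrow(hind_events),
       hit_rate = mean(hits),
       miss_rate = mean(!hits),
       replacement_rate = if (any(hits)) mean(hind_events$replacement[hits]) else NA_real_,
       mean_error_cm = mean(hind_events$error_cm),
       mean_abs_miss_error_cm = if (length(miss_err)) mean(miss_err) else NA_real_)
}

interior_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Per-frame sagittal joint angles
#'
#' Knee angle: interior angle at the knee between the thigh (hip-knee) and
#' shank (knee-ankle). Ankle angle: interior angle at the ankle between
#' shank and foot (ankle-toe tip). Hip angle: angle at the hip between the
#' thigh and the horizontal direction of travel (no trunk keypoint is
#' tracked). Frames with a missing keypoint give `NA` angles; all angles
#' are invariant to rigid translation and, for knee/ankle, rotation.
#'
#' @param trial A (filtered) `tracked_trial`.
#' @return data.frame: `time_s`, `hip_deg`, `knee_deg`, `ankle_deg`.
#' @export
joint_angles <- function(trial) {
  f <- trial$frames
  n <- nrow(f)
  get <- function(kp, i) c(f[[paste0(kp, "_x")]][i], f[[paste0(kp, "_y")]][i])
  travel <- sign(f$forefoot_x[n] - f$forefoot_x[1])
  if (is.na(travel) || travel == 0) travel <- 1
  out <- data.frame(time_s = f$time_s, hip_deg = NA_real_,
                    knee_deg = NA_real_, ankle_deg = NA_real_)
  for (i in seq_len(n)) {
    hip <- get("hip", i); knee <- get("knee", i)
    ankle <- get("ankle", i); toe <- get("toe_tip", i)
    if (anyNA(c(hip, knee, ankle, toe))) next
    out$knee_deg[i] <- interior_angle(hip, knee, ankle)
    out$ankle_deg[i] <- interior_angle(knee, ankle, toe)
    out$hip_deg[i] <- interior_angle(hip + c(travel, 0), hip, knee)
  }
  out
}
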