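mini_trial <- function(frames, frame_rate = 100, rungs = default_rungs()) {
  structure(list(frames = frames, frame_rate = frame_rate,
                 rung_positions = rungs, slope_deg = 10, truth = NULL),
            class = "tracked_trial")
}

flat_frames <- function(n = 10, conf = 1) {
  f <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / 100)
  for (kp in c("hip", "knee", "ankle", "toe_tip", "forefoot", "hindfoot")) {
    f[[paste0(kp, "_x")]] <- 1
    f[[paste0(kp, "_y")]] <- 1
    f[[paste0(kp, "_conf")]] <- conf
  }
  f
}

test_that("frame filters drop low-confidence and implausibly fast frames", {
  f <- flat_frames(10)
  f$knee_conf[c(3, 7)] <- 0.79
  t1 <- filter_frames(mini_trial(f))
  expect_equal(nrow(t1$frames), 8)
  expect_equal(t1$exclusion_report$n_confidence, 2)
  # a 2 cm jump in one 10 ms frame = 200 cm/s > 150 cm/s
  f2 <- flat_frames(10)
  f2$ankle_x[5] <- 3
  t2 <- filter_frames(mini_trial(f2))
  expect_equal(t2$exclusion_report$n_speed, 2)  # jump in and out
  expect_false(5 %in% t2$frames$frame)
  # clean static trial: nothing excluded
  t3 <- filter_frames(mini_trial(flat_frames(10)))
  expect_equal(t3$exclusion_report$n_kept, 10)
  expect_equal(t3$exclusion_report$n_input,
               with(t3$exclusion_report, n_kept + n_confidence + n_speed))
  expect_error(filter_frames(mini_trial(flat_frames(1)[0, ])), "empty")
})

test_that("placement detection recovers programmed stances", {
  g <- gait_with(miss_prob = 0, confidence_dropout_prob = 0,
                 keypoint_noise_sd = 0.005)
  trial <- simulate_ladder_trial(g, default_rungs(), 8, seed = 2)
  ev <- detect_placements(filter_frames(trial))
  expect_equal(sum(ev$foot == "hindfoot"), 8, tolerance = 0)
  expect_equal(sum(ev$foot == "forefoot"), 9, tolerance = 0)
  # continuous swing: no stances
  n <- 60
  f <- flat_frames(n)
  f$hindfoot_y <- 3 + 2 * sin(seq(0, 6 * pi, length.out = n))
  f$hindfoot_x <- seq(0, 30, length.out = n)
  f$forefoot_y <- f$hindfoot_y
  f$forefoot_x <- f$hindfoot_x
  expect_warning(ev2 <- detect_placements(mini_trial(f)), "no placements")
  expect_equal(nrow(ev2), 0)
})

test_that("hits, replacement and signed error follow the forefoot reporter", {
  ev <- data.frame(foot = c("forefoot", "hindfoot", "forefoot", "hindfoot"),
                   t_start = c(0, 1, 2, 3), t_end = c(0.5, 1.5, 2.5, 3.5),
                   placement_x = c(4, 4.02, 8, 6.28),
                   placement_y = 0)
  ev <- classify_hits(ev, default_rungs(), 0.5)
  expect_true(ev$hit[1]); expect_true(ev$hit[2]); expect_false(ev$hit[4])
  # midway between 4 cm-spaced rungs with 0.5 tolerance: miss
  mid <- classify_hits(data.frame(foot = "hindfoot", t_start = 0, t_end = 1,
                                  placement_x = 6, placement_y = 0),
                       default_rungs(), 0.5)
  expect_false(mid$hit)
  he <- replacement_and_error(ev, 0.5)
  expect_equal(nrow(he), 2)
  expect_true(he$replacement[1])
  expect_equal(he$error_cm[1], 0.02, tolerance = 1e-9)
  # second hindfoot lands 1.72 cm short of the forefoot rung at 8
  expect_false(he$replacement[2])
  expect_equal(he$error_cm[2], -1.72, tolerance = 1e-9)
  summ <- kinematic_summary(he)
  expect_equal(summ$hit_rate, 0.5)
  expect_equal(summ$mean_abs_miss_error_cm, 1.72)
})

test_that("generated miss rate and undershoot are recovered downstream", {
  g <- gait_with(miss_prob = 0, confidence_dropout_prob = 0.02)
  trial <- simulate_ladder_trial(g, default_rungs(40), 30, seed = 4)
  ev <- classify_hits(detect_placements(filter_frames(trial)),
                      trial$rung_positions, 0.5)
  he <- replacement_and_error(ev, 0.5)
  expect_equal(kinematic_summary(he)$hit_rate, 1)
})

test_that("joint angles are geometric and rigid-motion invariant", {
  f <- flat_frames(2)
  # collinear hip-knee-ankle, right angle at the ankle
  f$hip_x <- 0; f$hip_y <- 4
  f$knee_x <- 0; f$knee_y <- 2
  f$ankle_x <- 0; f$ankle_y <- 0
  f$toe_tip_x <- 2; f$toe_tip_y <- 0
  ja <- joint_angles(mini_trial(f))
  expect_equal(ja$knee_deg[1], 180)
  expect_equal(ja$ankle_deg[1], 90)
  # rotate + translate everything: knee/ankle angles unchanged
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g2 <- f
  for (kp in c("hip", "knee", "ankle", "toe_tip", "forefoot", "hindfoot")) {
    xy <- R %*% rbind(f[[paste0(kp, "_x")]], f[[paste0(kp, "_y")]]) + c(3, -1)
    g2[[paste0(kp, "_x")]] <- xy[1, ]; g2[[paste0(kp, "_y")]] <- xy[2, ]
  }
  ja2 <- joint_angles(mini_trial(g2))
  expect_equal(ja2$knee_deg, ja$knee_deg, tolerance = 1e-9)
  expect_equal(ja2$ankle_deg, ja$ankle_deg, tolerance = 1e-9)
  # missing keypoint: angles flagged missing for that frame
  f$knee_x[2] <- NA
  expect_true(is.na(joint_angles(mini_trial(f))$knee_deg[2]))
})

test_that("pose exports round-trip through the wide CSV format", {
  g <- gait_with(confidence_dropout_prob = 0)
  trial <- simulate_ladder_trial(g, default_rungs(), 5, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracked_trial(trial, path)
  back <- read_tracked_trial(path, rung_positions = trial$rung_positions)
  expect_equal(back$frame_rate, trial$frame_rate, tolerance = 1e-6)
  expect_equal(back$frames$hindfoot_x, trial$frames$hindfoot_x,
               tolerance = 1e-6)
})
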