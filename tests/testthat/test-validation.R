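test_that("valid sample fraction is a plain proportion", {
  rec <- function(v) {
    n <- length(v)
    gaze_recording((seq_len(n) - 1) / 120,
                   matrix(rep(c(0, 0, 1), n), nrow = n, ncol = 3,
                          byrow = TRUE),
                   matrix(rep(c(1, 0, 0, 0), n), nrow = n, ncol = 4,
                          byrow = TRUE),
                   matrix(0, n, 3), valid = v)
  }
  expect_equal(valid_sample_fraction(rec(rep(TRUE, 10))), 1)
  expect_equal(valid_sample_fraction(rec(rep(FALSE, 10))), 0)
  expect_equal(valid_sample_fraction(rec(rep(c(TRUE, FALSE),
                                             c(94, 6)))), 0.94)
  expect_error(valid_sample_fraction(rec(logical(0))), "empty")
})

test_that("main-sequence moments behave like standardised moments", {
  x <- c(seq(2, 10), seq(10, 2))  # symmetric
  ms <- main_sequence_stats(x, rep("g", length(x)))
  expect_equal(ms$skewness, 0, tolerance = 1e-9)

  set.seed(31)
  z <- rnorm(20000, 12, 3)
  ms2 <- main_sequence_stats(z, rep("n", length(z)))
  expect_equal(ms2$kurtosis, 3, tolerance = 0.1)  # non-excess convention
  expect_equal(ms2$mean_amplitude, 12, tolerance = 0.05)

  ms3 <- main_sequence_stats(rep(5, 10), rep("c", 10))
  expect_true(is.na(ms3$skewness) && is.na(ms3$kurtosis))

  both <- main_sequence_stats(c(x, z), rep(c("g", "n"),
                                           c(length(x), length(z))))
  expect_equal(nrow(both), 2)
})

test_that("pursuit validation separates static from moving objects", {
  sched <- rbind(one_trial("static", "parafoveal", 13),
                 one_trial("static", "peripheral", 13))
  sched$trial_id <- 1:2
  sim <- simulate_session(sched, params = quiet_params(seed = 14))
  sp <- compute_speeds(sim$recording)
  segs <- classify_recording(sim$recording, speeds = sp)
  rc <- raycast_series(sim$recording, sim$trials)
  pv <- pursuit_validation(segs, rc, sim$trials, truth = sim$truth)
  expect_lt(pv$pct_pursuit_on_static, 5)
  expect_true(is.na(pv$pct_pursuit_on_moving))  # no moving objects: NA
  expect_true(is.table(pv$confusion))
  expect_true(all(unlist(pv[c("pct_pursuit_on_static")]) >= 0))
})

test_that("fast pursuit over a moving disk is labelled smooth pursuit", {
  # hand-built scene: a dynamic peripheral disk tracked late in its
  # approach, where its angular speed is ~15-25 deg/s
  lay <- world_layout()
  fs <- 120
  t_since_cue <- seq(4.2, 5.2, by = 1 / fs)
  pos <- disk_position(lay, "peripheral", 0, 32, t_since_cue, "dynamic")
  az <- atan2(pos[, 1], pos[, 3]) * 180 / pi
  el <- atan2(pos[, 2], sqrt(pos[, 1]^2 + pos[, 3]^2)) * 180 / pi
  rec <- rec_from_angles(gaze_az = az, gaze_el = el)
  sp <- compute_speeds(rec)
  segs <- classify_recording(rec, speeds = sp)
  trials <- data.frame(trial_id = 1L, motion = "dynamic",
                       eccentricity = "peripheral", cue_distance = 32,
                       cued_disk_index = 0L, cue_time = -4.2,
                       target_time = -3, t_start = 0,
                       t_end = max(rec$t), i_start = 1L,
                       i_end = nrow(rec))
  rc <- raycast_series(rec, trials, lay)
  expect_true(all(rc$object == "disk:peripheral:0"))
  pv <- pursuit_validation(segs, rc, trials)
  expect_gte(pv$pct_pursuit_on_moving, 90)
  expect_gte(pv$moving["smooth_pursuit"], 90)
})

test_that("on-target gaze speed averages exclude catch-up bursts", {
  # 1 s on-target interval at a constant 9 deg/s gaze drift
  fs <- 120
  lay <- world_layout()
  n <- fs + 1
  az <- 9 * (seq_len(n) - 1) / fs
  rec <- rec_from_angles(gaze_az = az)
  sp <- compute_speeds(rec)
  segs <- classify_recording(rec, speeds = sp)
  rc <- data.frame(t = rec$t, object = "disk:parafoveal:2",
                   hit_distance = 13)
  trials <- data.frame(trial_id = 1L, motion = "static",
                       eccentricity = "parafoveal", cue_distance = 13,
                       cued_disk_index = 2L, cue_time = 0, target_time = 0.2,
                       t_start = 0, t_end = max(rec$t), i_start = 1L,
                       i_end = n)
  out <- target_interval_gaze_speed(segs, rc, sp, trials)
  expect_equal(out$mean_gaze_speed, 9, tolerance = 1e-6)

  # inject a 50 deg/s catch-up burst: the burst samples are excluded
  sp2 <- sp
  burst <- 60:62
  sp2$eye_speed[burst] <- 50
  sp2$gaze_speed[burst] <- 50
  out2 <- target_interval_gaze_speed(segs, rc, sp2, trials)
  expect_equal(out2$mean_gaze_speed,
               mean(sp2$gaze_speed[-c(burst)][
                 sp2$eye_speed[-c(burst)] <= 20]),
               tolerance = 1e-6)
  expect_lt(out2$mean_gaze_speed, 10)

  # eyes never on target: no value
  rc3 <- data.frame(t = rec$t, object = "cross", hit_distance = 11)
  out3 <- target_interval_gaze_speed(segs, rc3, sp, trials)
  expect_true(is.na(out3$mean_gaze_speed))
})

test_that("reaction times recover the scripted trial timing", {
  sched <- build_schedule(seed = 17)[c(1, 2, 97, 98), ]
  sched$trial_id <- 1:4
  sim <- simulate_session(sched, params = quiet_params(seed = 17))
  sp <- compute_speeds(sim$recording)
  segs <- classify_recording(sim$recording, speeds = sp)
  rc <- raycast_series(sim$recording, sim$trials)
  rt <- reaction_times(segs, sim$events, rc, sim$trials)
  # saccadic RT: detection onset sits within ~2 samples + the
  # sub-threshold ramp (~10 ms) of the scripted latency
  expect_true(all(abs(rt$saccadic_rt - sim$trials$saccade_latency) < 0.03))
  expect_equal(rt$button_rt, sim$trials$button_rt, tolerance = 1e-9)
  # disengagement: ray-cast leaves the disk within a few samples of the
  # scripted departure
  expect_true(all(abs(rt$disengagement_time -
                        (sim$trials$t_leave - sim$trials$soa)) < 0.05))
})

test_that("responses after the next cue are rejected, first response wins", {
  sim <- simulate_session(one_trial("static", "parafoveal"),
                          params = quiet_params(seed = 19))
  sp <- compute_speeds(sim$recording)
  segs <- classify_recording(sim$recording, speeds = sp)
  rc <- raycast_series(sim$recording, sim$trials)
  ev <- sim$events
  # add a second, later response: the first must be used
  extra <- ev[ev$kind == "response", ]
  extra$t <- extra$t + 0.4
  ev2 <- rbind(ev, extra)
  ev2 <- ev2[order(ev2$t), ]
  rt2 <- reaction_times(segs, ev2, rc, sim$trials)
  rt1 <- reaction_times(segs, ev, rc, sim$trials)
  expect_equal(rt2$button_rt, rt1$button_rt)
  # move the only response past the next cue: invalid
  ev3 <- ev
  ev3$t[ev3$kind == "response"] <- max(sim$recording$t) + 10
  trials2 <- rbind(sim$trials, sim$trials)
  trials2$trial_id <- 1:2
  trials2$cue_time[2] <- max(sim$recording$t) + 5  # next trial's cue
  rt3 <- reaction_times(segs, ev3, rc, trials2)
  expect_true(is.na(rt3$button_rt[1]))
})

test_that("label agreement and saccade recovery score against truth", {
  sim <- simulate_session(build_schedule(seed = 23)[1:6, ],
                          params = simulation_params(seed = 23))
  sp <- compute_speeds(sim$recording)
  segs <- classify_recording(sim$recording, speeds = sp)
  agree <- label_agreement(sim$truth, segs)
  expect_gt(agree, 0.85)
  rec_rate <- saccade_recovery(sim$truth, segs, sim$recording, sp)
  expect_gt(rec_rate$rate, 0.9)
  expect_lte(rec_rate$n_scored, rec_rate$n_total)
  uncond <- saccade_recovery(sim$truth, segs, sim$recording, sp,
                             require_usable = FALSE)
  expect_lte(uncond$rate, 1)
  expect_equal(uncond$n_scored, uncond$n_total)
})
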