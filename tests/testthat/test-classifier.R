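test_that("threshold scaling follows (1 + v_head/60) * base", {
  expect_equal(scale_threshold(0, 35), 35)
  expect_equal(scale_threshold(60, 35), 70)
  expect_equal(scale_threshold(30, 10), 15)
  expect_error(scale_threshold(-1, 35), "non-negative")
  v <- seq(0, 100, by = 5)
  expect_true(all(diff(scale_threshold(v, 35)) > 0))
})

test_that("saccade detection respects duration and scaled thresholds", {
  quiet <- speeds_from_values(rep(5, 100))
  expect_equal(nrow(detect_saccades(quiet)), 0)

  eye <- rep(5, 100); eye[40:43] <- 50  # 4 samples ~ 33 ms
  one <- detect_saccades(speeds_from_values(eye))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$i_start, one$i_end), c(40, 43))

  eye2 <- rep(5, 100); eye2[40:41] <- 50  # ~17 ms, too short
  expect_equal(nrow(detect_saccades(speeds_from_values(eye2))), 0)

  # head at 60 deg/s raises the cut to 70: eye at 50 is sub-threshold
  fast_head <- speeds_from_values(rep(50, 100), head = 60)
  expect_equal(nrow(detect_saccades(fast_head)), 0)

  # unusable samples break runs and are never bridged
  eye3 <- rep(5, 100); eye3[40:49] <- 50
  usable <- rep(TRUE, 100); usable[44] <- FALSE
  segs3 <- detect_saccades(speeds_from_values(eye3, usable = usable))
  expect_equal(segs3$i_start, c(40, 45))
  expect_equal(segs3$i_end, c(43, 49))
})

test_that("detector matches the brute-force window oracle on random traces", {
  set.seed(2024)
  for (k in 1:150) {
    n <- sample(50:500, 1)
    eye <- runif(n, 0, 20)
    burst_at <- sample(n, sample(0:5, 1))
    for (b in burst_at) {
      len <- sample(1:8, 1)
      eye[b:min(n, b + len)] <- runif(1, 30, 90)
    }
    sp <- speeds_from_values(eye, head = runif(n, 0, 80),
                             usable = runif(n) > 0.05)
    got <- detect_saccades(sp)
    want <- oracle_saccades(sp)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      expect_equal(got$i_start, want[, 1])
      expect_equal(got$i_end, want[, 2])
    }
  }
})

test_that("raising head speed never adds detected saccade samples", {
  set.seed(55)
  for (k in 1:10) {
    n <- 300
    eye <- runif(n, 0, 60)
    base_head <- runif(n, 0, 20)
    sp1 <- speeds_from_values(eye, head = base_head)
    sp2 <- speeds_from_values(eye, head = base_head + 15)
    count <- function(s) {
      d <- detect_saccades(s)
      if (!nrow(d)) 0L else sum(d$i_end - d$i_start + 1L)
    }
    expect_lte(count(sp2), count(sp1))
  }
})

test_that("saccade metrics measure the world-frame gaze shift", {
  # scripted 10 degree saccade embedded in fixation
  prof <- sample_saccade_profile(10, simulation_params())
  az <- c(rep(0, 30), cumsum(prof) * attr(prof, "dt"), rep(10, 30))
  rec <- rec_from_angles(gaze_az = az)
  sp <- compute_speeds(rec)
  segs <- detect_saccades(sp)
  expect_equal(nrow(segs), 1)
  segs <- saccade_metrics(segs, rec, sp)
  expect_equal(segs$amplitude, 10, tolerance = 0.2 / 10)
  expect_lte(segs$peak_velocity, attr(prof, "peak"))
  expect_gt(segs$peak_velocity, 0.8 * attr(prof, "peak"))

  # injected extreme peak is reported as-is
  eye <- rep(5, 60); eye[30:34] <- c(600, 900, 1200, 900, 600)
  sp2 <- speeds_from_values(eye)
  seg2 <- detect_saccades(sp2)
  seg2 <- saccade_metrics(seg2, rec_from_angles(rep(0, 60)), sp2)
  expect_equal(seg2$peak_velocity, 1200)
})

test_that("amplitude and peak-velocity exclusions relabel, never delete", {
  segs <- new_seg <- data.frame(
    i_start = c(1L, 10L, 20L), i_end = c(5L, 14L, 24L),
    t_start = 0, t_end = 0, label = "saccade",
    amplitude = c(2.9, 17, 10), peak_velocity = c(300, 400, 1050),
    mean_eye_speed = NA_real_, mean_head_speed = NA_real_,
    mean_gaze_speed = NA_real_)
  out <- filter_saccades(segs)
  expect_equal(out$label, c("excluded_saccade", "saccade",
                            "excluded_saccade"))
  expect_equal(nrow(out), 3)
  # boundary: exactly 1000 deg/s is excluded ("under 1,000" is kept)
  segs$peak_velocity <- c(1000, 999.99, 400)
  segs$amplitude <- c(10, 10, 3)  # amplitude must exceed 3
  out2 <- filter_saccades(segs)
  expect_equal(out2$label, c("excluded_saccade", "saccade",
                             "excluded_saccade"))
})

test_that("intersaccadic intervals tile into 100 ms epochs", {
  tile <- function(n_samples) {
    sp <- speeds_from_values(rep(1, n_samples))
    ep <- partition_intersaccadic(new_segments_for_test(), sp)
    ep$i_end - ep$i_start + 1L
  }
  expect_equal(tile(52), c(12, 12, 12, 16))  # 430 ms -> 100,100,100,130
  expect_equal(tile(12), 12)                 # one full epoch
  expect_equal(tile(9), 9)                   # 75 ms remainder keeps itself
  sp <- speeds_from_values(rep(1, 5))        # 40 ms fragment
  ep <- partition_intersaccadic(new_segments_for_test(), sp)
  expect_equal(ep$label, "unclassified")
})

test_that("epoch decision tree reproduces hand-evaluated cases", {
  cases <- rbind(
    # gaze, eye, head -> expected
    c(0, 0, 0),    # fixation: everything still
    c(3, 12, 12),  # vor: scaled low gaze (1+12/60)*10 = 12 > 3, head > 7
    c(25, 25, 1),  # smooth pursuit: gaze moving, head still
    c(25, 2, 25),  # head pursuit: eye below scaled low-eye threshold
    c(25, 18, 12)  # sp_vor: gaze, eye and head all moving
  )
  want <- c("fixation", "vor", "smooth_pursuit", "head_pursuit", "sp_vor")
  got <- classify_epoch(cases[, 1], cases[, 2], cases[, 3])
  expect_equal(got, want)
  # threshold equality resolves to the slower branch
  expect_equal(classify_epoch(10, 0, 0), "fixation")
  expect_equal(classify_epoch(25, 10, 0), "head_pursuit")
  expect_equal(classify_epoch(25, 25, 7), "smooth_pursuit")
})

test_that("full classification tiles the recording exactly once", {
  sim <- simulate_session(rbind(one_trial("static", "peripheral"),
                                one_trial("dynamic", "peripheral", 32)),
                          params = simulation_params(seed = 9))
  segs <- classify_recording(sim$recording)
  n <- nrow(sim$recording)
  cover <- integer(n)
  for (k in seq_len(nrow(segs)))
    cover[segs$i_start[k]:segs$i_end[k]] <-
      cover[segs$i_start[k]:segs$i_end[k]] + 1L
  expect_true(all(cover == 1L))
  expect_true(all(segs$label %in% c("saccade", "excluded_saccade",
                                    "fixation", "vor", "smooth_pursuit",
                                    "head_pursuit", "sp_vor", "noise",
                                    "unclassified")))
})

test_that("scripted sessions are classified as constructed", {
  # fixation-only: no saccades, every epoch fixation
  rec <- rec_from_angles(gaze_az = rep(0, 600))
  segs <- classify_recording(rec)
  expect_equal(sum(segs$label %in% c("saccade", "excluded_saccade")), 0)
  expect_true(all(segs$label == "fixation"))

  # ten injected >= 3 degree saccades are all found
  az <- numeric(0)
  for (k in 1:10) {
    prof <- sample_saccade_profile(8, simulation_params())
    step <- cumsum(prof) * attr(prof, "dt")
    lvl <- if (length(az)) az[length(az)] else 0
    az <- c(az, rep(lvl, 40), lvl + step * (-1)^k)
  }
  rec2 <- rec_from_angles(gaze_az = c(az, rep(az[length(az)], 40)))
  segs2 <- classify_recording(rec2)
  expect_equal(sum(segs2$label == "saccade"), 10)

  # VOR block: oscillating head with stabilised gaze
  rec3 <- vor_recording(duration = 4, head_amp = 25, freq = 0.6)
  segs3 <- classify_recording(rec3)
  ep <- segs3[!segs3$label %in% c("saccade", "excluded_saccade", "noise",
                                  "unclassified"), ]
  n_ep <- ep$i_end - ep$i_start + 1L
  expect_gte(sum(n_ep[ep$label == "vor"]) / sum(n_ep), 0.9)
})
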