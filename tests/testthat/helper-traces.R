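# Builders for analytic test traces. All recordings are constructed from
# scripted gaze/head angle trajectories so the expected kinematics are
# known in closed form.

FS <- 120

# recording from world gaze angles and head yaw/pitch (degrees); the
# eye-in-head direction is the inverse head rotation applied to gaze
rec_from_angles <- function(gaze_az, gaze_el = 0, head_az = 0, head_el = 0,
                            valid = TRUE, fs = FS) {
  n <- max(length(gaze_az), length(gaze_el), length(head_az),
           length(head_el))
  gaze_az <- rep_len(gaze_az, n); gaze_el <- rep_len(gaze_el, n)
  head_az <- rep_len(head_az, n); head_el <- rep_len(head_el, n)
  ga <- gaze_az * pi / 180; ge <- gaze_el * pi / 180
  gaze <- cbind(cos(ge) * sin(ga), sin(ge), cos(ge) * cos(ga))
  q <- quat_from_yaw_pitch(head_az, -head_el)
  eye <- quat_rotate(quat_conjugate(q), gaze)
  gaze_recording((seq_len(n) - 1) / fs, eye, q,
                 matrix(0, n, 3), valid = rep_len(valid, n))
}

# head oscillation with perfectly stabilised gaze (VOR signature)
vor_recording <- function(duration = 2, head_amp = 15, freq = 0.5,
                          fs = FS) {
  t <- seq(0, duration, by = 1 / fs)
  rec_from_angles(gaze_az = 0, head_az = head_amp * sin(2 * pi * freq * t),
                  fs = fs)
}

# speed series built directly (for detector tests that do not need a
# recording behind them)
speeds_from_values <- function(eye, head = 0, gaze = NULL, usable = TRUE,
                               fs = FS) {
  n <- length(eye)
  sp <- data.frame(t = (seq_len(n) - 1) / fs, eye_speed = eye,
                   head_speed = rep_len(head, n),
                   gaze_speed = rep_len(gaze %||% eye, n),
                   usable = rep_len(usable, n))
  class(sp) <- c("speed_series", "data.frame")
  sp
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force saccade oracle: explicit sample-by-sample run scan,
# independent of the rle-based implementation
oracle_saccades <- function(speeds, thr = threshold_set(),
                            min_duration = 0.020) {
  n <- nrow(speeds)
  dt <- 1 / FS
  above <- logical(n)
  for (i in seq_len(n)) {
    cut <- (1 + speeds$head_speed[i] / thr$scaling_denominator) *
      thr$theta_saccade
    above[i] <- speeds$usable[i] && speeds$eye_speed[i] > cut
  }
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if ((speeds$t[j] - speeds$t[i] + dt) >= min_duration - 1e-9)
        out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# one-trial schedule row for generator tests
one_trial <- function(motion = "static", eccentricity = "parafoveal",
                      cue_distance = if (motion == "dynamic") 32 else 13,
                      soa = 1.0, iti = 6.4, disk = 2) {
  data.frame(trial_id = 1L, block_id = 1L, motion = motion,
             eccentricity = eccentricity, cue_distance = cue_distance,
             cued_disk_index = disk, distractor_disk_index = (disk + 4) %% 8,
             soa = soa, target_dir = "left", iti = iti)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# an empty segment table (what detect_saccades returns on a quiet trace)
new_segments_for_test <- function() {
  detect_saccades(speeds_from_values(rep(0, 10)))
}

quiet_params <- function(...) {
  simulation_params(fixation_noise_sd = 0, dropout_rate = 0,
                    head_contribution = 0, ...)
}
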