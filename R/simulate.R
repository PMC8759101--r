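# Synthetic session generator: gaze recordings with per-sample kinematic
# ground truth for the cued visual-discrimination paradigm.
#
# Each trial is scripted in angular (azimuth/elevation) space: cross
# fixation, a cue-triggered saccade with main-sequence kinematics, target
# fixation (static trials) or velocity-gain pursuit of the approaching
# disk (dynamic trials), an optional head movement toward peripheral
# targets with compensatory VOR, a button response, and a return saccade
# to the cross. Head orientation is yaw/pitch; the eye-in-head direction
# is recovered exactly as the inverse head rotation applied to the gaze
# direction, so VOR falls out of the composition.

#' Simulation parameters
#'
#' @param sample_rate eye-tracker sampling rate, Hz.
#' @param saccade_latency_mean,saccade_latency_sd cue-to-saccade latency,
#'   seconds (normal, truncated to 0.1-0.35 s).
#' @param main_sequence_vmax,main_sequence_c main-sequence parameters:
#'   saccadic peak velocity is `vmax * (1 - exp(-A / c))` for amplitude
#'   `A` degrees (saturating exponential).
#' @param fixation_noise_sd fixational jitter magnitude, expressed as the
#'   mean eye speed it induces during fixation, deg/s. White angular noise
#'   low-passed near 20 Hz and rescaled to this speed.
#' @param pursuit_gain velocity gain of pursuit: gaze angular velocity is
#'   this fraction of the target's angular velocity.
#' @param vor_gain VOR gain; retinal slip during head movement is
#'   proportional to `(1 - vor_gain)` times head velocity.
#' @param head_contribution fraction of the gaze shift to peripheral
#'   targets carried by the head (parafoveal shifts leave the head still).
#' @param head_lag delay between peak saccadic eye speed and peak head
#'   speed, seconds.
#' @param head_duration duration of the minimum-jerk head rotation,
#'   seconds.
#' @param button_rt_mean,button_rt_sd button reaction time after target
#'   onset, seconds (normal, truncated to 0.3-0.9 s).
#' @param pre_cue cross-fixation time between trial start and cue onset,
#'   seconds.
#' @param dropout_rate expected fraction of invalid samples (dropped
#'   pupil frames), emulated as contiguous bursts.
#' @param pupil_mm constant simulated pupil diameter, millimetres.
#' @param seed integer seed governing all randomness in the generator.
#' @return a `simulation_params` (list).
#' @export
simulation_params <- function(sample_rate = 120,
                              saccade_latency_mean = 0.2,
                              saccade_latency_sd = 0.03,
                              main_sequence_vmax = 500,
                              main_sequence_c = 14,
                              fixation_noise_sd = 2,
                              pursuit_gain = 0.95,
                              vor_gain = 0.95,
                              head_contribution = 0.3,
                              head_lag = 0.2,
                              head_duration = 0.5,
                              button_rt_mean = 0.55,
                              button_rt_sd = 0.08,
                              pre_cue = 0.2,
                              dropout_rate = 0.06,
                              pupil_mm = 3.5,
                              seed = 1L) {
  if (sample_rate <= 0) stop_data("sample_rate must be positive")
  rates <- c(pursuit_gain, vor_gain, head_contribution, dropout_rate)
  if (any(rates < 0 | rates > 1)) stop_data("gains and rates must lie in [0, 1]")
  structure(as.list(environment()), class = "simulation_params")
}

#' Main-sequence saccade velocity profile
#'
#' Raised-cosine velocity waveform sampled at the tracker rate. Peak
#' velocity follows the saturating main sequence
#' `vmax * (1 - exp(-A / c))`; duration is `2 A / peak`, which stays above
#' 20 ms for all amplitudes; the discrete integral of the waveform equals
#' the amplitude (midpoint sampling of the raised cosine integrates
#' exactly).
#'
#' @param amplitude saccade amplitude, degrees (> 0).
#' @param params a [simulation_params()].
#' @return numeric vector of per-sample velocities, deg/s, with
#'   attributes `peak` (closed-form peak velocity, deg/s), `duration`
#'   (seconds) and `dt` (sample spacing of the waveform, seconds).
#' @export
sample_saccade_profile <- function(amplitude, params = simulation_params()) {
  if (amplitude <= 0) stop_data("amplitude must be positive")
  vp <- params$main_sequence_vmax *
    (1 - exp(-amplitude / params$main_sequence_c))
  dur <- 2 * amplitude / vp
  m <- max(3L, round(dur * params$sample_rate))
  dtm <- dur / m
  tt <- (seq_len(m) - 0.5) * dtm
  v <- vp / 2 * (1 - cos(2 * pi * tt / dur))
  structure(v, peak = vp, duration = dur, dt = dtm)
}

#' Emulate tracker dropout as contiguous invalid bursts
#'
#' Burst onsets are Bernoulli per sample with probability
#' `1 - (1 - rate)^(1/3)`; burst lengths are geometric with mean 3
#' samples, mimicking short dropped-pupil episodes. The expected invalid
#' fraction equals `rate` (to first order in the burst overlap).
#'
#' @param valid logical vector of current validity flags.
#' @param rate target invalid fraction in \[0, 1\].
#' @return logical vector with bursts cleared.
#' @export
add_dropout <- function(valid, rate) {
  if (rate < 0 || rate > 1) stop_data("rate must lie in [0, 1]")
  n <- length(valid)
  if (rate == 0 || n == 0) return(valid)
  if (rate == 1) return(rep(FALSE, n))
  p <- 1 - (1 - rate)^(1 / 3)
  starts <- which(runif(n) < p)
  lens <- stats::rgeom(length(starts), 1 / 3) + 1L
  for (k in seq_along(starts)) {
    hi <- min(n, starts[k] + lens[k] - 1L)
    valid[starts[k]:hi] <- FALSE
  }
  valid
}

#' Per-sample kinematic classification
#'
#' The decision rules of the epoch classifier applied at sample
#' resolution: `saccade` where eye speed exceeds the head-speed-scaled
#' saccade threshold, otherwise the [classify_epoch()] tree on the
#' instantaneous speeds. The generator uses this on its noiseless speed
#' traces to produce ground-truth labels.
#'
#' @param gaze_speed,eye_speed,head_speed instantaneous speeds, deg/s
#'   (vectorised).
#' @param thr a [threshold_set()].
#' @return character vector of labels.
#' @export
classify_samples <- function(gaze_speed, eye_speed, head_speed,
                             thr = threshold_set()) {
  sac <- eye_speed > scale_threshold(head_speed, thr$theta_saccade,
                                     thr$scaling_denominator)
  out <- classify_epoch(gaze_speed, eye_speed, head_speed, thr)
  out[sac] <- "saccade"
  out
}

# direction <-> angle helpers (degrees; left-handed y-up z-forward)
dirs_from_angles <- function(az, el) {
  az <- az * pi / 180; el <- el * pi / 180
  cbind(cos(el) * sin(az), sin(el), cos(el) * cos(az))
}
angles_from_dirs <- function(d) {
  cbind(az = atan2(d[, 1], d[, 3]) * 180 / pi,
        el = asin(clamp1(d[, 2])) * 180 / pi)
}
minjerk <- function(f) 10 * f^3 - 15 * f^4 + 6 * f^5

# great-circle interpolation from u0 toward u1 by fractions f
slerp_rows <- function(u0, u1, f) {
  om <- acos(clamp1(sum(u0 * u1)))
  if (om < 1e-12) return(matrix(rep(u1, each = length(f)), ncol = 3))
  (sin((1 - f) * om) %o% u0 + sin(f * om) %o% u1) / sin(om)
}

trunc_norm <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, rnorm(n, mean, sd)))

disk_label <- function(ring, index) sprintf("disk:%s:%d", ring, index)

# Script one trial in angle space. Returns per-sample gaze/head angles,
# ground-truth object, scripted saccade mask and relative event times.
script_trial <- function(trial, layout, params) {
  fs <- params$sample_rate
  n <- as.integer(round(trial$iti * fs))
  t_rel <- (seq_len(n) - 1) / fs - params$pre_cue
  pos <- disk_position(layout, trial$eccentricity, trial$cued_disk_index,
                       trial$cue_distance, t_rel, trial$motion)
  horiz <- sqrt(pos[, 1]^2 + pos[, 3]^2)
  daz <- atan2(pos[, 1], pos[, 3]) * 180 / pi
  del <- atan2(pos[, 2], horiz) * 180 / pi

  lat <- trunc_norm(1, params$saccade_latency_mean,
                    params$saccade_latency_sd, 0.10, 0.35)
  bt_rt <- trunc_norm(1, params$button_rt_mean, params$button_rt_sd,
                      0.30, 0.90)
  i_sac <- which(t_rel >= lat)[1]

  gaze_az <- numeric(n); gaze_el <- numeric(n)
  in_sacc <- rep(FALSE, n)
  obj <- rep("cross", n)

  # primary saccade: cross -> disk position at landing
  d0 <- c(0, 0, 1)
  a_land_guess <- i_sac
  d1 <- dirs_from_angles(daz[a_land_guess], del[a_land_guess])[1, ]
  amp1 <- acos(clamp1(sum(d0 * d1))) * 180 / pi
  prof1 <- sample_saccade_profile(amp1, params)
  m1 <- min(length(prof1), n - i_sac)
  frac1 <- cumsum(prof1 * attr(prof1, "dt"))[seq_len(m1)] / amp1
  sac1 <- i_sac:(i_sac + m1 - 1L)
  ang1 <- angles_from_dirs(slerp_rows(d0, d1, frac1))
  gaze_az[sac1] <- ang1[, 1]; gaze_el[sac1] <- ang1[, 2]
  in_sacc[sac1] <- TRUE
  obj[sac1] <- "background"
  i_land <- i_sac + m1

  # disengagement: static trials leave shortly after the button press;
  # dynamic trials track the approaching disk before returning
  t_leave <- if (trial$motion == "dynamic") {
    min(5.2, trial$iti - 0.8)
  } else {
    min(max(trial$soa + bt_rt + 0.15, trial$soa + 0.25),
        trial$iti - params$pre_cue - 0.6)
  }
  i_leave <- max(which(t_rel >= t_leave)[1], i_land + 2L)

  # tracking phase: static fixation or velocity-gain pursuit
  trk <- i_land:(i_leave - 1L)
  if (trial$motion == "dynamic") {
    g <- params$pursuit_gain
    gaze_az[trk] <- daz[i_land] + g * (daz[trk] - daz[i_land])
    gaze_el[trk] <- del[i_land] + g * (del[trk] - del[i_land])
  } else {
    gaze_az[trk] <- daz[trk]
    gaze_el[trk] <- del[trk]
  }
  obj[trk] <- disk_label(trial$eccentricity, trial$cued_disk_index)

  # return saccade to the cross
  d2 <- dirs_from_angles(gaze_az[i_leave - 1L], gaze_el[i_leave - 1L])[1, ]
  amp2 <- acos(clamp1(sum(d2 * c(0, 0, 1)))) * 180 / pi
  if (amp2 > 0.5 && i_leave < n) {
    prof2 <- sample_saccade_profile(amp2, params)
    m2 <- min(length(prof2), n - i_leave)
    frac2 <- cumsum(prof2 * attr(prof2, "dt"))[seq_len(m2)] / amp2
    sac2 <- i_leave:(i_leave + m2 - 1L)
    ang2 <- angles_from_dirs(slerp_rows(d2, c(0, 0, 1), frac2))
    gaze_az[sac2] <- ang2[, 1]; gaze_el[sac2] <- ang2[, 2]
    in_sacc[sac2] <- TRUE
    obj[sac2] <- "background"
  }

  # head contribution for peripheral targets: minimum-jerk rotation whose
  # speed peaks head_lag after the saccadic peak, then a return rotation
  head_az <- numeric(n); head_el <- numeric(n)
  if (trial$eccentricity == "peripheral" && params$head_contribution > 0) {
    hc <- params$head_contribution
    th <- params$head_duration
    h_az <- hc * daz[i_land]; h_el <- hc * del[i_land]
    t_h0 <- lat + (m1 / fs) / 2 + params$head_lag - th / 2
    fr <- pmin(1, pmax(0, (t_rel - t_h0) / th))
    fwd <- minjerk(fr)
    frb <- pmin(1, pmax(0, (t_rel - t_leave) / th))
    back <- 1 - minjerk(frb)
    head_az <- h_az * fwd * back
    head_el <- h_el * fwd * back
  }

  list(n = n, t_rel = t_rel, gaze_az = gaze_az, gaze_el = gaze_el,
       head_az = head_az, head_el = head_el, in_sacc = in_sacc, obj = obj,
       lat = lat, bt_rt = bt_rt, t_leave = t_leave)
}

#' Simulate a full session
#'
#' Generates a gaze recording, event log and per-sample ground truth for
#' a trial schedule. All randomness flows from `params$seed`: identical
#' parameters give identical sessions. Ground-truth labels are kinematic:
#' the noiseless generated speed traces passed through
#' [classify_samples()] at sample resolution, so a label is what an ideal
#' classifier with the same decision boundaries would produce given the
#' intended movement (slow pursuit of a parafoveal dynamic target is
#' therefore truly near-fixation; whether it is *on a moving object* is
#' tracked separately in the `object` column).
#'
#' @param schedule a `trial_schedule` from [build_schedule()], or any
#'   data frame of trials with the same columns (subsets are fine for
#'   smaller sessions).
#' @param layout a [world_layout()].
#' @param params a [simulation_params()].
#' @return list with elements `recording` ([gaze_recording()]), `events`
#'   ([event_log()] with an extra `cued_disk_index` column), `truth`
#'   (data frame `t, label, object`) and `trials` (the schedule with
#'   absolute cue times and window bounds).
#' @export
simulate_session <- function(schedule, layout = world_layout(),
                             params = simulation_params()) {
  fs <- params$sample_rate
  with_seed(params$seed, {
    scripts <- lapply(seq_len(nrow(schedule)), function(i)
      script_trial(schedule[i, ], layout, params))
    n_i <- vapply(scripts, `[[`, integer(1), "n")
    offs <- cumsum(c(0L, n_i[-length(n_i)]))
    N <- sum(n_i)
    t <- (seq_len(N) - 1) / fs
    gaze_az <- unlist(lapply(scripts, `[[`, "gaze_az"))
    gaze_el <- unlist(lapply(scripts, `[[`, "gaze_el"))
    head_az <- unlist(lapply(scripts, `[[`, "head_az"))
    head_el <- unlist(lapply(scripts, `[[`, "head_el"))
    in_sacc <- unlist(lapply(scripts, `[[`, "in_sacc"))
    obj <- unlist(lapply(scripts, `[[`, "obj"))

    # imperfect VOR: retinal slip proportional to head velocity
    if (params$vor_gain < 1) {
      slip <- (1 - params$vor_gain) * 0.05 * fs
      dv_az <- c(0, diff(head_az)); dv_el <- c(0, diff(head_el))
      gaze_az <- gaze_az + ifelse(in_sacc, 0, slip * dv_az)
      gaze_el <- gaze_el + ifelse(in_sacc, 0, slip * dv_el)
    }

    gaze_dir <- dirs_from_angles(gaze_az, gaze_el)
    head_q <- quat_from_yaw_pitch(head_az, -head_el)
    eye_dir <- quat_rotate(quat_conjugate(head_q), gaze_dir)

    # ground truth from the noiseless kinematics
    eye_v <- angular_speed(eye_dir, t)
    head_v <- head_angular_speed(head_q, t)
    gaze_v <- angular_speed(gaze_dir, t)
    truth_label <- classify_samples(gaze_v, eye_v, head_v)
    truth <- data.frame(t = t, label = truth_label, object = obj)
    class(truth) <- c("gaze_truth", "data.frame")

    # fixational noise on the eye-in-head direction (low-passed white
    # angular jitter, rescaled to the requested fixation eye speed)
    if (params$fixation_noise_sd > 0) {
      sm <- function(x) {
        y <- stats::filter(x, rep(1 / 6, 6), sides = 2)
        y[is.na(y)] <- 0
        as.numeric(y)
      }
      n_az <- sm(rnorm(N)); n_el <- sm(rnorm(N))
      spd <- sqrt(diff(n_az)^2 + diff(n_el)^2) * fs
      sc <- params$fixation_noise_sd / mean(spd)
      ea <- angles_from_dirs(eye_dir)
      eye_dir <- dirs_from_angles(ea[, 1] + sc * n_az, ea[, 2] + sc * n_el)
    }

    valid <- add_dropout(rep(TRUE, N), params$dropout_rate)

    # head position: forward ego-motion during dynamic trials
    dyn <- rep(schedule$motion == "dynamic", n_i)
    pos_z <- cumsum(ifelse(dyn, layout$observer_speed / fs, 0))
    head_pos <- cbind(0, layout$eye_height, pos_z)

    rec <- gaze_recording(t, eye_dir, head_q, head_pos, valid = valid,
                          pupil_mm = rep(params$pupil_mm, N))

    cue_t <- t[offs + 1L] + params$pre_cue
    ev <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
      tr <- schedule[i, ]
      s <- scripts[[i]]
      data.frame(
        t = cue_t[i] + c(-params$pre_cue, 0, tr$soa, tr$soa + s$bt_rt),
        kind = c("trial_start", "cue_onset", "target_onset", "response"),
        trial_id = tr$trial_id,
        condition_motion = tr$motion,
        condition_eccentricity = tr$eccentricity,
        cue_distance_m = tr$cue_distance,
        target_dir = tr$target_dir,
        response_side = c(NA, NA, NA, tr$target_dir),
        cued_disk_index = tr$cued_disk_index
      )
    }))
    events <- event_log(ev$t, ev$kind, ev$trial_id, ev$condition_motion,
                        ev$condition_eccentricity, ev$cue_distance_m,
                        ev$target_dir, ev$response_side)
    events$cued_disk_index <- ev$cued_disk_index

    trials <- as.data.frame(schedule)
    trials$cue_time <- cue_t
    trials$target_time <- cue_t + schedule$soa
    trials$t_start <- t[offs + 1L]
    trials$t_end <- trials$t_start + n_i / fs
    trials$i_start <- offs + 1L
    trials$i_end <- offs + n_i
    # scripted kinematic parameters, exposed as ground truth
    trials$saccade_latency <- vapply(scripts, `[[`, numeric(1), "lat")
    trials$button_rt <- vapply(scripts, `[[`, numeric(1), "bt_rt")
    trials$t_leave <- vapply(scripts, `[[`, numeric(1), "t_leave")

    list(recording = rec, events = events, truth = truth, trials = trials)
  })
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_session()] for a one-trial
#' schedule.
#'
#' @param trial one row of a `trial_schedule` (or an equivalent list with
#'   fields `trial_id, motion, eccentricity, cue_distance,
#'   cued_disk_index, soa, target_dir, iti`).
#' @param layout a [world_layout()].
#' @param params a [simulation_params()].
#' @return as [simulate_session()].
#' @export
simulate_trial <- function(trial, layout = world_layout(),
                           params = simulation_params()) {
  simulate_session(as.data.frame(as.list(trial)), layout, params)
}
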