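# Head-speed-scaled saccade detection and 100 ms intersaccadic epoch
# classification.
#
# Saccade detection runs first: eye speed is compared against a threshold
# scaled by the instantaneous head speed. The intervals between saccades
# are then cut into 100 ms epochs and each epoch is labelled from its mean
# gaze, eye and head speeds via a fixed decision tree.

SEGMENT_LABELS <- c("saccade", "excluded_saccade", "fixation", "vor",
                    "smooth_pursuit", "head_pursuit", "sp_vor", "noise",
                    "unclassified")

#' Scale a base threshold by head speed
#'
#' `threshold_scaled = (1 + v_head / 60) * threshold`: when the head is
#' stationary the base (stationary-head) threshold applies; a head turning
#' at 60 deg/s doubles it. Applies to the saccade, low-gaze and low-eye
#' thresholds; the head threshold itself is never scaled.
#'
#' @param v_head head speed, deg/s (vectorised; must be non-negative).
#' @param base base threshold, deg/s.
#' @param denominator scaling denominator, deg/s.
#' @return scaled threshold(s), deg/s.
#' @export
scale_threshold <- function(v_head, base, denominator = 60) {
  if (any(v_head < 0)) stop_data("v_head must be non-negative")
  (1 + v_head / denominator) * base
}

new_segments <- function(i_start = integer(), i_end = integer(),
                         t_start = numeric(), t_end = numeric(),
                         label = character(), amplitude = NA_real_,
                         peak_velocity = NA_real_,
                         mean_eye_speed = NA_real_,
                         mean_head_speed = NA_real_,
                         mean_gaze_speed = NA_real_) {
  m <- length(i_start)
  df <- data.frame(i_start = as.integer(i_start), i_end = as.integer(i_end),
                   t_start = t_start, t_end = t_end, label = label,
                   amplitude = rep_len(amplitude, m),
                   peak_velocity = rep_len(peak_velocity, m),
                   mean_eye_speed = rep_len(mean_eye_speed, m),
                   mean_head_speed = rep_len(mean_head_speed, m),
                   mean_gaze_speed = rep_len(mean_gaze_speed, m))
  class(df) <- c("gaze_segments", "data.frame")
  df
}

#' Detect saccades with a head-speed-scaled velocity threshold
#'
#' The label saccade applies to every maximal contiguous run of usable
#' samples whose (median-filtered) eye speed strictly exceeds
#' `scale_threshold(head_speed, theta_saccade)` at that sample, kept only
#' if the run lasts at least `min_duration` (20 ms). Runs broken by
#' unusable samples are never bridged. A sample's duration contribution is
#' one nominal sampling interval, so at 120 Hz a 3-sample run counts as
#' 25 ms.
#'
#' @param speeds a `speed_series` from [compute_speeds()].
#' @param thr a [threshold_set()].
#' @param min_duration minimum saccade duration, seconds.
#' @return a `gaze_segments` data frame with `label = "saccade"` rows.
#' @export
detect_saccades <- function(speeds, thr = threshold_set(),
                            min_duration = 0.020) {
  n <- nrow(speeds)
  if (n == 0) return(new_segments())
  cut <- scale_threshold(speeds$head_speed, thr$theta_saccade,
                         thr$scaling_denominator)
  above <- speeds$usable & speeds$eye_speed > cut
  runs <- true_runs(above)
  if (!nrow(runs)) return(new_segments())
  dt <- 1 / sampling_rate(speeds$t)
  dur <- speeds$t[runs[, 2]] - speeds$t[runs[, 1]] + dt
  keep <- dur >= min_duration - 1e-9
  runs <- runs[keep, , drop = FALSE]
  new_segments(runs[, 1], runs[, 2],
               speeds$t[runs[, 1]], speeds$t[runs[, 2]],
               rep("saccade", nrow(runs)))
}

#' Amplitude and peak velocity of detected saccades
#'
#' Amplitude is the angle between the world-frame gaze directions
#' bracketing the segment (one usable sample before its first and after
#' its last, where available): the detected run covers only the
#' above-threshold part of the movement, so the bracketing samples
#' recover the sub-threshold onset and offset of the gaze shift, which
#' is what the amplitude exclusion targets. Peak velocity is the maximum
#' filtered eye speed within the segment.
#'
#' @param segs `gaze_segments` from [detect_saccades()].
#' @param rec the source [gaze_recording()].
#' @param speeds the matching `speed_series`.
#' @return `segs` with `amplitude` and `peak_velocity` filled in.
#' @export
saccade_metrics <- function(segs, rec, speeds) {
  if (!nrow(segs)) return(segs)
  gaze <- gaze_direction(eye_matrix(rec), quat_matrix(rec))
  n <- nrow(rec)
  lo <- segs$i_start - 1L
  lo <- ifelse(lo >= 1L & speeds$usable[pmax(lo, 1L)], lo, segs$i_start)
  hi <- segs$i_end + 1L
  hi <- ifelse(hi <= n & speeds$usable[pmin(hi, n)], hi, segs$i_end)
  segs$amplitude <- angle_between_deg(gaze[lo, , drop = FALSE],
                                      gaze[hi, , drop = FALSE])
  segs$peak_velocity <- vapply(seq_len(nrow(segs)), function(k) {
    max(speeds$eye_speed[segs$i_start[k]:segs$i_end[k]])
  }, numeric(1))
  segs
}

#' Exclude implausible saccades
#'
#' Only saccades strictly over `min_amplitude` (3 degrees, excluding
#' small movements around the fixation cross) with peak velocity
#' strictly under `max_peak_velocity` (1000 deg/s, excluding improbable
#' eye movements) are retained as `saccade`; the rest are relabelled
#' `excluded_saccade`
#' and kept (they still delimit intersaccadic intervals, but are excluded
#' from analysis).
#'
#' @param segs `gaze_segments` with metrics from [saccade_metrics()].
#' @param min_amplitude degrees.
#' @param max_peak_velocity deg/s.
#' @return `segs` with labels updated; nothing deleted.
#' @export
filter_saccades <- function(segs, min_amplitude = 3,
                            max_peak_velocity = 1000) {
  sac <- segs$label %in% c("saccade", "excluded_saccade")
  excl <- sac & (segs$amplitude <= min_amplitude |
                   segs$peak_velocity >= max_peak_velocity)
  segs$label[sac] <- ifelse(excl[sac], "excluded_saccade", "saccade")
  segs
}

#' Partition intersaccadic intervals into 100 ms epochs
#'
#' Each maximal run of usable, non-saccade samples (between saccade
#' segments and recording edges) is tiled left to right with
#' `epoch_length` windows. A trailing remainder of at least half an epoch
#' becomes its own short epoch; a smaller remainder is merged into the
#' preceding epoch; an interval shorter than half an epoch with no
#' preceding epoch is labelled `unclassified`.
#'
#' @param segs `gaze_segments` containing the detected saccades.
#' @param speeds the `speed_series` (for the usable mask and timestamps).
#' @param epoch_length seconds.
#' @return a `gaze_segments` data frame of epoch windows with empty labels
#'   (`""`) for classifiable epochs and `"unclassified"` for fragments.
#' @export
partition_intersaccadic <- function(segs, speeds, epoch_length = 0.100) {
  n <- nrow(speeds)
  in_sacc <- rep(FALSE, n)
  sac <- segs[segs$label %in% c("saccade", "excluded_saccade"), ,
              drop = FALSE]
  for (k in seq_len(nrow(sac))) in_sacc[sac$i_start[k]:sac$i_end[k]] <- TRUE
  free <- speeds$usable & !in_sacc
  runs <- true_runs(free)
  fs <- sampling_rate(speeds$t)
  n_full <- max(1L, round(epoch_length * fs))
  n_min <- ceiling(n_full / 2)
  out <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    len <- runs[k, 2] - runs[k, 1] + 1L
    if (len < n_min) {
      out[[k]] <- new_segments(runs[k, 1], runs[k, 2],
                               speeds$t[runs[k, 1]], speeds$t[runs[k, 2]],
                               "unclassified")
      next
    }
    n_ep <- len %/% n_full
    rem <- len - n_ep * n_full
    sizes <- rep(n_full, n_ep)
    if (rem >= n_min) sizes <- c(sizes, rem)
    else if (rem > 0) sizes[length(sizes)] <- sizes[length(sizes)] + rem
    ends <- runs[k, 1] - 1L + cumsum(sizes)
    starts <- ends - sizes + 1L
    out[[k]] <- new_segments(starts, ends, speeds$t[starts], speeds$t[ends],
                             rep("", length(sizes)))
  }
  do.call(rbind, c(list(new_segments()), out))
}

#' Classify one intersaccadic epoch from its mean speeds
#'
#' Decision tree (all arguments vectorised):
#' if mean gaze speed is at or below the scaled low-gaze threshold the
#' gaze is stationary -- `fixation` if the head is at or below the head
#' threshold, else `vor`. If gaze is moving: `head_pursuit` if eye speed
#' is at or below the scaled low-eye threshold, else `smooth_pursuit` if
#' the head is at or below the head threshold, else `sp_vor` (smooth
#' pursuit with compensatory VOR). Exact threshold equality resolves to
#' the slower branch. Thresholds scale with the epoch's mean head speed.
#'
#' @param mean_gaze,mean_eye,mean_head epoch-mean speeds, deg/s.
#' @param thr a [threshold_set()].
#' @return character vector of labels.
#' @export
classify_epoch <- function(mean_gaze, mean_eye, mean_head,
                           thr = threshold_set()) {
  lowgaze <- scale_threshold(mean_head, thr$theta_lowgaze,
                             thr$scaling_denominator)
  loweye <- scale_threshold(mean_head, thr$theta_loweye,
                            thr$scaling_denominator)
  head_still <- mean_head <= thr$theta_head
  ifelse(mean_gaze <= lowgaze,
         ifelse(head_still, "fixation", "vor"),
         ifelse(mean_eye <= loweye, "head_pursuit",
                ifelse(head_still, "smooth_pursuit", "sp_vor")))
}

#' Classify a full recording
#'
#' Runs the complete pipeline: dropout masking, speed computation and
#' median filtering, saccade detection, amplitude/peak-velocity exclusion,
#' intersaccadic epoch partitioning and epoch classification. Unusable
#' stretches are labelled `noise`. The returned segments tile the
#' recording: every sample belongs to exactly one segment.
#'
#' @param rec a [gaze_recording()].
#' @param cfg a [pipeline_config()].
#' @param speeds optionally, a precomputed `speed_series` for `rec`.
#' @return a `gaze_segments` data frame ordered by time, with per-epoch
#'   mean speeds and per-saccade amplitude and peak velocity.
#' @export
classify_recording <- function(rec, cfg = pipeline_config(), speeds = NULL) {
  if (nrow(rec) < 2) stop_data("recording must have at least 2 samples")
  if (is.null(speeds)) speeds <- compute_speeds(rec, cfg)
  sac <- detect_saccades(speeds, cfg$thresholds, cfg$min_saccade_duration)
  sac <- saccade_metrics(sac, rec, speeds)
  sac <- filter_saccades(sac, cfg$min_amplitude, cfg$max_peak_velocity)
  ep <- partition_intersaccadic(sac, speeds, cfg$epoch_length)
  # epoch statistics via prefix sums (fast for long sessions)
  cs_eye <- c(0, cumsum(speeds$eye_speed))
  cs_head <- c(0, cumsum(speeds$head_speed))
  cs_gaze <- c(0, cumsum(speeds$gaze_speed))
  len <- ep$i_end - ep$i_start + 1L
  ep$mean_eye_speed <- (cs_eye[ep$i_end + 1L] - cs_eye[ep$i_start]) / len
  ep$mean_head_speed <- (cs_head[ep$i_end + 1L] - cs_head[ep$i_start]) / len
  ep$mean_gaze_speed <- (cs_gaze[ep$i_end + 1L] - cs_gaze[ep$i_start]) / len
  classifiable <- ep$label == ""
  ep$label[classifiable] <- classify_epoch(
    ep$mean_gaze_speed[classifiable], ep$mean_eye_speed[classifiable],
    ep$mean_head_speed[classifiable], cfg$thresholds)
  # noise segments: maximal unusable runs
  noise_runs <- true_runs(!speeds$usable)
  noise <- new_segments(noise_runs[, 1], noise_runs[, 2],
                        speeds$t[noise_runs[, 1]],
                        speeds$t[noise_runs[, 2]],
                        rep("noise", nrow(noise_runs)))
  segs <- rbind(sac, ep, noise)
  segs <- segs[order(segs$i_start), ]
  rownames(segs) <- NULL
  class(segs) <- c("gaze_segments", "data.frame")
  segs
}

#' Per-sample labels from a segment table
#'
#' Expands segments back to one label per sample (`unclassified` for any
#' sample not covered, which does not occur for [classify_recording()]
#' output).
#'
#' @param segs a `gaze_segments` data frame.
#' @param n number of samples in the source recording.
#' @return character vector of length `n`.
#' @export
segment_labels <- function(segs, n) {
  lab <- rep("unclassified", n)
  for (k in seq_len(nrow(segs)))
    lab[segs$i_start[k]:segs$i_end[k]] <- segs$label[k]
  lab
}

#' Write a segment table to CSV
#' @param segs a `gaze_segments` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  write.csv(as.data.frame(segs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
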