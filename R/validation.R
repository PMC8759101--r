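# Validation and behavioural summaries: pursuit misclassification rates
# against ray-cast ground truth, on-target gaze speed, main-sequence
# statistics, reaction times and data-quality measures.

PURSUIT_LABELS <- c("smooth_pursuit", "sp_vor", "head_pursuit")

pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Validate pursuit classification against ray-cast ground truth
#'
#' Joins per-sample classifier labels with the ray-cast foveated-object
#' labels. Reports the percentage of on-object usable samples labelled
#' as pursuit (smooth pursuit, smooth pursuit with compensatory VOR, or
#' head pursuit; per-label breakdown included) separately for stationary
#' objects (the cross, and disks in static trials) and moving objects
#' (disks in dynamic trials), with a moving-object breakdown by
#' eccentricity. Pursuit labels on stationary objects are
#' misclassifications; on moving objects they are expected. Samples
#' labelled noise or unclassified are excluded. Categories with no
#' samples are reported as `NA`, never 0.
#'
#' @param segments `gaze_segments` from [classify_recording()].
#' @param raycast a `raycast_series` from [raycast_series()].
#' @param trials trial table (see [raycast_series()]).
#' @param truth optional ground-truth data frame (`label` per sample);
#'   adds a label confusion table.
#' @return a `validation_report` (list).
#' @export
pursuit_validation <- function(segments, raycast, trials, truth = NULL) {
  n <- nrow(raycast)
  pred <- segment_labels(segments, n)
  scored <- !pred %in% c("noise", "unclassified")
  trial_motion <- rep(NA_character_, n)
  for (i in seq_len(nrow(trials)))
    trial_motion[trials$i_start[i]:trials$i_end[i]] <- trials$motion[i]
  obj <- raycast$object
  known <- !is.na(obj)
  on_disk <- known & startsWith(obj, "disk:")
  on_static <- scored & known & (obj %in% "cross" |
                                   (on_disk & trial_motion == "static"))
  on_moving <- scored & on_disk & trial_motion == "dynamic"
  is_pursuit <- pred %in% PURSUIT_LABELS

  breakdown <- function(mask) {
    c(pursuit = pct(sum(mask & is_pursuit), sum(mask)),
      smooth_pursuit = pct(sum(mask & pred == "smooth_pursuit"), sum(mask)),
      sp_vor = pct(sum(mask & pred == "sp_vor"), sum(mask)),
      head_pursuit = pct(sum(mask & pred == "head_pursuit"), sum(mask)),
      n = sum(mask))
  }
  ecc <- sub("^disk:([a-z]+):.*$", "\\1", raycast$object)
  rep_out <- list(
    pct_pursuit_on_static = pct(sum(on_static & is_pursuit), sum(on_static)),
    pct_pursuit_on_moving = pct(sum(on_moving & is_pursuit), sum(on_moving)),
    static = breakdown(on_static),
    moving = breakdown(on_moving),
    moving_parafoveal = breakdown(on_moving & ecc == "parafoveal"),
    moving_peripheral = breakdown(on_moving & ecc == "peripheral")
  )
  if (!is.null(truth)) {
    tl <- if (is.data.frame(truth)) truth$label else truth
    rep_out$confusion <- table(truth = tl[scored], predicted = pred[scored])
  }
  structure(rep_out, class = "validation_report")
}

#' Per-sample label agreement with ground truth
#'
#' Fraction of samples on which the classifier label equals the
#' ground-truth label, over samples the classifier actually labelled
#' (noise and unclassified excluded; a classifier cannot be scored on
#' samples it is required to discard).
#'
#' @param truth ground-truth data frame or label vector.
#' @param segments `gaze_segments` from [classify_recording()].
#' @param collapse_excluded treat `excluded_saccade` as `saccade` when
#'   comparing (the distinction is an analysis exclusion, not a
#'   kinematic class).
#' @return agreement fraction in \[0, 1\].
#' @export
label_agreement <- function(truth, segments, collapse_excluded = TRUE) {
  tl <- if (is.data.frame(truth)) truth$label else truth
  pred <- segment_labels(segments, length(tl))
  if (collapse_excluded) pred[pred == "excluded_saccade"] <- "saccade"
  keep <- !pred %in% c("noise", "unclassified")
  mean(pred[keep] == tl[keep])
}

#' Ground-truth saccade events from per-sample labels
#'
#' Contiguous runs of ground-truth `saccade` samples, with amplitude
#' measured like [saccade_metrics()] (world-frame gaze rotation across
#' the run).
#'
#' @param truth ground-truth data frame or label vector.
#' @param rec the source [gaze_recording()] (noiseless or recorded; used
#'   for amplitudes).
#' @return data frame `i_start, i_end, amplitude`.
#' @export
truth_saccades <- function(truth, rec) {
  tl <- if (is.data.frame(truth)) truth$label else truth
  runs <- true_runs(tl == "saccade")
  gaze <- gaze_direction(eye_matrix(rec), quat_matrix(rec))
  data.frame(
    i_start = runs[, 1], i_end = runs[, 2],
    amplitude = angle_between_deg(gaze[runs[, 1], , drop = FALSE],
                                  gaze[runs[, 2], , drop = FALSE])
  )
}

#' Saccade recovery rate against ground truth
#'
#' A true saccade counts as recovered when any detected saccade segment
#' (included or amplitude/velocity-excluded) overlaps it. By default
#' only true saccades whose samples are all usable are scored: a saccade
#' coinciding with a tracking dropout is unrecoverable in principle,
#' since detection never bridges unusable samples. Set
#' `require_usable = FALSE` for the unconditioned rate.
#'
#' @param truth ground-truth data frame or label vector.
#' @param segments `gaze_segments` from [classify_recording()].
#' @param rec the source recording.
#' @param speeds the `speed_series` (for the usable mask).
#' @param min_amplitude score only true saccades at least this large,
#'   degrees.
#' @param require_usable condition on fully usable true saccades.
#' @return list: `rate` (fraction recovered), `n_scored`, `n_total`.
#' @export
saccade_recovery <- function(truth, segments, rec, speeds,
                             min_amplitude = 3, require_usable = TRUE) {
  ts <- truth_saccades(truth, rec)
  ts <- ts[ts$amplitude >= min_amplitude, , drop = FALSE]
  n_total <- nrow(ts)
  if (require_usable && n_total) {
    ok <- vapply(seq_len(n_total), function(k)
      all(speeds$usable[ts$i_start[k]:ts$i_end[k]]), logical(1))
    ts <- ts[ok, , drop = FALSE]
  }
  det <- segments[segments$label %in% c("saccade", "excluded_saccade"), ]
  hit <- vapply(seq_len(nrow(ts)), function(k)
    any(det$i_start <= ts$i_end[k] & det$i_end >= ts$i_start[k]),
    logical(1))
  list(rate = if (nrow(ts)) mean(hit) else NA_real_,
       n_scored = nrow(ts), n_total = n_total)
}

#' Mean gaze speed over the on-target intersaccadic interval
#'
#' For each trial, selects the longest intersaccadic interval (between
#' detected saccade segments and trial-window edges) whose modal
#' ray-cast label is the cued disk, and averages gaze speed over its
#' usable samples after removing samples whose eye speed exceeds the
#' exclusion cutoff (suppressing catch-up saccade remnants). Trials
#' without such an interval get `NA`.
#'
#' @param segments `gaze_segments` from [classify_recording()].
#' @param raycast a `raycast_series`.
#' @param speeds the `speed_series`.
#' @param trials trial table (see [raycast_series()]).
#' @param exclusion eye-speed cutoff, deg/s.
#' @return data frame: `trial_id, motion, eccentricity,
#'   mean_gaze_speed, interval_duration`.
#' @export
target_interval_gaze_speed <- function(segments, raycast, speeds, trials,
                                       exclusion = 20) {
  n <- nrow(speeds)
  in_sacc <- rep(FALSE, n)
  det <- segments[segments$label %in% c("saccade", "excluded_saccade"), ]
  for (k in seq_len(nrow(det))) in_sacc[det$i_start[k]:det$i_end[k]] <- TRUE
  out <- trials[, c("trial_id", "motion", "eccentricity")]
  out$mean_gaze_speed <- NA_real_
  out$interval_duration <- NA_real_
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    target <- disk_label(tr$eccentricity, tr$cued_disk_index)
    idxs <- tr$i_start:tr$i_end
    runs <- true_runs(!in_sacc[idxs])
    if (!nrow(runs)) next
    runs <- runs + tr$i_start - 1L
    mode_lab <- apply(runs, 1, function(r) {
      tab <- table(raycast$object[r[1]:r[2]])  # NA (invalid) excluded
      if (!length(tab)) return(NA_character_)
      names(tab)[which.max(tab)]
    })
    cand <- which(mode_lab == target)
    if (!length(cand)) next
    len <- runs[, 2] - runs[, 1]
    best <- cand[which.max(len[cand])]
    sel <- runs[best, 1]:runs[best, 2]
    sel <- sel[speeds$usable[sel] & speeds$eye_speed[sel] <= exclusion]
    if (!length(sel)) next
    out$mean_gaze_speed[i] <- mean(speeds$gaze_speed[sel])
    out$interval_duration[i] <-
      (runs[best, 2] - runs[best, 1] + 1) / sampling_rate(speeds$t)
  }
  out
}

#' Main-sequence summary statistics by group
#'
#' Sample mean, skewness and kurtosis (standardised third and fourth
#' central moments; kurtosis is non-excess, so a normal sample tends to
#' 3) of saccade amplitudes per group. Groups with fewer than 3 saccades
#' or zero variance are flagged with `NA` moments.
#'
#' @param amplitude saccade amplitudes, degrees.
#' @param group grouping factor (e.g. motion x eccentricity).
#' @return data frame: `group, n, mean_amplitude, skewness, kurtosis`.
#' @export
main_sequence_stats <- function(amplitude, group) {
  groups <- split(amplitude, group)
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    m2 <- mean((x - mean(x))^2)
    if (n < 3 || m2 == 0)
      return(data.frame(group = g, n = n, mean_amplitude = mean(x),
                        skewness = NA_real_, kurtosis = NA_real_))
    data.frame(group = g, n = n, mean_amplitude = mean(x),
               skewness = mean((x - mean(x))^3) / m2^1.5,
               kurtosis = mean((x - mean(x))^4) / m2^2)
  })
  do.call(rbind, out)
}

#' Per-trial reaction times
#'
#' Saccadic reaction time: onset of the first included (at least 3 deg)
#' saccade after cue onset, minus cue onset. Button reaction time: first
#' response after target onset minus target onset, valid only if it
#' precedes the next trial's cue onset (later or repeated responses are
#' dropped). Disengagement time: first time after target onset at which
#' the ray-cast label leaves the cued disk, minus target onset.
#'
#' @param segments `gaze_segments` from [classify_recording()].
#' @param events an [event_log()].
#' @param raycast a `raycast_series`.
#' @param trials trial table with `cue_time`, `target_time`, windows.
#' @return data frame: `trial_id, saccadic_rt, button_rt,
#'   disengagement_time` (seconds, `NA` where undefined).
#' @export
reaction_times <- function(segments, events, raycast, trials) {
  sac <- segments[segments$label == "saccade", ]
  resp <- events[events$kind == "response", ]
  next_cue <- c(trials$cue_time[-1], Inf)
  out <- data.frame(trial_id = trials$trial_id, saccadic_rt = NA_real_,
                    button_rt = NA_real_, disengagement_time = NA_real_)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    onset <- sac$t_start[sac$t_start >= tr$cue_time &
                           sac$t_start < next_cue[i]]
    if (length(onset)) out$saccadic_rt[i] <- min(onset) - tr$cue_time
    rr <- resp$t[resp$trial_id == tr$trial_id]
    rr <- rr[rr >= tr$target_time & rr < next_cue[i]]
    if (length(rr)) out$button_rt[i] <- rr[1] - tr$target_time
    target <- disk_label(tr$eccentricity, tr$cued_disk_index)
    idxs <- tr$i_start:tr$i_end
    post <- idxs[raycast$t[idxs] >= tr$target_time &
                   !is.na(raycast$object[idxs])]
    off <- post[raycast$object[post] != target]
    if (length(off) && length(post) && off[1] > post[1])
      out$disengagement_time[i] <- raycast$t[off[1]] - tr$target_time
  }
  out
}

#' Fraction of valid eye samples
#'
#' @param rec a [gaze_recording()].
#' @return `count(valid) / count(all)`.
#' @export
valid_sample_fraction <- function(rec) {
  if (!nrow(rec)) stop_data("empty recording")
  mean(rec$valid)
}
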