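# Event log container and CSV interchange.

EVENT_KINDS <- c("trial_start", "cue_onset", "target_onset", "response")

EVENT_COLUMNS <- c("t", "kind", "trial_id", "condition_motion",
                   "condition_eccentricity", "cue_distance_m",
                   "target_dir", "response_side")

#' Construct an event log
#'
#' Records the paradigm's timeline: per trial a `trial_start`, a
#' `cue_onset` (a disk turns yellow), a `target_onset` (the cued disk turns
#' red and shows the discrimination target) and zero or more `response`
#' button events, each tagged with the trial's condition.
#'
#' @param t event times, seconds.
#' @param kind one of `trial_start`, `cue_onset`, `target_onset`, `response`.
#' @param trial_id integer trial identifier.
#' @param condition_motion `"static"` or `"dynamic"` (ego-motion at 5 m/s).
#' @param condition_eccentricity `"parafoveal"` (6 dva) or `"peripheral"`
#'   (20 dva).
#' @param cue_distance_m distance of the cued disk at cue onset, metres.
#' @param target_dir `"left"` or `"right"` (opening of the target "C").
#' @param response_side reported side for `response` events, else `NA`.
#' @return an `event_log` (data frame), sorted check enforced.
#' @export
event_log <- function(t, kind, trial_id, condition_motion = NA,
                      condition_eccentricity = NA, cue_distance_m = NA,
                      target_dir = NA, response_side = NA) {
  ev <- data.frame(
    t = as.numeric(t), kind = as.character(kind),
    trial_id = as.integer(trial_id),
    condition_motion = as.character(condition_motion),
    condition_eccentricity = as.character(condition_eccentricity),
    cue_distance_m = as.numeric(cue_distance_m),
    target_dir = as.character(target_dir),
    response_side = as.character(response_side)
  )
  class(ev) <- c("event_log", "data.frame")
  validate_events(ev)
}

#' Validate an event log
#'
#' Event kinds must come from the enumerated set, times must be
#' non-decreasing overall, and within each trial `cue_onset < target_onset
#' < response` for the kinds present.
#'
#' @param ev an `event_log`.
#' @return `ev` or an error.
#' @export
validate_events <- function(ev) {
  bad <- setdiff(unique(ev$kind), EVENT_KINDS)
  if (length(bad))
    stop_data("unknown event kind(s): %s", paste(bad, collapse = ", "))
  if (nrow(ev) > 1 && any(diff(ev$t) < 0))
    stop_data("event times must be non-decreasing")
  for (id in unique(ev$trial_id)) {
    tr <- ev[ev$trial_id == id, ]
    tc <- tr$t[tr$kind == "cue_onset"]
    tt <- tr$t[tr$kind == "target_onset"]
    rr <- tr$t[tr$kind == "response"]
    if (length(tc) && length(tt) && any(tt <= tc[1]))
      stop_data("trial %d: target_onset not after cue_onset", id)
    if (length(tt) && length(rr) && any(rr <= tt[1]))
      stop_data("trial %d: response not after target_onset", id)
  }
  ev
}

#' Read an event log from CSV
#' @param path CSV with columns `t, kind, trial_id, condition_motion,
#'   condition_eccentricity, cue_distance_m, target_dir, response_side`.
#' @return an `event_log`.
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing_cols))
    stop_data("event file lacks required column(s): %s",
              paste(missing_cols, collapse = ", "))
  ev <- event_log(df$t, df$kind, df$trial_id, df$condition_motion,
                  df$condition_eccentricity, df$cue_distance_m,
                  df$target_dir, df$response_side)
  if (!is.null(df$cued_disk_index)) ev$cued_disk_index <- df$cued_disk_index
  ev
}

#' Write an event log to CSV
#' @param ev an `event_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ev, path) {
  out <- as.data.frame(ev)
  out$t <- format(out$t, digits = 15, trim = TRUE)
  out$cue_distance_m <- format(out$cue_distance_m, digits = 15, trim = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
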