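# Pipeline configuration: classification thresholds and preprocessing
# parameters, with JSON round-trip.

#' Classification thresholds
#'
#' Stationary-head base thresholds for the event classifier. The saccade,
#' low-gaze and low-eye thresholds are scaled by instantaneous head speed
#' via [scale_threshold()]; the head threshold is not (scaling a head
#' threshold by head speed would be self-referential).
#'
#' @param theta_saccade saccade threshold on eye speed with the head
#'   stationary, deg/s.
#' @param theta_lowgaze lower-bound gaze speed threshold separating
#'   stationary from moving gaze, deg/s.
#' @param theta_head head speed threshold separating a stationary from a
#'   moving head, deg/s. Not scaled.
#' @param theta_loweye eye-in-head speed threshold separating head pursuit
#'   from the other pursuit labels, deg/s; scaled like the gaze threshold.
#' @param theta_highgaze optional upper gaze threshold; carried in the
#'   configuration but unused by the default classifier.
#' @param scaling_denominator denominator of the head-speed scaling
#'   `(1 + v_head / scaling_denominator)`, deg/s.
#' @return a `threshold_set` (list).
#' @export
threshold_set <- function(theta_saccade = 35, theta_lowgaze = 10,
                          theta_head = 7, theta_loweye = 10,
                          theta_highgaze = NULL,
                          scaling_denominator = 60) {
  thr <- list(theta_saccade = theta_saccade, theta_lowgaze = theta_lowgaze,
              theta_head = theta_head, theta_loweye = theta_loweye,
              theta_highgaze = theta_highgaze,
              scaling_denominator = scaling_denominator)
  num <- unlist(thr[!vapply(thr, is.null, logical(1))])
  if (any(num <= 0)) stop_data("all thresholds must be strictly positive")
  if (theta_lowgaze >= theta_saccade)
    stop_data("theta_lowgaze must be below theta_saccade")
  structure(thr, class = "threshold_set")
}

#' Pipeline configuration
#'
#' Bundles the thresholds with the preprocessing and segmentation
#' parameters used by [classify_recording()].
#'
#' @param thresholds a [threshold_set()].
#' @param median_window median filter width, samples (odd; 5 samples is
#'   40 ms at 120 Hz).
#' @param noise_pad guard band around invalid samples treated as noise,
#'   seconds.
#' @param epoch_length intersaccadic epoch length, seconds.
#' @param min_saccade_duration minimum above-threshold window to count as a
#'   saccade, seconds.
#' @param min_amplitude minimum saccade amplitude retained for analysis,
#'   degrees.
#' @param max_peak_velocity maximum plausible saccadic peak velocity,
#'   deg/s; faster detections are excluded.
#' @param pursuit_eye_speed_exclusion eye-speed cutoff used when averaging
#'   gaze speed over on-target intervals (excludes catch-up saccades),
#'   deg/s.
#' @return a `pipeline_config` (list).
#' @export
pipeline_config <- function(thresholds = threshold_set(),
                            median_window = 5, noise_pad = 0.040,
                            epoch_length = 0.100,
                            min_saccade_duration = 0.020,
                            min_amplitude = 3, max_peak_velocity = 1000,
                            pursuit_eye_speed_exclusion = 20) {
  durs <- c(median_window = median_window, noise_pad = noise_pad,
            epoch_length = epoch_length,
            min_saccade_duration = min_saccade_duration,
            min_amplitude = min_amplitude,
            max_peak_velocity = max_peak_velocity,
            pursuit_eye_speed_exclusion = pursuit_eye_speed_exclusion)
  if (any(durs <= 0))
    stop_data("all durations and speeds must be strictly positive")
  if (median_window %% 2 != 1)
    stop_data("median_window must be odd")
  structure(list(thresholds = thresholds, median_window = median_window,
                 noise_pad = noise_pad, epoch_length = epoch_length,
                 min_saccade_duration = min_saccade_duration,
                 min_amplitude = min_amplitude,
                 max_peak_velocity = max_peak_velocity,
                 pursuit_eye_speed_exclusion = pursuit_eye_speed_exclusion),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file mirroring the [pipeline_config()] fields (with a
#'   nested `thresholds` object).
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- do.call(threshold_set, as.list(x$thresholds))
  args <- x[setdiff(names(x), "thresholds")]
  do.call(pipeline_config, c(list(thresholds = thr), args))
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass_deep(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
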