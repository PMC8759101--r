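# Conversion of raw directions and poses into masked, filtered angular
# speed series for eye, head and gaze.
#
# Terminology: eye speed is the angular velocity of the eye relative to the
# head; head speed is the angular velocity of the head relative to the
# world; gaze speed is the angular velocity of the world-frame line of
# sight (eye and head combined).

#' World-frame gaze direction
#'
#' Composes the eye-in-head direction with the head orientation: the gaze
#' direction is the head rotation applied to the eye direction. Equals
#' `eye_dir` when `head_quat` is the identity.
#'
#' @param eye_dir n x 3 matrix (or length-3 vector) of unit eye-in-head
#'   directions.
#' @param head_quat n x 4 matrix (or length-4 vector) of unit head
#'   quaternions.
#' @return n x 3 matrix of unit world-frame gaze directions.
#' @export
gaze_direction <- function(eye_dir, head_quat) {
  if (is.null(dim(eye_dir))) eye_dir <- matrix(eye_dir, nrow = 1)
  n <- sqrt(rowSums(eye_dir^2))
  if (any(n == 0)) stop_data("eye_dir has zero norm")
  quat_rotate(head_quat, eye_dir / n)
}

#' Angular speed of a direction time series
#'
#' Backward-difference angular speed: `speed[i]` is the angle between
#' `dirs[i-1, ]` and `dirs[i, ]` divided by `t[i] - t[i-1]`, in deg/s,
#' assigned to the later sample. The first sample copies the second.
#'
#' @param dirs n x 3 matrix of unit directions.
#' @param t timestamps, seconds.
#' @return length-n vector of speeds, deg/s.
#' @export
angular_speed <- function(dirs, t) {
  if (nrow(dirs) < 2) stop_data("need at least 2 samples")
  dt <- diff(t)
  if (any(dt == 0)) stop_data("duplicate timestamps")
  ang <- angle_between_deg(dirs[-nrow(dirs), , drop = FALSE],
                           dirs[-1, , drop = FALSE])
  v <- ang / dt
  c(v[1], v)
}

#' Angular speed of a head orientation time series
#'
#' Geodesic rotation angle between successive quaternions divided by the
#' sampling interval, with the same conventions as [angular_speed()]
#' (backward difference, first sample copies the second). Quaternion sign
#' flips (q vs -q) do not produce spurious speed.
#'
#' @param quats n x 4 matrix of unit quaternions.
#' @param t timestamps, seconds.
#' @return length-n vector of speeds, deg/s.
#' @export
head_angular_speed <- function(quats, t) {
  if (nrow(quats) < 2) stop_data("need at least 2 samples")
  dt <- diff(t)
  if (any(dt == 0)) stop_data("duplicate timestamps")
  v <- quat_step_angle(quats) / dt
  c(v[1], v)
}

#' Centred running median filter
#'
#' Five samples (40 ms at 120 Hz) by default. Edges use shrunken symmetric
#' windows rather than invented padding values: at distance `d < (window-1)/2`
#' from either end the window half-width is `d`.
#'
#' @param x numeric vector.
#' @param window odd window width in samples.
#' @return filtered vector, same length.
#' @export
median_filter <- function(x, window = 5) {
  if (window %% 2 != 1) stop_data("window must be odd")
  n <- length(x)
  if (n == 0 || window == 1) return(x)
  if (n <= window) {
    return(vapply(seq_len(n), function(i) {
      h <- min((window - 1) / 2, i - 1, n - i)
      stats::median(x[(i - h):(i + h)])
    }, numeric(1)))
  }
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  h <- (window - 1) / 2
  for (i in seq_len(h)) {
    hh <- i - 1
    out[i] <- stats::median(x[(i - hh):(i + hh)])
    j <- n - i + 1
    out[j] <- stats::median(x[(j - hh):(j + hh)])
  }
  out
}

#' Mask samples contaminated by tracking dropouts
#'
#' Every invalid epoch, as well as a guard band before and after it
#' (40 ms by default), is treated as noise and excluded from
#' classification. The guard band is `ceiling(pad * fs)` samples on each
#' side (5 samples at 120 Hz), so one isolated invalid sample removes 11.
#'
#' @param valid logical vector of per-sample validity.
#' @param t timestamps, seconds.
#' @param pad guard band, seconds.
#' @return logical vector: `TRUE` where the sample is usable.
#' @export
mask_invalid <- function(valid, t, pad = 0.040) {
  stopifnot(length(valid) == length(t))
  n <- length(valid)
  if (n == 0) return(logical(0))
  if (all(valid)) return(rep(TRUE, n))
  n_pad <- if (n > 1) ceiling(pad * sampling_rate(t)) else 0L
  usable <- as.logical(valid)
  runs <- true_runs(!usable)
  for (k in seq_len(nrow(runs))) {
    lo <- max(1L, runs[k, 1] - n_pad)
    hi <- min(n, runs[k, 2] + n_pad)
    usable[lo:hi] <- FALSE
  }
  usable
}

#' Resample a stream onto target timestamps by nearest neighbour
#'
#' Head pose is often recorded at the display rate (90 Hz) while the eyes
#' are sampled at 120 Hz; this aligns the slower stream onto the eye
#' timestamps (worst-case skew is half the source interval, ~5.6 ms).
#'
#' @param t_src source timestamps.
#' @param x source values (vector or matrix, rows aligned with `t_src`).
#' @param t_dst target timestamps.
#' @return values of `x` at the nearest source sample for each `t_dst`.
#' @export
resample_nearest <- function(t_src, x, t_dst) {
  idx <- vapply(t_dst, function(tt) which.min(abs(t_src - tt)), integer(1))
  if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
}

#' Compute masked, filtered speed series for a recording
#'
#' Eye, head and gaze angular speeds are computed sample-to-sample,
#' median-filtered, and combined with the dropout mask from
#' [mask_invalid()]. Gaze speed is computed from composed world-frame gaze
#' directions ([gaze_direction()]), not as a sum of components.
#'
#' @param rec a [gaze_recording()].
#' @param cfg a [pipeline_config()].
#' @return a `speed_series` data frame with columns `t, eye_speed,
#'   head_speed, gaze_speed, usable`.
#' @export
compute_speeds <- function(rec, cfg = pipeline_config()) {
  if (nrow(rec) < 2) stop_data("recording must have at least 2 samples")
  eye <- eye_matrix(rec)
  q <- quat_matrix(rec)
  gaze <- gaze_direction(eye, q)
  sp <- data.frame(
    t = rec$t,
    eye_speed = median_filter(angular_speed(eye, rec$t), cfg$median_window),
    head_speed = median_filter(head_angular_speed(q, rec$t),
                               cfg$median_window),
    gaze_speed = median_filter(angular_speed(gaze, rec$t),
                               cfg$median_window),
    usable = mask_invalid(rec$valid, rec$t, cfg$noise_pad)
  )
  class(sp) <- c("speed_series", "data.frame")
  sp
}

#' Write a speed series to CSV
#' @param speeds a `speed_series` from [compute_speeds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_speeds <- function(speeds, path) {
  out <- as.data.frame(speeds)
  out$usable <- as.integer(out$usable)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
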