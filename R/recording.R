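# Gaze recording container and CSV interchange.
#
# One row per eye-tracker sample. Columns: t, eye_x, eye_y, eye_z (eye-in-head
# unit direction), head_qw..head_qz (head-to-world unit quaternion), pos_x..
# pos_z (head position, metres), valid (0/1), pupil_mm (optional).

REC_COLUMNS <- c("t", "eye_x", "eye_y", "eye_z",
                 "head_qw", "head_qx", "head_qy", "head_qz",
                 "pos_x", "pos_y", "pos_z", "valid")

#' Construct a gaze recording
#'
#' A `gaze_recording` is a data frame with one row per sample: time in
#' seconds from recording start, eye-in-head unit direction, head-to-world
#' unit quaternion, head position in metres and a per-sample validity flag
#' derived from the pupil signal. Samples flagged invalid carry the
#' placeholder direction (0, 0, 1); the flag, not the value, is
#' authoritative (HMD trackers typically interpolate position for dropped
#' frames but not pupil size, so validity is defined by the pupil signal).
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param eye_dir n x 3 matrix of eye-in-head unit directions.
#' @param head_quat n x 4 matrix of unit quaternions (w, x, y, z).
#' @param head_pos n x 3 matrix of head positions in metres.
#' @param valid logical vector; defaults to all valid.
#' @param pupil_mm optional pupil diameter in millimetres.
#' @return a `gaze_recording` (data frame).
#' @seealso [read_recording()], [write_recording()], [compute_speeds()]
#' @export
gaze_recording <- function(t, eye_dir, head_quat, head_pos,
                           valid = rep(TRUE, length(t)), pupil_mm = NULL) {
  eye_dir <- as.matrix(eye_dir); head_quat <- as.matrix(head_quat)
  head_pos <- as.matrix(head_pos)
  rec <- data.frame(
    t = as.numeric(t),
    eye_x = eye_dir[, 1], eye_y = eye_dir[, 2], eye_z = eye_dir[, 3],
    head_qw = head_quat[, 1], head_qx = head_quat[, 2],
    head_qy = head_quat[, 3], head_qz = head_quat[, 4],
    pos_x = head_pos[, 1], pos_y = head_pos[, 2], pos_z = head_pos[, 3],
    valid = as.logical(valid)
  )
  if (!is.null(pupil_mm)) rec$pupil_mm <- as.numeric(pupil_mm)
  rec[!rec$valid, c("eye_x", "eye_y", "eye_z")] <-
    rep(c(0, 0, 1), each = sum(!rec$valid))
  class(rec) <- c("gaze_recording", "data.frame")
  validate_recording(rec)
}

#' Validate a gaze recording's invariants
#'
#' Checks strictly increasing timestamps, unit eye directions on valid
#' samples and unit head quaternions (both to 1e-6).
#'
#' @param rec a `gaze_recording`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec) {
  if (nrow(rec) > 1 && any(diff(rec$t) <= 0))
    stop_data("timestamps must be strictly increasing")
  ed <- eye_matrix(rec)
  nv <- abs(sqrt(rowSums(ed[rec$valid, , drop = FALSE]^2)) - 1)
  if (length(nv) && max(nv) > 1e-6)
    stop_data("eye_dir must be unit length on valid samples (max dev %.2g)",
              max(nv))
  qn <- abs(sqrt(rowSums(quat_matrix(rec)^2)) - 1)
  if (length(qn) && max(qn) > 1e-6)
    stop_data("head_quat must be unit length (max dev %.2g)", max(qn))
  rec
}

eye_matrix  <- function(rec) cbind(rec$eye_x, rec$eye_y, rec$eye_z)
quat_matrix <- function(rec) cbind(rec$head_qw, rec$head_qx,
                                   rec$head_qy, rec$head_qz)
pos_matrix  <- function(rec) cbind(rec$pos_x, rec$pos_y, rec$pos_z)

#' Read a gaze recording from CSV
#'
#' Rows with missing eye-direction fields are kept with `valid = FALSE` and
#' the placeholder direction (0, 0, 1). Files with non-monotone timestamps
#' are rejected (never silently reordered).
#'
#' @param path path to a CSV file with columns `t, eye_x, eye_y, eye_z,
#'   head_qw, head_qx, head_qy, head_qz, pos_x, pos_y, pos_z, valid`
#'   and optionally `pupil_mm`.
#' @return a `gaze_recording`.
#' @export
read_recording <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REC_COLUMNS, names(df))
  if (length(missing_cols))
    stop_data("recording file lacks required column(s): %s",
              paste(missing_cols, collapse = ", "))
  eye <- cbind(df$eye_x, df$eye_y, df$eye_z)
  valid <- as.logical(df$valid) & !apply(is.na(eye), 1, any)
  eye[is.na(eye)] <- 0
  eye[!valid, ] <- rep(c(0, 0, 1), each = sum(!valid))
  gaze_recording(df$t, eye,
                 cbind(df$head_qw, df$head_qx, df$head_qy, df$head_qz),
                 cbind(df$pos_x, df$pos_y, df$pos_z),
                 valid = valid, pupil_mm = df$pupil_mm)
}

#' Write a gaze recording to CSV
#'
#' Round-trips through [read_recording()] to numeric tolerance 1e-9.
#' Invalid samples are written with `NA` eye fields (the placeholder token),
#' since their stored direction is a placeholder, not a measurement.
#'
#' @param rec a `gaze_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  out <- as.data.frame(rec)
  out[!out$valid, c("eye_x", "eye_y", "eye_z")] <- NA_real_
  out$valid <- as.integer(out$valid)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
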