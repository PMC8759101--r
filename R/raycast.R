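# Ray-cast ground truth: intersect the instantaneous gaze ray with the
# known scene objects to identify the foveated object at every sample.

#' Ray-cast a single gaze sample against scene objects
#'
#' Objects are modelled as spheres (disk facing is irrelevant at these
#' angular sizes); the nearest intersected object wins. The result
#' depends only on the ray's direction, not its magnitude.
#'
#' @param gaze_origin length-3 ray origin, metres (same frame as
#'   `objects`).
#' @param gaze_dir_world length-3 gaze direction (need not be unit
#'   length).
#' @param objects data frame with columns `label, x, y, z, radius`
#'   describing sphere centres and radii, metres.
#' @param layout a [world_layout()] (unused by the sphere test itself;
#'   kept so alternative object models can use scene metadata).
#' @return the label of the nearest hit object, or `"background"`.
#' @export
raycast <- function(gaze_origin, gaze_dir_world, objects,
                    layout = world_layout()) {
  d <- gaze_dir_world / sqrt(sum(gaze_dir_world^2))
  rel <- cbind(objects$x - gaze_origin[1], objects$y - gaze_origin[2],
               objects$z - gaze_origin[3])
  proj <- rel %*% d
  perp2 <- rowSums(rel^2) - proj^2
  hit <- proj > 0 & perp2 <= objects$radius^2
  if (!any(hit)) return("background")
  t_hit <- proj[hit] - sqrt(objects$radius[hit]^2 - perp2[hit])
  objects$label[hit][which.min(t_hit)]
}

#' Scene objects for one trial, observer-relative
#'
#' The recentering cross (always `cross_distance` ahead of the observer)
#' plus both disk rings at the trial's cue distance; in dynamic trials
#' the disks are world-fixed while the observer advances, so their
#' forward distance shrinks with time since cue.
#'
#' @param trial one row of a trial table (`motion`, `cue_distance`).
#' @param layout a [world_layout()].
#' @param t_since_cue seconds relative to cue onset (scalar).
#' @return data frame `label, x, y, z, radius` (positions relative to
#'   the observer's eye, metres).
#' @export
world_objects <- function(trial, layout, t_since_cue = 0) {
  rings <- names(layout$ring_eccentricities)
  disks <- do.call(rbind, lapply(rings, function(rg) {
    idx <- 0:(layout$disks_per_ring - 1L)
    pos <- t(vapply(idx, function(i)
      disk_position(layout, rg, i, trial$cue_distance, t_since_cue,
                    trial$motion)[1, ], numeric(3)))
    data.frame(label = disk_label(rg, idx), x = pos[, 1], y = pos[, 2],
               z = pos[, 3], radius = layout$disk_diameter / 2)
  }))
  rbind(data.frame(label = "cross", x = 0, y = 0,
                   z = layout$cross_distance,
                   radius = layout$cross_size / 2),
        disks)
}

#' Ray-cast every sample of a recording
#'
#' For each trial window the world-frame gaze ray is intersected with
#' that trial's scene objects. Positions are handled observer-relative,
#' so static and ego-motion trials share one code path.
#'
#' @param rec a [gaze_recording()].
#' @param trials trial table with `cue_time`, `i_start`, `i_end`,
#'   `motion`, `eccentricity`, `cue_distance` (from [simulate_session()]
#'   or [trials_from_events()]).
#' @param layout a [world_layout()].
#' @return a `raycast_series` data frame: `t, object, hit_distance`
#'   (`hit_distance` is `NA` for background).
#' @export
raycast_series <- function(rec, trials, layout = world_layout()) {
  gaze <- gaze_direction(eye_matrix(rec), quat_matrix(rec))
  n <- nrow(rec)
  object <- rep("background", n)
  hitd <- rep(NA_real_, n)
  rings <- names(layout$ring_eccentricities)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    idxs <- tr$i_start:tr$i_end
    ts <- rec$t[idxs] - tr$cue_time
    g <- gaze[idxs, , drop = FALSE]
    best_t <- rep(Inf, length(idxs))
    best_lab <- rep("background", length(idxs))
    for (rg in rings) {
      r_lat <- tr$cue_distance *
        tan(layout$ring_eccentricities[[rg]] * pi / 180)
      for (k in 0:(layout$disks_per_ring - 1L)) {
        psi <- ring_angle(k, layout$disks_per_ring)
        ox <- r_lat * cos(psi); oy <- r_lat * sin(psi)
        oz <- if (tr$motion == "dynamic")
          tr$cue_distance - layout$observer_speed * ts
        else rep(tr$cue_distance, length(ts))
        hit <- sphere_hit(g, ox, oy, oz, layout$disk_diameter / 2)
        better <- !is.na(hit) & hit < best_t
        best_t[better] <- hit[better]
        best_lab[better] <- disk_label(rg, k)
      }
    }
    hit <- sphere_hit(g, 0, 0, layout$cross_distance,
                      layout$cross_size / 2)
    better <- !is.na(hit) & hit < best_t
    best_t[better] <- hit[better]
    best_lab[better] <- "cross"
    object[idxs] <- best_lab
    hitd[idxs] <- ifelse(is.finite(best_t), best_t, NA_real_)
  }
  # invalid samples carry a placeholder direction, not a measurement
  object[!rec$valid] <- NA_character_
  hitd[!rec$valid] <- NA_real_
  out <- data.frame(t = rec$t, object = object, hit_distance = hitd)
  class(out) <- c("raycast_series", "data.frame")
  out
}

# vectorised ray-sphere intersection: rows of g against a sphere at
# (ox, oy, oz) (scalars or per-row vectors); returns hit distance or NA
sphere_hit <- function(g, ox, oy, oz, radius) {
  proj <- g[, 1] * ox + g[, 2] * oy + g[, 3] * oz
  perp2 <- ox^2 + oy^2 + oz^2 - proj^2
  ok <- proj > 0 & perp2 <= radius^2
  ifelse(ok, proj - sqrt(pmax(0, radius^2 - perp2)), NA_real_)
}

#' Reconstruct a trial table from an event log
#'
#' Builds the per-trial windows needed by [raycast_series()] and the
#' validation summaries from a recorded event log. Requires the
#' `cued_disk_index` payload column (written by [simulate_session()]) to
#' identify the cued object.
#'
#' @param events an [event_log()].
#' @param t_max end of the recording, seconds (bounds the last trial's
#'   window); defaults to the last event time.
#' @param fs sampling rate used to convert times to sample indices.
#' @param t0 recording start time.
#' @return data frame with one row per trial.
#' @export
trials_from_events <- function(events, t_max = max(events$t), fs = 120,
                               t0 = 0) {
  if (is.null(events$cued_disk_index))
    stop_data("events lack the cued_disk_index payload column")
  starts <- events[events$kind == "trial_start", ]
  cues <- events[events$kind == "cue_onset", ]
  targets <- events[events$kind == "target_onset", ]
  ord <- order(starts$t)
  starts <- starts[ord, ]
  t_start <- starts$t
  t_end <- c(t_start[-1], t_max)
  m <- match(starts$trial_id, cues$trial_id)
  mt <- match(starts$trial_id, targets$trial_id)
  data.frame(
    trial_id = starts$trial_id,
    motion = starts$condition_motion,
    eccentricity = starts$condition_eccentricity,
    cue_distance = starts$cue_distance_m,
    cued_disk_index = starts$cued_disk_index,
    target_dir = starts$target_dir,
    cue_time = cues$t[m],
    target_time = targets$t[mt],
    t_start = t_start, t_end = t_end,
    i_start = pmax(1L, as.integer(round((t_start - t0) * fs)) + 1L),
    i_end = as.integer(round((t_end - t0) * fs))
  )
}
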