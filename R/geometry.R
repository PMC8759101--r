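# World layout, visual-angle utilities, target trajectories under
# ego-motion and seeded trial-schedule generation.

#' Virtual world layout
#'
#' Geometry of the cued-discrimination scene: a recentering cross straight
#' ahead, surrounded by two concentric fronto-parallel rings of white
#' disks (parafoveal and peripheral), viewed from a seated observer who in
#' Dynamic trials translates forward at 5 m/s.
#'
#' @param cross_distance distance of the recentering cross, metres (always
#'   ahead of the observer).
#' @param cross_size cross extent, metres (0.18 m is 0.94 dva at 11 m).
#' @param disk_diameter disk diameter, metres.
#' @param ring_eccentricities ring eccentricities relative to the cross,
#'   dva, at cue time.
#' @param disks_per_ring disks per ring; 8 gives every disk a diametric
#'   opposite.
#' @param cue_distances possible distances of the cued disk at cue onset,
#'   metres (static trials use both; dynamic trials always cue at the
#'   larger).
#' @param observer_speed forward ego-motion speed in Dynamic trials, m/s.
#' @param letter_height height of the "O"/"C" letter, metres (subtends
#'   1.89 dva at 13 m and 0.77 dva at 32 m).
#' @param eye_height observer eye height, metres.
#' @return a `world_layout` (list).
#' @export
world_layout <- function(cross_distance = 11, cross_size = 0.18,
                         disk_diameter = 1.0,
                         ring_eccentricities = c(parafoveal = 6,
                                                 peripheral = 20),
                         disks_per_ring = 8,
                         cue_distances = c(13, 32),
                         observer_speed = 5,
                         letter_height = 0.429,
                         eye_height = 1.2) {
  lengths <- c(cross_distance, cross_size, disk_diameter, disks_per_ring,
               cue_distances, observer_speed, letter_height)
  if (any(lengths <= 0)) stop_data("all lengths must be positive")
  if (any(ring_eccentricities <= 0 | ring_eccentricities >= 90))
    stop_data("ring eccentricities must lie in (0, 90) dva")
  structure(list(cross_distance = cross_distance, cross_size = cross_size,
                 disk_diameter = disk_diameter,
                 ring_eccentricities = ring_eccentricities,
                 disks_per_ring = disks_per_ring,
                 cue_distances = cue_distances,
                 observer_speed = observer_speed,
                 letter_height = letter_height,
                 eye_height = eye_height),
            class = "world_layout")
}

#' Visual angle subtended by an extent at a distance
#'
#' `2 * atan(extent / (2 * distance))` in degrees of visual angle (dva):
#' a 0.1 m calibration point at 1.2 m subtends 4.77 dva; a 1 m disk
#' subtends 4.4 dva at 13 m and 1.8 dva at 32 m.
#'
#' @param extent object extent, metres (non-negative).
#' @param distance viewing distance, metres (positive).
#' @return angle in dva.
#' @export
visual_angle <- function(extent, distance) {
  if (any(distance <= 0)) stop_data("distance must be positive")
  if (any(extent < 0)) stop_data("extent must be non-negative")
  2 * atan(extent / (2 * distance)) * 180 / pi
}

#' Angular offset of a point from the forward axis
#'
#' `atan(sqrt(x^2 + y^2) / z)` in degrees: the eccentricity of a point at
#' lateral offset (x, y) and forward distance z. The corner calibration
#' points at (0.3, 0.15, 1.2) m sit 15.62 dva from the centre point.
#'
#' @param x,y lateral offsets, metres.
#' @param z forward distance, metres (positive).
#' @return angle in dva.
#' @export
offset_angle <- function(x, y, z) {
  if (any(z <= 0)) stop_data("z must be positive")
  atan(sqrt(x^2 + y^2) / z) * 180 / pi
}

#' Transfer a visual angle from one distance to another
#'
#' Inverts [visual_angle()] at `d1` to a metric extent and re-applies it
#' at `d2`: the 1.89 dva letter at 13 m subtends 0.77 dva at 32 m.
#'
#' @param angle_at_d1 angle at the first distance, dva.
#' @param d1,d2 distances, metres (positive).
#' @return angle at `d2`, dva.
#' @export
angle_at_distance <- function(angle_at_d1, d1, d2) {
  if (any(c(d1, d2) <= 0)) stop_data("distances must be positive")
  extent <- 2 * d1 * tan(angle_at_d1 / 2 * pi / 180)
  visual_angle(extent, d2)
}

#' Ring azimuthal position of a disk
#'
#' Disks are evenly spaced on the ring; index `i` (0-based) sits at angle
#' `360 * i / disks_per_ring` degrees, measured counterclockwise from the
#' +x (rightward) direction in the fronto-parallel plane.
#' @noRd
ring_angle <- function(disk_index, disks_per_ring) {
  2 * pi * disk_index / disks_per_ring
}

#' Observer-relative position of a disk
#'
#' Static trials: the disk sits at forward distance `cue_distance` with a
#' constant lateral offset `cue_distance * tan(eccentricity)` chosen so
#' the ring subtends its nominal eccentricity at cue time. Dynamic trials:
#' disks are world-fixed while the observer translates forward, so the
#' forward distance shrinks as `cue_distance - observer_speed *
#' t_since_cue` while the lateral offset stays constant (and the disk's
#' eccentricity and angular speed grow as it approaches).
#'
#' @param layout a [world_layout()].
#' @param ring `"parafoveal"` or `"peripheral"`.
#' @param disk_index 0-based index on the ring.
#' @param cue_distance forward distance at cue onset, metres.
#' @param t_since_cue seconds since cue onset (vectorised).
#' @param motion `"static"` or `"dynamic"`.
#' @return matrix (length(t) x 3) of observer-relative positions (x, y, z)
#'   in metres.
#' @export
disk_position <- function(layout, ring, disk_index, cue_distance,
                          t_since_cue, motion = c("static", "dynamic")) {
  motion <- match.arg(motion)
  ecc <- layout$ring_eccentricities[[ring]]
  r <- cue_distance * tan(ecc * pi / 180)
  psi <- ring_angle(disk_index, layout$disks_per_ring)
  z <- if (motion == "static") rep(cue_distance, length(t_since_cue))
       else cue_distance - layout$observer_speed * t_since_cue
  unname(cbind(r * cos(psi), r * sin(psi), z))
}

#' Build the 288-trial schedule
#'
#' Six blocks of 48 trials, two blocks per condition (Static with cues at
#' 13 m, Static at 32 m, Dynamic with cues at 32 m), block order
#' counterbalanced over conditions by a Latin square keyed on the
#' participant index. Within each block, parafoveal and peripheral cues
#' and left/right targets are balanced; the cued disk is uniform over its
#' ring with the distractor diametrically opposite; the stimulus onset
#' asynchrony (SOA, cue to target) is uniform on 0.6-1.6 s; cue-to-cue
#' spacing is uniform on 5.4-7.4 s (6.4 s mean). Identical seeds give
#' identical schedules.
#'
#' @param layout a [world_layout()].
#' @param seed integer seed for the schedule's randomisation.
#' @param participant participant index used only for block-order
#'   counterbalancing.
#' @return a `trial_schedule`: a data frame of 288 trials with attributes
#'   `seed` and `block_order`.
#' @export
build_schedule <- function(layout = world_layout(), seed = 1L,
                           participant = 1L) {
  conditions <- c("static_13", "static_32", "dynamic")
  latin <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  order3 <- conditions[latin[(participant - 1L) %% 3L + 1L, ]]
  block_cond <- c(order3, rev(order3))  # 6 blocks, 2 per condition
  n_per_block <- 48L
  with_seed(seed, {
    trials <- lapply(seq_along(block_cond), function(b) {
      cond <- block_cond[b]
      motion <- if (cond == "dynamic") "dynamic" else "static"
      cue_dist <- switch(cond, static_13 = min(layout$cue_distances),
                         dynamic = , static_32 = max(layout$cue_distances))
      ecc <- sample(rep(c("parafoveal", "peripheral"), n_per_block / 2))
      dir <- sample(rep(c("left", "right"), n_per_block / 2))
      disk <- sample(0:(layout$disks_per_ring - 1L), n_per_block,
                     replace = TRUE)
      data.frame(
        block_id = b, motion = motion, eccentricity = ecc,
        cue_distance = cue_dist, cued_disk_index = disk,
        distractor_disk_index =
          (disk + layout$disks_per_ring %/% 2L) %% layout$disks_per_ring,
        soa = runif(n_per_block, 0.6, 1.6),
        target_dir = dir,
        iti = runif(n_per_block, 5.4, 7.4)
      )
    })
    sched <- do.call(rbind, trials)
    sched$trial_id <- seq_len(nrow(sched))
    sched <- sched[c("trial_id", setdiff(names(sched), "trial_id"))]
    structure(sched, seed = seed, block_order = block_cond,
              class = c("trial_schedule", "data.frame"))
  })
}

#' Validate a full trial schedule
#'
#' Checks the paradigm's design counts: 288 trials, 6 blocks of 48, 96
#' trials per condition, balanced target direction, SOA within 0.6-1.6 s
#' and diametric distractors.
#'
#' @param sched a `trial_schedule`.
#' @return `sched` or an error.
#' @export
validate_schedule <- function(sched) {
  if (nrow(sched) != 288) stop_data("schedule must have 288 trials")
  if (!all(table(sched$block_id) == 48)) stop_data("blocks must have 48 trials")
  cond <- interaction(sched$motion, sched$cue_distance, drop = TRUE)
  if (!all(table(cond) == 96)) stop_data("need 96 trials per condition")
  if (!all(table(sched$target_dir) == 144))
    stop_data("target direction must be balanced 144/144")
  if (any(sched$soa < 0.6 | sched$soa > 1.6))
    stop_data("SOA out of bounds [0.6, 1.6] s")
  if (any((sched$cued_disk_index + 4) %% 8 != sched$distractor_disk_index))
    stop_data("distractor must be diametrically opposite the cue")
  sched
}
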