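test_that("gaze direction composes eye and head rotations", {
  expect_equal(gaze_direction(c(0, 0, 1), c(1, 0, 0, 0)),
               matrix(c(0, 0, 1), 1))
  # 90 degree yaw turns forward into rightward (+x) in the left-handed,
  # y-up, z-forward convention; expected value from the hand-written
  # rotation matrix for yaw: (x, y, z) -> (z sin, y, z cos)
  q90 <- quat_from_axis_angle(c(0, 1, 0), 90)
  expect_equal(gaze_direction(c(0, 0, 1), q90), matrix(c(1, 0, 0), 1),
               tolerance = 1e-12)
  expect_error(gaze_direction(c(0, 0, 0), c(1, 0, 0, 0)), "zero")
})

test_that("gaze direction preserves unit norm for random inputs", {
  set.seed(101)
  for (k in 1:25) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    g <- gaze_direction(v, q)
    expect_equal(sum(g^2), 1, tolerance = 1e-12)
  }
})

test_that("angular speed matches closed forms", {
  n <- 10
  t <- (seq_len(n) - 1) / 120
  const <- matrix(rep(c(0, 0, 1), n), n, byrow = TRUE)
  expect_equal(angular_speed(const, t), rep(0, n))

  az <- (seq_len(n) - 1) * 1  # 1 degree per sample at 120 Hz
  dirs <- cbind(sin(az * pi / 180), 0, cos(az * pi / 180))
  expect_equal(angular_speed(dirs, t), rep(120, n), tolerance = 1e-9)

  two <- rbind(c(0, 0, 1), c(1, 0, 0))
  expect_equal(angular_speed(two, c(0, 1 / 120)), rep(10800, 2),
               tolerance = 1e-9)
  expect_error(angular_speed(two, c(0, 0)), "duplicate")
})

test_that("head angular speed is geodesic and double-cover safe", {
  n <- 9
  t <- (seq_len(n) - 1) / 120
  qc <- matrix(rep(c(1, 0, 0, 0), n), n, byrow = TRUE)
  expect_equal(head_angular_speed(qc, t), rep(0, n))

  q <- quat_from_yaw_pitch((seq_len(n) - 1) * 0.5)  # 0.5 deg per sample
  expect_equal(head_angular_speed(q, t), rep(60, n), tolerance = 1e-9)

  qf <- q
  qf[5, ] <- -qf[5, ]  # sign flip encodes the same rotation
  expect_equal(head_angular_speed(qf, t), rep(60, n), tolerance = 1e-9)
})

test_that("median filter removes spikes and shrinks at edges", {
  expect_equal(median_filter(rep(3, 10)), rep(3, 10))
  expect_equal(median_filter(c(5, 5, 100, 5, 5)), rep(5, 5))
  x <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)
  once <- median_filter(x)
  expect_equal(median_filter(once)[3:8], once[3:8])  # interior idempotence
  expect_error(median_filter(1:5, window = 4), "odd")
  # edge windows shrink symmetrically: first output is the raw sample
  y <- c(100, 1, 1, 1, 1, 1, 1)
  expect_equal(median_filter(y)[1], 100)
  expect_equal(median_filter(y)[2], 1)
})

test_that("noise padding masks 40 ms around invalid epochs", {
  n <- 30
  t <- (seq_len(n) - 1) / 120
  expect_true(all(mask_invalid(rep(TRUE, n), t)))

  v <- rep(TRUE, n); v[15] <- FALSE
  u <- mask_invalid(v, t, pad = 0.040)
  expect_equal(sum(!u), 11)  # 5 samples each side plus the sample itself
  expect_equal(which(!u), 10:20)

  v2 <- rep(TRUE, n); v2[1:2] <- FALSE  # run at the boundary is clipped
  u2 <- mask_invalid(v2, t)
  expect_equal(which(!u2), 1:7)
})

test_that("masking is monotone in the invalid set", {
  set.seed(77)
  n <- 200
  t <- (seq_len(n) - 1) / 120
  for (k in 1:10) {
    v1 <- runif(n) > 0.05
    v2 <- v1 & runif(n) > 0.05  # strictly more invalid samples
    u1 <- mask_invalid(v1, t)
    u2 <- mask_invalid(v2, t)
    expect_true(all(u2 <= u1))  # nothing becomes usable
  }
})

test_that("speed series separates eye, head and gaze components", {
  # stationary eye and head
  rec0 <- rec_from_angles(gaze_az = rep(0, 50))
  sp0 <- compute_speeds(rec0)
  expect_true(all(abs(sp0$eye_speed) < 1e-9))
  expect_true(all(abs(sp0$gaze_speed) < 1e-9))

  # pure eye rotation with the head fixed: eye speed equals gaze speed
  rec1 <- rec_from_angles(gaze_az = seq(0, 10, length.out = 60))
  sp1 <- compute_speeds(rec1)
  expect_equal(sp1$eye_speed, sp1$gaze_speed, tolerance = 1e-6)

  # VOR: head oscillates, gaze pinned; head speed matches the imposed
  # rate while gaze speed stays near zero
  rec2 <- vor_recording(duration = 2, head_amp = 15, freq = 0.5)
  sp2 <- compute_speeds(rec2)
  mid <- sp2$t > 0.1 & sp2$t < 1.9
  expect_true(all(sp2$gaze_speed[mid] < 1))
  peak_rate <- 15 * 2 * pi * 0.5  # deg/s at oscillation midpoint
  expect_equal(max(sp2$head_speed[mid]), peak_rate, tolerance = 0.02)
  expect_gt(max(sp2$eye_speed[mid]), 0.9 * peak_rate)
})

test_that("nearest-neighbour resampling aligns slower streams", {
  t90 <- seq(0, 1, by = 1 / 90)
  x <- sin(t90)
  t120 <- seq(0, 1, by = 1 / 120)
  y <- resample_nearest(t90, x, t120)
  expect_equal(length(y), length(t120))
  expect_true(max(abs(y - sin(t120))) < max(abs(diff(x))))
})
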