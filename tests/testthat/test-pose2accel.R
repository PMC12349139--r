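dt46 <- 1 / 46

test_that("QC passes clean clips unchanged and rejects bad tracking", {
  p <- matrix(rnorm(60), 20, 3)
  traj <- joint_trajectory(p, dt46)
  out <- qc_and_fill(traj, qc_policy())
  expect_equal(out$positions, p)
  # 2-frame interior gap between (0,0,0) and (3,0,0) -> linear fill
  p2 <- matrix(0, 6, 3)
  p2[5, 1] <- 3; p2[6, 1] <- 4
  valid <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  filled <- qc_and_fill(joint_trajectory(p2, dt46, valid = valid),
                        qc_policy(min_valid_fraction = 0.5))
  expect_equal(filled$positions[3, ], c(1, 0, 0))
  expect_equal(filled$positions[4, ], c(2, 0, 0))
  # gap longer than max_gap_frames
  valid10 <- c(TRUE, rep(FALSE, 10), rep(TRUE, 9))
  expect_error(qc_and_fill(joint_trajectory(matrix(0, 20, 3), dt46,
                                            valid = valid10),
                           qc_policy(max_gap_frames = 3,
                                     min_valid_fraction = 0.4)),
               "max_gap_frames")
  # low valid fraction
  expect_error(qc_and_fill(joint_trajectory(matrix(0, 20, 3), dt46,
                                            valid = valid10), qc_policy()),
               "valid fraction")
})

test_that("temporal smoothing is a centered moving average", {
  p <- matrix(rnorm(30), 10, 3)
  traj <- joint_trajectory(p, dt46)
  expect_equal(smooth_trajectory(traj, 1)$positions, p)
  const <- joint_trajectory(matrix(5, 10, 3), dt46)
  expect_equal(smooth_trajectory(const, 5)$positions, const$positions)
  # interior impulse spreads to 1/5 over five frames
  imp <- matrix(0, 11, 3); imp[6, 2] <- 1
  sm <- smooth_trajectory(joint_trajectory(imp, dt46), 5)
  expect_equal(sm$positions[4:8, 2], rep(1 / 5, 5))
  expect_equal(sm$positions[3, 2], 0)
  expect_error(smooth_trajectory(traj, 4), "odd")
})

test_that("second differences recover constant acceleration exactly", {
  f <- 0:49
  # constant and linear trajectories differentiate to zero
  expect_true(all(acceleration_from_positions(
    joint_trajectory(matrix(3, 50, 3), dt46))$samples == 0))
  lin <- joint_trajectory(cbind(2 * f, -f, 0.5 * f), dt46)
  expect_lt(max(abs(acceleration_from_positions(lin)$samples)), 1e-9)
  # free-fall quadratic: p_z = 1/2 g t^2 -> a_z = g at every interior frame
  quad <- joint_trajectory(cbind(0 * f, 0 * f, 0.5 * 9.81 * (f * dt46)^2), dt46)
  a <- acceleration_from_positions(quad)
  expect_equal(nrow(a$samples), 48L)              # F - 2
  expect_lt(max(abs(a$samples[, 3] - 9.81)), 1e-6)
  expect_equal(a$rate_hz, 46)
  expect_error(joint_trajectory(matrix(0, 2, 3), dt46), "at least 3 frames")
})

test_that("differentiation is linear and O(dt^2)-accurate on cubics", {
  set.seed(8)
  f <- 0:29
  p1 <- matrix(rnorm(90), 30, 3); p2 <- matrix(rnorm(90), 30, 3)
  a1 <- acceleration_from_positions(joint_trajectory(p1, dt46))$samples
  a2 <- acceleration_from_positions(joint_trajectory(p2, dt46))$samples
  mix <- acceleration_from_positions(joint_trajectory(2 * p1 - 3 * p2, dt46))$samples
  expect_equal(mix, 2 * a1 - 3 * a2, tolerance = 1e-9)
  # cubic trajectory: second difference matches analytic 6ct + 2b to O(dt^2)
  tt <- f * dt46
  cub <- joint_trajectory(cbind(tt^3, 2 * tt^3 - tt^2, 0 * tt), dt46)
  acc <- acceleration_from_positions(cub)$samples
  analytic <- cbind(6 * tt[2:29], 12 * tt[2:29] - 2, 0)
  expect_lt(max(abs(acc - analytic)), 1e-4)
})

test_that("fall extraction crops, QCs, and marks the impact", {
  clip <- simulate_pose_clip(seed = 4)
  fps <- attr(clip, "fps"); fr <- attr(clip, "fall_frames")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(clip, path, row.names = FALSE)
  traj <- read_keypoints(path, "left_wrist", fps = fps)
  tr <- extract_fall_trial(traj, c(fr[1] - 1L, fr[2]), margin_s = 1.0,
                           policy = qc_policy())
  expect_s3_class(tr, "fall_trial")
  expect_length(tr$fall_intervals, 1L)
  mag <- sqrt(rowSums(tr$samples^2))
  iv <- tr$fall_intervals[[1]]
  expect_true(which.max(mag) >= iv[1] + 1 && which.max(mag) <= iv[2])
  # margin larger than the clip: clamps to the whole clip
  tr2 <- extract_fall_trial(traj, c(fr[1] - 1L, fr[2]), margin_s = 100)
  expect_equal(nrow(tr2$samples), nrow(traj$positions) - 2L)
  # occluded wrist beyond the gap budget propagates the QC rejection
  occ <- simulate_pose_clip(occlude_frames = fr[1] + 0:9, seed = 4)
  utils::write.csv(occ, path, row.names = FALSE)
  traj_occ <- read_keypoints(path, "left_wrist", fps = fps)
  expect_error(extract_fall_trial(traj_occ, c(fr[1] - 1L, fr[2]),
                                  policy = qc_policy(max_gap_frames = 3,
                                                     min_valid_fraction = 0.5)),
               "QC reject")
})

test_that("the pose pipeline is deterministic", {
  clip <- simulate_pose_clip(seed = 11)
  fr <- attr(clip, "fall_frames")
  mk <- function() {
    traj <- joint_trajectory(as.matrix(clip[, paste0("left_wrist_", c("x", "y", "z"))]),
                             1 / attr(clip, "fps"))
    extract_fall_trial(traj, c(fr[1] - 1L, fr[2]), margin_s = 1.0)
  }
  expect_identical(mk()$samples, mk()$samples)
})
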