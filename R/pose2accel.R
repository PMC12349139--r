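#' Construct a joint trajectory
#'
#' Per-frame 3D positions of one named skeleton joint, as produced by an
#' external 3D pose estimator, with the frame interval and a per-frame
#' validity mask (FALSE where tracking failed: occlusion, blur, low
#' resolution).
#'
#' @param positions numeric matrix `F x 3` in meters.
#' @param dt seconds per frame (default 1/46, a common video frame
#'   interval for pose pipelines).
#' @param joint_name one of [pose_joint_names()].
#' @param valid logical vector length F; default all TRUE.
#' @return An object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(positions, dt = 1 / 46, joint_name = "left_wrist",
                             valid = NULL) {
  positions <- as.matrix(positions)
  F_ <- nrow(positions)
  if (F_ < 3L) stop("trajectory needs at least 3 frames")
  if (ncol(positions) != 3L) stop("positions must be F x 3")
  if (dt <= 0) stop("dt must be positive")
  if (is.null(valid)) valid <- rep(TRUE, F_)
  stopifnot(length(valid) == F_)
  if (any(valid & !apply(is.finite(positions), 1, all))) {
    stop("non-finite position at a frame marked valid")
  }
  if (!joint_name %in% pose_joint_names()) {
    stop("unknown joint '", joint_name, "'")
  }
  structure(list(positions = positions, dt = dt, joint_name = joint_name,
                 valid = as.logical(valid)),
            class = "joint_trajectory")
}

#' Quality-control policy for pose trajectories
#'
#' @param max_gap_frames longest run of invalid frames that may be
#'   interpolated over; longer gaps reject the clip.
#' @param min_valid_fraction minimum fraction of validly tracked frames.
#' @param smoothing_window odd moving-average width (frames).
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(max_gap_frames = 3L, min_valid_fraction = 0.95,
                      smoothing_window = 5L) {
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L) {
    stop("smoothing_window must be an odd positive integer")
  }
  stopifnot(max_gap_frames >= 0L,
            min_valid_fraction > 0, min_valid_fraction <= 1)
  structure(list(max_gap_frames = as.integer(max_gap_frames),
                 min_valid_fraction = min_valid_fraction,
                 smoothing_window = smoothing_window),
            class = "qc_policy")
}

#' Occlusion QC and gap filling
#'
#' Rejects clips whose joint was not reliably tracked — valid fraction
#' under `min_valid_fraction`, or any invalid run longer than
#' `max_gap_frames`, or invalid endpoints (nothing to anchor the
#' interpolation) — and linearly interpolates the surviving interior gaps,
#' returning a fully valid trajectory.
#'
#' @param traj a [joint_trajectory()].
#' @param policy a [qc_policy()].
#' @return A fully valid `joint_trajectory`. Errors name the violated rule.
#' @export
qc_and_fill <- function(traj, policy = qc_policy()) {
  v <- traj$valid
  frac <- mean(v)
  if (frac < policy$min_valid_fraction) {
    stop(sprintf("QC reject: valid fraction %.3f < %.3f", frac,
                 policy$min_valid_fraction))
  }
  if (!v[1] || !v[length(v)]) stop("QC reject: clip starts or ends untracked")
  r <- rle(v)
  gaps <- r$lengths[!r$values]
  if (length(gaps) && max(gaps) > policy$max_gap_frames) {
    stop(sprintf("QC reject: occlusion gap of %d frames exceeds max_gap_frames=%d",
                 max(gaps), policy$max_gap_frames))
  }
  p <- traj$positions
  if (any(!v)) {
    idx <- which(v)
    for (a in 1:3) {
      p[, a] <- stats::approx(idx, p[idx, a], xout = seq_len(nrow(p)))$y
    }
  }
  joint_trajectory(p, traj$dt, traj$joint_name, rep(TRUE, nrow(p)))
}

#' Temporal smoothing of a trajectory
#'
#' Centered moving average per axis over `window` frames, correcting minor
#' tracking discontinuities before differentiation (which amplifies
#' high-frequency estimation noise quadratically). Near the edges the
#' window shrinks symmetrically; `window = 1` is the identity.
#'
#' @param traj a fully valid [joint_trajectory()].
#' @param window odd positive integer, `window <= F`.
#' @return The smoothed `joint_trajectory`.
#' @export
smooth_trajectory <- function(traj, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  F_ <- nrow(traj$positions)
  if (window > F_) stop("smoothing window exceeds clip length")
  if (window == 1L) return(traj)
  h <- window %/% 2L
  p <- traj$positions
  out <- p
  for (i in seq_len(F_)) {
    k <- min(h, i - 1L, F_ - i)         # shrink symmetrically at edges
    out[i, ] <- colMeans(p[(i - k):(i + k), , drop = FALSE])
  }
  joint_trajectory(out, traj$dt, traj$joint_name, traj$valid)
}

#' Acceleration from joint positions by discrete second differences
#'
#' Differentiates a joint's 3D position twice in time — velocity from
#' position changes, acceleration from velocity changes — via the central
#' second difference `a(f) = (p(f+1) - 2 p(f) + p(f-1)) / dt^2`, evaluated
#' independently per axis at interior frames. The result is a virtual
#' accelerometer stream at that joint: `F - 2` samples in m/s^2 at rate
#' `1/dt`.
#'
#' @param traj a fully valid [joint_trajectory()] with F >= 3.
#' @param subject_id,activity metadata for the resulting trial.
#' @param scale multiplier applied to positions before differentiation,
#'   for pose estimators that do not emit meters.
#' @return A [trial()] of length `F - 2`.
#' @export
acceleration_from_positions <- function(traj, subject_id = "pose",
                                        activity = "fall_video", scale = 1) {
  p <- traj$positions * scale
  F_ <- nrow(p)
  if (F_ < 3L) stop("need at least 3 frames to form a second difference")
  if (any(!traj$valid)) stop("trajectory must be fully valid (run qc_and_fill first)")
  a <- (p[3:F_, , drop = FALSE] - 2 * p[2:(F_ - 1L), , drop = FALSE] +
          p[1:(F_ - 2L), , drop = FALSE]) / traj$dt^2
  trial(a, rate_hz = 1 / traj$dt, subject_id = subject_id, activity = activity)
}

#' Extract a fall trial from a pose trajectory
#'
#' Crops the clip to the annotated fall frames plus a margin (clamped to
#' the clip bounds), then runs the QC -> smoothing -> second-difference
#' pipeline and maps the fall range into the cropped, differentiated index
#' space as the trial's fall interval.
#'
#' @param traj a [joint_trajectory()].
#' @param fall_frame_range length-2 `(start, end)` half-open 0-based frame
#'   interval of the fall.
#' @param margin_s seconds of context kept on each side (default 1.5).
#' @param policy a [qc_policy()].
#' @param subject_id metadata for the resulting trial.
#' @param scale position scale factor, as in
#'   [acceleration_from_positions()].
#' @return A [trial()] with one fall interval, or an error if QC rejects
#'   the clip.
#' @export
extract_fall_trial <- function(traj, fall_frame_range, margin_s = 1.5,
                               policy = qc_policy(), subject_id = "pose",
                               scale = 1) {
  F_ <- nrow(traj$positions)
  fs <- as.integer(fall_frame_range[1]); fe <- as.integer(fall_frame_range[2])
  if (fs < 0L || fe > F_ || fs >= fe) stop("fall_frame_range out of bounds")
  m <- as.integer(round(margin_s / traj$dt))
  c0 <- max(0L, fs - m); c1 <- min(F_, fe + m)
  cropped <- joint_trajectory(traj$positions[(c0 + 1L):c1, , drop = FALSE],
                              traj$dt, traj$joint_name,
                              traj$valid[(c0 + 1L):c1])
  cleaned <- qc_and_fill(cropped, policy)
  smoothed <- smooth_trajectory(cleaned, policy$smoothing_window)
  tr <- acceleration_from_positions(smoothed, subject_id = subject_id,
                                    activity = "fall_video", scale = scale)
  # frame f maps to accel sample f-1 (interior frames); clamp to output range
  L <- nrow(tr$samples)
  i0 <- as.integer(min(max(0L, fs - c0 - 1L), L - 1L))
  i1 <- as.integer(max(min(L, fe - c0 - 1L), i0 + 1L))
  tr$fall_intervals <- list(c(i0, i1))
  validate_trial(tr)
  tr
}

#' Read keypoint clips from delimited text
#'
#' Reads a CSV with one row per frame and columns `<joint>_{x,y,z}` (and
#' optionally `<joint>_valid`) for the 17 standard joints, returning the
#' trajectory of one requested joint.
#'
#' @param path CSV path.
#' @param joint_name joint to extract.
#' @param fps frames per second of the clip.
#' @return A [joint_trajectory()].
#' @export
read_keypoints <- function(path, joint_name = "left_wrist", fps = 46) {
  df <- utils::read.csv(path)
  cols <- paste0(joint_name, "_", c("x", "y", "z"))
  if (!all(cols %in% names(df))) {
    stop("keypoint file lacks columns for joint '", joint_name, "'")
  }
  vcol <- paste0(joint_name, "_valid")
  valid <- if (vcol %in% names(df)) as.logical(df[[vcol]]) else NULL
  joint_trajectory(as.matrix(df[, cols]), dt = 1 / fps,
                   joint_name = joint_name, valid = valid)
}
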