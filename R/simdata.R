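#' Simulator configuration
#'
#' Study conditions for the built-in signal simulator, which emulates the
#' structure of wearable fall datasets: activities of daily living (ADL)
#' as gravity projection plus gait-like oscillation and band-limited noise,
#' and falls as ADL prefix -> free-fall dip (acceleration magnitude drops
#' toward zero apparent weight) -> impact spike -> quiescent lying period.
#'
#' Defaults: 32 Hz sampling (so a 128-sample window spans ~4 s), ADL
#' amplitude 2 m/s^2 around the 9.81 m/s^2 gravity baseline, impact peaks
#' of 20-35 m/s^2, free-fall dips below 3 m/s^2 for 0.35 s, and a
#' per-subject amplitude multiplier with 0.15 spread. Fall trials at
#' default settings are separable from ADL trials by peak magnitude.
#'
#' @param rate_hz sampling rate.
#' @param n_subjects,trials_per_subject corpus size.
#' @param fall_fraction fraction of trials that are falls, in [0, 1].
#' @param adl_amp amplitude of ADL motion around gravity, m/s^2.
#' @param impact_amp_range length-2 `(lo, hi)` of impact peak magnitudes,
#'   m/s^2; `lo` must exceed any ADL magnitude.
#' @param freefall_floor magnitude bound the free-fall dip stays under, m/s^2.
#' @param freefall_dur_s,impact_dur_s phase durations, seconds.
#' @param adl_dur_range_s length-2 range of ADL trial durations, seconds.
#' @param subject_var spread of the per-subject amplitude multiplier.
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rate_hz = 32, n_subjects = 10L, trials_per_subject = 4L,
                       fall_fraction = 0.1, adl_amp = 2,
                       impact_amp_range = c(20, 35), freefall_floor = 3,
                       freefall_dur_s = 0.35, impact_dur_s = 0.3,
                       adl_dur_range_s = c(8, 20), subject_var = 0.15,
                       seed = 1L) {
  stopifnot(rate_hz > 0, length(impact_amp_range) == 2L,
            impact_amp_range[1] > adl_amp, freefall_floor < 9.81,
            freefall_dur_s > 0, impact_dur_s > 0, subject_var >= 0)
  if (fall_fraction < 0 || fall_fraction > 1) stop("fall_fraction must lie in [0, 1]")
  structure(list(rate_hz = rate_hz, n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 fall_fraction = fall_fraction, adl_amp = adl_amp,
                 impact_amp_range = impact_amp_range,
                 freefall_floor = freefall_floor,
                 freefall_dur_s = freefall_dur_s, impact_dur_s = impact_dur_s,
                 adl_dur_range_s = adl_dur_range_s,
                 subject_var = subject_var, seed = as.integer(seed)),
            class = "sim_config")
}

# unit gravity direction with small random tilt from "device flat" (z up)
random_gravity_dir <- function(tilt_sd = 0.15) {
  v <- c(stats::rnorm(2, 0, tilt_sd), 1)
  v / sqrt(sum(v^2))
}

# band-limited noise: moving-average-smoothed white noise, sd ~ scale
smoothed_noise <- function(n, scale, k = 5L) {
  if (scale <= 0) return(numeric(n))
  w <- stats::rnorm(n + k - 1L)
  sm <- stats::filter(w, rep(1 / k, k), sides = 1)
  scale * as.numeric(sm[k:(n + k - 1L)]) * sqrt(k)
}

# ADL segment: gravity projection + gait oscillation + band-limited noise
adl_segment <- function(n, cfg, mult, gdir) {
  amp <- cfg$adl_amp * mult
  t <- seq_len(n) / cfg$rate_hz
  f <- stats::runif(1, 1.5, 2.1)              # gait cadence, Hz
  ph <- stats::runif(3, 0, 2 * pi)
  ax_amp <- amp * stats::runif(3, 0.4, 1)
  osc <- sapply(1:3, function(a) ax_amp[a] * sin(2 * pi * f * t + ph[a]))
  noise <- sapply(1:3, function(a) smoothed_noise(n, 0.15 * amp))
  sweep(osc + noise, 2, 9.81 * gdir, `+`)
}

# dominant impact direction per fall type (unit vectors)
fall_axis_pattern <- function(fall_type) {
  v <- switch(fall_type,
              front      = c(0.85, 0.10, 0.52),
              back       = c(-0.85, -0.10, 0.52),
              left       = c(0.10, -0.90, 0.42),
              right      = c(0.10, 0.90, 0.42),
              rotational = c(0.58, 0.58, 0.58),
              stop("unknown fall type: ", fall_type))
  v / sqrt(sum(v^2))
}

#' Simulate an activity-of-daily-living trial
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject identifier.
#' @param seed optional integer seed.
#' @param mult per-subject amplitude multiplier (drawn by
#'   [simulate_corpus()]; default 1).
#' @return A [trial()] with empty fall intervals.
#' @export
simulate_adl <- function(cfg = sim_config(), subject_id = "S1", seed = NULL,
                         mult = 1) {
  run <- function() {
    dur <- stats::runif(1, cfg$adl_dur_range_s[1], cfg$adl_dur_range_s[2])
    n <- max(1L, round(dur * cfg$rate_hz))
    gdir <- random_gravity_dir()
    trial(adl_segment(n, cfg, mult, gdir), cfg$rate_hz, subject_id, "adl")
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Simulate a fall trial
#'
#' Structure: ~2 s of ADL motion, a free-fall dip where the acceleration
#' magnitude drops below `freefall_floor` (the body is near-unsupported,
#' apparent weight approaches zero), an impact spike with peak magnitude in
#' `impact_amp_range` along the axis pattern of `fall_type`, and ~1.5 s of
#' quiescent lying. The labeled fall interval spans from shortly before
#' the dip to shortly after the impact, the way bench datasets label fall
#' onset through post-impact.
#'
#' @inheritParams simulate_adl
#' @param fall_type one of `"front"`, `"back"`, `"left"`, `"right"`,
#'   `"rotational"`.
#' @return A [trial()] with one fall interval.
#' @export
simulate_fall <- function(cfg = sim_config(), subject_id = "S1",
                          fall_type = "front", seed = NULL, mult = 1) {
  run <- function() {
    r <- cfg$rate_hz
    n_pre <- round(2.0 * r); n_dip <- round(cfg$freefall_dur_s * r)
    n_imp <- round(cfg$impact_dur_s * r); n_post <- round(1.5 * r)
    gdir <- random_gravity_dir()
    pre <- adl_segment(n_pre, cfg, mult, gdir)
    # free-fall: magnitude well under the floor, small residual limb motion
    dip_dir <- random_gravity_dir(0.3)
    dip_mag <- stats::runif(n_dip, 0.1, 0.3) * cfg$freefall_floor
    dip <- dip_mag * matrix(dip_dir, n_dip, 3, byrow = TRUE) +
      matrix(stats::rnorm(n_dip * 3, 0, 0.05 * cfg$freefall_floor), n_dip, 3)
    peak <- stats::runif(1, cfg$impact_amp_range[1], cfg$impact_amp_range[2])
    idir <- fall_axis_pattern(fall_type)
    # half-sine impact pulse rising from ~gravity to the peak and back
    pulse <- sin(pi * (seq_len(n_imp) - 0.5) / n_imp)
    imp <- (9.81 + (peak - 9.81) * pulse) * matrix(idir, n_imp, 3, byrow = TRUE)
    if (fall_type == "rotational") {
      # tumbling: impact direction precesses during the pulse
      ang <- seq(0, pi, length.out = n_imp)
      for (i in seq_len(n_imp)) {
        Rz <- rotation_about_axis(c(0, 0, 1), ang[i])
        imp[i, ] <- as.numeric(Rz %*% imp[i, ])
      }
    }
    lie_dir <- fall_axis_pattern(fall_type)      # resting on the impacted side
    post <- 9.81 * matrix(lie_dir, n_post, 3, byrow = TRUE) +
      matrix(stats::rnorm(n_post * 3, 0, 0.05), n_post, 3)
    samples <- rbind(pre, dip, imp, post)
    s0 <- max(0L, n_pre - round(0.5 * r))
    s1 <- min(nrow(samples), n_pre + n_dip + n_imp + round(1.0 * r))
    trial(samples, r, subject_id, paste0("fall_", fall_type),
          fall_intervals = list(c(s0, s1)))
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Simulate a corpus of trials across subjects
#'
#' Generates `n_subjects x trials_per_subject` trials with the configured
#' fall fraction. Each subject receives an amplitude multiplier drawn once
#' from Gaussian(1, subject_var^2) (floored at 0.5); fall trials cycle
#' through the five fall types. Deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return A list of [trial()] objects, with the per-subject multipliers
#'   attached as attribute `"subject_multipliers"`.
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  if (cfg$fall_fraction < 0 || cfg$fall_fraction > 1) stop("fall_fraction must lie in [0, 1]")
  withr_seed(cfg$seed, {
    subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
    mult <- pmax(0.5, stats::rnorm(cfg$n_subjects, 1, cfg$subject_var))
    names(mult) <- subjects
    total <- cfg$n_subjects * cfg$trials_per_subject
    n_fall <- round(cfg$fall_fraction * total)
    # spread fall trials across subjects round-robin so several subjects own falls
    is_fall <- rep(FALSE, total)
    if (n_fall > 0) {
      slots <- (seq_len(n_fall) - 1L) * cfg$trials_per_subject %% total
      slots <- ((seq_len(n_fall) - 1L) %% cfg$n_subjects) * cfg$trials_per_subject +
        ((seq_len(n_fall) - 1L) %/% cfg$n_subjects) + 1L
      is_fall[slots] <- TRUE
    }
    types <- c("front", "back", "left", "right", "rotational")
    trials <- vector("list", total)
    k_fall <- 0L
    for (i in seq_len(total)) {
      s_idx <- (i - 1L) %/% cfg$trials_per_subject + 1L
      sid <- subjects[s_idx]
      if (is_fall[i]) {
        k_fall <- k_fall + 1L
        trials[[i]] <- simulate_fall(cfg, sid, types[(k_fall - 1L) %% 5L + 1L],
                                     mult = mult[s_idx])
      } else {
        trials[[i]] <- simulate_adl(cfg, sid, mult = mult[s_idx])
      }
    }
    attr(trials, "subject_multipliers") <- mult
    trials
  })
}

#' Simulate a 3D pose clip with a fall (keypoint fixture)
#'
#' Produces a 17-joint keypoint table emulating the output of a video 3D
#' pose estimator watching a fall: gentle swaying, then a parabolic drop of
#' the whole skeleton under gravity, then an abrupt deceleration (impact)
#' and stillness. Used to exercise the pose-to-acceleration pathway
#' without any video processing.
#'
#' @param fps frames per second (default 46).
#' @param sway_s,drop_s,still_s phase durations in seconds.
#' @param drop_height height of the fall in meters.
#' @param occlude_frames integer vector of frame indices (1-based) whose
#'   `left_wrist` validity flag is cleared, emulating occlusion.
#' @param seed integer seed.
#' @return A data.frame with columns `<joint>_{x,y,z}` and
#'   `<joint>_valid` for the 17 standard joints, plus attributes
#'   `"fps"` and `"fall_frames"` (1-based first/last frame of the drop).
#' @export
simulate_pose_clip <- function(fps = 46, sway_s = 1.5, drop_s = 0.45,
                               still_s = 1.5, drop_height = 1.0,
                               occlude_frames = integer(0), seed = 1L) {
  withr_seed(seed, {
    joints <- pose_joint_names()
    n_sway <- round(sway_s * fps); n_drop <- round(drop_s * fps)
    n_still <- round(still_s * fps)
    n <- n_sway + n_drop + n_still
    t_drop <- (seq_len(n_drop)) / fps
    # vertical profile shared by the skeleton: sway ~ still, then 1/2 g t^2 drop
    drop_z <- pmin(drop_height, 0.5 * 9.81 * t_drop^2)
    base_z <- c(rep(0, n_sway), -drop_z, rep(-max(drop_z), n_still))
    sway_x <- 0.02 * sin(2 * pi * 0.5 * seq_len(n) / fps)
    out <- data.frame(row.names = seq_len(n))
    for (j in joints) {
      off <- stats::runif(3, -0.3, 0.3)   # fixed offset of this joint from pelvis
      out[[paste0(j, "_x")]] <- off[1] + sway_x + stats::rnorm(n, 0, 0.002)
      out[[paste0(j, "_y")]] <- off[2] + stats::rnorm(n, 0, 0.002)
      out[[paste0(j, "_z")]] <- off[3] + base_z + stats::rnorm(n, 0, 0.002)
      valid <- rep(TRUE, n)
      if (j == "left_wrist" && length(occlude_frames)) valid[occlude_frames] <- FALSE
      out[[paste0(j, "_valid")]] <- valid
    }
    attr(out, "fps") <- fps
    attr(out, "fall_frames") <- c(n_sway + 1L, n_sway + n_drop)
    out
  })
}

#' Names of the 17 skeleton joints
#'
#' The joint set produced by standard 3D pose estimators (COCO-style plus
#' pelvis/spine), used to address columns in keypoint files.
#' @return Character vector of length 17.
#' @export
pose_joint_names <- function() {
  c("pelvis", "left_hip", "right_hip", "spine", "left_knee", "right_knee",
    "thorax", "left_ankle", "right_ankle", "neck", "head", "left_shoulder",
    "right_shoulder", "left_elbow", "right_elbow", "left_wrist", "right_wrist")
}
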