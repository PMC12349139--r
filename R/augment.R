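#' Augmentation configuration
#'
#' Bundles the parameters of the three classic IMU augmentations. The
#' defaults are conventional values for accelerometer augmentation: jitter
#' noise well below impact amplitudes, a gentle 4-knot magnitude warp, and
#' rotations within 30 degrees of the recorded orientation.
#'
#' @param jitter_sigma standard deviation of additive Gaussian noise, m/s^2.
#' @param warp_knots number of spline knots (>= 2, endpoints included).
#' @param warp_sigma spread of knot scaling factors around 1.
#' @param rot_max_deg maximum rotation angle magnitude, degrees, in [0, 180].
#' @param per_axis_warp draw an independent warp curve per axis? Default
#'   `FALSE`: one shared curve preserves inter-axis amplitude ratios.
#' @param seed integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(jitter_sigma = 0.3, warp_knots = 4L, warp_sigma = 0.2,
                           rot_max_deg = 30, per_axis_warp = FALSE, seed = 1L) {
  stopifnot(jitter_sigma >= 0, warp_knots >= 2L, warp_sigma >= 0,
            rot_max_deg >= 0, rot_max_deg <= 180)
  structure(list(jitter_sigma = jitter_sigma, warp_knots = as.integer(warp_knots),
                 warp_sigma = warp_sigma, rot_max_deg = rot_max_deg,
                 per_axis_warp = per_axis_warp, seed = as.integer(seed)),
            class = "augment_config")
}

#' Jittering: additive Gaussian noise
#'
#' Adds iid Gaussian noise of standard deviation `sigma` to every element,
#' simulating sensor noise and small real-world perturbations while
#' preserving the core temporal pattern.
#'
#' @param window numeric matrix `W x 3` (works for any `L x 3` signal).
#' @param sigma noise standard deviation in m/s^2 (>= 0).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A matrix of the same shape.
#' @export
jitter <- function(window, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  window <- as.matrix(window)
  if (sigma == 0) return(window)
  noise <- if (is.null(seed)) stats::rnorm(length(window), 0, sigma) else
    withr_seed(seed, stats::rnorm(length(window), 0, sigma))
  window + matrix(noise, nrow(window), ncol(window))
}

#' Magnitude warping: smooth amplitude modulation
#'
#' Draws scaling factors ~ Gaussian(1, sigma^2) at `knots` equally spaced
#' time points (endpoints included), interpolates them with a natural cubic
#' spline over the window, and multiplies the signal by the resulting
#' smooth curve. With `per_axis = FALSE` a single curve is shared by all
#' three axes.
#'
#' @param window numeric matrix `W x 3`, `W >= 4`.
#' @param knots number of knots (>= 2).
#' @param sigma knot-value spread around 1 (>= 0).
#' @param per_axis independent curve per axis?
#' @param seed optional integer seed.
#' @param knot_values test hook: matrix `knots x 3` (or vector length
#'   `knots`) of fixed knot values, bypassing the random draw.
#' @return A matrix of the same shape.
#' @export
magnitude_warp <- function(window, knots = 4L, sigma = 0.2, per_axis = FALSE,
                           seed = NULL, knot_values = NULL) {
  window <- as.matrix(window)
  W <- nrow(window)
  if (W < 4L) stop("magnitude warping needs W >= 4 (cubic spline underdetermined)")
  knots <- as.integer(knots)
  if (knots < 2L) stop("need at least 2 knots")
  if (sigma < 0) stop("sigma must be non-negative")
  kx <- seq(0, W - 1L, length.out = knots)
  draw <- function(n) stats::rnorm(n, mean = 1, sd = sigma)
  if (is.null(knot_values)) {
    vals <- if (is.null(seed)) {
      if (per_axis) matrix(draw(knots * 3L), knots, 3L) else matrix(draw(knots), knots, 3L)
    } else withr_seed(seed, {
      if (per_axis) matrix(draw(knots * 3L), knots, 3L) else matrix(draw(knots), knots, 3L)
    })
  } else {
    kv <- if (is.matrix(knot_values)) knot_values else matrix(knot_values, knots, 3L)
    vals <- kv
  }
  t_out <- seq_len(W) - 1L
  curve <- sapply(1:3, function(a) {
    if (knots == 2L) {
      # two knots: spline degenerates to the connecting line
      stats::approx(kx, vals[, a], xout = t_out)$y
    } else {
      stats::spline(kx, vals[, a], xout = t_out, method = "natural")$y
    }
  })
  window * curve
}

#' Random 3D rotation matrix
#'
#' Draws a proper rotation (orthogonal, determinant +1) about a uniformly
#' random axis by an angle ~ Uniform(-max_deg, +max_deg), via the Rodrigues
#' formula. Used to mimic alternative sensor placements/orientations.
#'
#' @param max_deg maximum angle magnitude in degrees, in [0, 180].
#' @param seed optional integer seed.
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function(max_deg = 30, seed = NULL) {
  if (max_deg < 0 || max_deg > 180) stop("max_deg must lie in [0, 180]")
  if (max_deg == 0) return(diag(3))
  draw <- function() {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, -max_deg, max_deg) * pi / 180
    list(ax = ax, th = th)
  }
  d <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  rotation_about_axis(d$ax, d$th)
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation matrix for axis `axis` (normalized internally) and
#' angle `theta` in radians.
#'
#' @param axis length-3 numeric axis.
#' @param theta angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotate a window by a rotation matrix
#'
#' Maps every sample vector by `R`, preserving the per-sample Euclidean
#' norm (the physically meaningful invariant of re-orientation). Labels
#' are unaffected by contract: rotation simulates a different placement of
#' the same event.
#'
#' @param window numeric matrix `W x 3`.
#' @param R 3x3 rotation matrix (orthogonality is checked).
#' @return The rotated `W x 3` matrix.
#' @export
rotate <- function(window, R) {
  R <- as.matrix(R)
  if (any(dim(R) != c(3L, 3L)) || max(abs(crossprod(R) - diag(3))) > 1e-8) {
    stop("R must be a 3x3 orthogonal rotation matrix")
  }
  as.matrix(window) %*% t(R)
}

#' Augment a set of fall windows with a classic method
#'
#' Applies one of the three augmentations to every window in `x`,
#' `copies` times, producing a pool of synthetic fall windows for
#' [balance_with_synthetic()]. Rotation draws one rotation per source
#' window copy.
#'
#' @param x `windowed_dataset` of real fall windows (label 1).
#' @param method `"jitter"`, `"magnitude_warp"` or `"rotation"`.
#' @param cfg an [augment_config()].
#' @param copies how many augmented copies of the pool to generate.
#' @return A `windowed_dataset` with provenance `"synthetic"`.
#' @export
augment_windows <- function(x, method = c("jitter", "magnitude_warp", "rotation"),
                            cfg = augment_config(), copies = 1L) {
  method <- match.arg(method)
  stopifnot(n_windows(x) > 0L, copies >= 1L)
  withr_seed(cfg$seed, {
    n <- n_windows(x)
    out <- array(0, dim = c(n * copies, dim(x$windows)[2], 3L))
    for (cpy in seq_len(copies)) {
      for (i in seq_len(n)) {
        w <- x$windows[i, , ]
        out[(cpy - 1L) * n + i, , ] <- switch(
          method,
          jitter = jitter(w, cfg$jitter_sigma),
          magnitude_warp = magnitude_warp(w, cfg$warp_knots, cfg$warp_sigma,
                                          per_axis = cfg$per_axis_warp),
          rotation = rotate(w, random_rotation(cfg$rot_max_deg)))
      }
    }
    windowed_dataset(out, rep(x$labels, copies),
                     rep(x$subjects, copies),
                     rep("synthetic", n * copies))
  })
}
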