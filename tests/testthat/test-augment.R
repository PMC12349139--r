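test_that("jitter is exact identity at sigma = 0 and calibrated otherwise", {
  w <- matrix(rnorm(128 * 3), 128, 3)
  expect_identical(jitter(w, 0), w)
  expect_error(jitter(w, -1), "non-negative")
  # pooled noise sd over ~1e5 elements
  big <- matrix(0, 34000, 3)
  out <- jitter(big, 1, seed = 7)
  expect_gt(stats::sd(out - big), 0.99)
  expect_lt(stats::sd(out - big), 1.01)
  expect_identical(jitter(w, 0.5, seed = 3), jitter(w, 0.5, seed = 3))
})

test_that("magnitude warp scales by the spline through the drawn knots", {
  w <- matrix(rnorm(128 * 3) + 5, 128, 3)
  expect_equal(magnitude_warp(w, 4, 0, seed = 1), w)       # sigma 0 -> knots all 1
  expect_equal(magnitude_warp(w, 4, 0.3, knot_values = rep(2, 4)), 2 * w)
  # spline interpolates the knot values exactly at knot positions
  kv <- matrix(c(0.8, 1.1, 1.3, 0.9), 4, 3)
  out <- magnitude_warp(w, 4, 0.3, knot_values = kv)
  kx <- round(seq(0, 127, length.out = 4)) + 1
  # endpoints are exact knot positions; interior knots of seq(0,127,length=4)
  # are non-integer, so check the exact endpoints and the continuity of ratio
  expect_equal(out[1, ] / w[1, ], rep(0.8, 3), tolerance = 1e-9)
  expect_equal(out[128, ] / w[128, ], rep(0.9, 3), tolerance = 1e-9)
  ratio <- out[, 1] / w[, 1]
  expect_equal(ratio, out[, 2] / w[, 2], tolerance = 1e-9)  # shared curve
  # sigma -> 0 converges to identity
  out2 <- magnitude_warp(w, 4, 1e-8, seed = 2)
  expect_lt(max(abs(out2 - w)), 1e-6)
  expect_error(magnitude_warp(w[1:3, ], 4, 0.1), "W >= 4")
})

test_that("warp knot interpolation matches an independent spline evaluation", {
  w <- matrix(1, 64, 3)                      # unit signal: output IS the curve
  kv <- matrix(c(1.2, 0.7, 1.5, 1.0, 0.85), 5, 3)
  out <- magnitude_warp(w, 5, 0.3, knot_values = kv)
  oracle <- stats::spline(seq(0, 63, length.out = 5), kv[, 1], xout = 0:63,
                          method = "natural")$y
  expect_equal(out[, 1], oracle, tolerance = 1e-9)
})

test_that("random rotations are proper rotations with bounded angle", {
  expect_equal(random_rotation(0), diag(3))
  set.seed(5)
  for (i in 1:100) {
    R <- random_rotation(30)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    # angle from trace stays within the bound
    ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    expect_lte(ang, 30 + 1e-6)
  }
  expect_error(random_rotation(200), "max_deg")
})

test_that("a half-turn about z negates x and y", {
  R <- rotation_about_axis(c(0, 0, 1), pi)
  expect_equal(as.numeric(R %*% c(1, 2, 3)), c(-1, -2, 3), tolerance = 1e-9)
})

test_that("rotate preserves per-sample norms and round-trips", {
  w <- matrix(rnorm(128 * 3), 128, 3)
  expect_equal(rotate(w, diag(3)), w)
  R <- random_rotation(170, seed = 9)
  out <- rotate(w, R)
  expect_equal(sqrt(rowSums(out^2)), sqrt(rowSums(w^2)), tolerance = 1e-9)
  expect_equal(rotate(out, t(R)), w, tolerance = 1e-9)     # inverse rotation
  expect_error(rotate(w, matrix(1, 3, 3)), "orthogonal")
})

test_that("augment_windows preserves shape and labels for all three methods", {
  wd <- fix_fall_windows()
  for (m in c("jitter", "magnitude_warp", "rotation")) {
    out <- augment_windows(wd, m, augment_config(seed = 4), copies = 2)
    expect_equal(dim(out$windows), c(2L * n_windows(wd), 128L, 3L))
    expect_equal(out$labels, rep(wd$labels, 2))
    expect_true(all(out$provenance == "synthetic"))
    out2 <- augment_windows(wd, m, augment_config(seed = 4), copies = 2)
    expect_identical(out$windows, out2$windows)            # seeded determinism
  }
})
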