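ns <- asNamespace("fallsynth")

test_that("padded length is the least multiple of 8 covering L_max", {
  for (L in 1:200) {
    expected <- 8L * ((L + 7L) %/% 8L)        # arithmetic oracle
    expect_equal(compute_new_length(L, 8L), expected)
  }
  expect_equal(compute_new_length(136L), 136L) # already a multiple
  expect_equal(compute_new_length(130L), 136L)
  expect_equal(compute_new_length(1L), 8L)
  expect_error(padding_spec(6L), "power of two")
})

test_that("padding repeats the last sample and round-trips through cropping", {
  t1 <- trial(matrix(rep(c(1, 2, 3), 3), 3, 3), 32)      # x=y=z=[1,2,3]
  pb <- pad_trials(list(t1), padding_spec())
  expect_equal(pb$L_new, 8L)
  expect_equal(pb$data[1, , 1], c(1, 2, 3, 3, 3, 3, 3, 3))
  # a trial already at L_new is unchanged
  t2 <- trial(matrix(rnorm(24), 8, 3), 32)
  pb2 <- pad_trials(list(t2))
  expect_equal(pb2$data[1, , ], t2$samples)
  # crop recovers every trial elementwise
  set.seed(1)
  trials <- lapply(c(5, 11, 16), function(L)
    trial(matrix(rnorm(L * 3), L, 3), 32))
  cropped <- crop_to_original(pad_trials(trials))
  for (i in seq_along(trials)) {
    expect_equal(cropped[[i]], trials[[i]]$samples)
  }
  expect_error(pad_trials(list()), "empty")
})

test_that("the noise schedule matches a brute-force cumulative product", {
  cfg <- diffusion_config(timesteps = 57L, beta_start = 1e-4, beta_end = 0.02)
  sch <- noise_schedule(cfg)
  expect_equal(sch$beta[1], 1e-4)
  expect_equal(sch$beta[57], 0.02)
  brute <- numeric(57)
  acc <- 1
  for (t in 1:57) { acc <- acc * (1 - sch$beta[t]); brute[t] <- acc }
  expect_equal(sch$alpha_bar, brute, tolerance = 1e-15)
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_gt(sch$alpha_bar[1], 0.999)
})

test_that("forward diffusion obeys its closed form at both extremes", {
  cfg <- diffusion_config(timesteps = 300L)
  sch <- noise_schedule(cfg)
  set.seed(2)
  x0 <- array(rnorm(40000), c(50, 800))      # unit-scale data
  early <- forward_diffuse(x0, 0L, sch, seed = 3)
  expect_lt(sqrt(sum((early$xt - x0)^2)) / sqrt(sum(x0^2)), 0.02)
  late <- forward_diffuse(x0, 299L, sch, seed = 4)
  expect_lt(abs(mean(late$xt)), 0.02)
  expect_lt(abs(stats::sd(late$xt) - 1), 0.02)
  # the returned eps is exactly the noise used
  ab <- sch$alpha_bar[300]
  expect_equal(late$xt, sqrt(ab) * x0 + sqrt(1 - ab) * late$eps)
  expect_identical(forward_diffuse(x0, 10L, sch, seed = 5)$xt,
                   forward_diffuse(x0, 10L, sch, seed = 5)$xt)
  expect_error(forward_diffuse(x0, 300L, sch), "out of range")
})

tiny_falls <- function(n = 6L) {
  fixture("tiny_falls", function() {
    cfg <- sim_config()
    lapply(seq_len(n), function(i)
      simulate_fall(cfg, "S1", fall_types[(i - 1) %% 5 + 1], seed = 40 + i))
  })
}

test_that("a smoke training run completes with finite, reproducible losses", {
  cfg <- tiny_dcfg(epochs = 3L, seed = 11)
  m <- train_ddpm(tiny_falls(), cfg)
  expect_true(all(is.finite(m$loss_curve)))
  expect_length(m$loss_curve, 3L)
  m2 <- train_ddpm(tiny_falls(), cfg)
  expect_identical(m$loss_curve, m2$loss_curve)   # seed governs everything
  expect_error(train_ddpm(tiny_falls()[1], cfg), "at least 2")
})

test_that("sampling crops to training lengths and stays finite", {
  cfg <- tiny_dcfg(epochs = 2L, seed = 12)
  m <- train_ddpm(tiny_falls(), cfg)
  s <- sample_ddpm(m, 5L, seed = 3)
  expect_length(s, 5L)
  lens <- vapply(s, function(t) nrow(t$samples), integer(1))
  expect_true(all(lens %in% m$lengths))
  for (t in s) {
    expect_true(all(is.finite(t$samples)))
    expect_equal(t$subject_id, "synthetic")
    expect_equal(t$fall_intervals[[1]], c(0L, nrow(t$samples)))
  }
  expect_identical(sample_ddpm(m, 2L, seed = 9)[[1]]$samples,
                   sample_ddpm(m, 2L, seed = 9)[[1]]$samples)
  expect_error(sample_ddpm(m, 0L), "positive")
})

test_that("checkpoints round-trip through write_ddpm/read_ddpm", {
  cfg <- tiny_dcfg(epochs = 1L, seed = 13)
  m <- train_ddpm(tiny_falls(), cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  write_ddpm(m, path)
  m2 <- read_ddpm(path)
  expect_equal(m2$params, m$params)
  expect_identical(sample_ddpm(m, 2L, seed = 1)[[1]]$samples,
                   sample_ddpm(m2, 2L, seed = 1)[[1]]$samples)
})
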