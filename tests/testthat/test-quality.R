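mk_windows <- function(arr, provenance = "real", labels = NULL) {
  n <- dim(arr)[1]
  windowed_dataset(arr, labels %||% rep(1L, n), rep("S1", n),
                   rep(provenance, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Jensen-Shannon divergence matches the hand-computed value", {
  # P=(1,0), Q=(0.5,0.5): JSD = 1 - 0.5*H2(0.25... ) computed by hand = 0.3113
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), 0.31128, tolerance = 1e-4)
  expect_equal(js_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)          # disjoint, base 2
})

test_that("jsd on windows: identical sets 0, disjoint supports 1, symmetric", {
  set.seed(1)
  a <- array(rnorm(40 * 32 * 3), c(40, 32, 3))
  wa <- mk_windows(a)
  expect_equal(jsd(wa, wa), 0)
  wb <- mk_windows(a + 100)                 # fully disjoint value ranges
  expect_equal(jsd(wa, wb), 1)
  wc <- mk_windows(array(rnorm(40 * 32 * 3, 0.5), c(40, 32, 3)))
  expect_equal(jsd(wa, wc), jsd(wc, wa))
  expect_error(jsd(wa, wc, bins = 1), "2 bins")
})

brute_ks <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  max(vapply(pool, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

test_that("KS D matches a brute-force ECDF scan and analytic shifts", {
  set.seed(2)
  # brute-force oracle on small pooled samples
  for (rep in 1:5) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    a <- array(rnorm(n1 * 8 * 3), c(n1, 8, 3))
    b <- array(rnorm(n2 * 8 * 3, 0.3), c(n2, 8, 3))
    ks <- ks_test(mk_windows(a), mk_windows(b))
    for (ax in 1:3) {
      expect_equal(ks$d_per_axis[ax],
                   brute_ks(as.numeric(a[, , ax]), as.numeric(b[, , ax])),
                   tolerance = 1e-12)
    }
    expect_equal(ks$dbar, mean(ks$d_per_axis))
  }
  # Uniform(0,1) vs Uniform(0.5,1.5): max CDF gap is 0.5
  u1 <- array(runif(3 * 12000), c(125, 96, 3))
  u2 <- array(runif(3 * 12000, 0.5, 1.5), c(125, 96, 3))
  ks2 <- ks_test(mk_windows(u1), mk_windows(u2))
  expect_true(all(abs(ks2$d_per_axis - 0.5) < 0.02))
  # identity and symmetry
  expect_equal(ks_test(mk_windows(u1), mk_windows(u1))$dbar, 0)
  expect_equal(ks_test(mk_windows(u1), mk_windows(u2))$dbar,
               ks_test(mk_windows(u2), mk_windows(u1))$dbar)
})

test_that("Frechet distance has the closed form d^2 for equal covariances", {
  set.seed(3)
  d <- 4L; n <- 500L
  z <- matrix(rnorm(n * d), n, d)
  # empirically whiten so the sample moments are exactly (0, I)
  z <- sweep(z, 2, colMeans(z))
  z <- z %*% solve(chol(stats::cov(z)))
  for (gap in c(0, 1, 2)) {
    shifted <- sweep(z, 2, c(gap, rep(0, d - 1)), `+`)
    expect_equal(frechet_distance(z, shifted), gap^2, tolerance = 1e-8)
  }
  expect_warning(frechet_distance(z[1:3, ], z), "rank-deficient")
})

test_that("context-FID is zero on itself and grows with mean shift", {
  wd <- fix_fall_windows()
  cfgE <- embedder_config(epochs = 4, seed = 2)
  f0 <- suppressWarnings(context_fid(wd, wd, cfgE))
  expect_lt(as.numeric(f0), 1e-6)
  emb <- attr(f0, "embedder")
  fids <- vapply(c(0, 0.5, 1, 2), function(s) {
    shifted <- wd
    shifted$windows <- shifted$windows + s * 3
    as.numeric(suppressWarnings(context_fid(wd, shifted, cfgE, embedder = emb)))
  }, numeric(1))
  expect_true(all(diff(fids) > 0))
})

test_that("discriminative score: indistinguishable ~ 0.5, separable ~ 1", {
  set.seed(4)
  base <- fix_adl_windows()
  n <- n_windows(base)
  half <- seq_len(n %/% 2)
  a <- subset_windows(base, half)
  b <- subset_windows(base, setdiff(seq_len(n), half))
  # real vs real (a split of one set): near-chance accuracy
  acc_rr <- discriminative_score(a, b, seed = 5, epochs = 4)
  expect_gte(acc_rr, 0.3)
  expect_lte(acc_rr, 0.7)
  # amplitude x10: trivially separable
  big <- a; big$windows <- big$windows * 10
  expect_gt(discriminative_score(a, big, seed = 5, epochs = 4), 0.9)
  expect_error(discriminative_score(subset_windows(a, 1:5), b), "20 windows")
})

test_that("predictive score: constants are perfectly predictable, TSTR ~ TRTR", {
  const <- mk_windows(array(7, c(25, 32, 3)))
  expect_lt(predictive_score(const, const, seed = 6, epochs = 2), 1e-6)
  wd <- fix_adl_windows()
  tstr <- predictive_score(wd, wd, seed = 7, epochs = 3)  # synth == real
  expect_gt(tstr, 0)
  # white-noise generator must forecast the structured signal worse
  wn <- wd
  set.seed(8)
  wn$windows <- array(rnorm(length(wd$windows), mean(wd$windows),
                            stats::sd(wd$windows)), dim(wd$windows))
  tstr_wn <- predictive_score(wd, wn, seed = 7, epochs = 3)
  expect_gt(tstr_wn, tstr)
  expect_error(predictive_score(wd, wd, horizon = 128L), "horizon")
})

test_that("distribution plots are written deterministically with three panels", {
  wd <- fix_fall_windows()
  synth <- wd; synth$windows <- synth$windows + 0.5
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  distribution_plot(wd, synth, p1)
  distribution_plot(wd, synth, p2)
  expect_true(file.exists(p1) && file.size(p1) > 1000)
  expect_equal(file.size(p1), file.size(p2))
})

test_that("evaluate_quality assembles a coherent report", {
  wd <- subset_windows(fix_adl_windows(), 1:60)
  synth <- wd
  synth$provenance <- rep("synthetic", n_windows(synth))
  rep <- suppressWarnings(
    evaluate_quality(wd, synth, embedder_config(epochs = 3), seed = 9))
  expect_s3_class(rep, "quality_report")
  expect_lt(rep$context_fid, 1e-6)
  expect_equal(rep$jsd, 0)
  expect_equal(rep$ks_dbar, 0)
  expect_gte(rep$discriminative, 0); expect_lte(rep$discriminative, 1)
  expect_gte(rep$predictive, 0)
})
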