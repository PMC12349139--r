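brute_force_starts <- function(L, W, step) {
  starts <- integer(0)
  s <- 0L
  while (s + W <= L) { starts <- c(starts, s); s <- s + step }
  starts
}

test_that("window count matches brute-force enumeration of start indices", {
  set.seed(42)
  for (i in 1:40) {
    W <- sample(2:120, 1)
    step <- sample(seq_len(W), 1)
    L <- sample(W:500, 1)
    tr <- trial(matrix(rnorm(L * 3), L, 3), 32)
    wd <- sliding_windows(tr, windowing_spec(W, step))
    expect_equal(n_windows(wd), length(brute_force_starts(L, W, step)),
                 info = sprintf("L=%d W=%d step=%d", L, W, step))
  }
  # the worked example: L=256, W=128, step=10 -> 13 windows
  wd <- sliding_windows(trial(matrix(0, 256, 3), 32), windowing_spec())
  expect_equal(n_windows(wd), 13L)
  expect_equal(n_windows(sliding_windows(trial(matrix(0, 128, 3), 32),
                                         windowing_spec())), 1L)
})

test_that("windows cover [i*step, i*step+W) and short trials error", {
  L <- 200L
  tr <- trial(matrix(seq_len(L), L, 3), 32)
  wd <- sliding_windows(tr, windowing_spec(64, 10))
  for (i in c(1, 5, n_windows(wd))) {
    s0 <- (i - 1) * 10
    expect_equal(wd$windows[i, , 1], as.numeric(s0 + 1:64))
  }
  expect_error(sliding_windows(trial(matrix(0, 100, 3), 32),
                               windowing_spec(128, 10)), "shorter than window")
})

test_that("window labels follow the overlap-fraction rule", {
  L <- 300L
  tr <- trial(matrix(0, L, 3), 32, fall_intervals = list(c(100, 228)))
  wd <- sliding_windows(tr, windowing_spec(128, 4, fall_overlap_threshold = 0.5))
  starts <- (seq_len(n_windows(wd)) - 1) * 4
  overlap <- pmax(0, pmin(starts + 128, 228) - pmax(starts, 100)) / 128
  expect_equal(wd$labels, as.integer(overlap >= 0.5))
  # fully inside -> 1, fully outside -> 0
  wd2 <- sliding_windows(trial(matrix(0, 300, 3), 32,
                               fall_intervals = list(c(0, 150))),
                         windowing_spec(128, 100))
  expect_equal(wd2$labels[1], 1L)   # [0,128) inside interval
  expect_equal(wd2$labels[2], 0L)   # [100,228): 50/128 overlap < 0.5... guard below
  expect_lt(50 / 128, 0.5)
})

test_that("subject split is subject-disjoint, exhaustive and deterministic", {
  cfg <- sim_config(adl_dur_range_s = c(8, 9))
  trials <- lapply(1:10, function(i) simulate_adl(cfg, sprintf("S%02d", i),
                                                  seed = i))
  wd <- window_trials(trials, windowing_spec())
  sp <- subject_split(wd, fold = 1, seed = 3)
  subj <- function(d) unique(d$subjects)
  expect_length(subj(sp$train), 7L)
  expect_length(subj(sp$val), 2L)
  expect_length(subj(sp$test), 1L)
  expect_length(intersect(subj(sp$train), subj(sp$val)), 0L)
  expect_length(intersect(subj(sp$train), subj(sp$test)), 0L)
  expect_length(intersect(subj(sp$val), subj(sp$test)), 0L)
  expect_equal(n_windows(sp$train) + n_windows(sp$val) + n_windows(sp$test),
               n_windows(wd))
  sp2 <- subject_split(wd, fold = 1, seed = 3)
  expect_identical(sp$train$subjects, sp2$train$subjects)
  # folds rotate membership
  sp3 <- subject_split(wd, fold = 2, seed = 3)
  expect_false(identical(sort(subj(sp$test)), sort(subj(sp3$test))))
  expect_error(subject_split(subset_windows(wd, wd$subjects %in% c("S01", "S02")),
                             fold = 1), "3 distinct subjects")
})

test_that("subject splits stay disjoint across random corpora", {
  set.seed(9)
  for (rep in 1:5) {
    n_sub <- sample(5:12, 1)
    wd <- windowed_dataset(array(rnorm(40 * 8 * 3), c(40, 8, 3)),
                           labels = rbinom(40, 1, 0.3),
                           subjects = sprintf("P%d", sample(n_sub, 40, TRUE)))
    for (fold in 1:3) {
      sp <- subject_split(wd, fold = fold, n_folds = 5, seed = rep)
      all_sub <- c(unique(sp$train$subjects), unique(sp$val$subjects),
                   unique(sp$test$subjects))
      expect_equal(anyDuplicated(all_sub), 0L)
      expect_setequal(all_sub, unique(wd$subjects))
    }
  }
})

make_labeled <- function(n0, n1, provenance = "real") {
  n <- n0 + n1
  windowed_dataset(array(rnorm(n * 8 * 3), c(n, 8, 3)),
                   labels = c(rep(0L, n0), rep(1L, n1)),
                   subjects = rep("S1", n),
                   provenance = rep(provenance, n))
}

test_that("balancing appends the minimal synthetic count", {
  train <- make_labeled(100, 20)
  pool <- make_labeled(0, 200, "synthetic")
  out <- balance_with_synthetic(train, pool, target_ratio = 0.5, tolerance = 0)
  expect_equal(n_windows(out), 200L)             # 80 synthetic added
  expect_equal(sum(out$provenance == "synthetic"), 80L)
  expect_equal(mean(out$labels), 0.5)
  # already balanced: nothing added
  bal <- make_labeled(50, 50)
  expect_equal(n_windows(balance_with_synthetic(bal, pool)), 100L)
  # insufficient pool: all added with a warning, fraction 50/130
  small <- make_labeled(0, 30, "synthetic")
  expect_warning(out2 <- balance_with_synthetic(train, small, tolerance = 0),
                 "adding all")
  expect_equal(n_windows(out2), 150L)
  expect_equal(mean(out2$labels), 50 / 150)
  expect_error(balance_with_synthetic(train, pool, target_ratio = 1.2),
               "target_ratio")
})

test_that("balancing is idempotent and never touches real windows", {
  train <- make_labeled(80, 10)
  pool <- make_labeled(0, 500, "synthetic")
  once <- balance_with_synthetic(train, pool, tolerance = 0.01)
  twice <- balance_with_synthetic(once, pool, tolerance = 0.01)
  expect_equal(n_windows(twice), n_windows(once))
  expect_equal(sum(once$provenance == "real"), n_windows(train))
  expect_true(all(once$labels[once$provenance == "synthetic"] == 1L))
})
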