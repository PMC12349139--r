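#' Windowing specification
#'
#' Parameters of the sliding-window segmentation used throughout: window
#' length `W` (samples), hop `step`, and the fraction of a window's samples
#' that must lie inside a fall interval for the window to be labeled a fall.
#' The defaults (`W = 128`, `step = 10`) give four-second windows at ~32 Hz
#' with a ten-sample hop, the configuration the downstream detector expects.
#'
#' @param window_size window length W in samples.
#' @param step hop between consecutive window starts, `step <= window_size`.
#' @param fall_overlap_threshold fraction in (0, 1]; a window is labeled 1
#'   (fall) when at least this fraction of its samples lies inside a fall
#'   interval.
#' @return An object of class `windowing_spec`.
#' @export
windowing_spec <- function(window_size = 128L, step = 10L,
                           fall_overlap_threshold = 0.5) {
  window_size <- as.integer(window_size); step <- as.integer(step)
  stopifnot(window_size >= 1L, step >= 1L)
  if (step > window_size) stop("step must not exceed window_size (windows must overlap or tile)")
  if (!(fall_overlap_threshold > 0 && fall_overlap_threshold <= 1)) {
    stop("fall_overlap_threshold must lie in (0, 1]")
  }
  structure(list(window_size = window_size, step = step,
                 fall_overlap_threshold = fall_overlap_threshold),
            class = "windowing_spec")
}

#' Construct a windowed dataset
#'
#' The unit of model training and balancing: a stack of fixed-length
#' `W x 3` windows with binary labels (1 = fall), subject provenance and a
#' real/synthetic provenance flag per window.
#'
#' @param windows numeric array `N x W x 3`.
#' @param labels integer/numeric vector of 0/1, length N.
#' @param subjects character vector, length N.
#' @param provenance character vector, each `"real"` or `"synthetic"`.
#' @return An object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(windows, labels, subjects,
                             provenance = rep("real", length(labels))) {
  stopifnot(length(dim(windows)) == 3L, dim(windows)[3] == 3L)
  n <- dim(windows)[1]
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, length(subjects) == n, length(provenance) == n,
            all(labels %in% c(0L, 1L)), all(provenance %in% c("real", "synthetic")))
  if (n > 0 && !all(is.finite(windows))) stop("windows contain non-finite values")
  structure(list(windows = windows, labels = labels,
                 subjects = as.character(subjects),
                 provenance = as.character(provenance)),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d x 3 | falls: %d (%.1f%%) | synthetic: %d | subjects: %d\n",
              n_windows(x), if (n_windows(x)) dim(x$windows)[2] else NA_integer_,
              sum(x$labels == 1L),
              if (n_windows(x)) 100 * mean(x$labels == 1L) else NA_real_,
              sum(x$provenance == "synthetic"),
              length(unique(x$subjects))))
  invisible(x)
}

#' Number of windows in a windowed dataset
#' @param x a `windowed_dataset`.
#' @return integer count.
#' @export
n_windows <- function(x) dim(x$windows)[1]

#' Subset a windowed dataset by window index
#' @param x a `windowed_dataset`.
#' @param idx integer or logical index over windows.
#' @return a `windowed_dataset` with the selected windows.
#' @export
subset_windows <- function(x, idx) {
  windowed_dataset(x$windows[idx, , , drop = FALSE], x$labels[idx],
                   x$subjects[idx], x$provenance[idx])
}

#' Concatenate windowed datasets
#' @param ... `windowed_dataset` objects with equal window length.
#' @return the row-bound `windowed_dataset`.
#' @export
bind_windows <- function(...) {
  parts <- Filter(function(p) n_windows(p) > 0L, list(...))
  if (!length(parts)) stop("nothing to bind")
  W <- dim(parts[[1]]$windows)[2]
  stopifnot(all(vapply(parts, function(p) dim(p$windows)[2], integer(1)) == W))
  n <- sum(vapply(parts, n_windows, integer(1)))
  w <- array(0, dim = c(n, W, 3L))
  at <- 0L
  for (p in parts) {
    k <- n_windows(p)
    w[at + seq_len(k), , ] <- p$windows
    at <- at + k
  }
  windowed_dataset(w, unlist(lapply(parts, `[[`, "labels")),
                   unlist(lapply(parts, `[[`, "subjects")),
                   unlist(lapply(parts, `[[`, "provenance")))
}

# fraction of samples in [start, start+W) covered by the trial's fall intervals
interval_overlap_fraction <- function(intervals, start, W) {
  if (!length(intervals)) return(0)
  covered <- 0L
  for (iv in intervals) {
    lo <- max(iv[1], start); hi <- min(iv[2], start + W)
    if (hi > lo) covered <- covered + (hi - lo)
  }
  covered / W
}

#' Segment a trial into overlapping windows
#'
#' Slides a window of `spec$window_size` samples over the trial with hop
#' `spec$step`; trailing samples that do not fill a window are dropped.
#' Window `i` (0-based) covers samples `[i*step, i*step + W)`. A window is
#' labeled 1 when the fraction of its samples inside any fall interval
#' reaches `spec$fall_overlap_threshold`.
#'
#' @param x a `fall_trial`.
#' @param spec a [windowing_spec()].
#' @param provenance `"real"` or `"synthetic"`, attached to every window.
#' @param force_label optional 0/1 overriding interval-derived labels (used
#'   for generated trials that are fall events in their entirety).
#' @return A [windowed_dataset()] with `floor((L - W)/step) + 1` windows.
#' @export
sliding_windows <- function(x, spec = windowing_spec(), provenance = "real",
                            force_label = NULL) {
  validate_trial(x)
  L <- nrow(x$samples); W <- spec$window_size; step <- spec$step
  if (L < W) stop("trial shorter than window (L=", L, " < W=", W, ")")
  n <- (L - W) %/% step + 1L
  w <- array(0, dim = c(n, W, 3L))
  labels <- integer(n)
  for (i in seq_len(n)) {
    s0 <- (i - 1L) * step
    w[i, , ] <- x$samples[s0 + seq_len(W), ]
    labels[i] <- if (!is.null(force_label)) as.integer(force_label) else {
      as.integer(interval_overlap_fraction(x$fall_intervals, s0, W) >=
                   spec$fall_overlap_threshold)
    }
  }
  windowed_dataset(w, labels, rep(x$subject_id, n), rep(provenance, n))
}

#' Window a list of trials
#'
#' Convenience wrapper mapping [sliding_windows()] over trials and binding
#' the result; trials shorter than the window are skipped with a message
#' rather than an error.
#'
#' @inheritParams sliding_windows
#' @param trials list of `fall_trial` objects.
#' @return A [windowed_dataset()].
#' @export
window_trials <- function(trials, spec = windowing_spec(), provenance = "real",
                          force_label = NULL) {
  parts <- list()
  for (tr in trials) {
    if (nrow(tr$samples) < spec$window_size) {
      message("skipping trial of ", nrow(tr$samples), " samples (< window)")
      next
    }
    parts[[length(parts) + 1L]] <-
      sliding_windows(tr, spec, provenance = provenance, force_label = force_label)
  }
  if (!length(parts)) stop("no trial was long enough to window")
  do.call(bind_windows, parts)
}

#' Subject-wise train/validation/test split
#'
#' Partitions windows by SUBJECT so that no individual contributes windows
#' to more than one of train/validation/test — the leakage guard required
#' for honest generalization estimates in human-activity recognition. The
#' fold index rotates which subjects land in validation/test, giving a
#' k-fold scheme over a fixed seeded subject permutation.
#'
#' @param x a `windowed_dataset`.
#' @param fractions length-3 numeric `(train, val, test)` summing to 1;
#'   applied to subject counts (default 70/20/10).
#' @param fold fold index in `1..n_folds`.
#' @param n_folds number of folds the rotation cycles over.
#' @param seed integer seed fixing the subject permutation.
#' @return A list with `windowed_dataset` elements `train`, `val`, `test`.
#' @export
subject_split <- function(x, fractions = c(0.7, 0.2, 0.1), fold = 1L,
                          n_folds = 5L, seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  subjects <- sort(unique(x$subjects))
  S <- length(subjects)
  if (S < 3L) stop("need at least 3 distinct subjects for a subject-wise split")
  fold <- as.integer(fold); n_folds <- as.integer(n_folds)
  stopifnot(fold >= 1L, fold <= n_folds)
  perm <- withr_seed(seed, sample(subjects))
  # rotate the permutation by fold so each fold sees different val/test subjects
  shift <- ((fold - 1L) * max(1L, S %/% n_folds)) %% S
  if (shift > 0L) perm <- c(perm[(shift + 1L):S], perm[seq_len(shift)])
  n_val  <- max(1L, round(fractions[2] * S))
  n_test <- max(1L, round(fractions[3] * S))
  if (n_val + n_test >= S) stop("fractions leave no training subject")
  val_s  <- perm[seq_len(n_val)]
  test_s <- perm[n_val + seq_len(n_test)]
  train_s <- perm[-(seq_len(n_val + n_test))]
  list(train = subset_windows(x, x$subjects %in% train_s),
       val   = subset_windows(x, x$subjects %in% val_s),
       test  = subset_windows(x, x$subjects %in% test_s))
}

# evaluate expr with a temporary RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Balance the fall class with synthetic windows
#'
#' Appends the minimum number of synthetic fall windows needed to bring the
#' fall fraction within `tolerance` of `target_ratio` (default 50/50).
#' Real windows are never removed and synthetic non-falls are never added:
#' synthesis is used only for the scarce class. If the pool is too small,
#' all of it is appended and a warning is raised.
#'
#' @param x training `windowed_dataset` (typically imbalanced).
#' @param synthetic_falls `windowed_dataset` of candidate windows, all with
#'   label 1 and provenance `"synthetic"`.
#' @param target_ratio desired fall fraction in (0, 1).
#' @param tolerance acceptable |fall fraction - target| after balancing.
#' @return The augmented `windowed_dataset`.
#' @export
balance_with_synthetic <- function(x, synthetic_falls, target_ratio = 0.5,
                                   tolerance = 0.01) {
  if (!(target_ratio > 0 && target_ratio < 1)) stop("target_ratio must lie in (0, 1)")
  if (n_windows(synthetic_falls) > 0) {
    stopifnot(all(synthetic_falls$labels == 1L),
              all(synthetic_falls$provenance == "synthetic"))
  }
  n <- n_windows(x); nf <- sum(x$labels == 1L)
  # smallest k with |(nf + k)/(n + k) - target| <= tolerance
  need <- function(k) abs((nf + k) / (n + k) - target_ratio) <= tolerance
  if (need(0)) return(x)
  if (nf / n > target_ratio) {
    warning("fall fraction already exceeds target; nothing to add")
    return(x)
  }
  # exact k for equality, then search outward for the tolerance band
  k_star <- ceiling((target_ratio * n - nf) / (1 - target_ratio))
  k <- k_star
  while (k > 0 && need(k - 1)) k <- k - 1
  avail <- n_windows(synthetic_falls)
  if (k > avail) {
    warning(sprintf("only %d synthetic fall windows available, %d needed; adding all",
                    avail, k))
    k <- avail
  }
  if (k == 0L) return(x)
  bind_windows(x, subset_windows(synthetic_falls, seq_len(k)))
}
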