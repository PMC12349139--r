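#' Detector configuration
#'
#' The downstream fall-detection network: an LSTM layer over the
#' `W x 3` window, batch normalization of the final hidden state, a dense
#' layer whose width matches the window size, and a single sigmoid output.
#' Trained with binary cross-entropy and Adam, early-stopping on
#' validation loss.
#'
#' @param window_size window length W (default 128).
#' @param lstm_hidden LSTM hidden units (default 128).
#' @param dense_units dense layer width; defaults to `window_size`.
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam learning rate.
#' @param epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param threshold decision threshold on the fall probability.
#' @param seed integer seed.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(window_size = 128L, lstm_hidden = 128L,
                            dense_units = window_size, batch_size = 64L,
                            learning_rate = 1e-3, epochs = 50L,
                            early_stop_patience = 5L, threshold = 0.5,
                            seed = 1L) {
  if (window_size <= 0) stop("window_size must be positive")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must lie in (0, 1)")
  structure(list(window_size = as.integer(window_size),
                 lstm_hidden = as.integer(lstm_hidden),
                 dense_units = as.integer(dense_units),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 threshold = threshold, seed = as.integer(seed)),
            class = "detector_config")
}

#' Build an untrained detector
#'
#' Initializes the LSTM -> BatchNorm -> Dense(W, ReLU) -> Dense(1, sigmoid)
#' network. Identical seeds give identical initial parameters.
#'
#' @param cfg a [detector_config()].
#' @return An object of class `fall_detector`.
#' @export
build_detector <- function(cfg = detector_config()) {
  withr_seed(cfg$seed, {
    H <- cfg$lstm_hidden
    params <- list(lstm = lstm_init(3L, H),
                   bn = bn_init(H),
                   d1 = lin_init(H, cfg$dense_units),
                   d2 = lin_init(cfg$dense_units, 1L))
    structure(list(params = params, cfg = cfg,
                   bn_running = list(mean = numeric(H), var = rep(1, H)),
                   trained = FALSE, history = NULL),
              class = "fall_detector")
  })
}

# forward pass to logits; training switches batchnorm statistics mode
detector_fwd <- function(model, X, training = FALSE) {
  cfg <- model$cfg; H <- cfg$lstm_hidden
  lf <- lstm_fwd(model$params$lstm, X, H)
  bn <- bn_fwd(model$params$bn, lf$h_last, model$bn_running, training = training)
  d1 <- lin_fwd(model$params$d1, bn$y)
  a1 <- pmax(d1$y, 0)
  d2 <- lin_fwd(model$params$d2, a1)
  list(logit = as.numeric(d2$y), running = bn$running,
       cache = list(lf = lf, bn = bn, d1 = d1, a1 = a1, d2 = d2))
}

detector_bwd <- function(model, cache, dlogit) {
  cfg <- model$cfg; H <- cfg$lstm_hidden
  B <- length(dlogit)
  b2 <- lin_bwd(model$params$d2, cache$d2$cache, matrix(dlogit, B, 1))
  da1 <- b2$dx * (cache$d1$y > 0)
  b1 <- lin_bwd(model$params$d1, cache$d1$cache, da1)
  bb <- bn_bwd(model$params$bn, cache$bn$cache, b1$dx)
  Tn <- dim(cache$lf$H)[2]
  dH <- array(0, dim(cache$lf$H))
  dH[, Tn, ] <- bb$dx                       # loss depends on the last state only
  bl <- lstm_bwd(model$params$lstm, cache$lf, dH, H)
  list(grads = list(lstm = bl$grads, bn = bb$grads, d1 = b1$grads, d2 = b2$grads))
}

#' Predict fall probabilities
#'
#' @param object a trained `fall_detector`.
#' @param newdata a `windowed_dataset`.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.fall_detector <- function(object, newdata, ...) {
  sigmoid(detector_fwd(object, newdata$windows, training = FALSE)$logit)
}

bce_loss <- function(logit, y) {
  # numerically stable BCE on logits
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

#' Train the fall detector
#'
#' Minimizes binary cross-entropy with Adam on minibatches, evaluating the
#' validation loss after each epoch and early-stopping (restoring the best
#' parameters) after `early_stop_patience` epochs without improvement.
#' Errors when the training set contains a single class: nothing can be
#' learned about the decision boundary.
#'
#' @param train,val `windowed_dataset` partitions.
#' @param cfg a [detector_config()].
#' @param verbose print per-epoch losses?
#' @return A trained `fall_detector` with a `history` data.frame.
#' @export
train_detector <- function(train, val, cfg = detector_config(), verbose = FALSE) {
  if (length(unique(train$labels)) < 2L) {
    stop("training set contains a single class; cannot fit a classifier")
  }
  model <- build_detector(cfg)
  n <- n_windows(train)
  withr_seed(cfg$seed + 1L, {
    opt <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, running = model$bn_running)
    wait <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(n, s + cfg$batch_size - 1L)]
        if (length(idx) < 2L) next          # batchnorm needs > 1 row
        X <- train$windows[idx, , , drop = FALSE]
        y <- train$labels[idx]
        fw <- detector_fwd(model, X, training = TRUE)
        model$bn_running <- fw$running
        p <- sigmoid(fw$logit)
        loss <- bce_loss(fw$logit, y)
        dlogit <- (p - y) / length(y)
        bw <- detector_bwd(model, fw$cache, dlogit)
        st <- adam_step(model$params, bw$grads, opt, lr = cfg$learning_rate)
        model$params <- st$params; opt <- st$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      vl <- bce_loss(detector_fwd(model, val$windows, training = FALSE)$logit,
                     val$labels)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
      if (verbose) message(sprintf("epoch %d  train %.4f  val %.4f", ep,
                                   ep_loss / nb, vl))
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params, running = model$bn_running)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    model$params <- best$params
    model$bn_running <- best$running
    model$trained <- TRUE
    model$history <- hist
    model
  })
}

#' Evaluate a detector on real windows
#'
#' Thresholds predicted probabilities and reports precision, recall, F1,
#' accuracy and the 2x2 confusion table. Synthetic windows are refused:
#' evaluation must be performed exclusively on real data.
#'
#' @param model a trained `fall_detector`.
#' @param test a `windowed_dataset` with provenance all `"real"`.
#' @param threshold decision threshold; defaults to the model's configured
#'   value.
#' @return An object of class `eval_result`.
#' @export
evaluate_detector <- function(model, test, threshold = NULL) {
  if (any(test$provenance != "real")) {
    stop("synthetic windows in the evaluation set; testing must use real data only")
  }
  threshold <- threshold %||% model$cfg$threshold
  p <- predict(model, test)
  eval_metrics(test$labels, as.integer(p >= threshold))
}

#' Classification metrics from labels and predictions
#'
#' @param truth,pred 0/1 integer vectors of equal length.
#' @return An `eval_result`: precision, recall, f1, accuracy and the
#'   confusion matrix (rows = truth, cols = prediction).
#' @export
eval_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0); tn <- sum(truth == 0 & pred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(precision = prec, recall = rec, f1 = f1,
                 accuracy = (tp + tn) / length(truth),
                 confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                                    dimnames = list(truth = c("0", "1"),
                                                    pred = c("0", "1")))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> P=%.3f R=%.3f F1=%.3f acc=%.3f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Five-fold synthetic-data utility protocol
#'
#' The experiment that quantifies whether synthetic falls help: for each
#' fold, split windows subject-wise 70/20/10, train (a) a baseline
#' detector on the real training partition only and (b) a detector on the
#' same partition balanced toward 50/50 with synthetic fall windows
#' ([balance_with_synthetic()]), then evaluate both on the untouched real
#' test partition. Synthetic data never reaches validation or test sets.
#'
#' @param dataset `windowed_dataset` of real windows.
#' @param synthetic_falls `windowed_dataset` of synthetic fall windows
#'   (may be empty: both arms then coincide).
#' @param cfg a [detector_config()].
#' @param n_folds number of folds (default 5).
#' @param fractions subject-split fractions (default 70/20/10).
#' @param target_ratio fall fraction targeted by balancing.
#' @param seed seed for the subject permutation.
#' @return List with per-fold `eval_result`s (`folds_baseline`,
#'   `folds_synthetic`) and their metric means (`baseline`, `with_synthetic`).
#' @export
run_protocol <- function(dataset, synthetic_falls, cfg = detector_config(),
                         n_folds = 5L, fractions = c(0.7, 0.2, 0.1),
                         target_ratio = 0.5, seed = 1L) {
  folds_base <- vector("list", n_folds)
  folds_syn <- vector("list", n_folds)
  for (fold in seq_len(n_folds)) {
    sp <- subject_split(dataset, fractions, fold = fold, n_folds = n_folds,
                        seed = seed)
    stopifnot(all(sp$val$provenance == "real"), all(sp$test$provenance == "real"))
    base <- train_detector(sp$train, sp$val, cfg)
    folds_base[[fold]] <- evaluate_detector(base, sp$test)
    if (n_windows(synthetic_falls) > 0L) {
      aug_train <- balance_with_synthetic(sp$train, synthetic_falls,
                                          target_ratio = target_ratio)
      aug <- train_detector(aug_train, sp$val, cfg)
      folds_syn[[fold]] <- evaluate_detector(aug, sp$test)
    } else {
      folds_syn[[fold]] <- folds_base[[fold]]
    }
  }
  mean_of <- function(folds, field) mean(vapply(folds, `[[`, numeric(1), field))
  summarize <- function(folds) {
    structure(list(precision = mean_of(folds, "precision"),
                   recall = mean_of(folds, "recall"),
                   f1 = mean_of(folds, "f1"),
                   accuracy = mean_of(folds, "accuracy"),
                   confusion = Reduce(`+`, lapply(folds, `[[`, "confusion"))),
              class = "eval_result")
  }
  list(baseline = summarize(folds_base), with_synthetic = summarize(folds_syn),
       folds_baseline = folds_base, folds_synthetic = folds_syn)
}
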