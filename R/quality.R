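#' Embedder configuration for the context Frechet distance
#'
#' The contextual feature extractor behind [context_fid()]: a small 1D
#' convolutional autoencoder trained on the real windows only; the
#' bottleneck activations are the "contextual representation" whose
#' real-vs-synthetic Gaussian fits are compared by Frechet distance.
#'
#' @param embed_dim bottleneck width (>= 2; default 32).
#' @param conv_channels channels of the two encoder conv layers.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed.
#' @return An object of class `embedder_config`.
#' @export
embedder_config <- function(embed_dim = 32L, conv_channels = c(8L, 16L),
                            epochs = 15L, batch_size = 64L,
                            learning_rate = 1e-3, seed = 1L) {
  stopifnot(embed_dim >= 2L, length(conv_channels) == 2L)
  structure(list(embed_dim = as.integer(embed_dim),
                 conv_channels = as.integer(conv_channels),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "embedder_config")
}

## ---- convolutional autoencoder ---------------------------------------------

ae_init <- function(W, cfg) {
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  if (W %% 4L != 0L) stop("window length must be divisible by 4 for the embedder")
  flat_dim <- (W %/% 4L) * c2
  list(e1 = conv_init(3L, c1, 7L), e2 = conv_init(c1, c2, 7L),
       el = lin_init(flat_dim, cfg$embed_dim),
       dl = lin_init(cfg$embed_dim, flat_dim),
       d1 = conv_init(c2, c1, 7L), d2 = conv_init(c1, 3L, 7L))
}

ae_encode <- function(p, X, cfg) {
  B <- dim(X)[1]
  c1 <- conv_fwd(p$e1, X, 7L, 3L); s1 <- silu_fwd(c1$y)
  p1 <- avgpool2_fwd(s1$y)
  c2 <- conv_fwd(p$e2, p1, 7L, 3L); s2 <- silu_fwd(c2$y)
  p2 <- avgpool2_fwd(s2$y)
  Z <- matrix(p2, B, prod(dim(p2)[2:3]))
  el <- lin_fwd(p$el, Z)
  list(emb = el$y,
       cache = list(c1 = c1, s1 = s1, c2 = c2, s2 = s2, el = el,
                    dim_p1 = dim(p1), dim_p2 = dim(p2), B = B))
}

ae_fwd <- function(p, X, cfg) {
  enc <- ae_encode(p, X, cfg)
  B <- enc$cache$B; dp2 <- enc$cache$dim_p2
  dl <- lin_fwd(p$dl, enc$emb)
  Zd <- array(dl$y, dp2)
  u1 <- upsample2_fwd(Zd)
  d1 <- conv_fwd(p$d1, u1, 7L, 3L); sd1 <- silu_fwd(d1$y)
  u2 <- upsample2_fwd(sd1$y)
  d2 <- conv_fwd(p$d2, u2, 7L, 3L)
  list(xhat = d2$y,
       cache = c(enc$cache, list(dl = dl, d1 = d1, sd1 = sd1, d2 = d2)))
}

ae_bwd <- function(p, cache, dXhat) {
  g <- list()
  b_d2 <- conv_bwd(p$d2, cache$d2$cache, dXhat, 7L, 3L); g$d2 <- b_d2$grads
  du2 <- upsample2_bwd(b_d2$dx)
  dsd1 <- silu_bwd(cache$sd1$cache, du2)
  b_d1 <- conv_bwd(p$d1, cache$d1$cache, dsd1, 7L, 3L); g$d1 <- b_d1$grads
  dZd <- upsample2_bwd(b_d1$dx)
  b_dl <- lin_bwd(p$dl, cache$dl$cache, matrix(dZd, cache$B)); g$dl <- b_dl$grads
  b_el <- lin_bwd(p$el, cache$el$cache, b_dl$dx); g$el <- b_el$grads
  dp2 <- array(b_el$dx, cache$dim_p2)
  ds2 <- silu_bwd(cache$s2$cache, avgpool2_bwd(dp2, cache$dim_p1[2]))
  b_e2 <- conv_bwd(p$e2, cache$c2$cache, ds2, 7L, 3L); g$e2 <- b_e2$grads
  dp1 <- avgpool2_bwd(b_e2$dx, dim(cache$s1$cache$x)[2])
  ds1 <- silu_bwd(cache$s1$cache, dp1)
  b_e1 <- conv_bwd(p$e1, cache$c1$cache, ds1, 7L, 3L); g$e1 <- b_e1$grads
  g
}

train_embedder <- function(real, cfg) {
  X <- real$windows
  mu <- apply(X, 3, mean); sdv <- pmax(apply(X, 3, stats::sd), 1e-8)
  for (a in 1:3) X[, , a] <- (X[, , a] - mu[a]) / sdv[a]
  W <- dim(X)[2]; n <- dim(X)[1]
  withr_seed(cfg$seed, {
    p <- ae_init(W, cfg)
    opt <- adam_init(p)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(n, s + cfg$batch_size - 1L)]
        xb <- X[idx, , , drop = FALSE]
        fw <- ae_fwd(p, xb, cfg)
        resid <- fw$xhat - xb
        grads <- ae_bwd(p, fw$cache, 2 * resid / length(resid))
        st <- adam_step(p, grads, opt, lr = cfg$learning_rate)
        p <- st$params; opt <- st$state
      }
    }
    list(params = p, norm = list(mean = mu, sd = sdv), cfg = cfg)
  })
}

embed_windows <- function(embedder, x) {
  X <- x$windows
  for (a in 1:3) {
    X[, , a] <- (X[, , a] - embedder$norm$mean[a]) / embedder$norm$sd[a]
  }
  ae_encode(embedder$params, X, embedder$cfg)$emb
}

## ---- Frechet distance -------------------------------------------------------

sym_sqrtm <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between Gaussian fits of two embedding sets
#'
#' `||mu_r - mu_s||^2 + tr(S_r + S_s - 2 (S_r^{1/2} S_s S_r^{1/2})^{1/2})`,
#' the symmetrized matrix-square-root form. When either set has fewer rows
#' than `dim + 1`, a small ridge is added to the covariances (with a
#' warning) instead of failing on rank deficiency.
#'
#' @param er,es numeric matrices `n x d` of embeddings.
#' @return Non-negative scalar distance.
#' @export
frechet_distance <- function(er, es) {
  d <- ncol(er)
  stopifnot(ncol(es) == d)
  mu_r <- colMeans(er); mu_s <- colMeans(es)
  S_r <- stats::cov(er); S_s <- stats::cov(es)
  if (nrow(er) < d + 1L || nrow(es) < d + 1L) {
    warning("embedding covariance is rank-deficient; applying ridge shrinkage")
    S_r <- S_r + diag(1e-6, d); S_s <- S_s + diag(1e-6, d)
  }
  R <- sym_sqrtm(S_r)
  covmean <- sym_sqrtm(R %*% S_s %*% R)
  max(0, sum((mu_r - mu_s)^2) + sum(diag(S_r)) + sum(diag(S_s)) -
        2 * sum(diag(covmean)))
}

#' Context Frechet distance between real and synthetic windows
#'
#' Trains the convolutional autoencoder of [embedder_config()] on the REAL
#' windows only, embeds both sets at the bottleneck, and returns the
#' Frechet distance between the Gaussian fits of the two embedding clouds.
#' Lower is better; 0 means the feature distributions coincide.
#'
#' @param real,synth `windowed_dataset`s with equal window length.
#' @param cfg an [embedder_config()].
#' @param embedder optional pre-trained embedder (from a previous call's
#'   attribute), so several synthetic sets can be scored against one real
#'   set without retraining.
#' @return The distance, with the trained embedder attached as attribute
#'   `"embedder"`.
#' @export
context_fid <- function(real, synth, cfg = embedder_config(), embedder = NULL) {
  stopifnot(n_windows(real) > 0L, n_windows(synth) > 0L,
            dim(real$windows)[2] == dim(synth$windows)[2])
  if (is.null(embedder)) embedder <- train_embedder(real, cfg)
  fid <- frechet_distance(embed_windows(embedder, real),
                          embed_windows(embedder, synth))
  attr(fid, "embedder") <- embedder
  fid
}

## ---- small recurrent models for the two learned scores ---------------------

rnn_clf_train <- function(X, y, hidden = 16L, epochs = 8L, batch = 64L,
                          lr = 5e-3) {
  p <- list(lstm = lstm_init(3L, hidden), out = lin_init(hidden, 1L))
  opt <- adam_init(p)
  n <- dim(X)[1]
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (s in seq(1L, n, by = batch)) {
      idx <- ord[s:min(n, s + batch - 1L)]
      xb <- X[idx, , , drop = FALSE]; yb <- y[idx]
      lf <- lstm_fwd(p$lstm, xb, hidden)
      ol <- lin_fwd(p$out, lf$h_last)
      logit <- as.numeric(ol$y)
      dlogit <- (sigmoid(logit) - yb) / length(yb)
      bo <- lin_bwd(p$out, ol$cache, matrix(dlogit, length(yb), 1))
      dH <- array(0, dim(lf$H)); dH[, dim(lf$H)[2], ] <- bo$dx
      bl <- lstm_bwd(p$lstm, lf, dH, hidden)
      st <- adam_step(p, list(lstm = bl$grads, out = bo$grads), opt, lr = lr)
      p <- st$params; opt <- st$state
    }
  }
  p
}

rnn_clf_predict <- function(p, X, hidden = 16L) {
  lf <- lstm_fwd(p$lstm, X, hidden)
  as.numeric(sigmoid(lin_fwd(p$out, lf$h_last)$y))
}

#' Discriminative score
#'
#' How well a small recurrent binary classifier can tell real from
#' synthetic windows: label real = 1 / synthetic = 0, split 80/20, train,
#' and report held-out accuracy. Accuracy near 0.5 means the classifier
#' cannot separate the sets (high similarity); near 1 means the synthetic
#' data is trivially distinguishable.
#'
#' @param real,synth `windowed_dataset`s with >= 20 windows each.
#' @param seed integer seed (shuffling, initialization).
#' @param hidden,epochs classifier size and training length.
#' @return Held-out accuracy in `[0, 1]`.
#' @export
discriminative_score <- function(real, synth, seed = 1L, hidden = 16L,
                                 epochs = 8L) {
  if (n_windows(real) < 20L || n_windows(synth) < 20L) {
    stop("need at least 20 windows per set for the discriminative score")
  }
  withr_seed(seed, {
    X <- abind_windows(real$windows, synth$windows)
    y <- c(rep(1L, n_windows(real)), rep(0L, n_windows(synth)))
    mu <- apply(X, 3, mean); sdv <- pmax(apply(X, 3, stats::sd), 1e-8)
    for (a in 1:3) X[, , a] <- (X[, , a] - mu[a]) / sdv[a]
    n <- dim(X)[1]
    ord <- sample(n)
    n_tr <- floor(0.8 * n)
    tr <- ord[seq_len(n_tr)]; te <- ord[(n_tr + 1L):n]
    p <- rnn_clf_train(X[tr, , , drop = FALSE], y[tr], hidden = hidden,
                       epochs = epochs)
    pred <- as.integer(rnn_clf_predict(p, X[te, , , drop = FALSE], hidden) >= 0.5)
    mean(pred == y[te])
  })
}

abind_windows <- function(a, b) {
  stopifnot(dim(a)[2] == dim(b)[2])
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], 3L))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Predictive score (train on synthetic, test on real)
#'
#' The utility of synthetic data for forecasting: a small recurrent
#' one-step-ahead predictor is fitted on the SYNTHETIC windows and its
#' next-step root-mean-squared error is measured over the REAL windows,
#' in the signal's units (m/s^2). Lower is better; synthetic data that
#' carries the real temporal structure transfers well.
#'
#' @param real,synth `windowed_dataset`s.
#' @param horizon forecast horizon in samples (must be < window length;
#'   the predictor is trained for one-step prediction and scored at this
#'   offset grid).
#' @param seed integer seed.
#' @param hidden,epochs predictor size and training length.
#' @return RMSE >= 0.
#' @export
predictive_score <- function(real, synth, horizon = 1L, seed = 1L,
                             hidden = 16L, epochs = 8L) {
  W <- dim(synth$windows)[2]
  if (horizon >= W) stop("horizon must be smaller than the window length")
  withr_seed(seed, {
    mu <- apply(synth$windows, 3, mean)
    sdv <- pmax(apply(synth$windows, 3, stats::sd), 1e-8)
    std <- function(X) { for (a in 1:3) X[, , a] <- (X[, , a] - mu[a]) / sdv[a]; X }
    Xs <- std(synth$windows); Xr <- std(real$windows)
    p <- list(lstm = lstm_init(3L, hidden), out = lin_init(hidden, 3L))
    opt <- adam_init(p)
    n <- dim(Xs)[1]
    Tin <- W - horizon
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (s in seq(1L, n, by = 64L)) {
        idx <- ord[s:min(n, s + 63L)]
        xb <- Xs[idx, seq_len(Tin), , drop = FALSE]
        yb <- Xs[idx, horizon + seq_len(Tin), , drop = FALSE]
        lf <- lstm_fwd(p$lstm, xb, hidden)
        Hm <- flat3(lf$H)
        ol <- lin_fwd(p$out, Hm)
        resid <- unflat3(ol$y, length(idx), Tin) - yb
        dout <- 2 * resid / length(resid)
        bo <- lin_bwd(p$out, ol$cache, flat3(dout))
        bl <- lstm_bwd(p$lstm, lf, unflat3(bo$dx, length(idx), Tin), hidden)
        st <- adam_step(p, list(lstm = bl$grads, out = bo$grads), opt, lr = 5e-3)
        p <- st$params; opt <- st$state
      }
    }
    # score on real windows, error de-standardized to m/s^2
    lf <- lstm_fwd(p$lstm, Xr[, seq_len(Tin), , drop = FALSE], hidden)
    pred <- unflat3(lin_fwd(p$out, flat3(lf$H))$y, dim(Xr)[1], Tin)
    resid <- pred - Xr[, horizon + seq_len(Tin), , drop = FALSE]
    for (a in 1:3) resid[, , a] <- resid[, , a] * sdv[a]
    sqrt(mean(resid^2))
  })
}

## ---- distribution metrics ---------------------------------------------------

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 logarithms, so the result lies in `[0, 1]`; 0 for identical
#' distributions, 1 for disjoint supports.
#'
#' @param p,q non-negative vectors summing to 1 (normalized internally).
#' @return Scalar in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon divergence between real and synthetic value distributions
#'
#' Per axis, pools all sample values of both sets, histograms them on the
#' shared min-max range with `bins` bins, computes the base-2
#' Jensen-Shannon divergence of the two histograms, and averages the three
#' axes.
#'
#' @param real,synth `windowed_dataset`s.
#' @param bins number of shared-range histogram bins (default 50).
#' @return Scalar in `[0, 1]`.
#' @export
jsd <- function(real, synth, bins = 50L) {
  if (bins < 2L) stop("need at least 2 bins")
  if (n_windows(real) == 0L || n_windows(synth) == 0L) stop("empty dataset")
  per_axis <- vapply(1:3, function(a) {
    r <- as.numeric(real$windows[, , a]); s <- as.numeric(synth$windows[, , a])
    rng <- range(c(r, s))
    if (rng[1] == rng[2]) return(0)
    brk <- seq(rng[1], rng[2], length.out = bins + 1L)
    hr <- tabulate(pmin(findInterval(r, brk, rightmost.closed = TRUE), bins), bins)
    hs <- tabulate(pmin(findInterval(s, brk, rightmost.closed = TRUE), bins), bins)
    js_divergence(hr / length(r), hs / length(s))
  }, numeric(1))
  mean(per_axis)
}

#' Two-sample Kolmogorov-Smirnov comparison per axis
#'
#' Pools each axis's sample values from both sets and computes the
#' two-sample KS D statistic (maximum empirical-CDF gap) per axis with its
#' asymptotic p-value; `dbar` is the mean of the three D's — the single
#' similarity number reported alongside the other metrics.
#'
#' @param real,synth `windowed_dataset`s.
#' @return List with `dbar`, `d_per_axis` (length 3), `p_per_axis`.
#' @export
ks_test <- function(real, synth) {
  if (n_windows(real) == 0L || n_windows(synth) == 0L) stop("empty dataset")
  d <- numeric(3); pv <- numeric(3)
  for (a in 1:3) {
    r <- as.numeric(real$windows[, , a]); s <- as.numeric(synth$windows[, , a])
    if (length(r) < 2L || length(s) < 2L) stop("axis ", a, " has fewer than 2 values")
    kt <- suppressWarnings(stats::ks.test(r, s, exact = FALSE))
    d[a] <- unname(kt$statistic); pv[a] <- kt$p.value
  }
  list(dbar = mean(d), d_per_axis = d, p_per_axis = pv)
}

#' Overlaid real-vs-synthetic value histograms
#'
#' Writes a three-panel PNG (axes x, y, z) of overlaid frequency
#' histograms of real and synthetic accelerometer values on shared bins —
#' the standard visual check that a generator reproduces the value
#' distribution of real falls.
#'
#' @param real,synth `windowed_dataset`s.
#' @param path output PNG path.
#' @param bins shared histogram bins.
#' @return `path`, invisibly.
#' @export
distribution_plot <- function(real, synth, path, bins = 50L) {
  grDevices::png(path, width = 1200, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  axes <- c("x", "y", "z")
  for (a in 1:3) {
    r <- as.numeric(real$windows[, , a]); s <- as.numeric(synth$windows[, , a])
    brk <- seq(min(r, s), max(r, s), length.out = bins + 1L)
    hr <- graphics::hist(r, breaks = brk, plot = FALSE)
    hs <- graphics::hist(s, breaks = brk, plot = FALSE)
    ylim <- c(0, max(hr$counts, hs$counts))
    graphics::plot(hr, col = grDevices::rgb(0.2, 0.4, 0.8, 0.5), ylim = ylim,
                   main = paste0("axis ", axes[a]),
                   xlab = expression(paste("acceleration (m/", s^2, ")")))
    graphics::plot(hs, col = grDevices::rgb(0.9, 0.4, 0.2, 0.5), add = TRUE)
    graphics::legend("topright", fill = c(grDevices::rgb(0.2, 0.4, 0.8, 0.5),
                                          grDevices::rgb(0.9, 0.4, 0.2, 0.5)),
                     legend = c("real", "synthetic"), bty = "n")
  }
  invisible(path)
}

#' Full quality report for one real-vs-synthetic comparison
#'
#' Computes all five metrics — context Frechet distance, discriminative
#' score, predictive score, Jensen-Shannon divergence, and averaged KS D —
#' for a pair of window sets.
#'
#' @param real,synth `windowed_dataset`s.
#' @param embed_cfg an [embedder_config()].
#' @param bins histogram bins for the JSD.
#' @param seed seed for the two learned scores.
#' @return An object of class `quality_report`.
#' @export
evaluate_quality <- function(real, synth, embed_cfg = embedder_config(),
                             bins = 50L, seed = 1L) {
  ks <- ks_test(real, synth)
  rep <- structure(list(
    context_fid = as.numeric(context_fid(real, synth, embed_cfg)),
    discriminative = discriminative_score(real, synth, seed = seed),
    predictive = predictive_score(real, synth, seed = seed),
    jsd = jsd(real, synth, bins = bins),
    ks_dbar = ks$dbar,
    ks_pvalues = ks$p_per_axis,
    config_digest = paste0("embed", embed_cfg$embed_dim, "_bins", bins,
                           "_seed", seed)),
    class = "quality_report")
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("<quality_report>\n  context-FID:   %.4f\n",
                     "  discriminative:%.4f\n  predictive:    %.4f\n",
                     "  JSD:           %.4f\n  KS dbar:       %.4f\n"),
              x$context_fid, x$discriminative, x$predictive, x$jsd, x$ks_dbar))
  invisible(x)
}
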