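# The layer set is hand-written, so every backward pass is checked against
# central finite differences on small inputs.

ns <- asNamespace("fallsynth")

test_that("conv1d forward matches a naive direct convolution", {
  set.seed(1)
  B <- 2L; L <- 9L; C <- 3L; Co <- 4L; K <- 7L; pad <- 3L
  X <- array(rnorm(B * L * C), c(B, L, C))
  p <- ns$conv_init(C, Co, K)
  out <- ns$conv_fwd(p, X, K, pad)$y
  for (b in 1:B) for (l in 1:L) for (co in 1:Co) {
    acc <- p$b[co]
    for (o in 1:K) {
      li <- l + o - 1L - pad
      if (li >= 1 && li <= L) {
        acc <- acc + sum(X[b, li, ] * p$W[(o - 1) * C + 1:C, co])
      }
    }
    expect_equal(out[b, l, co], acc, tolerance = 1e-10)
  }
})

test_that("conv1d backward matches finite differences", {
  set.seed(2)
  B <- 2L; L <- 8L; C <- 3L; Co <- 4L; K <- 3L; pad <- 1L
  X <- array(rnorm(B * L * C), c(B, L, C))
  p <- ns$conv_init(C, Co, K)
  fw <- ns$conv_fwd(p, X, K, pad)
  bw <- ns$conv_bwd(p, fw$cache, 2 * fw$y, K, pad)
  fX <- function(v) sum(ns$conv_fwd(p, array(v, dim(X)), K, pad)$y^2)
  expect_lt(rel_err(as.numeric(bw$dx), num_grad(fX, as.numeric(X))), 1e-6)
  fW <- function(v) { p2 <- p; p2$W <- matrix(v, nrow(p$W))
    sum(ns$conv_fwd(p2, X, K, pad)$y^2) }
  expect_lt(rel_err(as.numeric(bw$grads$W), num_grad(fW, as.numeric(p$W))), 1e-6)
})

test_that("RMSNorm output rows have unit RMS before the gain", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  p <- ns$rmsnorm_init(4)            # gain = 1
  y <- ns$rmsnorm_fwd(p, X)$y
  expect_equal(sqrt(rowMeans(y^2)), rep(1, 10), tolerance = 1e-6)
  # gradient check including a non-unit gain
  p$g <- runif(4, 0.5, 1.5)
  fw <- ns$rmsnorm_fwd(p, X)
  bw <- ns$rmsnorm_bwd(p, fw$cache, 2 * fw$y)
  fX <- function(v) sum(ns$rmsnorm_fwd(p, matrix(v, 10))$y^2)
  expect_lt(rel_err(as.numeric(bw$dx), num_grad(fX, as.numeric(X))), 1e-6)
})

test_that("the fused RMSNorm+SiLU kernel equals its composed parts", {
  set.seed(4)
  X <- matrix(rnorm(60), 15, 4)
  g <- runif(4, 0.5, 1.5)
  fused <- ns$norm_act_fwd_cpp(X, g, 1e-8)
  r <- ns$rmsnorm_fwd(list(g = g), X)
  s <- ns$silu_fwd(r$y)
  expect_equal(fused$y, s$y, tolerance = 1e-12)
  # fused backward against finite differences
  dY <- matrix(rnorm(60), 15, 4)
  bw <- ns$norm_act_bwd_cpp(X, fused$r, g, dY)
  fX <- function(v) sum(ns$norm_act_fwd_cpp(matrix(v, 15), g, 1e-8)$y * dY)
  expect_lt(rel_err(as.numeric(bw$dx), num_grad(fX, as.numeric(X))), 1e-6)
  fg <- function(gv) sum(ns$norm_act_fwd_cpp(X, gv, 1e-8)$y * dY)
  expect_lt(rel_err(as.numeric(bw$dg), num_grad(fg, g)), 1e-6)
})

test_that("linear attention backward matches finite differences", {
  set.seed(5)
  C <- 4L
  X <- array(rnorm(2 * 6 * C), c(2, 6, C))
  p <- ns$attn_init(C)
  fw <- ns$attn_fwd(p, X)
  bw <- ns$attn_bwd(p, fw$cache, 2 * fw$y)
  fX <- function(v) sum(ns$attn_fwd(p, array(v, dim(X)))$y^2)
  expect_lt(rel_err(as.numeric(bw$dx), num_grad(fX, as.numeric(X))), 1e-6)
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    fW <- function(v) { p2 <- p; p2[[nm]] <- matrix(v, C)
      sum(ns$attn_fwd(p2, X)$y^2) }
    expect_lt(rel_err(as.numeric(bw$grads[[nm]]),
                      num_grad(fW, as.numeric(p[[nm]]))), 1e-6)
  }
})

test_that("LSTM BPTT matches finite differences", {
  set.seed(6)
  H <- 5L
  X <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  p <- ns$lstm_init(3L, H)
  fw <- ns$lstm_fwd(p, X, H)
  dH <- array(rnorm(2 * 4 * H), c(2, 4, H))
  bw <- ns$lstm_bwd(p, fw, dH, H)
  fW <- function(v) { p2 <- p; p2$W <- matrix(v, nrow(p$W))
    sum(ns$lstm_fwd(p2, X, H)$H * dH) }
  expect_lt(rel_err(as.numeric(bw$grads$W), num_grad(fW, as.numeric(p$W))), 1e-6)
  fX <- function(v) sum(ns$lstm_fwd(p, array(v, dim(X)), H)$H * dH)
  expect_lt(rel_err(as.numeric(bw$dX), num_grad(fX, as.numeric(X))), 1e-6)
})

test_that("the tiny U-Net backward matches finite differences on spot leaves", {
  cfg <- tiny_dcfg()
  set.seed(7)
  X <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
  tt <- c(1L, 5L)
  randomize_zeros <- function(p) {
    if (is.list(p)) return(lapply(p, randomize_zeros))
    if (length(p) > 1 && all(p == 0)) p[] <- stats::rnorm(length(p), 0, 0.2)
    p
  }
  p <- randomize_zeros(ns$unet_init(cfg, seed = 2))
  fw <- ns$unet_fwd(p, X, tt, cfg)
  g <- ns$unet_bwd(p, fw$cache, 2 * fw$y, cfg)
  loss_at <- function(pm) sum(ns$unet_fwd(pm, X, tt, cfg)$y^2)
  spots <- list(
    list(get = function(p) p$conv_in$W,
         set = function(p, v) { p$conv_in$W[] <- v; p },
         grd = function(g) g$conv_in$W),
    list(get = function(p) p$down[[1]]$res[[1]]$c1$W,
         set = function(p, v) { p$down[[1]]$res[[1]]$c1$W[] <- v; p },
         grd = function(g) g$down[[1]]$res[[1]]$c1$W),
    list(get = function(p) p$mid$attn$Wk,
         set = function(p, v) { p$mid$attn$Wk[] <- v; p },
         grd = function(g) g$mid$attn$Wk),
    list(get = function(p) p$up[[2]]$res[[1]]$skip$W,
         set = function(p, v) { p$up[[2]]$res[[1]]$skip$W[] <- v; p },
         grd = function(g) g$up[[2]]$res[[1]]$skip$W),
    list(get = function(p) p$t1$W,
         set = function(p, v) { p$t1$W[] <- v; p },
         grd = function(g) g$t1$W),
    list(get = function(p) p$final_norm$g,
         set = function(p, v) { p$final_norm$g[] <- v; p },
         grd = function(g) g$final_norm$g))
  for (sp in spots) {
    cur <- sp$get(p)
    idx <- sample(length(cur), min(3, length(cur)))
    for (i in idx) {
      eps <- 1e-5
      v <- cur; v[i] <- v[i] + eps; up <- loss_at(sp$set(p, v))
      v[i] <- v[i] - 2 * eps; dn <- loss_at(sp$set(p, v))
      gnum <- (up - dn) / (2 * eps)
      expect_equal(sp$grd(g)[i], gnum, tolerance = 1e-4)
    }
  }
})

test_that("the U-Net maps any admissible length to the same output shape", {
  cfg <- tiny_dcfg()
  p <- ns$unet_init(cfg, seed = 3)
  for (L in c(8L, 16L, 32L, 64L, 128L)) {
    X <- array(rnorm(2 * L * 3), c(2, L, 3))
    y <- ns$no_cache(ns$unet_fwd(p, X, c(0L, 1L), cfg))$y
    expect_equal(dim(y), dim(X))
  }
  expect_error(ns$unet_fwd(p, array(0, c(2, 9, 3)), c(0L, 1L), cfg),
               "not divisible")
})
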