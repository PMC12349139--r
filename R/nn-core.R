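# Minimal neural-network layer set: explicit forward/backward passes on BLAS
# matrix ops, enough for the 1D U-Net denoiser, the LSTM models and the
# convolutional embedder. Parameters live in nested named lists of arrays;
# gradients mirror the structure; Adam walks it recursively. All backward
# passes are verified against finite differences in the test suite.
#
# Array convention: a batch of 1D multichannel signals is an array
# [B, L, C] (batch fastest in memory), so dim<- c(B*L, C) yields the
# per-position matrix with row index b + B*(l-1).

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

flat3 <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
unflat3 <- function(x, B, L) { dim(x) <- c(B, L, ncol(x)); x }

## ---- activations -----------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

silu_fwd <- function(x) {
  s <- sigmoid(x)
  list(y = x * s, cache = if (.nn_state$keep) list(x = x, s = s))
}
silu_bwd <- function(cache, dy) dy * (cache$s * (1 + cache$x * (1 - cache$s)))

## ---- dense layer (matrix [N x Din]) ---------------------------------------

lin_init <- function(d_in, d_out, zero = FALSE) {
  list(W = if (zero) matrix(0, d_in, d_out) else he_init(d_in, d_out),
       b = numeric(d_out))
}

add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))
mul_cols <- function(Y, g) Y * rep(g, each = nrow(Y))

lin_fwd <- function(p, X) {
  list(y = add_bias(X %*% p$W, p$b), cache = if (.nn_state$keep) X)
}

lin_bwd <- function(p, cache, dY) {
  list(dx = dY %*% t(p$W),
       grads = list(W = crossprod(cache, dY), b = colSums(dY)))
}

## ---- 1D convolution, stride 1, zero padding --------------------------------
# With batch-major flattening (row = b + B*(l-1)) every kernel offset maps
# input positions to output positions by a CONTIGUOUS row-block shift, so
# the convolution is a sum of K shifted submatrix products - no im2col
# buffer and no index arithmetic. Weights are stored [C_in*K, C_out] with
# the offset-o block in rows (o-1)*C_in + 1..o*C_in.

# forward-only mode: layers skip cache retention inside no_cache(); used by
# the diffusion sampling loop, which never backpropagates
.nn_state <- new.env(parent = emptyenv())
.nn_state$keep <- TRUE

no_cache <- function(expr) {
  old <- .nn_state$keep
  .nn_state$keep <- FALSE
  on.exit(.nn_state$keep <- old)
  expr
}

conv_init <- function(c_in, c_out, K, zero = FALSE) {
  list(W = if (zero) matrix(0, c_in * K, c_out) else
         he_init(c_in * K, c_out, fan_in = c_in * K),
       b = numeric(c_out))
}

conv_fwd <- function(p, X, K, pad) {
  d <- dim(X); B <- d[1]; L <- d[2]
  Xm <- flat3(X)
  Ym <- conv1d_fwd_cpp(Xm, p$W, p$b, B, L, K, pad)
  list(y = unflat3(Ym, B, L),
       cache = if (.nn_state$keep) list(Xm = Xm, B = B, L = L))
}

conv_bwd <- function(p, cache, dY, K, pad) {
  B <- cache$B; L <- cache$L
  out <- conv1d_bwd_cpp(cache$Xm, p$W, flat3(dY), B, L, K, pad)
  list(dx = unflat3(out$dXm, B, L), grads = list(W = out$dW, b = out$db))
}

## ---- RMSNorm over channels --------------------------------------------------

rmsnorm_init <- function(C) list(g = rep(1, C))

# X: matrix [N x C]; y_i = g_i * x_i / rms(x), rms over channels
rmsnorm_fwd <- function(p, X, eps = 1e-8) {
  r <- sqrt(rowMeans(X^2) + eps)
  U <- X / r
  list(y = mul_cols(U, p$g),
       cache = if (.nn_state$keep) list(X = X, r = r, U = U))
}

rmsnorm_bwd <- function(p, cache, dY) {
  C <- ncol(cache$X)
  dYg <- mul_cols(dY, p$g)
  s <- rowSums(dYg * cache$X)
  dX <- dYg / cache$r - cache$X * (s / (C * cache$r^3))
  list(dx = dX, grads = list(g = colSums(dY * cache$U)))
}

## ---- pooling / resampling ---------------------------------------------------

avgpool2_fwd <- function(X) {
  d <- dim(X)
  (X[, seq(1, d[2], 2), , drop = FALSE] + X[, seq(2, d[2], 2), , drop = FALSE]) / 2
}

avgpool2_bwd <- function(dY, L) {
  d <- dim(dY)
  dX <- array(0, c(d[1], L, d[3]))
  dX[, seq(1, L, 2), ] <- dY / 2
  dX[, seq(2, L, 2), ] <- dY / 2
  dX
}

upsample2_fwd <- function(X) {
  d <- dim(X)
  Y <- array(0, c(d[1], 2 * d[2], d[3]))
  Y[, seq(1, 2 * d[2], 2), ] <- X
  Y[, seq(2, 2 * d[2], 2), ] <- X
  Y
}

upsample2_bwd <- function(dY) {
  d <- dim(dY)
  dY[, seq(1, d[2], 2), , drop = FALSE] + dY[, seq(2, d[2], 2), , drop = FALSE]
}

space_to_depth_fwd <- function(X) {
  d <- dim(X); C <- d[3]
  Y <- array(0, c(d[1], d[2] %/% 2L, 2L * C))
  Y[, , seq_len(C)] <- X[, seq(1, d[2], 2), , drop = FALSE]
  Y[, , C + seq_len(C)] <- X[, seq(2, d[2], 2), , drop = FALSE]
  Y
}

space_to_depth_bwd <- function(dY) {
  d <- dim(dY); C <- d[3] %/% 2L
  dX <- array(0, c(d[1], 2L * d[2], C))
  dX[, seq(1, 2 * d[2], 2), ] <- dY[, , seq_len(C), drop = FALSE]
  dX[, seq(2, 2 * d[2], 2), ] <- dY[, , C + seq_len(C), drop = FALSE]
  dX
}

## ---- sinusoidal timestep embedding -----------------------------------------

sinusoidal_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(1L, half - 1L))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

## ---- linear attention (single head) ----------------------------------------

# the output projection starts at zero so the block is the identity at
# initialization (residual branches come online gradually during training)
attn_init <- function(C, zero_out = TRUE) {
  list(Wq = he_init(C, C, C), Wk = he_init(C, C, C), Wv = he_init(C, C, C),
       Wo = if (zero_out) matrix(0, C, C) else he_init(C, C, C),
       bo = numeric(C))
}

row_maxs <- function(M) {
  mx <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) mx <- pmax(mx, M[, j])
  mx
}

# X: [B, L, C]. q softmax over channels per position; k softmax over
# positions per channel; out = Q (K^T V) -- linear-complexity attention.
# Softmaxes are computed on the full [B*L x C] matrices; only the C x C
# context products loop over the batch.
attn_fwd <- function(p, X) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Xm <- flat3(X)
  Qp <- (Xm %*% p$Wq) / sqrt(C); Kp <- Xm %*% p$Wk; Vp <- Xm %*% p$Wv
  core <- attn_core_cpp(Qp, Kp, Vp, B, L)
  out <- lin_fwd(list(W = p$Wo, b = p$bo), core$Y)
  list(y = unflat3(out$y, B, L) + X,
       cache = if (.nn_state$keep) {
         list(Xm = Xm, Y = core$Y, Q = core$Q, Kx = core$Kx, Vp = Vp,
              ctxs = core$ctxs, B = B, L = L, C = C)
       })
}

attn_bwd <- function(p, cache, dOut) {
  B <- cache$B; L <- cache$L; C <- cache$C
  dOm <- flat3(dOut)
  dY <- dOm %*% t(p$Wo)
  dq <- matrix(0, B * L, C); dk <- dq; dv <- dq
  for (b in seq_len(B)) {
    rw <- seq.int(b, B * L, by = B)
    dYb <- dY[rw, , drop = FALSE]
    ctx <- cache$ctxs[, (b - 1L) * C + seq_len(C), drop = FALSE]
    dq[rw, ] <- dYb %*% t(ctx)
    dctx <- crossprod(cache$Q[rw, , drop = FALSE], dYb)
    dk[rw, ] <- cache$Vp[rw, , drop = FALSE] %*% t(dctx)
    dv[rw, ] <- cache$Kx[rw, , drop = FALSE] %*% dctx
  }
  # softmax backward: over channels for q, over positions (per batch) for k
  dq_pre <- (dq - rowSums(dq * cache$Q)) * cache$Q
  grp <- rep(seq_len(B), times = L)
  s_bc <- rowsum(dk * cache$Kx, grp, reorder = TRUE)[grp, , drop = FALSE]
  dk_pre <- (dk - s_bc) * cache$Kx
  grads <- list(Wq = crossprod(cache$Xm, dq_pre) / sqrt(C),
                Wk = crossprod(cache$Xm, dk_pre),
                Wv = crossprod(cache$Xm, dv),
                Wo = crossprod(cache$Y, dOm), bo = colSums(dOm))
  dXm <- dq_pre %*% t(p$Wq) / sqrt(C) + dk_pre %*% t(p$Wk) + dv %*% t(p$Wv)
  list(dx = unflat3(dXm, B, L) + dOut, grads = grads)
}

## ---- Adam over nested parameter lists --------------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

grad_axpy <- function(a, b) {                # a + b elementwise over nested lists
  if (is.list(a)) mapply(grad_axpy, a, b, SIMPLIFY = FALSE) else a + b
}

# exponential moving average over nested parameter lists (matched by name)
ema_update <- function(ema, params, decay) {
  if (is.list(ema)) {
    keys <- names(ema) %||% seq_along(ema)
    out <- lapply(keys, function(k) ema_update(ema[[k]], params[[k]], decay))
    names(out) <- names(ema)
    out
  } else {
    decay * ema + (1 - decay) * params
  }
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tstep <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)      # match grads by name, not position
      out <- lapply(keys, function(k) upd(p[[k]], g[[k]], m[[k]], v[[k]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tstep); vh <- v / (1 - beta2^tstep)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = tstep))
}

## ---- LSTM (batch-first [B, T, D]) ------------------------------------------

lstm_init <- function(d_in, hidden) {
  W <- he_init(d_in + hidden, 4L * hidden, fan_in = d_in + hidden)
  b <- numeric(4L * hidden)
  b[hidden + seq_len(hidden)] <- 1          # forget-gate bias
  list(W = W, b = b)
}

# returns all hidden states H [B, T, hidden] and caches for BPTT
lstm_fwd <- function(p, X, hidden) {
  d <- dim(X); B <- d[1]; Tn <- d[2]
  h <- matrix(0, B, hidden); cc <- matrix(0, B, hidden)
  H <- array(0, c(B, Tn, hidden))
  caches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B)
    z <- add_bias(cbind(xt, h) %*% p$W, p$b)
    i <- sigmoid(z[, seq_len(hidden), drop = FALSE])
    f <- sigmoid(z[, hidden + seq_len(hidden), drop = FALSE])
    g <- tanh(z[, 2 * hidden + seq_len(hidden), drop = FALSE])
    o <- sigmoid(z[, 3 * hidden + seq_len(hidden), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    caches[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f,
                        g = g, o = o, c_new = c_new, tc = tc)
    h <- h_new; cc <- c_new
    H[, t, ] <- h
  }
  list(H = H, h_last = h, caches = caches)
}

# dH: gradient on every hidden state [B, T, hidden] (zeros where unused)
lstm_bwd <- function(p, fwd, dH, hidden) {
  Tn <- dim(dH)[2]; B <- dim(dH)[1]
  d_in <- nrow(p$W) - hidden
  dW <- p$W * 0; db <- p$b * 0
  dh_next <- matrix(0, B, hidden); dc_next <- matrix(0, B, hidden)
  dX <- array(0, c(B, Tn, d_in))
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$caches[[t]]
    dh <- matrix(dH[, t, ], B) + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    inp <- cbind(cc$xt, cc$h_prev)
    dW <- dW + crossprod(inp, dz)
    db <- db + colSums(dz)
    dinp <- dz %*% t(p$W)
    dX[, t, ] <- dinp[, seq_len(d_in)]
    dh_next <- dinp[, d_in + seq_len(hidden), drop = FALSE]
    dc_next <- dc * cc$f
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

## ---- batch normalization (over batch of [B, H]) ----------------------------

bn_init <- function(H) list(gamma = rep(1, H), beta = numeric(H))

bn_fwd <- function(p, X, running, momentum = 0.1, training = TRUE, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(sweep(X, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean; va <- running$var
  }
  xhat <- mul_cols(add_bias(X, -mu), 1 / sqrt(va + eps))
  y <- add_bias(mul_cols(xhat, p$gamma), p$beta)
  list(y = y, running = running,
       cache = list(xhat = xhat, va = va, eps = eps, X = X, mu = mu))
}

bn_bwd <- function(p, cache, dY) {
  n <- nrow(dY)
  dxhat <- mul_cols(dY, p$gamma)
  istd <- 1 / sqrt(cache$va + cache$eps)
  # standard batchnorm backward
  dX <- mul_cols(add_bias(dxhat, -colMeans(dxhat)) -
                   mul_cols(cache$xhat, colMeans(dxhat * cache$xhat)),
                 istd)
  list(dx = dX,
       grads = list(gamma = colSums(dY * cache$xhat), beta = colSums(dY)))
}
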