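# 1D convolutional U-Net denoiser for the diffusion model. Signals are
# [B, L, 3]; the network predicts the injected noise at a given diffusion
# timestep. Structure per resolution level: ResNet blocks (RMSNorm -> SiLU
# -> conv k7/p3, with a per-channel timestep shift) followed by a linear
# attention block; downsampling is space-to-depth + projection, upsampling
# nearest-neighbour + projection; skip connections concatenate channels.
#
# Internally everything runs on batch-major flattened matrices
# [B*L x C] (row = b + B*(l-1)); the RMSNorm+SiLU pairs and the
# convolutions use the compiled kernels.

unet_channels <- function(cfg) cfg$base_channels * cfg$channel_mults

# the closing conv starts at zero: at initialization the block reduces to
# its skip path, so input signal reaches the output unattenuated no matter
# how deep the network is, and each branch fades in during training
resblock_init <- function(c_in, c_out, K, time_dim) {
  p <- list(n1 = rmsnorm_init(c_in), c1 = conv_init(c_in, c_out, K),
            tp = lin_init(time_dim, c_out),
            n2 = rmsnorm_init(c_out), c2 = conv_init(c_out, c_out, K, zero = TRUE))
  if (c_in != c_out) p$skip <- lin_init(c_in, c_out)
  p
}

# Xm: [B*L x C_in]; temb_s: [B x time_dim] (already SiLU-activated)
resblock_fwd <- function(p, Xm, B, L, temb_s, K, pad) {
  na1 <- norm_act_fwd_cpp(Xm, p$n1$g, 1e-8)
  h1 <- conv1d_fwd_cpp(na1$y, p$c1$W, p$c1$b, B, L, K, pad)
  tp <- lin_fwd(p$tp, temb_s)
  hm <- h1 + tp$y[rep(seq_len(B), times = L), , drop = FALSE]
  na2 <- norm_act_fwd_cpp(hm, p$n2$g, 1e-8)
  h2 <- conv1d_fwd_cpp(na2$y, p$c2$W, p$c2$b, B, L, K, pad)
  ym <- if (!is.null(p$skip)) h2 + add_bias(Xm %*% p$skip$W, p$skip$b) else h2 + Xm
  list(y = ym,
       cache = if (.nn_state$keep) {
         list(Xm = Xm, r1 = na1$r, a1 = na1$y, hm = hm, r2 = na2$r,
              a2 = na2$y, tpX = tp$cache, B = B, L = L)
       })
}

resblock_bwd <- function(p, cache, dY, K, pad) {
  B <- cache$B; L <- cache$L
  g <- list()
  b2 <- conv1d_bwd_cpp(cache$a2, p$c2$W, dY, B, L, K, pad)
  g$c2 <- list(W = b2$dW, b = b2$db)
  n2 <- norm_act_bwd_cpp(cache$hm, cache$r2, p$n2$g, b2$dXm)
  g$n2 <- list(g = n2$dg)
  dtp_y <- rowsum(n2$dx, group = rep(seq_len(B), times = L), reorder = TRUE)
  b_tp <- lin_bwd(p$tp, cache$tpX, dtp_y); g$tp <- b_tp$grads
  b1 <- conv1d_bwd_cpp(cache$a1, p$c1$W, n2$dx, B, L, K, pad)
  g$c1 <- list(W = b1$dW, b = b1$db)
  n1 <- norm_act_bwd_cpp(cache$Xm, cache$r1, p$n1$g, b1$dXm)
  g$n1 <- list(g = n1$dg)
  if (!is.null(p$skip)) {
    g$skip <- list(W = crossprod(cache$Xm, dY), b = colSums(dY))
    dX <- n1$dx + dY %*% t(p$skip$W)
  } else {
    dX <- n1$dx + dY
  }
  list(dx = dX, dtemb_s = b_tp$dx, grads = g)
}

# attention on flattened matrices
attn_fwd_m <- function(p, Xm, B, L) {
  fa <- attn_fwd(p, unflat3(Xm, B, L))
  list(y = flat3(fa$y), cache = fa$cache)
}

attn_bwd_m <- function(p, cache, dYm) {
  ba <- attn_bwd(p, cache, unflat3(dYm, cache$B, cache$L))
  list(dx = flat3(ba$dx), grads = ba$grads)
}

# row-index helpers for resampling on flattened matrices
rows_for_l <- function(B, lvec) rep((lvec - 1L) * B, each = B) + seq_len(B)

# sinusoidal sequence-position channels, replicated across the batch in
# batch-major row order; gives the (translation-equivariant) convolutions
# absolute position, which the padding-aligned trials make meaningful
position_channels <- function(B, L, dim) {
  if (dim <= 0L) return(NULL)
  P <- sinusoidal_embedding(seq_len(L) - 1L, dim)
  P[rep(seq_len(L), each = B), , drop = FALSE]
}

unet_init <- function(cfg, seed = NULL) {
  build <- function() {
    chs <- unet_channels(cfg)
    nl <- length(chs); nb <- cfg$resnet_blocks_per_level
    K <- cfg$kernel_size; time_dim <- 2L * cfg$embed_dim
    p <- list(
      t1 = lin_init(cfg$embed_dim, time_dim),
      t2 = lin_init(time_dim, time_dim),
      conv_in = conv_init(3L + (cfg$pos_dim %||% 0L), chs[1], K),
      down = vector("list", nl), up = vector("list", nl),
      final_norm = rmsnorm_init(chs[1]),
      final = lin_init(chs[1], 3L, zero = TRUE))
    for (i in seq_len(nl)) {
      lev <- list(res = lapply(seq_len(nb), function(j)
        resblock_init(chs[i], chs[i], K, time_dim)),
        attn = attn_init(chs[i]))
      if (i < nl) lev$down_proj <- lin_init(2L * chs[i], chs[i + 1])
      p$down[[i]] <- lev
    }
    p$mid <- list(res1 = resblock_init(chs[nl], chs[nl], K, time_dim),
                  attn = attn_init(chs[nl]),
                  res2 = resblock_init(chs[nl], chs[nl], K, time_dim))
    for (i in seq_len(nl)) {
      c_in_first <- chs[i] + chs[i]                # concat(current, skip)
      lev <- list(res = c(list(resblock_init(c_in_first, chs[i], K, time_dim)),
                          lapply(seq_len(max(0L, nb - 1L)), function(j)
                            resblock_init(chs[i], chs[i], K, time_dim))),
                  attn = attn_init(chs[i]))
      if (i > 1) lev$up_proj <- lin_init(chs[i], chs[i - 1])
      p$up[[i]] <- lev
    }
    p
  }
  if (is.null(seed)) build() else withr_seed(seed, build())
}

# X: [B, L, 3]; t: integer vector [B] of diffusion timesteps (0-based)
unet_fwd <- function(params, X, t, cfg) {
  chs <- unet_channels(cfg); nl <- length(chs)
  K <- cfg$kernel_size; pad <- cfg$conv_padding
  d <- dim(X); B <- d[1]; L <- d[2]
  if (L %% 2^(nl - 1) != 0) stop("input length ", L, " not divisible by ", 2^(nl - 1))
  keep <- .nn_state$keep
  emb <- sinusoidal_embedding(t, cfg$embed_dim)
  tl1 <- lin_fwd(params$t1, emb); ts1 <- silu_fwd(tl1$y)
  tl2 <- lin_fwd(params$t2, ts1$y); ts2 <- silu_fwd(tl2$y)
  temb_s <- ts2$y
  Xin <- flat3(X)
  pc <- position_channels(B, L, cfg$pos_dim %||% 0L)
  if (!is.null(pc)) Xin <- cbind(Xin, pc)
  h <- conv1d_fwd_cpp(Xin, params$conv_in$W, params$conv_in$b, B, L, K, pad)
  cache <- list(Xm = if (keep) Xin, tl1 = tl1, ts1 = ts1, tl2 = tl2,
                ts2 = ts2, down = vector("list", nl),
                up = vector("list", nl), B = B, L = L)
  curL <- L
  skips <- vector("list", nl); skipL <- integer(nl)
  for (i in seq_len(nl)) {
    lev <- params$down[[i]]; cl <- list(res = list())
    for (j in seq_along(lev$res)) {
      rb <- resblock_fwd(lev$res[[j]], h, B, curL, temb_s, K, pad)
      cl$res[[j]] <- rb$cache; h <- rb$y
    }
    at <- attn_fwd_m(lev$attn, h, B, curL); cl$attn <- at$cache; h <- at$y
    skips[[i]] <- h; skipL[i] <- curL
    if (i < nl) {
      # space-to-depth: channels <- (odd positions, even positions)
      odd <- rows_for_l(B, seq(1L, curL, 2L)); even <- odd + B
      s2d <- cbind(h[odd, , drop = FALSE], h[even, , drop = FALSE])
      dp <- lin_fwd(lev$down_proj, s2d)
      cl$dp <- dp; cl$L_in <- curL
      curL <- curL %/% 2L
      h <- dp$y
    }
    cache$down[[i]] <- cl
  }
  m1 <- resblock_fwd(params$mid$res1, h, B, curL, temb_s, K, pad)
  ma <- attn_fwd_m(params$mid$attn, m1$y, B, curL)
  m2 <- resblock_fwd(params$mid$res2, ma$y, B, curL, temb_s, K, pad)
  cache$mid <- list(m1 = m1$cache, ma = ma$cache, m2 = m2$cache)
  h <- m2$y
  for (i in rev(seq_len(nl))) {
    lev <- params$up[[i]]; cl <- list(res = list())
    cl$c_cur <- ncol(h)
    h <- cbind(h, skips[[i]])
    for (j in seq_along(lev$res)) {
      rb <- resblock_fwd(lev$res[[j]], h, B, curL, temb_s, K, pad)
      cl$res[[j]] <- rb$cache; h <- rb$y
    }
    at <- attn_fwd_m(lev$attn, h, B, curL); cl$attn <- at$cache; h <- at$y
    if (i > 1) {
      gather <- rows_for_l(B, rep(seq_len(curL), each = 2L))
      hu <- h[gather, , drop = FALSE]        # nearest-neighbour x2
      upj <- lin_fwd(lev$up_proj, hu)
      cl$upj <- upj; cl$L_in <- curL
      curL <- curL * 2L
      h <- upj$y
    }
    cache$up[[i]] <- cl
  }
  fn <- norm_act_fwd_cpp(h, params$final_norm$g, 1e-8)
  fo <- lin_fwd(params$final, fn$y)
  cache$fin <- if (keep) list(hm = h, r = fn$r, foX = fo$cache)
  list(y = unflat3(fo$y, B, L), cache = cache)
}

unet_bwd <- function(params, cache, dY, cfg) {
  chs <- unet_channels(cfg); nl <- length(chs)
  K <- cfg$kernel_size; pad <- cfg$conv_padding
  B <- cache$B; L <- cache$L
  g <- list(down = vector("list", nl), up = vector("list", nl))
  dtemb_s <- 0

  bf <- lin_bwd(params$final, cache$fin$foX, flat3(dY)); g$final <- bf$grads
  nf <- norm_act_bwd_cpp(cache$fin$hm, cache$fin$r, params$final_norm$g, bf$dx)
  g$final_norm <- list(g = nf$dg)
  dh <- nf$dx
  curL <- L

  dskips <- vector("list", nl)
  for (i in seq_len(nl)) {                 # reverse of the up path (i ascending)
    lev <- params$up[[i]]; cl <- cache$up[[i]]; gl <- list(res = list())
    if (i > 1) {
      bu <- lin_bwd(lev$up_proj, cl$upj$cache, dh); gl$up_proj <- bu$grads
      curL <- cl$L_in
      odd <- rows_for_l(B, seq(1L, 2L * curL, 2L)) # rows duplicated on the way up
      dh <- bu$dx[odd, , drop = FALSE] + bu$dx[odd + B, , drop = FALSE]
    }
    ba <- attn_bwd_m(lev$attn, cl$attn, dh); gl$attn <- ba$grads; dh <- ba$dx
    for (j in rev(seq_along(lev$res))) {
      rb <- resblock_bwd(lev$res[[j]], cl$res[[j]], dh, K, pad)
      gl$res[[j]] <- rb$grads; dh <- rb$dx; dtemb_s <- dtemb_s + rb$dtemb_s
    }
    cc <- cl$c_cur
    dskips[[i]] <- dh[, cc + seq_len(chs[i]), drop = FALSE]
    dh <- dh[, seq_len(cc), drop = FALSE]
    g$up[[i]] <- gl
  }

  bm2 <- resblock_bwd(params$mid$res2, cache$mid$m2, dh, K, pad)
  dtemb_s <- dtemb_s + bm2$dtemb_s
  bma <- attn_bwd_m(params$mid$attn, cache$mid$ma, bm2$dx)
  bm1 <- resblock_bwd(params$mid$res1, cache$mid$m1, bma$dx, K, pad)
  dtemb_s <- dtemb_s + bm1$dtemb_s
  g$mid <- list(res1 = bm1$grads, attn = bma$grads, res2 = bm2$grads)
  dh <- bm1$dx

  for (i in rev(seq_len(nl))) {            # reverse of the down path
    lev <- params$down[[i]]; cl <- cache$down[[i]]; gl <- list(res = list())
    if (i < nl) {
      bd <- lin_bwd(lev$down_proj, cl$dp$cache, dh); gl$down_proj <- bd$grads
      curL <- cl$L_in
      Ci <- chs[i]
      dhd <- matrix(0, B * curL, Ci)       # undo space-to-depth
      odd <- rows_for_l(B, seq(1L, curL, 2L))
      dhd[odd, ] <- bd$dx[, seq_len(Ci), drop = FALSE]
      dhd[odd + B, ] <- bd$dx[, Ci + seq_len(Ci), drop = FALSE]
      dh <- dhd
    }
    # at i == nl the incoming dh is the gradient from the mid block itself
    dh <- dh + dskips[[i]]                 # skip connection gradient joins here
    ba <- attn_bwd_m(lev$attn, cl$attn, dh); gl$attn <- ba$grads; dh <- ba$dx
    for (j in rev(seq_along(lev$res))) {
      rb <- resblock_bwd(lev$res[[j]], cl$res[[j]], dh, K, pad)
      gl$res[[j]] <- rb$grads; dh <- rb$dx; dtemb_s <- dtemb_s + rb$dtemb_s
    }
    g$down[[i]] <- gl
  }
  bci <- conv1d_bwd_cpp(cache$Xm, params$conv_in$W, dh, B, L, K, pad)
  g$conv_in <- list(W = bci$dW, b = bci$db)

  dts2 <- silu_bwd(cache$ts2$cache, dtemb_s)
  bt2 <- lin_bwd(params$t2, cache$tl2$cache, dts2); g$t2 <- bt2$grads
  dts1 <- silu_bwd(cache$ts1$cache, bt2$dx)
  bt1 <- lin_bwd(params$t1, cache$tl1$cache, dts1); g$t1 <- bt1$grads
  g
}
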