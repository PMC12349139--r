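#' Diffusion model configuration
#'
#' Hyperparameters of the denoising diffusion probabilistic model (DDPM)
#' and its 1D U-Net denoiser. Defaults are desk-scale: 300 diffusion steps
#' with a linear beta schedule from 1e-4 to 0.06 (the endpoint is scaled so
#' that the terminal signal fraction alpha_bar_T is ~1e-4 at T=300, as the
#' conventional 0.02 endpoint achieves at T=1000 — sampling assumes the
#' terminal state is indistinguishable from pure noise), a three-level U-Net
#' (channels 32/64/128, two ResNet blocks plus one linear-attention block
#' per level, kernel 7 / padding 3, RMSNorm, sinusoidal time embeddings),
#' trained with Adam on the noise-prediction MSE.
#'
#' @param timesteps number of diffusion steps T.
#' @param beta_schedule only `"linear"` is implemented.
#' @param beta_start,beta_end endpoints of the linear beta schedule,
#'   `0 < beta_start < beta_end < 1`.
#' @param base_channels U-Net base channel count.
#' @param channel_mults per-level channel multipliers; length = number of
#'   resolution levels.
#' @param resnet_blocks_per_level ResNet blocks per level.
#' @param kernel_size,conv_padding 1D convolution geometry (default 7/3).
#' @param embed_dim sinusoidal time-embedding dimension.
#' @param epochs,batch_size,learning_rate training loop parameters.
#' @param ema_decay exponential-moving-average decay for the sampling
#'   weights; 0 (the default) disables it. At desk-scale step counts the
#'   average lags too far behind the live iterate to help; the option is
#'   kept for longer runs.
#' @param pos_dim number of sinusoidal sequence-position channels
#'   concatenated to the input, giving the convolutional denoiser absolute
#'   position information (trials are padded into temporal alignment, so
#'   the fall phases live at consistent positions).
#' @param seed governs initialization, batching and noise draws.
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(timesteps = 300L, beta_schedule = "linear",
                             beta_start = 1e-4, beta_end = 0.06,
                             base_channels = 32L, channel_mults = c(1L, 2L, 4L),
                             resnet_blocks_per_level = 2L,
                             kernel_size = 7L, conv_padding = 3L,
                             embed_dim = 32L, pos_dim = 8L,
                             epochs = 30L, batch_size = 2L,
                             learning_rate = 1e-3, ema_decay = 0,
                             seed = 1L) {
  if (!identical(beta_schedule, "linear")) stop("only the linear beta schedule is implemented")
  if (!(beta_start > 0 && beta_start < beta_end && beta_end < 1)) {
    stop("need 0 < beta_start < beta_end < 1")
  }
  structure(list(timesteps = as.integer(timesteps), beta_schedule = beta_schedule,
                 beta_start = beta_start, beta_end = beta_end,
                 base_channels = as.integer(base_channels),
                 channel_mults = as.integer(channel_mults),
                 resnet_blocks_per_level = as.integer(resnet_blocks_per_level),
                 kernel_size = as.integer(kernel_size),
                 conv_padding = as.integer(conv_padding),
                 embed_dim = as.integer(embed_dim),
                 pos_dim = as.integer(pos_dim),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, ema_decay = ema_decay,
                 seed = as.integer(seed)),
            class = "diffusion_config")
}

#' Padding specification for variable-length trials
#'
#' Trials of different lengths are standardized by extending every trial to
#' the smallest multiple of `multiple` that is at least the longest trial's
#' length, repeating each trial's last sample vector. `multiple` must match
#' the U-Net's halving depth (8 for three levels).
#'
#' @param multiple round-up granularity (power of two; default 8).
#' @return An object of class `padding_spec`.
#' @export
padding_spec <- function(multiple = 8L) {
  multiple <- as.integer(multiple)
  if (multiple < 1L || bitwAnd(multiple, multiple - 1L) != 0L) {
    stop("multiple must be a positive power of two")
  }
  structure(list(multiple = multiple, pad_value_rule = "last_element"),
            class = "padding_spec")
}

#' Round a length up to the next multiple
#'
#' The padded length rule: the smallest multiple of `multiple` that is
#' >= `L_max`, i.e. `ceil(L_max / multiple) * multiple`.
#'
#' @param L_max longest trial length (>= 1).
#' @param multiple granularity (default 8).
#' @return Integer padded length.
#' @export
compute_new_length <- function(L_max, multiple = 8L) {
  stopifnot(L_max >= 1L)
  as.integer(ceiling(L_max / multiple) * multiple)
}

#' Pad trials to equal length with their last value
#'
#' Stacks trials into a `[B, L_new, 3]` tensor, extending each trial by
#' repeating its final sample vector per axis; original lengths are kept so
#' samples can be cropped back after generation. Truncation never occurs.
#'
#' @param trials non-empty list of [trial()] objects.
#' @param spec a [padding_spec()].
#' @return An object of class `padded_batch` with elements `data`
#'   (`B x L_new x 3`), `original_lengths`, `L_new`.
#' @export
pad_trials <- function(trials, spec = padding_spec()) {
  if (!length(trials)) stop("empty trial list")
  lens <- vapply(trials, function(tr) nrow(tr$samples), integer(1))
  L_new <- compute_new_length(max(lens), spec$multiple)
  B <- length(trials)
  data <- array(0, c(B, L_new, 3L))
  for (b in seq_len(B)) {
    s <- trials[[b]]$samples
    L <- nrow(s)
    data[b, seq_len(L), ] <- s
    if (L < L_new) {
      data[b, (L + 1L):L_new, ] <- matrix(s[L, ], L_new - L, 3L, byrow = TRUE)
    }
  }
  structure(list(data = data, original_lengths = lens, L_new = L_new),
            class = "padded_batch")
}

#' Crop a padded batch back to original lengths
#' @param pb a [pad_trials()] result.
#' @return List of `L_i x 3` matrices.
#' @export
crop_to_original <- function(pb) {
  lapply(seq_along(pb$original_lengths), function(b)
    pb$data[b, seq_len(pb$original_lengths[b]), , drop = TRUE])
}

#' Noise schedule tables
#'
#' Linear beta schedule with its derived quantities: `alpha = 1 - beta`
#' and the cumulative product `alpha_bar`, strictly decreasing in t.
#'
#' @param cfg a [diffusion_config()].
#' @return List with `beta`, `alpha`, `alpha_bar` (length `timesteps`).
#' @export
noise_schedule <- function(cfg) {
  beta <- seq(cfg$beta_start, cfg$beta_end, length.out = cfg$timesteps)
  alpha <- 1 - beta
  list(beta = beta, alpha = alpha, alpha_bar = cumprod(alpha))
}

#' Closed-form forward diffusion
#'
#' Noises clean data directly to timestep `t`:
#' `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`, returning
#' both the noised tensor and the exact noise drawn (the training target).
#'
#' @param x0 numeric array/matrix of clean data.
#' @param t integer timestep in `0 .. timesteps-1` (scalar, applied to all
#'   of `x0`).
#' @param schedule a [noise_schedule()].
#' @param seed optional integer seed.
#' @return List with `xt` and `eps`, both shaped like `x0`.
#' @export
forward_diffuse <- function(x0, t, schedule, seed = NULL) {
  Tn <- length(schedule$alpha_bar)
  if (t < 0 || t >= Tn) stop("t out of range [0, ", Tn - 1, "]")
  draw <- function() array(stats::rnorm(length(x0)), dim = dim(x0) %||% length(x0))
  eps <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  ab <- schedule$alpha_bar[t + 1L]
  list(xt = sqrt(ab) * x0 + sqrt(1 - ab) * eps, eps = eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the DDPM on fall trials
#'
#' Pads the trials ([pad_trials()]), standardizes by the training set's
#' global per-axis mean/sd (inverted exactly at sampling time, so the
#' no-normalization contract holds at the I/O boundary), and minimizes the
#' noise-prediction mean squared error with Adam. One seed governs
#' initialization, batching and noise draws, so runs are reproducible.
#'
#' @param falls list of fall [trial()] objects (>= 2).
#' @param cfg a [diffusion_config()].
#' @param pad_spec a [padding_spec()]; its `multiple` must cover the
#'   U-Net's halving depth.
#' @param verbose print per-epoch losses?
#' @return An object of class `ddpm_model`: U-Net parameters, config,
#'   schedule tables, normalization constants, training lengths, and the
#'   per-epoch `loss_curve`.
#' @export
train_ddpm <- function(falls, cfg = diffusion_config(),
                       pad_spec = padding_spec(), verbose = FALSE) {
  if (length(falls) < 2L) stop("need at least 2 trials to train")
  nl <- length(cfg$channel_mults)
  pb <- pad_trials(falls, pad_spec)
  if (pb$L_new %% 2^(nl - 1) != 0) {
    stop("padded length ", pb$L_new, " not divisible by U-Net depth factor ", 2^(nl - 1))
  }
  mu <- apply(pb$data, 3, mean)
  sdv <- pmax(apply(pb$data, 3, stats::sd), 1e-8)
  X <- pb$data
  for (a in 1:3) X[, , a] <- (X[, , a] - mu[a]) / sdv[a]
  x0_range <- range(X)                       # clip bound for denoised sampling
  sch <- noise_schedule(cfg)
  B_all <- dim(X)[1]
  withr_seed(cfg$seed, {
    params <- unet_init(cfg)
    ema <- params
    dec <- cfg$ema_decay %||% 0
    opt <- adam_init(params)
    losses <- numeric(cfg$epochs)
    total_steps <- cfg$epochs * ceiling(B_all / cfg$batch_size)
    step <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(B_all)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, B_all, by = cfg$batch_size)) {
        idx <- ord[s:min(B_all, s + cfg$batch_size - 1L)]
        x0 <- X[idx, , , drop = FALSE]
        tt <- sample.int(cfg$timesteps, length(idx), replace = TRUE) - 1L
        eps <- array(stats::rnorm(length(x0)), dim = dim(x0))
        ab <- sch$alpha_bar[tt + 1L]
        xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps   # ab recycles over batch dim
        fw <- unet_fwd(params, xt, tt, cfg)
        resid <- fw$y - eps
        loss <- mean(resid^2)
        grads <- unet_bwd(params, fw$cache, 2 * resid / length(resid), cfg)
        step <- step + 1L
        # cosine decay: late steps refine at small rates, sharpening the fit
        lr_t <- cfg$learning_rate * 0.5 * (1 + cos(pi * (step - 1) / total_steps))
        st <- adam_step(params, grads, opt, lr = lr_t)
        params <- st$params; opt <- st$state
        if (dec > 0) ema <- ema_update(ema, params, dec)
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, cfg$epochs, losses[ep]))
    }
    structure(list(params = if (dec > 0) ema else params, cfg = cfg,
                   schedule = sch,
                   norm = list(mean = mu, sd = sdv), x0_range = x0_range,
                   lengths = pb$original_lengths, L_new = pb$L_new,
                   rate_hz = falls[[1]]$rate_hz,
                   loss_curve = losses),
              class = "ddpm_model")
  })
}

#' @export
print.ddpm_model <- function(x, ...) {
  cat(sprintf("<ddpm_model> T=%d, L_new=%d, trained %d epochs (loss %.4f -> %.4f)\n",
              x$cfg$timesteps, x$L_new, length(x$loss_curve),
              x$loss_curve[1], x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}

#' Sample synthetic fall trials from a trained DDPM
#'
#' Ancestral DDPM sampling: starting from Gaussian noise, iteratively
#' denoises through all T timesteps — converting each noise prediction to
#' an implied clean signal, clipping it to the training data's value range
#' (the standard stabilizer against compounding prediction error in the
#' reverse chain), and drawing from the corresponding posterior — then
#' de-standardizes and crops each generated signal to a length drawn from
#' the empirical distribution of training lengths. Each result is a
#' [trial()] labeled as a fall over its whole extent, with
#' `subject_id = "synthetic"`.
#'
#' @param model a [train_ddpm()] result.
#' @param n number of trials to generate (> 0).
#' @param seed integer seed for the sampling noise.
#' @return List of `n` [trial()] objects.
#' @export
sample_ddpm <- function(model, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  cfg <- model$cfg; sch <- model$schedule
  Tn <- cfg$timesteps; L <- model$L_new
  clip <- model$x0_range %||% c(-Inf, Inf)
  withr_seed(seed, {
    x <- array(stats::rnorm(n * L * 3L), c(n, L, 3L))
    for (t in rev(seq_len(Tn) - 1L)) {
      eps_hat <- no_cache(unet_fwd(model$params, x, rep(t, n), cfg))$y
      a_t <- sch$alpha[t + 1L]; ab_t <- sch$alpha_bar[t + 1L]
      ab_prev <- if (t > 0) sch$alpha_bar[t] else 1
      x0_hat <- (x - sqrt(1 - ab_t) * eps_hat) / sqrt(ab_t)
      x0_hat[x0_hat < clip[1]] <- clip[1]
      x0_hat[x0_hat > clip[2]] <- clip[2]
      mean_t <- (sqrt(ab_prev) * sch$beta[t + 1L] * x0_hat +
                   sqrt(a_t) * (1 - ab_prev) * x) / (1 - ab_t)
      if (t > 0) {
        var_t <- (1 - ab_prev) / (1 - ab_t) * sch$beta[t + 1L]
        x <- mean_t + sqrt(var_t) * array(stats::rnorm(length(x)), dim(x))
      } else {
        x <- mean_t
      }
    }
    for (a in 1:3) x[, , a] <- x[, , a] * model$norm$sd[a] + model$norm$mean[a]
    lens <- sample(model$lengths, n, replace = TRUE)
    lapply(seq_len(n), function(b) {
      Lb <- lens[b]
      trial(x[b, seq_len(Lb), , drop = TRUE], rate_hz = model$rate_hz %||% 32,
            subject_id = "synthetic", activity = "fall_synthetic",
            fall_intervals = list(c(0L, Lb)))
    })
  })
}

#' Save / load a DDPM checkpoint
#'
#' The checkpoint is a self-describing list (config, schedule tables,
#' normalization, lengths, parameters) serialized with `saveRDS`.
#'
#' @param model a `ddpm_model`.
#' @param path checkpoint path.
#' @return `path` (write) / the `ddpm_model` (read).
#' @export
write_ddpm <- function(model, path) { saveRDS(unclass(model), path); invisible(path) }

#' @rdname write_ddpm
#' @export
read_ddpm <- function(path) {
  obj <- readRDS(path)
  class(obj) <- "ddpm_model"
  class(obj$cfg) <- "diffusion_config"
  obj
}
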