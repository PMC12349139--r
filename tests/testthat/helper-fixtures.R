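# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fall_types <- c("front", "back", "left", "right", "rotational")

# small set of simulated fall trials across subjects
fix_falls <- function(n = 16L, subjects = 4L, seed0 = 100L) {
  fixture(paste0("falls", n, "_", subjects), function() {
    cfg <- sim_config()
    lapply(seq_len(n), function(i)
      simulate_fall(cfg, sprintf("S%02d", (i - 1L) %% subjects + 1L),
                    fall_types[(i - 1L) %% 5L + 1L], seed = seed0 + i))
  })
}

fix_adls <- function(n = 12L, subjects = 6L, seed0 = 300L) {
  fixture(paste0("adls", n, "_", subjects), function() {
    cfg <- sim_config(adl_dur_range_s = c(8, 10))
    lapply(seq_len(n), function(i)
      simulate_adl(cfg, sprintf("S%02d", (i - 1L) %% subjects + 1L),
                   seed = seed0 + i))
  })
}

# windowed fall set (one window per trial at default step)
fix_fall_windows <- function() {
  fixture("fall_windows", function() window_trials(fix_falls(), windowing_spec()))
}

fix_adl_windows <- function() {
  fixture("adl_windows", function() window_trials(fix_adls(), windowing_spec()))
}

# a deterministic mixed windowed dataset with both classes over >= 5 subjects
fix_mixed_windows <- function() {
  fixture("mixed_windows", function() {
    bind_windows(fix_adl_windows(),
                 window_trials(fix_falls(16L, subjects = 6L), windowing_spec()))
  })
}

# tiny diffusion config for fast structural tests
tiny_dcfg <- function(...) {
  args <- list(timesteps = 20L, base_channels = 4L, channel_mults = c(1L, 2L),
               resnet_blocks_per_level = 1L, kernel_size = 3L,
               conv_padding = 1L, embed_dim = 4L, epochs = 2L,
               batch_size = 4L)
  do.call(diffusion_config, utils::modifyList(args, list(...)))
}

# numerical gradient of f at x (vector/matrix), central differences
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
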