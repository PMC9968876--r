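# Shared fixtures, built in code. Heavier objects are created once per
# test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

# one noiseless 30 s trial (no stomp, no drift) at the given velocity
noiseless_trial <- function(velocity = 3.35, duration = 30, seed = 5,
                            mass = 70) {
  key <- paste0("trial_", velocity, "_", duration, "_", seed)
  if (is.null(.fixtures[[key]])) {
    prof <- runner_profile("P01", mass)
    .fixtures[[key]] <- simulate_force(prof, velocity, duration,
                                       seed = seed, noise_scale = 0)
  }
  .fixtures[[key]]
}

# windows with a deterministic learnable structure: the target is an
# affine image of channel 1, mirroring the sacrum-to-force construction
learnable_windows <- function(n, seed = 42, n_channels = 24, len = 400L) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    x <- matrix(stats::rnorm(len * n_channels), len, n_channels)
    x[, 1] <- sin(2 * pi * seq_len(len) / 50 + k)
    y <- pmax(0.5 + 0.45 * x[, 1], 0)
    window_pair(x, y, paste0("T", k), 1L,
                participant_id = paste0("P", (k %% 4) + 1))
  })
}

# half-sine stance waveform sampled at `rate`, padded with flight zeros
half_sine_stance <- function(tc = 0.3, peak = pi / 2, rate = 1000,
                             pad_s = 0.1) {
  t <- seq(0, tc, by = 1 / rate)
  c(numeric(round(pad_s * rate)), peak * sin(pi * t / tc),
    numeric(round(pad_s * rate)))
}
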