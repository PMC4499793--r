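# Shared synthetic fixtures, built once per test run.

# Small locomotion recording: 20 s, event trains and annotation only.
fix_session <- local({
  cfg <- sim_config(seed = 42, duration = 20, ephys_fs = 2000, tau_rise = 2,
                    modulation_depth = 0.8)
  steps <- generate_step_sequence(cfg)
  list(cfg = cfg,
       steps = steps,
       epsc = generate_modulated_events(steps, cfg, "epsc"))
})

# Construct a voltage-clamp trace from explicit event onsets/amplitudes.
make_trace <- function(onsets, amps, fs = 10000, duration = NULL,
                       tau = c(1, 10), noise_sd = 0, spill = NULL,
                       seed = 1) {
  if (is.null(duration)) duration <- max(onsets, 0) + 0.5
  n <- round(duration * fs)
  tr <- numeric(n)
  if (length(onsets)) {
    k <- zeta(tau[1], tau[2], (seq_len(ceiling(0.1 * fs)) - 1) / fs * 1000)
    k <- k / max(k)
    for (j in seq_along(onsets)) {
      i0 <- round(onsets[j] * fs) + 1L
      idx <- i0:min(n, i0 + length(k) - 1L)
      tr[idx] <- tr[idx] + amps[j] * k[seq_along(idx)]
    }
  }
  if (!is.null(spill)) tr <- tr + spill[seq_len(n)]
  if (noise_sd > 0) { set.seed(seed); tr <- tr + rnorm(n, 0, noise_sd) }
  ts_trace(tr, fs, "pA")
}

# Reference causal convolution (direct, via base convolve).
conv_ref <- function(x, k) {
  stats::convolve(x, rev(k), type = "open")[seq_along(x)]
}

# Regular event train helper.
regular_train <- function(rate_hz, duration, modality = "generic") {
  event_train(seq(1 / rate_hz, duration, by = 1 / rate_hz) - 1e-9,
              modality = modality, duration = duration)
}
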