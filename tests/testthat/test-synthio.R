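test_that("generators are deterministic under a fixed configuration", {
  cfg <- sim_config(seed = 3, duration = 6, ephys_fs = 2000, tau_rise = 2)
  s1 <- generate_step_sequence(cfg)
  s2 <- generate_step_sequence(cfg)
  expect_identical(s1, s2)
  e1 <- generate_modulated_events(s1, cfg, "epsc")
  e2 <- generate_modulated_events(s2, cfg, "epsc")
  expect_identical(e1, e2)
  v1 <- synthesize_trace(e1, cfg, "voltage_clamp")
  v2 <- synthesize_trace(e2, cfg, "voltage_clamp")
  expect_identical(v1$trace$values, v2$trace$values)
  f1 <- generate_motion_frames(s1, cfg)
  f2 <- generate_motion_frames(s2, cfg)
  expect_identical(f1$frames, f2$frames)
})

test_that("step counts match the configured cycle duration", {
  # 120 ms swing + 200 ms stance: a continuous 10 s bout holds ~ 10/0.32
  # = 31 cycles (direct-simulation oracle, Poissonish spread)
  cfg <- sim_config(seed = 8, duration = 10, loco_fraction = 1)
  st <- generate_step_sequence(cfg)
  n_cycles <- length(swing_onsets(st, "right"))
  expect_gt(n_cycles, 31 - 6)
  expect_lt(n_cycles, 31 + 6)
  # two limbs, lag about a quarter cycle
  expect_setequal(unique(st$intervals$limb), c("left", "right"))
})

test_that("degenerate step configurations behave", {
  expect_error(generate_step_sequence(
    sim_config(seed = 1, duration = 0.1, loco_fraction = 1)),
    "too short")
  st0 <- generate_step_sequence(sim_config(seed = 1, duration = 5,
                                           loco_fraction = 0))
  expect_equal(nrow(st0$intervals), 0)
  expect_equal(length(generate_modulated_events(
    st0, sim_config(seed = 1, duration = 0), "epsc")), 0)
})

test_that("event rates follow the quiet/locomotion structure", {
  cfg <- sim_config(seed = 5, duration = 60, modulation_depth = 0,
                    loco_fraction = 1, refractory_ms = 0)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  # depth 0: empirical rate within 3 SE of the locomotion rate
  n <- length(ev$times)
  expect_lt(abs(n - cfg$loco_rate * 60), 3 * sqrt(cfg$loco_rate * 60))
})

test_that("cosine phase modulation concentrates events at the preferred phase", {
  cfg <- sim_config(seed = 6, duration = 120, modulation_depth = 1,
                    loco_fraction = 1, refractory_ms = 0)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  ph <- step_phase(st, ev$times)
  ph <- ph[!is.na(ph)]
  pref <- mean(abs((ph - cfg$preferred_phase_deg + 180) %% 360 - 180) < 30)
  anti <- mean(abs((ph - cfg$preferred_phase_deg) %% 360 - 180) < 30)
  # rate at preferred phase is 2x mean, and ~0 at the antiphase
  expect_gt(pref / (60 / 360), 1.6)
  expect_lt(anti / (60 / 360), 0.25)
})

test_that("trace synthesis composes phasic, spillover and noise exactly", {
  cfg <- sim_config(seed = 9, duration = 4, ephys_fs = 10000)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  vc <- synthesize_trace(ev, cfg, "voltage_clamp")
  recon <- vc$truth$phasic + vc$truth$spillover + vc$truth$noise
  expect_equal(vc$trace$values, recon, tolerance = 1e-12)
  expect_true(all(vc$truth$spillover <= 0))

  # spillover_gain 0: pure phasic sum
  cfg0 <- sim_config(seed = 9, duration = 4, ephys_fs = 10000,
                     spillover_gain = 0)
  vc0 <- synthesize_trace(generate_modulated_events(st, cfg0, "epsc"),
                          cfg0, "voltage_clamp")
  expect_identical(vc0$truth$spillover, numeric(length(vc0$trace$values)))
})

test_that("a single noiseless event has the configured peak amplitude", {
  cfg <- sim_config(seed = 2, duration = 1, ephys_fs = 20000, noise_sd = 0,
                    spillover_gain = 0)
  ev <- event_train(0.5, -20, "epsc", duration = 1)
  vc <- synthesize_trace(ev, cfg, "voltage_clamp")
  expect_equal(min(vc$trace$values), -20, tolerance = 1e-3)
  tpk <- 0.5 + biexp_peak(cfg$tau_rise, cfg$tau_fall)$t_peak / 1000
  expect_lt(abs(which.min(vc$trace$values) / 20000 - tpk), 2e-4)
  # no events -> noise only
  vc0 <- synthesize_trace(event_train(numeric(0), modality = "epsc",
                                      duration = 1), cfg, "voltage_clamp")
  expect_identical(vc0$trace$values, numeric(20000))
})

test_that("too-low sampling rates are rejected", {
  cfg <- sim_config(seed = 1, duration = 1, ephys_fs = 1000)
  expect_error(synthesize_trace(event_train(0.5, -20, "epsc", 1), cfg,
                                "voltage_clamp"), "too low")
})

test_that("granule-cell trains are sparse at rest and bursty in bouts", {
  cfg <- sim_config(seed = 7, duration = 60, ephys_fs = 2000, tau_rise = 2)
  st <- generate_step_sequence(cfg)
  gc <- generate_modulated_events(st, cfg, "gc_spike")
  bursts <- group_bursts(gc, min_spikes = 3, max_isi_ms = 50)
  expect_gt(nrow(bursts), 0)
  expect_true(all(bursts$n_spikes >= 3))
  # quiet periods carry only the sparse background rate
  bouts <- locomotion_bouts(st)
  inb <- rep(FALSE, length(gc$times))
  for (k in seq_len(nrow(bouts)))
    inb <- inb | (gc$times >= bouts$start_s[k] & gc$times < bouts$end_s[k])
  quiet_t <- 60 - sum(bouts$end_s - bouts$start_s)
  expect_lt(sum(!inb) / quiet_t, 1)  # well under 1 Hz at rest
})

test_that("quiet video frames are static and bout frames are not", {
  cfg <- sim_config(seed = 4, duration = 8, ephys_fs = 2000, tau_rise = 2,
                    loco_fraction = 0.5)
  st <- generate_step_sequence(cfg)
  fr <- generate_motion_frames(st, cfg)
  mv <- attr(fr, "moving")
  expect_true(any(mv) && any(!mv))
  qf <- which(!mv)
  qf <- qf[qf > 1 & !mv[pmax(1, qf - 1)]]
  dq <- max(abs(fr$frames[, , qf[length(qf)]] -
                  fr$frames[, , qf[length(qf)] - 1]))
  expect_equal(dq, 0)
})
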