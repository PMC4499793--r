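test_that("a single constructed event is detected at its peak", {
  tr <- make_trace(1.0, -30, fs = 20000, duration = 2, noise_sd = 5)
  det <- detect_events(tr)
  tpk <- 1.0 + biexp_peak(1, 10)$t_peak / 1000
  expect_lt(min(abs(det$times - tpk)), 5e-4)
  i <- which.min(abs(det$times - tpk))
  expect_lt(det$amps[i], -20)
})

test_that("noise-only traces yield only threshold-statistics false positives", {
  set.seed(11)
  tr <- ts_trace(rnorm(40000, 0, 5), 20000, "pA")
  det <- detect_events(tr)
  # detections exist (a 2 SD threshold crosses in pure noise) but none is
  # deep: every amplitude stays above ~5 noise SDs
  expect_true(all(det$amps > -5 * 5))
  expect_lt(abs(attr(det, "noise_sd") - 5), 0.5)
})

test_that("spike detection counts upward threshold crossings", {
  fs <- 20000
  vm <- rep(-67, fs)
  for (t0 in c(0.2, 0.5, 0.8)) {
    i <- round(t0 * fs)
    vm[i:(i + 20)] <- -67 + 80 * sin(seq(0, pi, length.out = 21))
  }
  det <- detect_events(ts_trace(vm, fs, "mV"), mode = "spike_vm")
  expect_equal(length(det$times), 3)
  expect_equal(det$times, c(0.2, 0.5, 0.8), tolerance = 1e-3)
})

test_that("detection recovers strong events with high hit rate and timing", {
  cfg <- sim_config(seed = 13, duration = 30, ephys_fs = 20000,
                    quiet_rate = 40, loco_fraction = 0, epsc_amp_mean = 25,
                    epsc_amp_cv = 0.2, spillover_gain = 0, noise_sd = 5,
                    refractory_ms = 2)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  vc <- synthesize_trace(ev, cfg, "voltage_clamp")
  det <- detect_events(vc$trace)
  tpk <- ev$times + biexp_peak(1, 10)$t_peak / 1000
  d <- vapply(tpk, function(t) min(abs(det$times - t)), numeric(1))
  expect_gte(mean(d <= 0.002), 0.95)
  expect_lte(median(d), 0.002)
})

test_that("burst grouping follows the run rule", {
  # ISIs [10, 10, 10, 500, 10] ms: one 4-spike burst (hand enumeration)
  tt <- cumsum(c(0.1, 0.01, 0.01, 0.01, 0.5, 0.01))
  b <- group_bursts(event_train(tt, duration = 1), min_spikes = 3,
                    max_isi_ms = 50)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 4)
  expect_equal(b$onset_s, 0.1)
  # all ISIs 100 ms: nothing
  b2 <- group_bursts(regular_train(10, 2), 3, 50)
  expect_equal(nrow(b2), 0)
  # EPSC-burst rule: 5+ events at 200 Hz <=> max_isi 5 ms
  t200 <- cumsum(c(0.5, rep(0.004, 5)))
  b3 <- group_bursts(event_train(t200, duration = 1), min_spikes = 5,
                     max_isi_ms = 5)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_spikes, 6)
  expect_error(group_bursts(event_train(tt, duration = 1), min_spikes = 1),
               ">= 2")
})

test_that("burst grouping ignores events that create no qualifying run", {
  tt <- cumsum(c(0.1, 0.01, 0.01, 0.01))
  base <- group_bursts(event_train(tt, duration = 2), 3, 50)
  extra <- sort(c(tt, 0.5, 1.0, 1.5))
  aug <- group_bursts(event_train(extra, duration = 2), 3, 50)
  expect_equal(nrow(aug), nrow(base))
  expect_equal(aug$n_spikes, base$n_spikes)
  expect_equal(aug$onset_s, base$onset_s)
})

test_that("rate series conserve the event count in both modes", {
  tr <- regular_train(10, 1)
  rb <- rate_series(tr, bin_s = 1)
  expect_equal(rb$values, 10)
  rk <- rate_series(tr, causal_exp_tau_ms = 50, fs = 2000, duration = 2)
  expect_equal(sum(rk$values) / 2000, 10, tolerance = 1e-6)
  # single event: jump to ~1/tau then e-fold decay per tau
  r1 <- rate_series(event_train(0.1, duration = 1),
                    causal_exp_tau_ms = 50, fs = 20000)
  i0 <- which.max(r1$values)
  expect_equal(r1$values[i0], 20, tolerance = 0.05)
  expect_equal(r1$values[i0 + 0.05 * 20000] / r1$values[i0], exp(-1),
               tolerance = 0.01)
  expect_error(rate_series(tr, bin_s = -1), "positive")
  expect_error(rate_series(tr), "exactly one")
})

test_that("train statistics report CV correctly", {
  st <- train_statistics(regular_train(10, 2))
  expect_equal(st$isi_cv, 0)
  set.seed(20)
  pois <- event_train(sort(runif(4000, 0, 100)), duration = 100)
  stp <- train_statistics(pois)
  expect_equal(stp$isi_cv, 1, tolerance = 0.08)
  expect_warning(st2 <- train_statistics(event_train(c(1, 2), duration = 3)),
                 "CV undefined")
  expect_true(is.na(st2$isi_cv))
  expect_equal(st2$mean_isi_s, 1)
})

test_that("burst depolarisation windows follow the 1/5 ms and 180 ms rule", {
  fs <- 20000
  flat <- ts_trace(rep(-67, fs), fs, "mV")
  b <- list(onset_s = 0.5)
  expect_equal(burst_depolarization(flat, b), 0)
  # +5 mV step exactly at burst onset
  vm <- rep(-67, fs); vm[(0.5 * fs):fs] <- -62
  expect_equal(burst_depolarization(ts_trace(vm, fs, "mV"), b), 5,
               tolerance = 1e-6)
  # linear drift: window-mean difference has a closed form
  slope <- 10  # mV per s
  vm2 <- -67 + slope * (seq_len(fs) - 1) / fs
  got <- burst_depolarization(ts_trace(vm2, fs, "mV"), b)
  resp_mid <- 0.5 + (0.001 + 0.006) / 2
  base_mid <- 0.5 - (0.200 + 0.020) / 2
  expect_equal(got, slope * (resp_mid - base_mid), tolerance = 0.01)
  expect_error(burst_depolarization(flat, list(onset_s = 0.05)), "bounds")
})

test_that("rate-ratio bootstrap brackets the true ratio", {
  set.seed(30)
  a <- event_train(sort(runif(8000, 0, 100)), duration = 100)
  b <- event_train(sort(runif(2000, 0, 100)), duration = 100)
  ci <- bootstrap_ratio_ci(a, b, n_boot = 500, seed = 2)
  expect_lt(ci$lower, 4)
  expect_gt(ci$upper, 4)
  expect_lt(ci$upper - ci$lower, 2)
  # identical trains, paired resampling: degenerate interval at 1
  ci1 <- bootstrap_ratio_ci(a, a, n_boot = 200, paired = TRUE, seed = 3)
  expect_equal(c(ci1$lower, ci1$upper), c(1, 1))
  expect_error(bootstrap_ratio_ci(a, b, n_boot = 0), ">= 100")
})
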