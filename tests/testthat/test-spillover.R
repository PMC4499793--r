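test_that("the biexponential kernel matches its printed formula", {
  expect_equal(zeta(1, 10, 0), 0)
  expect_lt(zeta(1, 10, 500), 1e-12)
  expect_identical(zeta(1, 10, -5), 0)
  # analytic peak: t* = log(tf/tr) / (1/tr - 1/tf)
  tstar <- log(10) / (1 - 0.1)
  expect_equal(tstar, 2.5584, tolerance = 1e-4)
  expect_equal(zeta(1, 10, tstar), 0.0774, tolerance = 1e-3)
  tg <- seq(0, 50, by = 0.01)
  expect_equal(max(zeta(1, 10, tg)), zeta(1, 10, tstar), tolerance = 1e-6)
  expect_error(zeta(5, 5, 1), "degenerate")
})

test_that("a noiseless single event is recovered nearly exactly", {
  tr <- make_trace(1.0, -40, fs = 10000, duration = 5, noise_sd = 0)
  init <- event_train(1.0 + biexp_peak(1, 10)$t_peak / 1000,
                      modality = "epsc", duration = 5)
  attr(init, "noise_sd") <- 0.5
  f <- fit_episode(tr, init, optimize_tau = FALSE, refine = 0)
  expect_equal(nrow(f$events), 1)
  expect_equal(f$events$amp_pA, -40, tolerance = 0.4)
  expect_lt(max(abs(f$beta)), 1)
})

test_that("a slow half-sinusoid with no events lands in the spline", {
  fs <- 5000
  n <- 5 * fs
  slow <- -30 * sin(pi * (seq_len(n) - 1) / n)  # inward half-sinusoid
  tr <- ts_trace(slow + rnorm(n, 0, 1), fs, "pA")
  set.seed(2)
  init <- event_train(numeric(0), modality = "epsc", duration = 5)
  attr(init, "noise_sd") <- 1
  f <- fit_episode(tr, init, optimize_tau = FALSE, refine = 0)
  expect_equal(nrow(f$events), 0)
  expect_gt(cor(f$beta, slow), 0.99)
  # flat zero trace: no events, beta identically ~0
  fz <- fit_episode(ts_trace(rnorm(n, 0, 1), fs, "pA"), init,
                    optimize_tau = FALSE, refine = 0)
  expect_lt(max(abs(fz$beta)), 1.5)
})

test_that("the fit reconstruction identity holds exactly", {
  cfg <- sim_config(seed = 17, duration = 5, ephys_fs = 10000,
                    loco_fraction = 0, quiet_rate = 60)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  vc <- synthesize_trace(ev, cfg, "voltage_clamp")
  f <- suppressWarnings(fit_episode(vc$trace, optimize_tau = FALSE))
  recon <- phasic_trace(f) + f$beta + f$offset + f$residual
  expect_equal(recon, vc$trace$values, tolerance = 1e-10)
  expect_equal(max(f$beta), 0)  # max-zeroing is exact
})

test_that("fit_spillover recovers amplitudes and the spillover trace", {
  cfg <- sim_config(seed = 23, duration = 20, ephys_fs = 10000,
                    loco_fraction = 0, quiet_rate = 77.5, noise_sd = 5)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  vc <- synthesize_trace(ev, cfg, "voltage_clamp")
  f <- suppressWarnings(fit_spillover(vc$trace, tau_strategy = "trace"))
  expect_equal(length(f$episodes), 4)
  i_near <- vapply(ev$times, function(t)
    which.min(abs(f$events$onset_s - t)), integer(1))
  dt <- abs(f$events$onset_s[i_near] - ev$times)
  hit <- dt <= 0.002
  expect_gte(mean(hit), 0.95)
  err <- f$events$amp_pA[i_near][hit] - ev$amps[hit]
  expect_lte(sqrt(mean(err^2)) / sqrt(mean(ev$amps[hit]^2)), 0.10)
  pc <- vapply(seq_along(f$episodes), function(e) {
    fe <- f$episodes[[e]]
    i1 <- round(fe$t0 * 10000) + 1
    cor(fe$beta, vc$truth$spillover[i1:(i1 + fe$n - 1)])
  }, numeric(1))
  expect_gte(mean(pc), 0.9)
  # fitted time constants near the generating kinetics
  expect_equal(unname(f$episodes[[1]]$tau), c(1, 10), tolerance = 0.15)
})

test_that("spillover summaries behave at the edges", {
  cfg <- sim_config(seed = 19, duration = 10, ephys_fs = 10000,
                    loco_fraction = 0, quiet_rate = 60, spillover_gain = 0)
  st <- generate_step_sequence(cfg)
  ev <- generate_modulated_events(st, cfg, "epsc")
  vc <- synthesize_trace(ev, cfg, "voltage_clamp")
  f <- suppressWarnings(fit_spillover(vc$trace, tau_strategy = "fixed"))
  s <- spillover_summaries(f)
  # no spillover: phasic fraction ~ 1 wherever events fall
  pf <- s$phasic_fraction$phasic_fraction
  expect_true(all(pf[!is.na(pf)] > 0.9))
  # charge with the (near-zero) spillover component >= charge without
  expect_true(all(s$charge$charge_with_pC >=
                    s$charge$charge_without_pC - 0.05))
})

test_that("rate-to-spillover cross-correlation finds the built-in lag", {
  # construction oracle: spillover = rate convolved with a causal kernel
  # peaking at delta -> measured peak lag = delta within one 33 ms bin
  set.seed(33)
  fs <- 1000
  dur <- 120
  tt <- sort(runif(dur * 60, 0, dur))
  tr <- event_train(tt, duration = dur)
  rate <- rate_series(tr, causal_exp_tau_ms = 50, fs = fs)
  kern <- zeta(35, 45, (0:(fs / 2)) / fs * 1000)  # narrow, peak near 40 ms
  tpk <- log(45 / 35) / (1 / 35 - 1 / 45)
  spill <- -conv_ref(rate$values, kern / sum(kern))
  fake <- structure(list(
    episodes = list(list(beta = spill, t0 = 0, fs = fs, n = length(spill))),
    events = data.frame(onset_s = tt, amp_pA = rep(-30, length(tt))),
    fs = fs, n = length(spill), t0 = 0),
    class = "spillover_fit")
  xc <- xcorr_rate_spillover(fake, window_s = 2)
  expect_lt(abs(xc$peak_lag - tpk / 1000), 1 / 30 + 1e-9)
  expect_gt(xc$peak_corr, 0.5)
})

test_that("self cross-correlation peaks at one and zero lag", {
  set.seed(7)
  fs <- 1000; dur <- 30
  tt <- sort(runif(dur * 50, 0, dur))
  tr <- event_train(tt, duration = dur)
  rate <- rate_series(tr, causal_exp_tau_ms = 50, fs = fs)
  fake <- structure(list(
    episodes = list(list(beta = -rate$values, t0 = 0, fs = fs,
                         n = length(rate$values))),
    events = data.frame(onset_s = tt, amp_pA = rep(-30, length(tt))),
    fs = fs, n = length(rate$values), t0 = 0),
    class = "spillover_fit")
  xc <- xcorr_rate_spillover(fake, window_s = 2)
  expect_equal(xc$peak_lag, 0)
  expect_gt(xc$peak_corr, 0.99)
})

test_that("burst-triggered spillover flags the no-burst case", {
  fake <- structure(list(
    episodes = list(list(beta = numeric(1000), t0 = 0, fs = 1000,
                         n = 1000)),
    events = data.frame(onset_s = c(0.1, 0.5, 0.9),
                        amp_pA = rep(-30, 3)),
    fs = 1000, n = 1000, t0 = 0),
    class = "spillover_fit")
  expect_warning(out <- burst_triggered_spillover(fake), "no qualifying")
  expect_equal(out$n_bursts, 0)
})

test_that("relate_to_motion validates its smoothing constant", {
  fake <- structure(list(
    episodes = list(list(beta = numeric(3000), t0 = 0, fs = 1000, n = 3000)),
    events = data.frame(onset_s = c(0.5, 1.5), amp_pA = c(-30, -20)),
    fs = 1000, n = 3000, t0 = 0), class = "spillover_fit")
  mi <- structure(list(values = rep(0.5, 90), fps = 30),
                  class = "motion_index_series")
  expect_error(relate_to_motion(fake, mi, tau_ms = 0), "positive")
  out <- relate_to_motion(fake, mi)
  expect_equal(nrow(out), 90)
  # constant motion: the smoothed index rises monotonically to its
  # asymptote (causal kernel settling), with no overshoot
  expect_true(all(diff(out$mi_smooth) >= -1e-12))
  expect_lte(max(out$mi_smooth), 0.5 + 1e-9)
})
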