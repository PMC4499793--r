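#' Configuration for synthetic recordings
#'
#' Bundles every parameter of the synthetic-recording generator.  Defaults
#' encode the study conditions the downstream analyses assume: quiet EPSC
#' rates near 77.5 Hz rising to 144 Hz during locomotion, mossy-fiber spiking
#' near 21 Hz at rest, sparse bursty granule-cell spiking, a slow spillover
#' current that lags the EPSC rate and grows supralinearly with it, and
#' step-phase-locked rate modulation.
#'
#' @param seed Integer RNG seed; all generator outputs are deterministic
#'   functions of the configuration including this seed.
#' @param duration Recording duration, seconds.
#' @param ephys_fs Electrophysiology sampling rate, Hz.
#' @param video_fps Video frame rate, Hz.
#' @param quiet_rate,loco_rate EPSC rates (Hz) during quiet wakefulness and
#'   locomotion.
#' @param mf_quiet_rate,mf_loco_rate Mossy-fiber spike rates (Hz).
#' @param gc_quiet_rate Granule-cell spike rate at rest (Hz); locomotion
#'   spiking is generated as bursts (see `burst_*`).
#' @param modulation_depth Fractional depth of the cosine step-phase
#'   modulation of the locomotion rate, in \[0, 1\].
#' @param preferred_phase_deg Preferred step phase (degrees, 0 = swing onset
#'   of the reference limb).
#' @param swing_ms,stance_ms Mean swing and stance durations, ms.
#' @param step_shape Gamma shape of step-interval durations (CV ~ 0.35 at the
#'   default 8).
#' @param phase_lag_deg Phase offset of the second forelimb, degrees.
#' @param loco_fraction Long-run fraction of time spent locomoting, in
#'   \[0, 1\]; 0 generates a fully quiet recording.
#' @param bout_s Mean locomotion-bout duration, seconds.
#' @param epsc_amp_mean,epsc_amp_cv Mean magnitude (pA) and coefficient of
#'   variation of the lognormal EPSC amplitude distribution.  Inward currents
#'   are emitted as negative values.
#' @param noise_sd Gaussian recording-noise SD, pA.
#' @param tau_rise,tau_fall Fast-event biexponential time constants, ms.
#' @param spillover_gain Spillover current magnitude (pA) at the 100 Hz
#'   reference EPSC rate; 0 disables spillover.
#' @param spill_tau_rise,spill_tau_fall Slow spillover kernel time constants,
#'   ms.  The defaults (30/150) place the kernel peak, and therefore the
#'   rate-to-spillover cross-correlation peak, a few tens of ms after the
#'   driving events; they are tunables, not claims about the biology.
#' @param supralinearity Exponent (>= 1) of the rate dependence of the
#'   spillover current.
#' @param refractory_ms Dead time imposed on generated event trains, ms.
#' @param burst_min,burst_max,burst_isi_ms,interburst_s Granule-cell burst
#'   statistics during locomotion: spikes per burst, intra-burst ISI (ms) and
#'   mean interval between bursts (s).
#' @param frame_h,frame_w Video frame size in pixels.
#' @param frame_noise_sd Optional per-pixel Gaussian noise SD (8-bit units).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration = 60, ephys_fs = 20000,
                       video_fps = 30,
                       quiet_rate = 77.5, loco_rate = 144,
                       mf_quiet_rate = 21, mf_loco_rate = 46.4,
                       gc_quiet_rate = 0.1,
                       modulation_depth = 0.5, preferred_phase_deg = 90,
                       swing_ms = 120, stance_ms = 200, step_shape = 8,
                       phase_lag_deg = 90,
                       loco_fraction = 0.5, bout_s = 8,
                       epsc_amp_mean = 30, epsc_amp_cv = 0.3,
                       noise_sd = 5,
                       tau_rise = 1, tau_fall = 10,
                       spillover_gain = 35,
                       spill_tau_rise = 30, spill_tau_fall = 150,
                       supralinearity = 1.5,
                       refractory_ms = 1,
                       burst_min = 4, burst_max = 15, burst_isi_ms = 10,
                       interburst_s = 1.88,
                       frame_h = 64, frame_w = 64, frame_noise_sd = 0) {
  cfg <- as.list(environment())
  if (cfg$duration < 0) stopf("duration must be >= 0")
  for (f in c("quiet_rate", "loco_rate", "mf_quiet_rate", "mf_loco_rate",
              "gc_quiet_rate"))
    if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  if (cfg$modulation_depth < 0 || cfg$modulation_depth > 1)
    stopf("modulation_depth must lie in [0, 1]")
  if (cfg$loco_fraction < 0 || cfg$loco_fraction > 1)
    stopf("loco_fraction must lie in [0, 1]")
  for (f in c("tau_rise", "tau_fall", "spill_tau_rise", "spill_tau_fall"))
    if (cfg[[f]] <= 0) stopf("%s must be > 0", f)
  if (cfg$supralinearity < 1) stopf("supralinearity must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d, %.0f s; EPSC %.1f/%.1f Hz ",
                     "(quiet/loco), depth %.2f; step %g+%g ms; spillover ",
                     "gain %g pA @100 Hz, exponent %g\n"),
              x$seed, x$duration, x$quiet_rate, x$loco_rate,
              x$modulation_depth, x$swing_ms, x$stance_ms, x$spillover_gain,
              x$supralinearity))
  invisible(x)
}

#' Generate a synthetic gait annotation
#'
#' Produces alternating swing/stance intervals for two forelimbs, organised
#' into locomotion bouts separated by quiet gaps.  Step-interval durations
#' are gamma distributed around the configured means; the second limb is
#' offset by `phase_lag_deg` of the concurrent cycle.
#'
#' @param cfg A [sim_config()].
#' @return A [step_annotation()] covering `cfg$duration`.
#' @export
generate_step_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cyc_s <- (cfg$swing_ms + cfg$stance_ms) / 1000
  if (cfg$loco_fraction > 0 && cfg$duration < cyc_s)
    stopf("duration too short for one full step cycle (%.3f s)", cyc_s)
  empty <- data.frame(limb = character(0), phase = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      stringsAsFactors = FALSE)
  if (cfg$loco_fraction == 0 || cfg$duration == 0)
    return(step_annotation(empty, cfg$video_fps, cfg$duration))

  with_seed(child_seed(cfg$seed, 1L), {
    f <- cfg$loco_fraction
    gap_mean <- if (f >= 1) 0 else cfg$bout_s * (1 - f) / f
    rows <- list()
    t <- if (gap_mean > 0) stats::rgamma(1, shape = 2, scale = gap_mean / 2 / 2) else 0
    while (t < cfg$duration - cyc_s) {
      bout_end <- min(cfg$duration,
                      t + stats::rgamma(1, shape = 4, scale = cfg$bout_s / 4))
      tt <- t
      # constant interlimb lag keeps the left-limb intervals ordered even
      # when successive cycle durations vary
      lag <- (cfg$phase_lag_deg / 360) * cyc_s
      while (tt < bout_end - 0.02) {
        sw <- stats::rgamma(1, shape = cfg$step_shape,
                            scale = cfg$swing_ms / 1000 / cfg$step_shape)
        st <- stats::rgamma(1, shape = cfg$step_shape,
                            scale = cfg$stance_ms / 1000 / cfg$step_shape)
        for (ph in c("swing", "stance")) {
          a <- if (ph == "swing") tt else tt + sw
          b <- if (ph == "swing") tt + sw else tt + sw + st
          rows[[length(rows) + 1L]] <- data.frame(
            limb = "right", phase = ph,
            start_s = min(a, bout_end), end_s = min(b, bout_end),
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            limb = "left", phase = ph,
            start_s = min(a + lag, bout_end), end_s = min(b + lag, bout_end),
            stringsAsFactors = FALSE)
        }
        tt <- tt + sw + st
      }
      t <- bout_end +
        if (gap_mean > 0) stats::rgamma(1, shape = 4, scale = gap_mean / 4) else 0
      if (gap_mean == 0) t <- bout_end  # continuous locomotion
      if (gap_mean == 0 && bout_end >= cfg$duration) break
    }
    if (!length(rows)) return(step_annotation(empty, cfg$video_fps,
                                              cfg$duration))
    iv <- do.call(rbind, rows)
    iv <- iv[iv$end_s - iv$start_s > 1e-6, ]
    iv <- iv[order(iv$limb, iv$start_s), ]
    row.names(iv) <- NULL
    step_annotation(iv, cfg$video_fps, cfg$duration)
  })
}

# Piecewise rate function on a 1-ms grid: base rate by behavioural state
# times the cosine phase modulation.  Used by the thinning sampler below.
modulated_rate_grid <- function(steps, cfg, quiet, loco, dt = 1e-3) {
  n <- max(1L, round(cfg$duration / dt))
  t <- (seq_len(n) - 0.5) * dt
  r <- rep(quiet, n)
  bouts <- locomotion_bouts(steps)
  inb <- rep(FALSE, n)
  for (k in seq_len(nrow(bouts)))
    inb <- inb | (t >= bouts$start_s[k] & t < bouts$end_s[k])
  ph <- step_phase(steps, t)
  mod <- 1 + cfg$modulation_depth *
    cos((ph - cfg$preferred_phase_deg) * pi / 180)
  mod[is.na(mod)] <- 1
  r[inb] <- loco * mod[inb]
  list(t = t, rate = pmax(r, 0), dt = dt, in_bout = inb)
}

# Inhomogeneous Poisson sampling by thinning, followed by dead-time pruning.
thin_poisson <- function(grid, duration, refractory_s) {
  rmax <- max(grid$rate)
  if (rmax <= 0 || duration <= 0) return(numeric(0))
  n <- stats::rpois(1, rmax * duration)
  cand <- sort(stats::runif(n, 0, duration))
  lam <- grid$rate[pmin(length(grid$rate), floor(cand / grid$dt) + 1L)]
  keep <- stats::runif(length(cand)) < lam / rmax
  tt <- unique(cand[keep])  # runif granularity can produce exact ties
  if (refractory_s > 0 && length(tt) > 1) {
    out <- tt[1]
    last <- tt[1]
    for (x in tt[-1]) if (x - last >= refractory_s) { out <- c(out, x); last <- x }
    tt <- out
  }
  tt
}

#' Generate a phase-modulated synthetic event train
#'
#' EPSC and mossy-fiber trains are inhomogeneous Poisson processes whose rate
#' switches between the quiet and locomotion base rates and is modulated as
#' `rate * (1 + depth * cos(phase - preferred))` within locomotion bouts.
#' Granule-cell spiking is burst-gated: quiet singles at the configured low
#' rate, plus high-frequency bursts whose onsets follow a phase-modulated
#' Poisson process during bouts.
#'
#' @param steps A [step_annotation()] covering the configured duration.
#' @param cfg A [sim_config()].
#' @param modality `"epsc"`, `"mf_spike"` or `"gc_spike"`.
#' @return An [event_train()]; EPSC trains carry negative amplitudes in pA.
#' @export
generate_modulated_events <- function(steps, cfg,
                                      modality = c("epsc", "mf_spike",
                                                   "gc_spike")) {
  stopifnot(inherits(cfg, "sim_config"), inherits(steps, "step_annotation"))
  modality <- match.arg(modality)
  if (cfg$modulation_depth > 1) stopf("modulation_depth must be <= 1")
  if (cfg$duration == 0)
    return(event_train(numeric(0), modality = modality, duration = 0))
  off <- c(epsc = 11L, mf_spike = 12L, gc_spike = 13L)[[modality]]
  with_seed(child_seed(cfg$seed, off), {
    refr <- cfg$refractory_ms / 1000
    if (modality == "gc_spike") {
      quiet_tt <- thin_poisson(
        modulated_rate_grid(steps, cfg, cfg$gc_quiet_rate, 0),
        cfg$duration, refr)
      bgrid <- modulated_rate_grid(steps, cfg, 0, 1 / cfg$interburst_s)
      onsets <- thin_poisson(bgrid, cfg$duration, 2 * cfg$burst_isi_ms / 1000)
      spikes <- lapply(onsets, function(t0) {
        ns <- sample(cfg$burst_min:cfg$burst_max, 1)
        isis <- stats::rgamma(ns - 1, shape = 10,
                              scale = cfg$burst_isi_ms / 1000 / 10)
        t0 + c(0, cumsum(isis))
      })
      tt <- sort(c(quiet_tt, unlist(spikes)))
      tt <- tt[tt < cfg$duration]
      if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) >= refr)]
      return(event_train(tt, modality = "gc_spike",
                         duration = cfg$duration))
    }
    quiet <- if (modality == "epsc") cfg$quiet_rate else cfg$mf_quiet_rate
    loco <- if (modality == "epsc") cfg$loco_rate else cfg$mf_loco_rate
    tt <- thin_poisson(modulated_rate_grid(steps, cfg, quiet, loco),
                       cfg$duration, refr)
    amps <- NULL
    if (modality == "epsc" && length(tt)) {
      sdl <- sqrt(log(1 + cfg$epsc_amp_cv^2))
      mag <- stats::rlnorm(length(tt),
                           meanlog = log(cfg$epsc_amp_mean) - sdl^2 / 2,
                           sdlog = sdl)
      amps <- -mag
    }
    event_train(tt, amps, modality = modality, duration = cfg$duration)
  })
}

# Unit-peak biexponential sampled at fs; support runs to ~7 fall times.
sampled_biexp <- function(tau_rise_ms, tau_fall_ms, fs, unit = c("peak", "integral")) {
  unit <- match.arg(unit)
  tms <- (seq_len(ceiling(7 * tau_fall_ms / 1000 * fs)) - 1) / fs * 1000
  k <- zeta(tau_rise_ms, tau_fall_ms, tms)
  if (unit == "peak") k / biexp_peak(tau_rise_ms, tau_fall_ms)$peak
  else k / sum(k) * fs  # unit integral in continuous time
}

#' Synthesise a current- or voltage-clamp trace from an event train
#'
#' In voltage clamp the trace is the sum of a phasic component (each event
#' contributes its amplitude times a unit-peak biexponential), a slow
#' spillover current obtained by convolving the event train with a slow
#' biexponential kernel and scaling supralinearly with the smoothed event
#' rate, and Gaussian noise.  Inward currents are negative.  In current clamp
#' a resting potential near -67 mV carries spikes at the event times and a
#' slow depolarisation that follows the spillover drive.
#'
#' @param events An [event_train()]; EPSC trains need amplitudes.
#' @param cfg A [sim_config()].
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @return List with elements `trace` (a [ts_trace()]) and `truth` (ground
#'   truth: the events plus the exact phasic and spillover components, which
#'   sum with the stored noise to the emitted trace).
#' @export
synthesize_trace <- function(events, cfg,
                             mode = c("voltage_clamp", "current_clamp")) {
  stopifnot(inherits(cfg, "sim_config"), inherits(events, "event_train"))
  mode <- match.arg(mode)
  fs <- cfg$ephys_fs
  if (fs * cfg$tau_rise / 1000 < 2)
    stopf("sampling rate %g Hz too low to resolve tau_rise = %g ms",
          fs, cfg$tau_rise)
  n <- max(1L, round(cfg$duration * fs))
  if (any(events$times < 0 | events$times > cfg$duration))
    stopf("events outside [0, duration]")
  idx <- pmin(n, floor(events$times * fs) + 1L)
  counts <- numeric(n)
  if (length(idx)) {
    tb <- tapply(rep(1, length(idx)), idx, sum)
    counts[as.integer(names(tb))] <- tb
  }

  if (mode == "voltage_clamp") {
    amps <- events$amps
    if (is.null(amps)) amps <- rep(-cfg$epsc_amp_mean, length(events$times))
    asig <- numeric(n)
    if (length(idx)) {
      ab <- tapply(amps, idx, sum)
      asig[as.integer(names(ab))] <- ab
    }
    phasic <- if (length(idx))
      conv_causal(asig, sampled_biexp(cfg$tau_rise, cfg$tau_fall, fs))
    else numeric(n)
    spill <- numeric(n)
    if (cfg$spillover_gain > 0 && length(idx)) {
      s0 <- conv_causal(counts,
                        sampled_biexp(cfg$spill_tau_rise, cfg$spill_tau_fall,
                                      fs, unit = "integral"))
      spill <- -cfg$spillover_gain * (pmax(s0, 0) / 100)^cfg$supralinearity
    }
    noise <- with_seed(child_seed(cfg$seed, 21L),
                       stats::rnorm(n, 0, cfg$noise_sd))
    trace <- ts_trace(phasic + spill + noise, fs, units = "pA")
    truth <- list(events = events, phasic = phasic, spillover = spill,
                  noise = noise, fs = fs)
    return(list(trace = trace, truth = truth))
  }

  # current clamp: resting Vm with spikes at the event times and a slow
  # depolarisation proportional to the spillover drive
  depol <- numeric(n)
  if (length(idx)) {
    s0 <- conv_causal(counts,
                      sampled_biexp(cfg$spill_tau_rise, cfg$spill_tau_fall,
                                    fs, unit = "integral"))
    depol <- 4 * (pmax(s0, 0) / (1 / cfg$interburst_s))^0.8  # mV, saturating-ish
  }
  vm <- -67 + depol
  spike_w <- round(fs / 1000)  # 1 ms
  tpl <- 90 * sin(seq(0, pi, length.out = spike_w))  # to ~ +23 mV
  for (i in idx) {
    j <- i:min(n, i + spike_w - 1L)
    vm[j] <- vm[j] + tpl[seq_along(j)]
  }
  noise <- with_seed(child_seed(cfg$seed, 22L), stats::rnorm(n, 0, 0.3))
  trace <- ts_trace(vm + noise, fs, units = "mV")
  list(trace = trace,
       truth = list(events = events, depolarization = depol, fs = fs))
}

#' Render synthetic behaviour video frames
#'
#' Draws a static textured background with two limb blobs whose position
#' sweeps with the step cycle (forward in swing, backward in stance, as on a
#' treadmill) and a body region whose texture decorrelates frame-to-frame
#' during locomotion bouts with a cycling contrast, a stylised stand-in for
#' the fluctuating motion energy of a running mouse.  Quiet frames are
#' static up to optional pixel noise.
#'
#' @param steps A [step_annotation()].
#' @param cfg A [sim_config()].
#' @return A [frame_stack()] of 8-bit grayscale frames with attribute
#'   `moving`, the ground-truth per-frame locomotion flag.
#' @export
generate_motion_frames <- function(steps, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(steps, "step_annotation"))
  h <- cfg$frame_h; w <- cfg$frame_w
  nfr <- max(1L, round(cfg$duration * cfg$video_fps))
  with_seed(child_seed(cfg$seed, 31L), {
    bg <- matrix(sample(20:60, h * w, replace = TRUE), h, w)
    bouts <- locomotion_bouts(steps)
    tmid <- (seq_len(nfr) - 0.5) / cfg$video_fps
    moving <- rep(FALSE, nfr)
    for (k in seq_len(nrow(bouts)))
      moving <- moving | (tmid >= bouts$start_s[k] & tmid < bouts$end_s[k])

    limbs <- sort(unique(steps$intervals$limb))
    base_x <- c(14, 44)[seq_along(limbs)]
    amp <- 10
    states <- if (length(limbs)) frame_states(steps) else NULL
    # swing/stance progress per frame per limb -> blob x offset
    offs <- matrix(0L, nfr, max(1L, length(limbs)))
    for (li in seq_along(limbs)) {
      iv <- steps$intervals[steps$intervals$limb == limbs[li], ]
      for (r in seq_len(nrow(iv))) {
        sel <- which(tmid >= iv$start_s[r] & tmid < iv$end_s[r])
        if (!length(sel)) next
        prog <- (tmid[sel] - iv$start_s[r]) / (iv$end_s[r] - iv$start_s[r])
        offs[sel, li] <- if (iv$phase[r] == "swing")
          round(amp * prog) else round(amp * (1 - prog))
      }
    }
    body_rows <- 17:40; body_cols <- 17:48
    contrast <- c(50, 120, 85)
    frames <- array(0L, dim = c(h, w, nfr))
    for (i in seq_len(nfr)) {
      fr <- bg
      if (moving[i]) {
        tex <- matrix(stats::runif(length(body_rows) * length(body_cols), -1, 1),
                      length(body_rows))
        fr[body_rows, body_cols] <- 120 + contrast[(i %% 3) + 1L] * tex
      }
      for (li in seq_along(limbs)) {
        x0 <- base_x[li] + offs[i, li]
        fr[45:52, x0:(x0 + 5)] <- 220
      }
      if (cfg$frame_noise_sd > 0)
        fr <- fr + stats::rnorm(h * w, 0, cfg$frame_noise_sd)
      frames[, , i] <- pmax(0L, pmin(255L, round(fr)))
    }
    out <- frame_stack(frames, cfg$video_fps)
    attr(out, "moving") <- moving
    out
  })
}

#' Simulate a complete synthetic recording session
#'
#' Convenience wrapper running the full generator: gait annotation, EPSC /
#' mossy-fiber / granule-cell event trains, a voltage-clamp trace with ground
#' truth, and (optionally) behaviour video frames.
#'
#' @param cfg A [sim_config()].
#' @param video Render frames as well (slower)?
#' @return List with `steps`, `epsc`, `mf`, `gc`, `vc` (trace + truth) and
#'   optionally `frames`.
#' @export
simulate_recording <- function(cfg, video = FALSE) {
  steps <- generate_step_sequence(cfg)
  epsc <- generate_modulated_events(steps, cfg, "epsc")
  out <- list(steps = steps,
              epsc = epsc,
              mf = generate_modulated_events(steps, cfg, "mf_spike"),
              gc = generate_modulated_events(steps, cfg, "gc_spike"),
              vc = synthesize_trace(epsc, cfg, "voltage_clamp"))
  if (video) out$frames <- generate_motion_frames(steps, cfg)
  out
}
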