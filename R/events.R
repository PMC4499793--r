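#' Detect synaptic events or spikes by amplitude threshold
#'
#' EPSC mode applies the classic 2 x SD amplitude-threshold rule: the trace
#' is detrended with a running median (which removes slow baseline and
#' spillover components without touching fast events), the baseline-noise SD
#' is estimated robustly from the detrended trace (MAD), and local minima
#' deflecting beyond `k_sd` noise SDs are reported.  Event time is the peak
#' time and amplitude the peak relative to the local baseline (negative for
#' inward currents).  Spike mode reports upward threshold crossings of a
#' membrane-potential trace with a refractory gap.
#'
#' @param trace A [ts_trace()] in pA (`epsc`) or mV (`spike_vm`).
#' @param mode `"epsc"` or `"spike_vm"`.
#' @param k_sd Threshold in baseline-noise SDs (EPSC mode).
#' @param median_ms Running-median detrending window, ms.
#' @param min_sep_ms Minimum separation enforced between detected events, ms.
#' @param spike_thr_mv Voltage threshold for spike mode, mV.
#' @param refractory_ms Spike-mode refractory period, ms.
#' @return An [event_train()]; EPSC events carry negative peak amplitudes.
#'   The estimated noise SD is attached as attribute `noise_sd`.
#' @export
detect_events <- function(trace, mode = c("epsc", "spike_vm"), k_sd = 2,
                          median_ms = 20, min_sep_ms = 1,
                          spike_thr_mv = -10, refractory_ms = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "ts_trace"))
  x <- trace$values
  if (!length(x)) stopf("empty trace")
  fs <- trace$fs

  if (mode == "spike_vm") {
    if (trace$units != "mV") stopf("spike_vm mode expects a voltage trace in mV")
    up <- which(x[-1] >= spike_thr_mv & x[-length(x)] < spike_thr_mv) + 1L
    if (length(up) > 1) {
      # enforce sequential refractory, not just pairwise
      last <- up[1]; sel <- up[1]
      for (i in up[-1]) if ((i - last) / fs >= refractory_ms / 1000) {
        sel <- c(sel, i); last <- i
      }
      up <- sel
    }
    return(event_train(trace$t0 + (up - 1) / fs, modality = "gc_spike",
                       duration = trace$t0 + length(x) / fs))
  }

  if (trace$units != "pA") stopf("epsc mode expects a current trace in pA")
  k <- 2L * floor(median_ms / 1000 * fs / 2) + 1L  # odd window
  base <- stats::runmed(x, k, endrule = "median")
  d <- x - base
  # robust baseline-noise estimate from successive differences: slow
  # components cancel and the sparse fast-event rises are rejected by the
  # median, leaving the white recording noise
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (noise_sd == 0) stopf("no baseline variability found")
  thr <- -k_sd * noise_sd
  ev <- find_negative_peaks(d, fs, thr, min_sep_ms)
  if (!length(ev))
    return(structure(event_train(numeric(0), numeric(0), "epsc",
                                 trace$t0 + length(x) / fs),
                     noise_sd = noise_sd))
  structure(event_train(trace$t0 + (ev - 1) / fs, d[ev], "epsc",
                        trace$t0 + length(x) / fs),
            noise_sd = noise_sd)
}

# Local minima below `thr` separated by at least min_sep_ms, keeping the
# deeper peak of any conflicting pair.
find_negative_peaks <- function(d, fs, thr, min_sep_ms) {
  n <- length(d)
  cand <- which(d < thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[d[cand] <= d[cand - 1L] & d[cand] < d[cand + 1L]]
  if (!length(cand)) return(integer(0))
  sep <- max(1L, round(min_sep_ms / 1000 * fs))
  ord <- cand[order(d[cand])]  # most negative first
  taken <- integer(0)
  for (i in ord)
    if (!length(taken) || min(abs(taken - i)) >= sep) taken <- c(taken, i)
  sort(taken)
}

#' Group events into bursts
#'
#' A burst is a maximal run of consecutive inter-event intervals shorter
#' than `max_isi_ms` containing at least `min_spikes` events.  With the
#' defaults this is the current-clamp rule (3+ spikes, ISI < 50 ms); setting
#' `min_spikes = 5, max_isi_ms = 5` reproduces the EPSC-burst rule (5+
#' events at 200 Hz or more).
#'
#' @param train An [event_train()].
#' @param min_spikes Minimum events per burst (>= 2).
#' @param max_isi_ms Maximum intra-burst inter-event interval, ms.
#' @return Data frame, one row per burst: `onset_s`, `n_spikes`,
#'   `mean_isi_ms`, `first`, `last` (indices into the train).
#' @export
group_bursts <- function(train, min_spikes = 3, max_isi_ms = 50) {
  stopifnot(inherits(train, "event_train"))
  if (min_spikes < 2) stopf("min_spikes must be >= 2")
  tt <- train$times
  out <- data.frame(onset_s = numeric(0), n_spikes = integer(0),
                    mean_isi_ms = numeric(0), first = integer(0),
                    last = integer(0))
  if (length(tt) < min_spikes) return(out)
  fast <- diff(tt) < max_isi_ms / 1000
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths >= min_spikes - 1L)) {
    i1 <- starts[j]; i2 <- ends[j] + 1L  # event indices
    out <- rbind(out, data.frame(
      onset_s = tt[i1], n_spikes = i2 - i1 + 1L,
      mean_isi_ms = mean(diff(tt[i1:i2])) * 1000,
      first = i1, last = i2))
  }
  out
}

#' Event rate as a binned or kernel-smoothed series
#'
#' Either bins event counts (counts / bin width, Hz) or convolves the delta
#' train with a causal exponential kernel of unit integral, so that in both
#' cases the time integral of the rate equals the event count.
#'
#' @param train An [event_train()].
#' @param bin_s Bin width in seconds (binned mode).
#' @param causal_exp_tau_ms Kernel time constant in ms (kernel mode);
#'   supply exactly one of `bin_s` / `causal_exp_tau_ms`.
#' @param fs Output sampling rate for kernel mode, Hz.
#' @param duration Series duration (defaults to the train's duration).
#' @return A [rate_series_obj()].
#' @export
rate_series <- function(train, bin_s = NULL, causal_exp_tau_ms = NULL,
                        fs = 1000, duration = NULL) {
  stopifnot(inherits(train, "event_train"))
  if (is.null(duration)) duration <- train$duration
  if (is.null(bin_s) == is.null(causal_exp_tau_ms))
    stopf("specify exactly one of bin_s or causal_exp_tau_ms")
  if (!is.null(bin_s)) {
    if (bin_s <= 0) stopf("bin width must be positive")
    cnt <- bin_counts(train$times, duration, bin_s)
    return(rate_series_obj(cnt / bin_s, 1 / bin_s,
                           kind = sprintf("binned %.4g s", bin_s)))
  }
  if (causal_exp_tau_ms <= 0) stopf("tau must be positive")
  n <- max(1L, round(duration * fs))
  counts <- numeric(n)
  idx <- pmin(n, floor(train$times * fs) + 1L)
  if (length(idx)) {
    tb <- tapply(rep(1, length(idx)), idx, sum)
    counts[as.integer(names(tb))] <- tb
  }
  rate_series_obj(exp_rate_filter(counts, fs, causal_exp_tau_ms / 1000), fs,
                  kind = sprintf("causal exp tau %g ms", causal_exp_tau_ms))
}

#' Summary statistics of an event train
#'
#' Mean rate, mean instantaneous frequency, ISI coefficient of variation,
#' and burst statistics if bursts are supplied.  The CV needs at least two
#' intervals (three events); with fewer it is returned as `NA` with a
#' warning rather than silently.
#'
#' @param train An [event_train()].
#' @param bursts Optional burst table from [group_bursts()].
#' @return Named list of statistics.
#' @export
train_statistics <- function(train, bursts = NULL) {
  stopifnot(inherits(train, "event_train"))
  tt <- train$times
  n <- length(tt)
  dur <- train$duration
  isi <- diff(tt)
  cv <- NA_real_
  if (length(isi) >= 2) cv <- stats::sd(isi) / mean(isi)
  else warnf("ISI CV undefined: need at least 3 events, got %d", n)
  out <- list(n_events = n,
              mean_rate_hz = if (dur > 0) n / dur else NA_real_,
              mean_inst_freq_hz = if (length(isi)) mean(1 / isi) else NA_real_,
              mean_isi_s = if (length(isi)) mean(isi) else NA_real_,
              isi_cv = cv)
  if (!is.null(bursts)) {
    out$n_bursts <- nrow(bursts)
    out$mean_spikes_per_burst <- if (nrow(bursts)) mean(bursts$n_spikes) else NA_real_
    out$mean_intraburst_isi_ms <- if (nrow(bursts)) mean(bursts$mean_isi_ms) else NA_real_
    out$mean_interburst_s <- if (nrow(bursts) > 1) mean(diff(bursts$onset_s)) else NA_real_
  }
  out
}

#' Subthreshold depolarisation underlying a burst
#'
#' Mean membrane potential over the 5-ms window starting 1 ms after the
#' first spike of the burst, minus a baseline defined as the mean over a
#' 180-ms window ending 20 ms before the first spike.
#'
#' @param vm A [ts_trace()] in mV.
#' @param burst One row of a [group_bursts()] table (or a list with
#'   `onset_s`).
#' @return Signed depolarisation in mV.
#' @export
burst_depolarization <- function(vm, burst) {
  stopifnot(inherits(vm, "ts_trace"), vm$units == "mV")
  onset <- burst$onset_s
  fs <- vm$fs
  i0 <- round((onset - vm$t0) * fs) + 1L
  resp <- (i0 + round(0.001 * fs)):(i0 + round(0.006 * fs))
  base <- (i0 - round(0.200 * fs)):(i0 - round(0.020 * fs))
  if (min(base) < 1 || max(resp) > length(vm$values))
    stopf("burst at %.3f s: analysis windows exceed trace bounds", onset)
  mean(vm$values[resp]) - mean(vm$values[base])
}

#' Bootstrap confidence interval for a rate ratio
#'
#' Percentile CI for the ratio of mean event rates of two recordings.
#' Because resampling raw event times cannot change a count, resampling is
#' done over 1-s segments of each train (or over cells when lists of trains
#' are supplied), with replacement.  `paired = TRUE` reuses the same
#' resample indices for numerator and denominator, which makes the interval
#' degenerate at 1 for identical inputs.
#'
#' @param numerator,denominator [event_train()] objects, or lists of trains
#'   (one per cell) for cell-level resampling.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param level Confidence level.
#' @param segment_s Segment length for within-train resampling, seconds.
#' @param paired Use common resample indices for both trains?
#' @param seed RNG seed.
#' @return List with `ratio`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_ratio_ci <- function(numerator, denominator, n_boot = 1000,
                               level = 0.95, segment_s = 1, paired = FALSE,
                               seed = 1L) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  seg_rates <- function(x) {
    if (inherits(x, "event_train")) {
      if (x$duration < segment_s) stopf("train shorter than one segment")
      nseg <- floor(x$duration / segment_s)
      bin_counts(x$times, nseg * segment_s, segment_s) / segment_s
    } else vapply(x, function(tr) length(tr$times) / tr$duration, numeric(1))
  }
  num <- seg_rates(numerator)
  den <- seg_rates(denominator)
  if (mean(den) == 0) stopf("denominator has no events")
  ratio <- mean(num) / mean(den)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(num), replace = TRUE)
      j <- if (paired && length(den) == length(num)) i
           else sample.int(length(den), replace = TRUE)
      d <- mean(den[j])
      if (d == 0) NA_real_ else mean(num[i]) / d
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    list(ratio = ratio, lower = qs[1], upper = qs[2], n_boot = length(reps))
  })
}
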