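#' Timestamped point-process container
#'
#' An event train is the basic representation of detected or simulated point
#' events: EPSC times, granule-cell spikes, or mossy-fiber spikes, with
#' optional per-event amplitudes in pA (inward currents are negative).
#'
#' @param times Numeric vector of event times in seconds, strictly increasing.
#' @param amps Optional numeric vector of amplitudes (pA), same length as
#'   `times`.
#' @param modality One of `"epsc"`, `"gc_spike"`, `"mf_spike"`, `"generic"`.
#' @param duration Recording duration in seconds (defaults to the last event
#'   time); used to compute rates.
#' @return An object of class `event_train`.
#' @export
event_train <- function(times, amps = NULL, modality = "generic",
                        duration = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stopf("event times must be strictly increasing")
  if (!is.null(amps) && length(amps) != length(times))
    stopf("amps must match times in length")
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  structure(list(times = times, amps = amps, modality = modality,
                 duration = as.numeric(duration)),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  r <- if (x$duration > 0) length(x$times) / x$duration else NA_real_
  cat(sprintf("<event_train> %s: %d events over %.1f s (%.2f Hz)%s\n",
              x$modality, length(x$times), x$duration, r,
              if (is.null(x$amps)) "" else ", with amplitudes"))
  invisible(x)
}

#' @export
length.event_train <- function(x) length(x$times)

#' Uniformly sampled current or voltage trace
#'
#' @param values Numeric vector of samples (pA for current, mV for voltage).
#' @param fs Sampling rate in Hz.
#' @param units `"pA"` or `"mV"`.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `ts_trace`.
#' @export
ts_trace <- function(values, fs, units = c("pA", "mV"), t0 = 0) {
  units <- match.arg(units)
  if (fs <= 0) stopf("fs must be positive")
  if (!all(is.finite(values))) stopf("trace values must be finite")
  structure(list(values = as.numeric(values), fs = fs, units = units,
                 t0 = t0),
            class = "ts_trace")
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("<ts_trace> %d samples at %g kHz (%.2f s), units %s\n",
              length(x$values), x$fs / 1000, length(x$values) / x$fs, x$units))
  invisible(x)
}

#' @export
plot.ts_trace <- function(x, ...) {
  t <- x$t0 + seq_along(x$values) / x$fs
  graphics::plot(t, x$values, type = "l", xlab = "time (s)",
                 ylab = x$units, ...)
}

trace_times <- function(trace) trace$t0 + (seq_along(trace$values) - 1) / trace$fs

#' Binned or kernel-smoothed rate series
#'
#' @param values Rate samples (Hz), or mean current (pA) for spillover
#'   summaries.
#' @param fs Sample rate of the series (1/bin width) in Hz.
#' @param kind Description of how the series was formed.
#' @param units Unit tag, default `"Hz"`.
#' @return An object of class `rate_series`.
#' @export
rate_series_obj <- function(values, fs, kind = "binned", units = "Hz") {
  structure(list(values = as.numeric(values), fs = fs, kind = kind,
                 units = units),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %s, %d samples at %.4g Hz, mean %.2f %s\n",
              x$kind, length(x$values), x$fs, mean(x$values), x$units))
  invisible(x)
}

#' Per-limb swing/stance annotation on the video timebase
#'
#' Stores, for each forelimb, the ordered swing and stance intervals in
#' seconds, together with the video frame rate.  The swing phase starts when
#' the paw leaves the ball and ends at renewed contact; frames outside
#' locomotion bouts carry no step label ("quiet").
#'
#' @param intervals Data frame with columns `limb`, `phase`
#'   (`"swing"`/`"stance"`), `start_s`, `end_s`.
#' @param fps Video frame rate, Hz.
#' @param duration Total duration covered, seconds.
#' @return An object of class `step_annotation`.
#' @export
step_annotation <- function(intervals, fps, duration) {
  stopifnot(all(c("limb", "phase", "start_s", "end_s") %in% names(intervals)))
  if (nrow(intervals)) {
    if (any(intervals$end_s <= intervals$start_s))
      stopf("empty or reversed step intervals")
    for (lb in unique(intervals$limb)) {
      iv <- intervals[intervals$limb == lb, ]
      iv <- iv[order(iv$start_s), ]
      if (nrow(iv) > 1 && any(iv$start_s[-1] < iv$end_s[-nrow(iv)] - 1e-9))
        stopf("overlapping intervals for limb %s", lb)
    }
  }
  structure(list(intervals = intervals, fps = fps, duration = duration),
            class = "step_annotation")
}

#' @export
print.step_annotation <- function(x, ...) {
  ns <- sum(x$intervals$phase == "swing")
  cat(sprintf("<step_annotation> %d swing intervals on %d limb(s), %.1f s at %g fps\n",
              ns, length(unique(x$intervals$limb)), x$duration, x$fps))
  invisible(x)
}

#' Swing-onset times for one limb
#'
#' @param ann A [step_annotation()].
#' @param limb Limb name; defaults to the first annotated limb.
#' @return Numeric vector of swing-start times in seconds.
#' @export
swing_onsets <- function(ann, limb = NULL) {
  iv <- ann$intervals
  if (is.null(limb)) limb <- sort(unique(iv$limb))[1]
  sort(iv$start_s[iv$limb == limb & iv$phase == "swing"])
}

#' Stance-onset times for one limb
#' @inheritParams swing_onsets
#' @return Numeric vector of stance-start times in seconds.
#' @export
stance_onsets <- function(ann, limb = NULL) {
  iv <- ann$intervals
  if (is.null(limb)) limb <- sort(unique(iv$limb))[1]
  sort(iv$start_s[iv$limb == limb & iv$phase == "stance"])
}

#' Locomotion bouts implied by a step annotation
#'
#' A bout spans from the first swing onset to the last swing end of a group
#' of steps separated by gaps shorter than `max_gap_s`.
#'
#' @param ann A [step_annotation()].
#' @param max_gap_s Gap that terminates a bout, seconds.
#' @return Data frame with `start_s`, `end_s`.
#' @export
locomotion_bouts <- function(ann, max_gap_s = 1) {
  iv <- ann$intervals
  iv <- iv[order(iv$start_s), ]
  if (!nrow(iv)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  brk <- c(TRUE, iv$start_s[-1] - iv$end_s[-nrow(iv)] > max_gap_s)
  grp <- cumsum(brk)
  data.frame(start_s = tapply(iv$start_s, grp, min),
             end_s = tapply(iv$end_s, grp, max), row.names = NULL)
}

#' Step-cycle phase at arbitrary times
#'
#' Phase is defined per cycle of the given limb: 0 degrees at swing onset,
#' increasing linearly to 360 degrees at the next swing onset.  Times outside
#' any complete cycle get `NA`.
#'
#' @param ann A [step_annotation()].
#' @param t Numeric vector of times, seconds.
#' @param limb Limb name.
#' @return Phase in degrees, `NA` outside locomotion.
#' @export
step_phase <- function(ann, t, limb = NULL) {
  on <- swing_onsets(ann, limb)
  if (length(on) < 2) return(rep(NA_real_, length(t)))
  idx <- findInterval(t, on)
  ph <- rep(NA_real_, length(t))
  ok <- idx >= 1 & idx < length(on)
  # exclude cycles interrupted by a quiet gap (> 2x median cycle)
  cyc <- diff(on)
  med <- stats::median(cyc)
  ok[ok] <- cyc[idx[ok]] <= 2.5 * med
  ph[ok] <- 360 * (t[ok] - on[idx[ok]]) / cyc[idx[ok]]
  ph
}

#' Per-frame swing/stance/quiet state matrix
#'
#' @param ann A [step_annotation()].
#' @return Character matrix, frames x limbs, entries `"swing"`, `"stance"`
#'   or `"quiet"`.
#' @export
frame_states <- function(ann) {
  n <- max(1L, round(ann$duration * ann$fps))
  limbs <- sort(unique(ann$intervals$limb))
  if (!length(limbs)) limbs <- "limb1"
  tmid <- (seq_len(n) - 0.5) / ann$fps
  out <- matrix("quiet", n, length(limbs), dimnames = list(NULL, limbs))
  for (lb in limbs) {
    iv <- ann$intervals[ann$intervals$limb == lb, ]
    for (k in seq_len(nrow(iv))) {
      sel <- tmid >= iv$start_s[k] & tmid < iv$end_s[k]
      out[sel, lb] <- iv$phase[k]
    }
  }
  out
}
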