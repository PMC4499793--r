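#' Convert a synaptic current trace to a conductance trace
#'
#' Divides the current magnitude by the driving force (70 mV for excitation
#' at a -70 mV holding potential), giving nS.  Applied to the phasic sum or
#' the spillover trace of a [fit_spillover()] decomposition before feeding
#' the point-neuron model.
#'
#' @param trace A [ts_trace()] in pA, or a numeric vector in pA.
#' @param driving_force_mv Driving force, mV.
#' @param fs Sampling rate when a bare vector is passed, Hz.
#' @return An object of class `conductance_trace`: `g_ns` (>= 0), `fs`,
#'   `reversal_mv` (0 for excitation).
#' @export
current_to_conductance <- function(trace, driving_force_mv = 70, fs = NULL) {
  if (inherits(trace, "ts_trace")) {
    if (trace$units != "pA") stopf("expected a current trace in pA")
    v <- trace$values; fs <- trace$fs
  } else {
    if (is.null(fs)) stopf("fs required for a bare vector")
    v <- as.numeric(trace)
  }
  structure(list(g_ns = abs(v) / driving_force_mv, fs = fs,
                 reversal_mv = 0),
            class = "conductance_trace")
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf("<conductance_trace> %d samples at %g kHz, mean %.3f nS (Erev %g mV)\n",
              length(x$g_ns), x$fs / 1000, mean(x$g_ns), x$reversal_mv))
  invisible(x)
}

#' Point-neuron parameters for the granule-cell surrogate
#'
#' Exponential integrate-and-fire constants sized for a cerebellar granule
#' cell (small capacitance, high input resistance), with a fixed 1-nS tonic
#' inhibitory conductance reversing at -70 mV and a standard sigmoidal
#' magnesium block for the optional NMDA conductance.
#'
#' @param C_pF Membrane capacitance.
#' @param g_leak_nS Leak conductance.
#' @param E_leak_mV Leak reversal.
#' @param V_T_mV Exponential-threshold parameter.
#' @param delta_T_mV Spike-initiation sharpness.
#' @param V_cut_mV Numerical spike cutoff.
#' @param V_reset_mV Post-spike reset.
#' @param refractory_ms Absolute refractory period.
#' @param g_tonic_inh_nS Tonic inhibitory conductance.
#' @param E_inh_mV Inhibitory reversal.
#' @param mg_mM,mg_slope_per_mV,mg_K_mM Magnesium-block sigmoid parameters
#'   `B(V) = 1 / (1 + Mg * exp(-slope * V) / K)`.
#' @return List of class `gc_params`.
#' @export
gc_params <- function(C_pF = 3, g_leak_nS = 1.5, E_leak_mV = -75,
                      V_T_mV = -40, delta_T_mV = 1.5, V_cut_mV = -20,
                      V_reset_mV = -65, refractory_ms = 2,
                      g_tonic_inh_nS = 1, E_inh_mV = -70,
                      mg_mM = 1, mg_slope_per_mV = 0.062, mg_K_mM = 3.57) {
  p <- as.list(environment())
  if (p$C_pF <= 0 || p$g_leak_nS <= 0) stopf("C and g_leak must be positive")
  structure(p, class = "gc_params")
}

#' Magnesium block factor of the NMDA conductance
#' @param v_mV Membrane potential, mV.
#' @param p A [gc_params()] list.
#' @return Fraction of NMDA conductance unblocked, in (0, 1).
#' @export
mg_block <- function(v_mV, p = gc_params()) {
  1 / (1 + p$mg_mM * exp(-p$mg_slope_per_mV * v_mV) / p$mg_K_mM)
}

#' Integrate the granule-cell point neuron
#'
#' Fixed-step (exponential integrate-and-fire) integration of
#' `C dV/dt = -gL (V - EL) + gL dT exp((V - VT)/dT) - g_inh (V - E_inh)
#' - g_exc V - g_nmda B(V) V` with spike cutoff, reset, and refractoriness.
#'
#' @param g_exc Excitatory conductance drive: a [current_to_conductance()]
#'   trace or numeric vector, nS.
#' @param params A [gc_params()].
#' @param fs Sampling rate when `g_exc` is a bare vector, Hz.
#' @param g_nmda_ratio NMDA:AMPA conductance ratio (0 disables NMDA).
#' @param v0 Initial potential, mV.
#' @return List: `spike_times_s`, `rate_hz`, `vm` (mV trace).
#' @export
simulate_gc <- function(g_exc, params = gc_params(), fs = NULL,
                        g_nmda_ratio = 0, v0 = NULL) {
  if (inherits(g_exc, "conductance_trace")) { g <- g_exc$g_ns; fs <- g_exc$fs }
  else { g <- as.numeric(g_exc); if (is.null(fs)) stopf("fs required") }
  p <- params
  dt <- 1 / fs * 1000  # ms
  if (dt > 0.1) stopf("integration step %.3g ms too large; use fs >= 10 kHz", dt)
  n <- length(g)
  if (is.null(v0))
    v0 <- (p$g_leak_nS * p$E_leak_mV + p$g_tonic_inh_nS * p$E_inh_mV) /
      (p$g_leak_nS + p$g_tonic_inh_nS)
  v <- numeric(n)
  v[1] <- v0
  refr_steps <- round(p$refractory_ms / dt)
  refr <- 0L
  spikes <- numeric(0)
  tau_fac <- dt / p$C_pF  # ms / pF -> mV per (nS*mV)
  for (i in 2:n) {
    if (refr > 0L) {
      v[i] <- p$V_reset_mV
      refr <- refr - 1L
      next
    }
    vi <- v[i - 1]
    I <- -p$g_leak_nS * (vi - p$E_leak_mV) +
      p$g_leak_nS * p$delta_T_mV * exp((vi - p$V_T_mV) / p$delta_T_mV) -
      p$g_tonic_inh_nS * (vi - p$E_inh_mV) -
      g[i] * vi -
      g_nmda_ratio * g[i] * mg_block(vi, p) * vi
    vn <- vi + tau_fac * I
    if (vn >= p$V_cut_mV || !is.finite(vn)) {
      spikes <- c(spikes, (i - 1) / fs)
      v[i] <- p$V_reset_mV
      refr <- refr_steps
    } else v[i] <- max(vn, p$E_inh_mV - 5)
  }
  list(spike_times_s = spikes, rate_hz = length(spikes) / (n / fs), vm = v)
}

#' Spike output from phasic, spillover and combined conductances
#'
#' Feeds the phasic and spillover excitatory conductances separately and
#' summated into the granule-cell point neuron and reports the spike rate
#' per condition, including the combined drive with an NMDA conductance
#' (ratio 0.2, magnesium-blocked).  The synergy of interest is
#' `rate(combined) > rate(phasic) + rate(spillover)`.
#'
#' @param g_phasic,g_spill [current_to_conductance()] traces on a common
#'   timebase.
#' @param params A [gc_params()].
#' @param nmda_ratio NMDA:AMPA ratio for the NMDA condition.
#' @return Named numeric vector of rates (Hz): `spillover`, `phasic`,
#'   `combined`, `combined_nmda`.
#' @export
simulate_and_compare <- function(g_phasic, g_spill, params = gc_params(),
                                 nmda_ratio = 0.2) {
  stopifnot(inherits(g_phasic, "conductance_trace"),
            inherits(g_spill, "conductance_trace"))
  if (g_phasic$fs != g_spill$fs) stopf("conductances must share a timebase")
  n <- min(length(g_phasic$g_ns), length(g_spill$g_ns))
  gp <- g_phasic$g_ns[seq_len(n)]
  gs <- g_spill$g_ns[seq_len(n)]
  fs <- g_phasic$fs
  c(spillover = simulate_gc(gs, params, fs = fs)$rate_hz,
    phasic = simulate_gc(gp, params, fs = fs)$rate_hz,
    combined = simulate_gc(gp + gs, params, fs = fs)$rate_hz,
    combined_nmda = simulate_gc(gp + gs, params, fs = fs,
                                g_nmda_ratio = nmda_ratio)$rate_hz)
}
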