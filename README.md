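# gaitcode

Cerebellar granule cells sit at the input layer of the cerebellar cortex,
are electrically compact, and receive only ~4 mossy-fiber inputs — few
enough that individual excitatory postsynaptic currents (EPSCs) can be
resolved in whole-cell recordings from awake mice walking on a spherical
treadmill. `gaitcode` is an R package for the analyses that link such
recordings to locomotion, aimed at in vivo electrophysiologists working on
sensorimotor coding:

- **Motion-energy video analysis**: recursive background
  `BG_i = α·Frame_i + (1−α)·BG_{i−1}`, difference image, time-smoothed
  motion map, a thresholded motion index, quiet/movement epoch
  classification (0.025 a.u./frame over ≥ 30 frames), activity-triggered
  maps, and 8-frame spatiotemporal PCA with ROI-based component labelling.
- **Event analysis**: 2×SD amplitude-threshold EPSC detection, −10 mV
  spike detection, burst grouping, binned and causal-exponential rate
  series, ISI statistics, burst-associated depolarisation, and a
  segment/cell bootstrap for rate ratios.
- **Spillover decomposition**: per 5-s episode, a nonlinear least-squares
  fit of `g(t) = ß(t) + Σᵢ ampᵢ · ζ(τ_rise, τ_fall, t − Tᵢ)` — a cubic
  spline ß (max-zeroed per episode as drift correction, the putative
  glutamate-spillover current) beneath a train of shared-kinetics
  biexponential events ζ — plus phasic/spillover balance vs EPSC rate,
  charge transfer, rate-to-spillover cross-correlation, and
  burst-triggered spillover averages.
- **Step-cycle analysis**: 40-bin (1.32 s) step-triggered averages σ, the
  modulation index `m = (max σ − min σ)/(max σ + min σ)` with a
  random-window bootstrap, polar phase tuning `R(θ)`, interlimb summaries,
  and the biexponential (50/100 ms) low-pass control.
- **Gait decoding**: an unsupervised two-state hidden Markov model
  (mixture-of-4-Gaussians emissions over sliding 360-ms activity windows,
  Baum–Welch, Viterbi) that reconstructs the swing/stance sequence from a
  single cell's EPSCs or spikes, scored against the annotation with a
  Gaussian-kernel (σ = 100 ms) spike-train similarity and a shuffle null.
- **A granule-cell point-neuron surrogate** (exponential
  integrate-and-fire, 1 nS tonic inhibition, 70 mV driving force,
  magnesium-blocked NMDA option) for testing the phasic/spillover synergy.
- **A seeded synthetic-recording generator** (`sim_config()`,
  `simulate_recording()`) producing gait annotations, phase-modulated
  event trains, voltage/current-clamp traces with exact ground truth, and
  stylised behaviour video, so every stage has a parameter-recovery test.

## Worked example

```r
library(gaitcode)

cfg <- sim_config(seed = 7, duration = 30, ephys_fs = 10000)
rec <- simulate_recording(cfg)
rec$epsc
#> <event_train> epsc: 2892 events over 30.0 s (96.40 Hz), with amplitudes

fit <- fit_spillover(rec$vc$trace, tau_strategy = "trace")
summary(fit)
#> Events: 2879 (96.0 Hz), mean amplitude -29.7 pA
#> Time constants (median): rise 0.96 ms, fall 10.6 ms
#> Spillover: mean -19.4 pA, extreme -67.6 pA
#> Residual RMS: 5.01 pA
```

The fit re-detects essentially all 2892 generated events, recovers the
generating kinetics (τ = 1/10 ms) and amplitude scale (−30 pA mean), and
the residual RMS matches the 5 pA noise floor — the trace is fully
explained by phasic events plus the slow spillover current (here tens of
pA, growing supralinearly with EPSC rate during locomotion bouts).

```r
rate <- rate_series(rec$epsc, bin_s = 1/30)
sta  <- step_triggered_average(rate, rec$steps, limb = "right")
modulation_index(sta, seed = 1)
#> m = 0.332 (z = 5.30, p = 5.7e-08)

evaluate_gait_decoding(rate, rec$steps, "epsc", runs = 5,
                       n_shuffles = 10, shuffle_runs = 1, seed = 2,
                       max_iter = 30)
#> <prediction_score> 13.9% (best limb: left; 5 runs), z = 1.66, p = 0.0486
```

The EPSC rate is significantly modulated by the step cycle (m = 0.33,
far outside the random-window bootstrap null), and the HMM's decoded
stance-to-swing transitions match the annotated steps better than the
shuffled-activity null (one-sided p < 0.05) even on this short,
half-depth-modulated recording; with strong modulation the decoding z
scores reach 6–12.

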