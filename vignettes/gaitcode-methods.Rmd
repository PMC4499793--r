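---
title: "Methods: decoding locomotion from single granule-cell activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding locomotion from single granule-cell activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcode)
```

Cerebellar granule cells are electrically compact and receive only about
four mossy-fiber inputs, which makes it possible to resolve individual
excitatory postsynaptic currents (EPSCs) in whole-cell recordings from
awake, head-fixed mice walking on a spherical treadmill. `gaitcode`
implements the full analysis chain that links those recordings to
locomotion: motion-energy video quantification, threshold event detection,
decomposition of voltage-clamp traces into fast phasic EPSCs and a slow
glutamate-spillover current, step-cycle phase tuning, and an unsupervised
two-state hidden Markov model (HMM) that reconstructs the swing/stance
sequence of a forelimb from a single cell's activity. Because no
recordings are distributed with the package, every stage is exercised
against a seeded synthetic-recording generator with exact ground truth.

## The synthetic recording generator

`sim_config()` fixes the study conditions. The defaults encode the rates
the analyses assume: EPSCs at 77.5 Hz during quiet wakefulness rising to
144 Hz during locomotion, mossy-fiber spiking near 21 Hz at rest,
granule-cell spiking at ~0.1 Hz at rest with high-frequency bursts (4–15
spikes, ~10 ms intra-burst ISI, ~1.9 s between bursts) during movement,
and a cosine step-phase modulation of depth `modulation_depth` around a
preferred phase. Step intervals are gamma distributed (shape 8, CV ≈
0.35) around 120 ms swing / 200 ms stance means — gait statistics are not
constrained by published values, so these are plausible defaults, chosen
once, not fitted. The two forelimbs are offset by a constant quarter-cycle
lag (90°), consistent with the observed clustering of interlimb phase
differences near 90°.

Voltage-clamp traces are composed additively and returned with their exact
decomposition as ground truth:

* a **phasic** component: each event contributes its amplitude (lognormal,
  mean 30 pA, CV 0.3, inward therefore negative) times a unit-peak
  biexponential with τ~rise~ = 1 ms, τ~fall~ = 10 ms;
* a **spillover** component: the event train convolved with a slow
  biexponential kernel (30 ms rise, 150 ms decay — a tunable whose peak
  places the rate-to-spillover lag at a few tens of ms, not a biological
  claim) and scaled supralinearly with the smoothed rate
  (`(rate/100 Hz)^1.5`, 35 pA at the 100 Hz reference), reflecting the
  cooperative accumulation of glutamate in the glomerulus;
* Gaussian recording noise (SD 5 pA).

One convention runs through the package: the printed biexponential
`zeta()` has a peak well below one, so amplitudes multiplying the raw
kernel would not be in units of peak current. Both the generator and the
fitter therefore use the unit-peak-normalised kernel, making every
amplitude a peak picoamp. This is an exact reparameterisation of the same
model.

Event trains are sampled by thinning an inhomogeneous Poisson intensity on
a 1-ms grid, followed by a 1-ms dead time. Everything is a deterministic
function of the configuration, including the seed: per-operation child
seeds keep outputs independent of call order.

The behaviour video is deliberately stylised ("blobs suffice"): a static
textured background, limb blobs that sweep forward in swing and back in
stance (as on a treadmill), and a body region whose texture decorrelates
frame-to-frame during bouts with a cycling contrast — a stand-in for the
strongly fluctuating motion energy of a running mouse. The generator
reproduces the *statistical structure* the analyses assume (static quiet
frames, sustained large frame-to-frame change during bouts, step-locked
limb displacement); it does not attempt realistic appearance, occlusion,
lighting or camera noise, so a green test here says the pipeline's
arithmetic is right, not that it would segment real video.

## Motion-energy pipeline

The video pipeline is the classic recursive background scheme: background
`BG_i = 0.3 Frame_i + 0.7 BG_{i-1}`, difference image `|Frame_i − BG_i|`,
and a time-smoothed difference image (`β = 0.9`) as the motion map. With
α = 0.3 the cumulative recency weight `1 − 0.7^n` first reaches 99.5% at
n = 15 frames, which is the sense in which the background averages "about
the last 15 frames" (`background_window_frames()`). The motion index
counts map pixels above 40 (8-bit) and normalises to the video maximum.
Quiet and movement epochs are runs of at least 30 frames whose index
changes by less (more) than 0.025 a.u. per frame; shorter runs stay
unlabeled, and a 15-frame warm-up guard excludes the background
initialisation transient.

One numerical consequence of the recursion matters for testing: after
motion stops, the contaminated background decays by a factor 0.7 per
frame, so the difference image needs about five frames to fall back below
the map threshold (`255·0.7^k < 40` at k = 5). Frame-exact epoch recovery
is therefore only a well-posed requirement away from transitions; the
epoch-recovery checks assert exact agreement outside a 5-frame settling
margin plus the 30-frame run-length window around each transition.

Motion PCA slides an 8-frame window (stride 1) across the 2×-downsampled
map and takes principal components of the windows-by-pixels matrix
(`stats::prcomp`); region labelling applies the framewise pixel-change
statistic Δ over ROIs with a default threshold of 3000. That threshold
presupposes a particular component scaling; with unit-norm components the
same Δ machinery applies but a correspondingly smaller threshold is
appropriate, so the threshold is exposed rather than hard-wired into any
conclusion.

## Event detection and the spillover decomposition

EPSCs are detected with the 2 × SD amplitude-threshold rule. No standard definition of the baseline segment exists for in vivo
recordings with sustained synaptic bombardment, so the noise SD is
estimated robustly: the trace is detrended with a 20-ms running median (which
removes spillover and drift but not fast events) and the SD taken as
`mad(diff(x))/√2`, which rejects the sparse fast rises and recovers the
white-noise SD accurately even at 100 Hz event rates. Event time is the
peak; amplitude is the peak relative to the local baseline. A 2 × SD
threshold crosses regularly in pure noise — as it must — so downstream
fitting, not detection, is responsible for pruning spurious events.

`fit_spillover()` decomposes each 5-s episode as a cubic-spline slow
baseline plus a train of shared-kinetics biexponential events, the model

$$g(t) = \beta_{C_1\ldots C_N}(t) + \sum_i \mathrm{amp}_i\,
\zeta(\tau_\mathrm{rise}, \tau_\mathrm{fall}, t - T_i).$$

Spline coefficients and amplitudes enter linearly and are profiled out
exactly (sparse normal equations), so the nonlinear search is only over
the τ pair. Design choices that proved load-bearing:

* **Knot spacing 100 ms** (default; exposed as `knot_ms`). A cubic spline
  with 100-ms knots cannot absorb 1/10-ms fast events, but it *can* track
  a spillover current with a 30-ms rise. Coarser spacings leave
  unexplained slow variance that the dense event columns soak up,
  corrupting the amplitudes (amplitude RMS error roughly triples at
  250-ms knots on the synthetic fixture).
* **Onsets held fixed during the τ fit**, then refined separately. The
  event list itself is refined by: residual-driven additions (negative
  residual peaks beyond 2.5 × the residual MAD), backward elimination of
  amplitudes weaker than the 2 × SD event criterion, merging of
  sub-millisecond duplicates, a closed-form two-kernel split test that
  resolves event pairs below the detector's separation limit, and
  cluster-wise joint onset refinement by coordinate descent with the
  member amplitudes re-solved in closed form at every candidate — the
  amplitude attribution of overlapping events is acutely sensitive to
  onset placement, and these steps bring it close to the
  maximum-likelihood optimum. All steps remain within the
  threshold-and-least-squares family; there is no template matching or
  deconvolution.
* **τ optimised after refinement.** Profiling the τ objective on the raw
  detections is treacherous: jittered or merged onsets mimic slow
  kinetics and drive τ to its bounds. With refined onsets the profiled
  objective is well conditioned and Nelder-Mead recovers the generating
  kinetics to a few percent. Bounds are τ~rise~ ∈ [0.2, 5] ms, τ~fall~ ∈
  [2, 50] ms. `fit_spillover()` can re-optimise τ per episode (default),
  estimate it once per trace (`tau_strategy = "trace"`, several-fold
  faster and appropriate since synaptic kinetics are stable within a
  recording), or hold it fixed.

After fitting, the spline trace is shifted so its per-episode maximum is
zero; the shifted trace is the putative spillover current. This drift
correction leaves each episode's DC level unidentified, with two
consequences the package makes explicit. First, the exact reconstruction
identity needs the stored `offset`: phasic + β + offset + residual equals
the input trace to machine precision. Second, fit quality against ground
truth is judged by the per-episode correlation (episodes that never
quiesce are max-zeroed onto the wrong level, which deflates a pooled
correlation for reasons unrelated to fit quality).

Spillover summaries follow directly: the per-event phasic/spillover
balance binned by the τ = 50 ms exponentially smoothed EPSC rate, the
charge transferred per 100-ms window with and without the spillover
component, sliding-window (2 s) normalised cross-correlation between rate
and spillover magnitude on the 33.3-ms video timebase, the average
spillover aligned on bursts of ≥ 5 EPSCs at ≥ 200 Hz, and pairing with
the τ = 660 ms smoothed motion index.

## Step-cycle analysis

Activity binned at the frame duration is triggered on stance (or swing)
onsets into 40-bin (1.32 s) episodes and averaged into σ. The modulation
index is `m = (max σ − min σ)/(max σ + min σ)`, with significance from a
bootstrap that re-triggers one random window per real step; z-scores are
converted to one-sided normal p-values and Bonferroni-corrected by the
family size. The polar representation interpolates σ onto 360°, takes the
absolute deviation from the mean as the radius, and min-subtracts /
max-normalises into [0, 1]; by convention 0° is swing onset. Two
step-window conventions circulate (40 × 33 ms = 1.32 s vs 360 × 5 ms =
1.8 s, which are inconsistent with each other); the 40-bin definition is
taken as authoritative and the polar mapping is a resampling of it. The low-pass control convolves the rate
with a unit-integral biexponential (50 ms rise, 100 ms decay) and
recomputes m, demonstrating that temporal filtering alone suppresses
step-cycle modulation — the argument for why a slow spillover current can
correlate strongly with EPSC rate yet carry no step phase information.

## The gait HMM

Observations are sliding 360-ms windows (11 bins of 33.3 ms, stride one
bin) of the binned activity: EPSC windows divided by the whole-trace mean
rate, spike windows minus the mean of their first 90 ms (3 bins). The 360/90-ms window lengths fix the preprocessing but not the bin
width; the frame duration matches every other analysis and is the
documented choice. The
model is a two-state HMM with four-component Gaussian-mixture emissions.
Covariances are diagonal by default — at 11 dimensions with a few hundred
windows per state, full covariances are poorly conditioned. Priors and
transitions are initialised from the annotation's swing/stance dwell
statistics (`a_{ss} = 1 − 1/\bar d_s` in bins, state 1 anchored to
"swing"); the annotation is never shown to the learning procedure beyond
this initialisation. Emission parameters start at random; Baum-Welch runs
with scaled forward-backward until the relative log-likelihood gain falls
below `tol` (degenerate mixture components are re-seeded and counted, and
the log-likelihood is non-decreasing across clean iterations to 1e-9).
Viterbi decoding produces the state path; stance-to-swing transitions are
the predicted swing onsets.

Predictions are scored by converting predicted and annotated step
sequences into transition trains, convolving both with a σ = 100 ms
Gaussian, and taking the peak of the normalised, mean-subtracted
cross-correlation. Normalisation is per lag over the overlapping segment,
so a pure time shift within the searched range (± 500 ms, exposed) scores
exactly 1; negative peaks are clamped to 0 so the score lies in [0, 1]
(the unclamped value is kept as an attribute). A cell's score is the mean
over 10 train/decode runs, scored per limb with the best-predicted limb
reported, and significance comes from re-running the whole procedure on
shuffled versions of the binned activity. One model is trained per cell
and scored against each limb.

A caveat worth stating: on synthetic recordings containing both quiet and
locomotion, the dominant two-state structure is quiet-versus-moving, and
EM often converges to it rather than to swing-versus-stance. The shuffle
null is computed through the identical procedure, so the significance
statement — "the decoded transition train matches the annotated steps far
better than chance" — remains calibrated, as the depth-0 control
demonstrates.

## The granule-cell point-neuron surrogate

The multi-compartment granule-cell model used for the original
simulations is out of scope; in its place stands an exponential
integrate-and-fire surrogate with granule-cell-like constants (C = 3 pF,
g~leak~ = 1.5 nS, threshold −40 mV, reset −65 mV, 2 ms refractory), a
fixed 1-nS tonic inhibitory conductance reversing at −70 mV, and a 70-mV
driving force converting recorded currents to excitatory conductances.
The NMDA option scales the excitatory conductance by the NMDA:AMPA ratio
(0.2) under a standard magnesium-block sigmoid
(`B(V) = 1/(1 + [Mg] e^{−0.062V}/3.57)`, [Mg] = 1 mM), which passes less
than 5% of the NMDA conductance at −70 mV. Integration is forward Euler
at the 50-µs data step.

The property of interest is qualitative: the combined phasic + spillover
drive produces more spikes than the two components separately summed —
the sustained spillover depolarisation moves the cell close to threshold
so that phasic events, which alone are mostly subthreshold, trigger
spikes. The surrogate reproduces this synergy robustly. Its absolute
rates are not comparable to the published simulation rates, which depend
on the unreleased recorded conductances and the compartmental model, and
near its operating point the surrogate's rate is steeply sensitive to
small current changes, so the NMDA condition raises the rate by more than
the few percent a compartmental model shows; only the direction (a modest
increase, from a conductance that is > 95% blocked at rest) is asserted.

## Statistical machinery

Shuffle significance uses full random permutation of the binned activity
(destroying autocorrelation; a block shuffle is available), a z-score
against the permutation null, one-sided normal p-values, and Bonferroni
correction — including the normal approximation, which keeps the machinery simple
and, as the calibration runs show, slightly conservative. The rate-ratio bootstrap resamples 1-s segments (or cells,
for grouped input) because resampling raw event times cannot change a
count; the paired option reproduces the degenerate interval for identical
inputs.

## Problem sizes and what the tests show

The test suite and the acceptance script run entirely on the generator:
spillover recovery on ten 60-s, ~100-Hz traces at 20 kHz (amplitude
errors pooled across ~58,000 events); gait decoding on twenty continuously locomoting 40-s
recordings per modulation depth with 10 training runs and 16 shuffle
replicates each (continuous locomotion isolates step-phase information:
with quiet gaps present, bout timing alone correlates decoded
transitions with the annotation and would confound the zero-depth null); modulation calibration on 200 unmodulated replicates;
epoch recovery on a 60-s video. These sizes were chosen to give stable
statistics at single-digit-minute runtimes on one CPU. Passing them
establishes parameter recovery and calibration under the generator's
assumptions — Poisson-like trains, stationary kinetics, additive Gaussian
noise, stylised video — and says nothing about electrode drift, series
resistance changes, movement artifacts, or real video statistics, all of
which the original study handled by inspection and exclusion.
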