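---
title: "Recurrence-network analysis of subthalamic LFPs for demand-driven DBS"
author: "tremorRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-network analysis of subthalamic LFPs for demand-driven DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorRN)
```

## The problem

Resting tremor in Parkinson's disease is treated, when medication fails,
by high-frequency deep brain stimulation (DBS) of the sub-thalamic
nucleus (STN). Current stimulators run continuously; a demand-driven
device would instead switch stimulation on just before overt tremor and
off once the patient returns to rest. That requires a signal, readable
from the STN local field potential (LFP) alone, that changes *ahead of*
the physical symptom.

The working hypothesis implemented here is dynamical: STN activity is an
essentially linear-stochastic process at rest (`NT`), becomes markedly
nonlinear during overt tremor (`T`), and the transition (`TO`, tremor
onset) carries an abrupt, transient rise of nonlinearity that precedes
the symptom. The package quantifies that nonlinearity window by window
with epsilon-recurrence networks and builds a closed-loop start/stop
controller on top of it.

## The pipeline

1. **Conditioning.** LFPs are downsampled to 125 Hz (anti-alias FIR +
   exact-grid resampling) and band-passed 2-45 Hz with a 500th-order
   Hamming FIR, using two seconds of the recording's own edge data as
   filter padding and compensating the group delay, so window time stamps
   stay aligned. EMG is high-passed above 30 Hz (zero-phase), rectified
   by the Hilbert envelope, then band-passed 2-45 Hz; its amplitude
   grounds the tremor timing: the onset is the earliest sample whose
   amplitude exceeds three times the mean over the first 5 s *and* whose
   following 5 s stay above that threshold on average (single spikes do
   not trigger).
2. **Windowing.** 2-s windows with 90% overlap (hop 0.2 s); each
   window's measures are assigned to its mid-point.
3. **Embedding.** The delay `tau` is the first local minimum of the
   auto-mutual information; the dimension `m` is the first for which the
   false-nearest-neighbour fraction drops to 1%. Both are estimated once
   per recording, from its initial (assumed atremorous) stretch, and
   held fixed across windows so the networks are comparable.
4. **Recurrence network.** Within each window the delay vectors become
   vertices; two vertices are linked when their maximum-norm distance is
   at most epsilon, where epsilon is set per window so that 3% of state
   pairs are recurrent (fixed recurrence rate rather than fixed
   epsilon). Global clustering `C`, transitivity `T` and degree
   assortativity `A` summarise the attractor geometry: structured,
   low-dimensional dynamics close more triangles at equal edge density.
5. **Significance bands.** Each measure's series is smoothed by a
   centred 21-window moving median; the residual scale `sigma` yields
   `+/-2 sigma` and `+/-3 sigma` bands around the median track, read as
   nominal p < 0.05 / p < 0.01 transient labels.
6. **Controller.** With stimulation off, the mean of the current and
   four previous clustering values is compared against
   `median + 2 sigma`; exceedance triggers `START`. With stimulation
   on, a per-patient SVM (radial kernel, class-balanced, features =
   per-window `(C, T, A)` plus their five-window means, standardised)
   classifies each window; an `NT` verdict triggers `STOP`. Validity is
   reported from ten-fold cross-validation as a pooled confusion matrix
   (ACC, sensitivity, specificity, FPR = 100 - specificity,
   FNR = 100 - sensitivity).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| target rate | 125 | Hz | twice the 45-Hz band edge plus margin; keeps windows at 250 samples |
| band | 2-45 | Hz | removes movement artefacts (~1 Hz) and 50-Hz line noise |
| filter order | 500 | taps | narrow transitions at 125 Hz; 2 s of padding absorbs the transient |
| window / overlap | 2 s / 90% | | short enough for non-stationarity, dense enough for 0.2-s resolution |
| recurrence rate | 0.03 | | equal edge budget across windows makes measures comparable |
| median window | 21 | windows | ~4.2 s: smooths estimation noise, passes few-second transients |
| trigger | 2 sigma | | conservative relative to the 3-sigma peaks seen at transitions |
| memory | 4 | windows | the controller stores only the four previous measures |

## Numerical and design choices

* **Mutual information** is a plug-in histogram estimate on a coarse
  8-bin equal-width partition, averaged over four shifted histogram
  origins. Origin averaging suppresses lattice artefacts on strongly
  periodic signals; with it, a tremor-band sinusoid attains its first
  local minimum at a quarter period, the canonical benchmark. (An
  equal-occupancy partition was tried first and rejected: on a noiseless
  sinusoid its dense-limit curve has no quarter-period minimum at all.)
  Weak local minima resolve to the smallest lag; a curve with no
  interior minimum falls back to the first drop below `MI(0)/e`.
* **FNN** uses the two Kennel criteria (ratio threshold 10, absolute
  threshold 2 attractor sizes), a loneliness guard that drops points
  whose nearest neighbour is farther than one standard deviation, and a
  relative distance floor so exact trajectory revisits of periodic
  signals are not scored as false from floating-point noise ratios.
* **Epsilon quantile.** Epsilon is the smallest pairwise distance whose
  cumulative fraction reaches the requested rate; boundary distances
  count as recurrent, so the achieved rate is never below the request
  and is tie-stable.
* **Low-degree vertices** contribute a zero local clustering
  coefficient rather than being dropped, keeping `C` defined on sparse
  windows; assortativity on a regular (zero-variance) degree sequence is
  reported as missing, never fabricated.
* **Sigma of the bands** is the Gaussian-consistent Rousseeuw-Croux
  `Qn` scale of the residuals over the whole recording. Three properties
  forced this choice, each measured by Monte-Carlo on synthetic
  recordings: a 5-s baseline pool contains only ~4 effectively
  independent residuals (windows overlap 90%), so its scale estimate is
  noisy enough to break the nominal 3-sigma calibration under the null;
  a plain standard deviation over the whole recording is inflated ~40%
  by tremor-segment residuals and masks the transition peak; and the
  low-efficiency MAD re-breaks the null calibration. `Qn` combines
  50% breakdown with near-normal efficiency. The 5-s-baseline pool
  remains available (`baseline = "baseline"`).
* **Controller hysteresis.** After a `STOP` the start trigger stays
  disarmed until the averaged measure has returned to the median track.
  Windows straddling the tremor offset combine elevated measures with
  rest labels; without hysteresis the loop chatters `START`/`STOP`
  across that boundary.
* **Cross-validation.** Stratified random folds are the default; a
  contiguous-block mode is provided and recommended for honest error
  estimates, because 90%-overlapping windows leak heavily between
  random folds.

## What the synthetic generator emulates — and what it does not

`generateRecording()` builds labelled LFP+EMG pairs from the model the
method assumes:

* `NT`: a unit-variance resonant AR(2) process (poles near 20 Hz,
  ~20 Hz bandwidth) plus white measurement noise at 10 dB SNR —
  band-limited, linear, stochastic.
* `T`: the x-component of a Rossler oscillator, integrated so its
  dominant frequency is the tremor frequency (default 5 Hz), mixed at
  weight 0.8 with the rest process — nonlinear, oscillatory, weakly
  chaotic.
* `TO`: the mixing weight follows the default `"overshoot"` schedule —
  an abrupt surge (Gaussian transient, ~3 s wide: long enough to
  survive the 2-s analysis window, shorter than the 4.2-s median
  filter) that recedes to an intermediate level and rises again into
  `T`. This reproduces the phenomenology the method exploits: the
  clustering coefficient spikes early in the transition, relaxes, and
  climbs again just before overt tremor. Plain monotone `"sigmoid"` and
  `"linear"` cross-fades are available; note that a monotone ramp is
  largely absorbed by the moving-median bands, which is itself an
  informative negative control.
* EMG: a 40-120 Hz carrier whose amplitude is multiplied by
  tremor-locked bursts beginning midway through `TO` — the muscle lags
  the neural change, which is precisely the window a demand-driven
  trigger exploits.

The generator does **not** emulate: non-stationary baseline drift,
stimulation or movement artefacts, beta-band bursting unrelated to
tremor, electrode noise with 1/f structure, or any biophysical
basal-ganglia circuitry. Passing tests therefore demonstrate that the
pipeline detects an abrupt nonlinearity transient against a stationary
linear background at realistic SNR — not that it would survive every
artefact of a clinical recording.

Scale of the shipped validations: Monte-Carlo suites use 100 seeds of
40-55-s recordings at a 1 kHz synthesis rate; embedding benchmarks use
2000-5000 samples. These sizes give binomial standard errors of ~3
percentage points on the reported rates.

## Degenerate inputs and edge handling

Constant windows, or windows whose embedded states are all identical,
are flagged and carried as missing, never interpolated; missing
assortativity values are excluded from its median and sigma. The
centred moving median shrinks its half-window near the series ends
rather than padding; in "baseline" sigma mode, edge windows whose
median support had to shrink are excluded from the scale pool (their
residuals are structurally near zero). Label intervals are half-open
`[start, end)`, so adjacent segments tile the recording without
overlap.

## Known limitations

* The closed loop's `START` specificity is bounded by the 2-sigma
  trigger itself: with ~0.2-s hops and four-window memory, rest-state
  fluctuations cross a 2-sigma band roughly once per minute of
  exposure, so over long rest stretches occasional false starts (each
  corrected by the stop classifier within a window) are expected by
  construction. The trigger level and memory are configurable.
* The per-recording embedding selection inherits FNN's noise
  sensitivity: at 10 dB SNR the false-neighbour fraction plateaus above
  1% and the selector falls back to the largest dimension tested, with
  a warning. The measures are robust to this (see the dimension sweep
  in `robustnessSweep()`), which is the design argument for fixing
  parameters at implantation time.
* EDF support is a minimal 16-bit continuous-EDF reader/writer;
  amplitudes round-trip only to one quantization step.
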