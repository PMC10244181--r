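---
title: "Methods: closed-loop slow-oscillation stimulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop slow-oscillation stimulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sleeploop implements the analysis stack of a closed-loop deep-brain
stimulation sleep experiment: during NREM sleep, slow oscillations detected
online on a medial-temporal-lobe (MTL) probe trigger brief electrical pulse
trains timed into the slow-wave active phase; the analysis then asks whether
stimulation enhanced sleep spindles, ripple-slow-wave coupling, spike-field
phase locking, and overnight memory. This vignette records the models, the
parameter choices, and the numerical decisions behind each stage, and what
the synthetic ground-truth conditions do and do not establish about real
recordings.

## The synthetic recording and what it emulates

Real iEEG of this kind is not publicly available, so every stage is
validated against `generate_recording()`, which synthesizes NREM sleep with
a complete ground-truth ledger. Per channel it sums:

* **1/f^a background** (default a = 1.5, SD 10 uV) plus 60-Hz mains hum
  (5 uV).
* **Continuous NREM band activity**: 0.5-2 Hz delta (SD 15 uV) and 9-16 Hz
  sigma (SD 2 uV) noise present only in NREM. These give the sleep scorer
  its state contrast, and the delta component supplies the population of
  small slow-wave candidates against which the slow-wave detector's
  75th-percentile amplitude criterion operates.
* **Slow waves**: one tapered sine cycle (positive/inactive half then
  negative/active half, mean 350 uV peak-to-trough, 15% CV, 0.75-1.15 Hz so
  durations span 0.9-1.3 s). Waves are placed as a quasi-rhythmic
  gamma-renewal train (11/min with a 0.6-s refractory gap) rather than a
  Poisson process: slow oscillations arrive in regular trains, and the
  renewal train holds the injected population near one quarter of all
  slow-band candidates — the operating point at which an exact
  top-quartile amplitude rule can be both sensitive and precise. The short
  (10%) edge taper keeps the waveform C1-smooth; un-tapered cycles leave
  derivative kinks whose broadband splatter trips the spindle detector's
  20-30 Hz veto.
* **Spindles**: 13-Hz bursts with a flat-top (Tukey, 30% taper) envelope,
  30 uV, 0.6-1.8 s. The flat envelope matters: with a fully tapered (Hann)
  envelope the detector's mean + 1 SD boundary threshold sees less than
  0.5 s of a short burst and the duration gate rejects it. With probability
  `spindle_coupling_prob` (default 0.7) the spindle peak is placed within
  1.5 s after a slow-wave positive peak.
* **Ripples**: 90-Hz Hann bursts, 50-100 ms, 20 uV, coupled to the
  slow-wave positive peak at a 200-ms delay with probability 0.7.
* **Interictal-discharge-like transients**: one sharp biphasic cycle,
  30-60 ms, amplitude 8 SD *of the composite NREM signal* — the same scale
  the IED detector z-scores against.

The generator reproduces the statistical structure the detectors assume
(spectral content, durations, coupling windows, amplitude scales) but not
waveform realism: no travelling waves, no sleep-depth drift, no
multi-channel volume conduction, no true epileptiform morphology. Passing
the validation suite therefore shows the algorithms implement their
definitions correctly at realistic SNR; it does not certify detection
performance on clinical data.

## Preprocessing

Line noise is removed with zero-phase 2-Hz-wide second-order Butterworth
band-stops at 60 Hz and harmonics below Nyquist. IED detection z-scores
three per-sample features over valid NREM time — absolute amplitude,
gradient, and the Hilbert envelope of the high-passed signal — and flags
events where the envelope exceeds +5 SD, or amplitude and gradient both do.
Two numerical choices deserve note. First, the amplitude/gradient
conjunction is event-level (both features above threshold somewhere inside
one merged run): within a single transient the amplitude extremum and the
steepest gradient never coincide at one sample. Second, the <70-ms duration
cap applies to the conjunction path only; the envelope path has no cap,
because the zero-phase high-pass ringing outlasts the transient itself. The
envelope high-pass defaults to 250 Hz and is lowered to 0.4x the sampling
rate for recordings sampled below 625 Hz, where 250 Hz is not below
Nyquist. Detections closer than 50 ms merge; +/-500 ms around each IED is
blanked; channels above 5 IEDs/min are excluded; kurtosis/skewness outliers
against same-electrode channels (|z| > 3) are flagged for review only,
preserving the human-in-the-loop step as a report.

## Sleep scoring

Thirty-second epochs yield mean power in the slow-wave (0.5-4 Hz) and
sigma (9-16 Hz) bands; epochs more than half masked are missing, lesser
gaps are linearly interpolated. A two-component full-covariance Gaussian
mixture is fitted to the joint log10 powers (mclust's
hierarchical-agglomeration initialization, deterministic); log transforming
Gaussianizes band power and makes labels invariant to a common signal
rescaling. The NREM component is the one with higher summed mean log power;
epochs take the maximal-posterior label. Single-cluster inputs are refused:
the fit aborts when a one-component model has at least the BIC of the
two-component model. Standalone 30-s NREM detections more than 60 s from
any other NREM epoch (strictly; a 60-s start-to-start gap survives) are
relabelled; all decisions are taken against the input labels
simultaneously, which makes consolidation idempotent. A Gaussian smoothing
of the posterior trace exists in `plot_hypnogram()` for display only and
plays no part in scoring.

## Single-event detection

**Slow waves** are zero-crossing candidates of the 0.16-1.25 Hz two-pass
FIR-filtered signal (order = three cycles of the low cutoff) with a
positive peak before a trough and durations of 0.8-2 s; events at or above
the 75th percentile of candidate peak-to-trough amplitudes (type-7
linear-interpolation quantile, with 0.5% relative tolerance so exact ties
at the threshold survive) are retained. **Spindles** threshold the Hilbert
envelope of the 9-16 Hz fourth-order Butterworth-filtered signal at
mean + 3 SD with mean + 1 SD boundaries, keep durations of 0.5-2 s, merge
within 1 s (in that order, so merged events may exceed 2 s), and are vetoed
by 20-30 Hz control events above mean + 5 SD. Peak frequency comes from the
mean inter-peak interval of the filtered event; above 11 Hz a spindle is
"fast". Channels qualify for spindle detection when their NREM sigma power
exceeds a fitted 1/f^a spectral model: the per-10-s-epoch maximal sigma
residual is compared against the maximal residual over an equal-width
17-24 Hz control band by a one-sided unpaired t-test at P < 0.001 (the
model alone cannot serve as the null — the maximum of noisy residuals is
positive on average even on pure 1/f input). **Ripples** are detected on
the (optionally bipolar gray-minus-white) signal filtered 80-100 Hz: the
20-ms moving-average RMS must exceed its 99th percentile for at least
38 ms, and the corresponding raw segment (3-point moving average) must
contain at least three local maxima or three local minima. Because the
20-ms RMS window smears each burst by half a window per side, runs are
shrunk by 10 ms per side before the duration test — otherwise the
smoothing kernel, not the burst, sets the measured duration. Channels
qualify with at least 20 baseline-period detections.

## The closed-loop controller

`run_closed_loop()` replays a probe signal causally: a 50th-order FIR
band-pass (0.5-4 Hz) runs sample by sample, and each positive-going
crossing of the adaptive threshold (initial 80 uV) is an online slow-wave
detection. Crossing timestamps are corrected by the filter's symmetric
group delay (order/2 samples) so the log is in signal time. In stimulation
blocks (5 min, alternating with 5-min pauses) a detection triggers a
stimulation at crossing + delay; detection resumes 3 s after each
stimulation, which bounds all inter-stimulation intervals below by the
lockout. Every 400 s the threshold becomes the median positive-half-wave
peak of the trailing window's detections — a ratchet under stationary
amplitudes (the median of an above-threshold sample cannot fall below the
threshold), which real recordings escape through amplitude drift; the
simulator implements the rule literally. The adaptive delay variant uses
the mean peak-to-trough time bounded to 80-600 ms. Mixed-phase mode keeps
the identical detection, lockout and block machinery but jitters each
stimulation uniformly over the recent inter-detection cycle, an explicit
approximation. The post-hoc audit measures each stimulation's delay to the
immediately preceding *offline* positive peak — all duration-qualified
slow-band candidates, not only the amplitude-retained quartile, since the
online controller never applied the offline amplitude criterion — and
classifies the session sync when strictly more than 55% of delays fall in
80-280 ms. Because the delay is anchored at the threshold crossing while
the criterion is anchored at the peak, the in-phase geometry depends on the
crossing-to-peak gap; `calibrate_delay()` measures that gap on pre-recorded
sleep and sets the delay to land 180 ms after the peak (the center of the
in-phase window), mirroring the participant-specific delay calibration the
protocol allows alongside its fixed 400-ms fallback.

## Stimulation-locked analyses

Sham events replicate each stimulation's own delay-from-peak onto a
randomly chosen slow-wave peak in the following pause block (resampling
with replacement when peaks are scarce, logged), so shams share the
real stimulations' phase relation to the slow-wave cycle. The
trigger-locked TFR uses Hann-tapered sliding windows of at least five
cycles per frequency (5-30 Hz, 1-Hz steps, -1 to 2.5 s); power is averaged
across triggers first and then expressed as percent change from the
average's own -1-0 s baseline. Normalizing each trigger by its own noisy
baseline estimate before averaging biases the null upward
(E[post/baseline] > 1, about +20% at desk-scale trigger counts), so the
averaged form — whose baseline mean is exactly 0% per frequency by
construction — is used. Event probability after a trigger is total
detections in the window (3 s for slow waves and spindles, 200 ms for
ripples) divided by the trigger count; enhancement uses the contrast index
(A - B)/(A + B), undefined (excluded) at 0/0. The prolonged contrast pools
the first minute after each stimulation block against the last minute of
the following pause block. Co-occurrence: spindle peaks up to 1.5 s after
a slow-wave positive peak form sequences (each spindle pairs with its
nearest preceding peak); ripple-slow-wave couples use |delta| in 50-400 ms
by default — the "away from" reading — with a signed option; triples
require the ripple to precede a sequence's slow wave by 50-400 ms in the
signed direction, and each ripple joins at most one couple and one triple,
which enforces triples <= couples <= min(#ripples, #slow waves).

## Spike-field phase locking

Phase comes from the Hilbert transform of the 0.5-2 Hz zero-phase
Butterworth-filtered probe (0 degrees at the positive/inactive peak,
+/-180 degrees at the active trough; the online controller's 0.5-4 Hz band
is available as an option). Spike phases are binned into 18 twenty-degree
bins over [-180, 180) and fitted with f(phi) = a cos(phi + b) + c by
closed-form linear least squares on a cos/sin/intercept design — the exact
global optimum, normalized to a >= 0 — with locking depth
LD = 2a/(2a + c). Units need 0.1 Hz mean rate and 18 spikes per condition;
spikes within 500 ms after a stimulation are excluded from
stimulation-block fits. Significance gating uses the Rayleigh test (Zar's
approximation) at P < 0.05; R^2 > 0.25 flags fit quality. The preferred
phase within 90 degrees of the trough labels a unit ON-locked, otherwise
OFF. Two validations mirror the study design: a 10,000-draw label
permutation of paired LD values (exact enumeration below 5 pairs), and a
rate-matched control that refits on 90% of the smaller condition's spike
count from both conditions, 1,000 times.

One sample-size fact governs LD recovery tests: for an unmodulated unit
the fitted amplitude a = sqrt(A^2 + B^2) has a Rayleigh-distributed noise
floor, so E[LD] at m = 0 is about 0.08 with 1,800 spikes and falls as
1/sqrt(n), crossing 0.05 only beyond roughly 5,000 spikes. Recovery checks
therefore use 8-Hz units over 30 minutes (~14,000 spikes, an MTL-typical
rate), where all of m in {0, 0.2, 0.5, 1} recover 2m/(2m + 1) within 0.05.

## Behavioral scoring

Recognition accuracy is hits/25 minus false alarms/15; overnight change is
morning minus evening; intervention efficacy is the stimulation night's
change minus the undisturbed night's, with participants excluded when any
single test scores below 0.1. The superiority test is the upper-tail
binomial probability at p = 0.5 with a Clopper-Pearson interval on the
proportion; bootstrap confidence estimates resample 25 targets and 15
lures with replacement 1,000 times; vigilance change is the
morning-minus-evening difference of median reaction times; physiology-
memory association uses two-sided Spearman correlation.

## Problem sizes and reproducibility

The validation suite and `scripts/acceptance.R` run at desk scale, chosen
as the smallest sizes at which each property is stable: 10-minute
recordings at 400 Hz for detector validation (three fixtures averaged),
one 60-minute session at 200 Hz for sleep scoring, a 12-minute session at
400 Hz for the closed-loop audit, fifty 10-minute sessions at 200 Hz for
the stim-vs-sham null calibration, and 30-minute spike trains for locking
depth. Every random quantity is seeded; the acceptance script derives all
sub-seeds from its `--seed` argument, and identical seeds reproduce every
output bit for bit.

## Known limitations

The mixed-phase jitter model and the crossing-anchored delay calibration
are documented approximations of an imperfectly specified online system;
the threshold ratchet is faithful to its stated update rule rather than to
long-horizon behavior; the generator's inter-channel independence means
cross-channel couple/triple analyses are validated on constructed event
tables rather than on emergent multi-channel signals; and EDF output
quantizes to 16 bits over each channel's observed range.
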