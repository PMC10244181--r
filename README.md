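# sleeploop

Analysis stack for closed-loop slow-oscillation-targeted stimulation
studies of human sleep, built around intracranial EEG (iEEG).

During NREM sleep the cortex alternates between silent (OFF, iEEG positive
peak) and active (ON, iEEG trough) phases of the ~1-Hz slow oscillation.
Closed-loop experiments detect these waves online on a medial-temporal-lobe
(MTL) probe and deliver brief electrical pulse trains timed into the active
phase, asking whether synchronized stimulation strengthens the slow-wave /
spindle / ripple dialogue that supports overnight memory consolidation.
sleeploop implements every stage of that analysis as composable, tested R
functions:

* **Synthetic ground truth** — `generate_recording()` synthesizes 1/f iEEG
  with NREM/desynchronized structure, slow waves, coupled spindles and
  ripples, interictal-discharge-like transients, plus phase-modulated
  Poisson spike trains and Bernoulli recognition-memory sessions, all with
  a complete event ledger.
* **Preprocessing** — mains-harmonic band-stops; interictal-discharge (IED)
  detection by 5-SD envelope/amplitude/gradient criteria; ±500-ms validity
  masking and channel exclusion above 5 IEDs/min.
* **Sleep scoring** — slow-wave (0.5–4 Hz) and sigma (9–16 Hz) power per
  30-s epoch, two-component Gaussian-mixture NREM labelling, and
  consolidation of isolated detections.
* **Event detection** — slow waves (0.16–1.25 Hz candidates, top-quartile
  amplitude rule), spindles (9–16 Hz Hilbert envelope, mean+3 SD with
  mean+1 SD boundaries, 20–30 Hz veto, fast subtype above 11 Hz), ripples
  (80–100 Hz RMS above the 99th percentile for ≥ 38 ms with ≥ 3 discrete
  peaks, bipolar referencing, 20-ripple baseline qualification).
* **Closed-loop simulation** — a causal replay of the online controller
  (adaptive 80-µV threshold on a 0.5–4 Hz FIR stream, 400-s updates, 3-s
  lockout, 5-min stimulation/pause blocks, sync and mixed-phase modes) and
  the post-hoc timing audit (> 55 % of stimulations within 80–280 ms of
  the preceding slow-wave peak ⇒ "sync").
* **Stimulation response** — delay-matched sham events from pause blocks,
  trigger-locked time–frequency maps (≥ 5-cycle Hann windows, % change
  from baseline), event probabilities, immediate and prolonged enhancement
  indices `(A − B)/(A + B)`, and slow-wave/spindle/ripple co-occurrence.
* **Phase locking** — spike-phase histograms (18 × 20° bins) fitted with
  `a·cos(φ + b) + c` in closed form; locking depth `LD = 2a/(2a + c)`;
  Rayleigh gating; label-shuffle and rate-matched-subsampling controls.
* **Behavior** — recognition accuracy (hits/25 − false alarms/15),
  overnight change and intervention efficacy, exact binomial superiority
  tests, bootstrap intervals, vigilance (median reaction time) change, and
  Spearman physiology–memory correlation.

Results are tibbles (or small S3 objects with `tidy()`/`glance()` and
`autoplot()` methods), so pipelines compose with dplyr and ggplot2.
`run_pipeline()` chains simulate → preprocess → score → detect → closed
loop → respond, and writes tidy CSVs plus a JSON manifest.

## Worked example

Simulate a 12-minute NREM session, run the closed-loop controller with a
delay calibrated on the first two minutes, audit its timing, and measure
the spindle response against matched shams:

```r
library(sleeploop)

cfg <- synthetic_config(duration_s = 720, rate_hz = 400,
                        ripple_rate_per_min = 4, seed = 42)
sim <- generate_recording(cfg)
dplyr::count(sim$truth$events, kind)
#>   kind          n
#> 1 ripple       53
#> 2 slow_wave   134
#> 3 spindle      29

x <- channel_signal(sim$recording, "ch1")
delay_ms <- calibrate_delay(x[1:(120 * 400)], 400)   # 317 ms
log <- run_closed_loop(x, 400,
         stim_protocol(initial_delay_ms = delay_ms,
                       block_s = 120, pause_s = 120), seed = 42)
log
#> <sleeploop_stimlog> 54 stimulation(s) in 3 STIM block(s), mode sync

cand <- detect_slow_waves(x, 400, amplitude_criterion = FALSE)
aud <- audit_stim_timing(log, cand$peak_s)
#> in-phase fraction 0.81 -> sync; mean delay 210 ms
```

81 % of stimulations landed 80–280 ms after the preceding slow-wave
positive peak, so the session is classified sync-stimulation (the criterion
is a strict 55 %). Spindle probability in the 3 s after stimulations versus
matched shams gives the immediate enhancement index:

```r
sp <- detect_spindles(x, 400)
in_pause <- vapply(cand$peak_s, function(p)
  any(log$blocks$kind == "PAUSE" & log$blocks$start_s <= p &
        p < log$blocks$end_s), logical(1))
sham <- generate_sham_events(log, cand$peak_s[in_pause], seed = 42)
immediate_contrast(
  event_probability(sp$peak_s, log$stims$time_s, window_s = 3)$probability,
  event_probability(sp$peak_s, sham$time_s,      window_s = 3)$probability)
#>   value p_stim p_sham excluded
#> 1     0 0.0741 0.0741 FALSE
```

The index is 0 — as it must be here, since the simulated stimulation does
not actually influence spindle generation; shams control for the endogenous
coupling of spindles to slow-wave phase. Spike–field locking for a unit
with known modulation depth m = 0.5 (expected LD = 2m/(2m+1) = 0.5):

```r
ph <- slow_wave_phase(x, 400)
spikes <- generate_spike_trains(ph, 400,
            tibble::tibble(unit_id = "u1", base_rate_hz = 5,
                           m = 0.5, phi0_deg = 170), seed = 42)
fit_spike_phase_cosine(spikes$time_s, ph, 400)
#> <sleeploop_plfit> LD = 0.519 (a = 110.57, b = -165.2 deg, c = 204.67),
#>                   R2 = 0.949, Rayleigh p = 6.7e-122, n = 3684

binomial_superiority(6, 6)$p_value   # 6/6 participants better: (1/2)^6
#> [1] 0.015625
```

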