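---
title: "Deriving interbreath intervals and apnoeas from the impedance pneumograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving interbreath intervals and apnoeas from the impedance pneumograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibidetect)
```

## The measurement and its failure modes

The impedance pneumograph (IP) records thoracic electrical impedance
through the ECG electrodes; each breath modulates the impedance, so the IP
is a quasi-periodic waveform whose amplitude is arbitrary and unstable.
Three failure modes dominate neonatal IP analysis and shape this package's
design:

* **cardiac-frequency noise** — the beating heart modulates thoracic
  impedance at the heart rate (1.5–4.5 Hz in infants), close enough to fast
  neonatal breathing (up to ~1.3 Hz) that naive low-pass filtering either
  leaves it in or destroys the breathing band;
* **movement artefacts** — large excursions unrelated to respiration;
* **artefactually low amplitude** — electrode placement or shallow
  breathing reduces the excursion until no breath can be detected, which
  looks exactly like a central apnoea.

The pipeline addresses these in order: mask artefacts, zero the baseline,
notch out the cardiac component, detect breaths with an adaptive threshold,
and separate true apnoeas from low-amplitude false alarms with a
classifier.

## Preprocessing

**Artefact masking.** After removing a running-median baseline, a sample is
an artefact candidate when its magnitude exceeds `k_mad` (default 6) times
a rolling MAD-based scale (window default 20 s, evaluated on a coarse grid
and interpolated). Three refinements matter in practice and are deliberate
design choices:

* *Two-pass scale*: first-pass detections (dilated) are excluded from the
  second scale estimate, so a large artefact cannot inflate its own
  threshold. The window default is 20 s rather than 10 s because a typical
  5 s artefact would occupy half a 10 s window — precisely the breakdown
  point of the MAD.
* *Scale floor at half the recording-wide MAD*: a long apnoea is a
  genuinely quiet span; without the floor the rolling scale collapses
  inside it and the normal breaths bordering the pause are flagged as
  outliers, invalidating the very interval that constitutes the apnoea.
  Low amplitude is signal to be classified, not artefact to be masked.
* *Dual-threshold hysteresis*: each strong excursion (above `k_mad` ×
  scale) is grown outward through samples above `k_mad/3` × scale, so the
  full extent of an artefact is masked rather than only its core. Both
  thresholds scale with `k_mad`, so the mask remains monotone in `k_mad`.

Masked spans are bridged by linear interpolation before the spectral
filters run (so an artefact cannot leak across the spectrum), set to zero
in the output, and excluded from every downstream SD/RMS computation.

**Baseline zeroing.** All Fourier content below `baseline_cutoff_hz`
(default 0.1 Hz), including DC, is zeroed. Bin-zeroing is an orthogonal
projection: it is exactly idempotent, rejects constant offsets completely,
and adding an offset to the input provably does not change the output.
The price is edge leakage — a non-periodic drift rings slightly near the
recording's first and last seconds. For threshold-based breath detection
this is immaterial (the threshold adapts), and it buys an operation whose
algebraic properties can be asserted exactly in tests.

**Cardiac notch.** The notch must track the heart rate, since neonatal
bradycardias move the cardiac tone by an octave within a minute. Where the
HR numeric is present the notch centre is `hr/60` interpolated to the IP
timebase; where absent, the short-time spectral argmax in 1.5–4.5 Hz. The
filter processes 50%-overlapping Hann frames (default 32 s) and zeroes the
bins within `notch_halfwidth_hz` (default 0.3 Hz) plus one spectral
mainlobe of the frame centre frequency; constant-overlap-add reconstructs
unmodified content exactly. The 32 s frame is what makes the contract
"≥ 20 dB within ±0.3 Hz of the cardiac frequency, < 1 dB below 1.2 Hz"
achievable at the worst case (cardiac at 100 bpm = 1.67 Hz, breathing at
1.2 Hz leaves a 0.17 Hz transition): the frame's mainlobe half-width of
1/16 Hz fits inside that transition, and Hann sidelobes at −31 dB bound
both the stopband residual and the passband ripple. Measured on two-tone
inputs the notch attains > 40 dB attenuation with < 0.001 dB passband
ripple.

An ECG-based subtraction of cardiac interference is deliberately out of
scope: no ECG channel is assumed, and R-peak detection on noisy neonatal
ECG is itself fragile. The HR-steered notch needs only channels every
monitor exports.

## Adaptive-threshold breath detection

A breath is the upward crossing of the current threshold

\[ T = \alpha \cdot \mathrm{SD}\big(x\ \text{over the span of the previous } N \text{ detected breaths}\big), \]

with defaults $\alpha = 0.4$, $N = 15$ — the operating point at which
false-positive and false-negative breath detections balance. Until $N$
breaths exist, the SD is taken over the trailing `init_window` (15 s) of
signal; the threshold is recomputed after each accepted breath and frozen
during masked artefact spans, so artefacts neither produce breaths nor
corrupt the threshold.

Three disambiguations the threshold rule itself does not fix:

* **One breath per excursion, re-armed at zero.** After a crossing, the
  signal must return below *zero* (not merely below the threshold) before
  the next crossing counts. Re-arming at the threshold line lets noise
  chatter on the falling edge double-count breaths — at 30 breaths/min
  under default noise this produced a ~17% false-discovery rate; re-arming
  at zero removes it entirely while preserving one-breath-per-excursion.
* **Refractory period** of 0.3 s (a 200 breaths/min ceiling), guarding
  against residual cardiac oscillation double-triggering.
* **IBIs are onset-to-onset**: the crossing is the only breath landmark
  defined, so interbreath intervals run from crossing to crossing, and an
  interval overlapping masked samples beyond `max_artefact_overlap`
  (default 10%) is invalid — loss of signal is never counted as a pause.

The SD is the plain sample SD of the unmasked samples across the N-breath
span (not a per-breath statistic); the brute-force reference in the test
suite recomputes this window from scratch at every sample and must agree
exactly.

Candidate central apnoeas are valid IBIs ≥ 20 s; pauses in breathing are
valid IBIs ≥ 5 s. Both thresholds are inclusive.

## Apnoea classification

Five features per candidate: RMS of the filtered IP during the episode, in
the 10 s before, and in the 10 s after; and the changes in HR and SpO₂
within 60 s of onset. "Change" is operationalised as (window minimum) −
(median over the 10 s before onset): the minimum-versus-baseline captures
the depth of a bradycardia or desaturation, the physiologically relevant
quantity, with negative values meaning decline. A true apnoea has low RMS
*during* but normal RMS around it and negative deltas; a low-amplitude
false alarm has uniformly low RMS and no physiological response.

The classifier is a linear soft-margin SVM (cost 1, features standardised;
both exposed in the config). Candidates whose feature windows are less
than half covered by usable data are classified *indeterminate* rather
than forced into a class. Evaluation is leave-one-subject-out: training
folds never contain the held-out infant's episodes, so within-subject
correlation cannot inflate accuracy. Metrics are accuracy, FPR, FNR and
the Matthews correlation coefficient (reported 0 when a marginal is zero).

## Epoch statistics

Per epoch and subject the package reports mean, median and SD of the valid
IBIs, the proportions of IBIs strictly longer than 5 s and 10 s, and the
time-averaged respiratory rate (trailing 30 s window; during warm-up the
count is normalised by the elapsed window so the trace is not biased low).

Before/after comparisons use a paired sign-flip permutation test: the
statistic is the one-sample t of within-subject differences, the null is
built by randomly negating each subject's difference — the correct
exchangeability for paired designs. When $2^n \le n_{\text{perm}}$ the
full enumeration is used and the p-value is exact ($\#\{|t^*| \ge
|t|\}/2^n$); otherwise the Monte-Carlo p uses the add-one convention
$(1 + \#\text{extreme})/(1 + n_{\text{perm}})$, which keeps the test valid
at finite permutation counts and p strictly positive. Tests are two-sided
by default (one-sided available); the six metric p-values are adjusted
with Hochberg's step-up method. With 2000 permutations and 15 subjects the
empirical type-I error at nominal 0.05 sits within the binomial 99%
interval of the attainable level 100/2001.

## The simulator: what it emulates, and what it does not

The generator produces the conditions the pipeline is designed for: a
phase-accumulator breathing sinusoid (instantaneous rate = mean × (1 +
jitter·AR(1)), correlation time 5 s) whose phase crossings *are* the
ground-truth breath onsets; slow sinusoidal amplitude drift (maximal slope
`amplitude_drift` per minute, period 240 s); a cardiac tone whose
instantaneous frequency follows the HR numeric — so a simulated
bradycardia moves the tone exactly as the HR-steered notch expects — and
white measurement noise. Defaults: 62.5 Hz IP and 1 Hz numerics (typical
monitor-export rates), 50 breaths/min, 10% rate jitter, cardiac amplitude
20% of breathing, noise SD 5% of breathing amplitude, HR 150 bpm,
SpO₂ 97%. Real signal-to-noise levels in monitor exports are not publicly
characterised; these values are plausible rather than calibrated, and they
are fixed once — they are the study conditions, not tuning knobs.

Injected events: pauses (breathing removed; cardiac retained at half
amplitude; ≥ 20 s for apnoea kinds, any duration for a plain pause) with
optional raised-cosine HR/SpO₂ dips reaching the nadir at +30 s and
recovering by +90 s; low-amplitude episodes (breathing scaled to 10%,
truth breaths retained as present-yet-undetectable); movement artefacts
(half-sine excursions ≥ 3× breathing amplitude). The pause suppression
gate snaps outward to breath onsets, where the waveform is zero: the cut
is step-free and every retained truth breath keeps its full lobe. The
truth therefore records both the requested interval and the achieved
breath-free gap, and recovery tests compare detections against the gap.

What the simulator does *not* model: airway mechanics and waveform
morphology (breaths are sinusoidal lobes, not asymmetric flow shapes),
obstructive apnoea (chest movement without airflow is invisible to IP by
construction), cardiorespiratory coupling beyond the shared HR, electrode
pop/step artefacts, and periodic breathing. Passing tests therefore show
the algorithm is implemented correctly and behaves as designed under
controlled conditions; they do not certify clinical accuracy on real
recordings, whose artefact structure is richer.

## Numerical and degenerate-input choices

* An identically zero signal yields a zero threshold and no breaths (a
  crossing must strictly exceed the threshold).
* An all-constant signal yields an empty artefact mask (zero scale never
  divides).
* MCC with a zero marginal is reported as 0.
* Permutation t with zero-variance differences: t = 0 (all differences
  zero, p = 1) or ±∞ (all equal, nonzero), handled without NaN.
* Tie comparison in permutation counts uses a relative 1e-12 epsilon so
  enumerated ties (the mirrored flip) are counted deterministically.
* Sampling-rate inference from CSV snaps the numeric rate to the nearest
  integer when within 5%, since time stamps are quantised to the waveform
  grid.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to exercise every code path while keeping a full run in
tens of seconds: breath recovery on twenty 5-minute recordings spanning
30–80 breaths/min; pause recovery on ten 5-minute recordings with four
pauses each; classifier evaluation on 120–300 episodes across 15 subjects;
permutation calibration with 1000 null replicates of 15 subjects at 2000
permutations; and a 15-subject epoch comparison with 5-minute epochs where
the after-epoch pause rate is tripled and the breathing rate lowered
50 → 42 breaths/min, the analogue of a respiratory-depressant exposure.
Epochs of an hour behave identically at proportionally higher cost; the
algorithms are O(n) or O(n log n) in recording length.

## Known limitations

* The Fourier baseline and notch assume offline, full-recording access;
  this is an analysis tool, not a bedside alarm.
* The adaptive threshold eventually adapts *down* during prolonged
  low-amplitude breathing (that is its purpose), so a sufficiently long
  shallow-breathing span is eventually re-detected as breaths; the
  classifier stage, not the detector, is the defence against low-amplitude
  false alarms — mirroring the design rationale of the three-stage
  pipeline.
* EDF input is not supported (no EDF reader available to R here); CSV with
  documented columns is the interchange format.
* The SVM is linear by design; no probability calibration is provided.
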