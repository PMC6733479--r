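---
title: "Detecting and quantifying sawtooth clock-skew artifacts in pulse transit time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying sawtooth clock-skew artifacts in pulse transit time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pulse transit time (PTT) — the interval from the ECG R peak to the arrival
of the corresponding pressure pulse at a peripheral photoplethysmography
(PPG) site — is a convenient surrogate for pulse-wave velocity and,
inversely, blood pressure. Because bedside patient monitors already record
both ECG and PPG, it is tempting to compute PTT from data dumped from such
monitors. Those devices, however, were not designed or calibrated for
beat-to-beat inter-channel timing. PTT series computed from monitor dumps
can contain a striking non-physiological oscillation: a linear ramp with an
abrupt reset, repeating with an almost constant period of roughly 75–150 s,
at dominant frequencies between 0.0067 and 0.1 Hz.

This package provides the full analysis chain needed to study that
artifact: a mechanistic simulator that reproduces it, the PTT extraction
pipeline, power-spectral quantification, a de-shape short-time Fourier
transform (dsSTFT) for time-frequency visualization, cohort averaging, and
an optional period-synchronous removal stage.

## The dual-clock model

The physical cause of the artifact inside commercial monitors is not
public; the model implemented here is a *hypothesis sufficient to reproduce
the phenomenology*, and is documented as such. Two acquisition clocks —
one timing the ECG samples, one the PPG — differ by a relative rate
$\delta = \mathrm{drift\_ppm} \times 10^{-6}$. The accumulated alignment
offset between the channels grows linearly at $\delta$ s/s until it
reaches a trigger threshold, at which point the chain corrects it by an
instantaneous jump of one quantum $q$ (one nominal PPG sample period,
$q = 1/125\,\mathrm{s} = 8$ ms, by default). The offset is therefore a
sawtooth with amplitude $q$ and period

$$T = \frac{q}{\delta}.$$

A drift of 80 ppm with an 8 ms quantum yields $T = 0.008/(80 \times
10^{-6}) = 100$ s; 53.33 and 106.67 ppm yield the 150 s and 75 s periods
also seen clinically (presets `"skwhsmh"`, `"cgmh150"`, `"cgmh75"`,
`"cgmh10"`, `"clean"`). The skew is applied to the PPG channel only — only
the *inter-channel* alignment matters for PTT, and one-sided drift is the
minimal model. The correction is modeled as an instantaneous offset reset
(a dropped/held sample), not a gradual slew, because only an abrupt reset
produces the ramp-and-jump shape. Since the extracted PTT is (true PTT −
alignment offset), the artifact appears in PTT with amplitude equal to one
PPG sample (8 ms).

```{r clock}
library(pttsaw)
rec <- simulate_recording(sim_config(duration = 1600, seed = 1),
                          clock_preset("skwhsmh"))
rec$correction_times # 100, 200, ..., every q / drift seconds
```

## The synthetic recordings

`sim_config()` fixes the study conditions: ECG at 500 Hz (lead-II-like),
PPG at 125 Hz — the rates delivered by the monitors on which the artifact
was observed — and 1600 s records, the shortest record length used for
cohort displays of the longer clinical database (the other database held
5-minute records, on which the artifact is much harder to resolve; see
"resolution guards" below).

Defaults, chosen once as what a physiologist would call a realistic
monitored adult:

* mean heart rate 75 bpm; RR modulated by respiratory sinus arrhythmia
  (0.25 Hz, 20 ms) and a low-frequency component (0.1 Hz, 30 ms), plus
  10 ms white RR jitter;
* PTT baseline 250 ms, modulated by respiration (0.25 Hz, 2 ms) and a
  Mayer-wave component (0.1 Hz, 1.5 ms), with optional piecewise-linear
  trends and timed "episodes" for transient physiology;
* ECG noise SD 0.05 of the unit R amplitude (SNR 20); PPG noise SD 0.002
  of the unit pulse amplitude — a monitor pleth is band-limited and
  visually clean, so the dominant arrival-timing error is the native 8 ms
  sampling, not sensor noise. These modulation amplitudes put the
  recordings in the artifact-dominant regime that the clinical power
  spectra display.

The ECG is a train of narrow Gaussian bumps (SD 8 ms) at the beat times —
morphological realism (P/T waves, arrhythmia, motion artifact) is a
non-goal, since only R-peak timing enters PTT. The PPG pulse is a
raised-cosine upstroke (width $w$ = 120 ms) followed by an exponential
decay ($\tau$ = 300 ms); this closed form has its steepest ascent exactly
at $w/2$ after onset, so each pulse is placed with its steepest-ascent
instant at `beat_time + true_ptt` and every detector can be tested against
an analytic oracle. Each simulation draws all randomness from deterministic
sub-streams of one seed, so recordings are bit-reproducible.

What the generator does **not** emulate: real PPG morphology variation
(dicrotic notch, amplitude modulation), baseline wander, motion artifact,
ectopy, and the pre-ejection period (so the simulated quantity is a pure
transit delay, while clinical "PTT" from the R peak includes pre-ejection
time). Passing tests therefore demonstrate the *mechanism* — a drifting,
periodically corrected clock reproduces the published artifact numbers —
not that the pipeline is robust to every clinical signal-quality problem.

## PTT extraction

Following standard practice for monitor data, the PPG is first upsampled
to 500 Hz by linear interpolation. R peaks are detected with a
Pan–Tompkins-style scheme (5–25 Hz zero-phase band-pass, squared
derivative, 120 ms moving integration, adaptive signal/noise threshold,
250 ms refractory period) and refined to the raw-ECG local maximum;
detections within 0.5 s of the record ends are dropped because filter
transients mislocalize truncated complexes. The pulse arrival for each R
peak is the instant of steepest PPG ascent — the maximum first difference
restricted to rising segments — searched in a physiological window 100 to
700 ms after the R peak.

One numerical subtlety: after linear upsampling, the first difference is
constant across each native 8 ms PPG segment, so the bare argmax localizes
the arrival only to a segment (±4 ms). Worse, the raised-cosine derivative
is almost flat near its maximum, so with any noise the selected segment
wanders several segments (±10 ms). The default therefore refines the
arrival by a least-squares parabola fitted through the slopes of the five
neighboring native segments; the vertex (clamped to ±1.5 native samples)
is the arrival. `refine = "none"` restores the bare argmax. Beats whose
window has no rising segment or runs past the record end are missing, and
missing beats are simply absent knots downstream (no imputation). Pairs
with PTT outside (100, 700) ms are dropped; fewer than 10 valid beats is
an error.

The beat-indexed series is resampled at 4 Hz by a natural cubic spline
through the (R-time, PTT) knots, on a grid anchored at the first beat with
spacing exactly 0.25 s, confined to the beat-time span.

```{r extract}
ps <- extract_ptt(rec)
glance(ps)
autoplot(ps)
```

## Spectral quantification

`power_spectrum()` computes a one-sided periodogram of the linearly
detrended, Hann-tapered 4 Hz series, scaled so that
$\sum_k P_k \, \Delta f$ equals the mean square of the detrended, tapered
input (a Parseval identity asserted to $10^{-6}$ in the tests). A single
full-record taper is the default because separating the clinically
reported 0.01 and 0.012 Hz lines needs the full-record resolution
($\Delta f = 4/N$ Hz, i.e. 0.000625 Hz at 1600 s); Welch averaging is
available via `segments` and is the right tool when testing for the
*absence* of a line (a full-resolution periodogram of white noise always
contains bins several times its median — an order statistics fact, not an
artifact).

Linear detrending is applied first because PTT tracks (the reciprocal of)
blood pressure on large scales, and such trends would mask the
low-frequency artifact peaks.

`dominant_frequency()` reports the argmax of power in a band of
0.004–0.15 Hz — wide enough for every clinically reported dominant, while
excluding DC and the cardiac/respiratory lines — and classifies it into
the bins {0.0067, 0.01, 0.012, 0.0133, 0.1} Hz with a ±15% relative
tolerance (nearest bin by relative distance; exact ties in power break
toward the lower frequency). Two resolution guards protect against
over-claiming: the band floor is raised to two grid bins when the record
is short (with a warning), and a warning is issued when the record holds
fewer than three periods of the dominant frequency — the regime in which
5-minute records make the sawtooth pattern unclear.

## The de-shape STFT

A sawtooth is highly non-sinusoidal: its Fourier series has harmonics
decaying as $1/k$, so an ordinary spectrogram of a 100 s sawtooth shows
lines at 0.01, 0.02, 0.03, ... Hz and any automatic ridge reading is
ambiguous. The de-shape transform suppresses the harmonics and keeps only
the fundamental:

1. **STFT**: Hann-windowed, per-frame linearly detrended, zero-padded
   frames give $|V(t, f)|$.
2. **Short-time cepstrum**: per frame, the inverse Fourier transform over
   frequency of $|V(t, \cdot)|^{\gamma}$ with a small exponent
   $\gamma$ (default 0.3) flattening the spectral envelope. A harmonic
   frame with period $T$ produces cepstral peaks at quefrencies
   $T, 2T, \dots$ Each frame is soft-thresholded at its 0.9 cepstral
   quantile and clipped at zero.
3. **Inversion and masking**: the thresholded cepstrum evaluated at
   quefrency $1/f$ (linear interpolation; quefrencies above the window
   length excluded, 0 Hz excluded from the grid) gives $U(t, f)$, and the
   output is $W(t, f) = |V(t, f)| \cdot U(t, f) \ge 0$.

A fundamental at $f_0$ survives because both factors peak there; the
harmonic at $2 f_0$ is suppressed because the cepstrum has no peak at
quefrency $1/(2 f_0)$.

Defaults: window 400 s (4 cycles of a 0.01 Hz artifact), hop 10 s,
$\gamma = 0.3$, threshold quantile 0.9, display grid of 512 bins over
0.004–0.15 Hz, FFT zero-padding factor 8. No published parameter set
exists for this application, so all of these are exposed in
`deshape_params()`. Two practical notes established by the property tests:
the ridge of a fundamental is unbiased only when the window holds at least
three of its cycles (at the 0.004 Hz display floor the stock 400 s window
holds 1.6, hence the constructor's warning), and the per-frame linear
detrend is what keeps the large PTT baseline from leaking into the
lowest display bins.

`extract_ridge()` reads the per-frame argmax (median-smoothed over 5
frames, missing where a frame has no energy), and `stft_tfr()` exposes the
plain STFT on the same grid for harmonic-suppression comparisons.

```{r dsstft}
tf <- dsstft(ps)
autoplot(tf)
extract_ridge(tf)
```

## Cohort averaging

`average_tf()` max-normalizes each subject's TF map to 1 and then takes
the elementwise mean, after `truncate_to_common()` cuts all subjects to
the shortest record. Normalization is needed because PTT oscillation
amplitudes differ across subjects; whether the original analysis
normalized per subject is unstated, so this is this package's own choice,
recorded here. The scientific point of the average is an argument about
artifact vs physiology: a rhythm locked to a common period in *all*
subjects (the clock artifact) survives averaging, while idiosyncratic,
differently timed physiological episodes attenuate roughly with the
cohort size. The tests assert both directions quantitatively.

## Sawtooth removal

The correction stage is deliberately simple and transparent:
period-synchronous template estimation. The detrended 4 Hz series is
folded modulo the artifact period (taken from `dominant_frequency()`), the
per-phase median across cycles forms a zero-mean one-period template
(content incoherent with the period averages out), the template's phase is
matched by cross-correlation, and the tiled template is subtracted. The
original analysis used an unpublished manifold-learning denoiser for this
step; no attempt is made to reproduce it, and this stand-in applies only
to the constant-period case.

A no-harm guard makes removal refuse (returning the input unchanged)
whenever the template RMS is below twice a phase-shuffled null — the
template RMS obtained after circularly rotating each cycle by a random
amount, which estimates what pure physiology and noise would fold into a
template. This guarantees, and the tests assert, that removal never
increases the error against ground truth on artifact-free data.

```{r removal}
res <- remove_sawtooth(ps, period = 100)
res$applied
```

## Degenerate inputs and numerical conventions

All timestamps are in seconds with $t_0 = 0$ and sample $i$ (0-based) at
$i/f_s$. Flat ECG yields zero detections with a warning; windows past the
record end yield missing arrivals; duplicate beat times, non-finite
samples, non-uniform grids, empty search bands, sub-3-cycle folding and
$\gamma \le 0$ are errors. Ties in the piecewise-constant PPG derivative
resolve to the center of the tied run; ties in spectral argmax resolve to
the lower frequency. JSON/CSV round-trips are asserted bit-identical for
waveforms and to full double precision elsewhere.

## Problem sizes

The test-suite simulations use 1600 s records (the cohort display length)
for every resolution-sensitive check, 20 simulated subjects for the
cohort-persistence check, 100 seeded replicates for the spectral
detection-power property, and 300 s records where only timing accuracy is
at stake. A single 1600 s subject simulates and extracts in about two
seconds.

## Known limitations

* The clock model is one sufficient mechanism, not a verified account of
  any vendor's firmware; other mechanisms (buffer flushes, resampling
  firmware, transmission scheduling) could produce the same sawtooth.
* Arrival timing is floor-limited by the native 125 Hz PPG sampling;
  linear upsampling cannot create sub-sample information, so beat-level
  PTT carries a ±4 ms quantization unless the parabolic refinement's
  smoothness assumption holds.
* The removal stage assumes a constant period; drifting-period artifacts
  are out of scope.
* Dominant-frequency classification on 5-minute records is resolution
  limited (the guards warn rather than silently report).
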