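---
title: "Simulating and analysing speech-evoked auditory brainstem responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing speech-evoked auditory brainstem responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechABR)
```

## The measurement

A speech-ABR is the scalp-recorded brainstem response to a short
consonant-vowel token, here a 40 ms [da]: a 10 ms plosive burst followed by
a voiced formant transition with a rising fundamental (F0, 103–125 Hz). The
response to this token has a stereotyped morphology: an onset complex
(positive wave V, negative wave A), three transition-period troughs
(D, E, F) riding on an envelope-following response (EFR) phase-locked to
F0 — so the D–E and E–F spacings are about one F0 wavelength
(8.0–9.7 ms) — and an offset trough (O). Two quantities summarise F0
encoding: the latency and amplitude of the envelope maximum of the complex
cross-correlation between the averaged response and the stimulus's
fundamental waveform.

The package implements this full analysis chain and a ground-truth
simulator of the four-condition recording design (aided/unaided ×
quiet/noise), so the chain can be validated end to end by parameter
recovery rather than by eye.

## Stimulus synthesis

`synthesize_da()` is a cascade terminal-analog synthesiser. The voicing
source is an impulse train at the instantaneous F0 (linearly interpolated
103–125 Hz over the voiced 10–40 ms), shaped by a second-order glottal
low-pass (bandwidth 80 Hz by default) and a first-difference radiation
characteristic. This source spectrum, falling at about −6 dB/octave, is
what makes the fundamental prominent enough for empirical mode
decomposition (EMD) to isolate: with a bare delta train the F0 component
carries too little relative energy and the decomposition mode-mixes.
Voicing amplitude rises linearly over the first 10 ms of the vowel, as in
natural tokens; an abrupt voicing onset concentrates F0-band energy at the
very start of the vowel, exactly where the response analysis window is
zeroed, and destabilises the F0 latency measurement. The source drives
five time-varying second-order resonators (F1 220→720, F2 1700→1240,
F3 2580→2500, F4 3600, F5 4500 Hz; bandwidths 90/110/170/250/300 Hz,
conventional synthesis values). The burst is seeded band-passed
(1.5–5 kHz) white noise with 1 ms raised-cosine ramps. Synthesis is at
48 kHz; all response-domain work uses the token resampled to the 20 kHz
acquisition rate by exact FFT (band-limited) resampling.

## The response simulator and its defaults

`generate_epochs()` builds each epoch as

    clean response (delayed by the acoustic path, + HA delay when aided)
    + polarity × polarity-locked component
    + white Gaussian noise
    + (rarely) a large transient

on a −10…+65 ms window at 20 kHz. Defaults, chosen once as a plausible
adult recording and used by every test:

| parameter | default | unit | rationale |
|---|---|---|---|
| peak latencies V,A,D,E,F,O | 7.5, 9.5, 24.4*, 33.2*, 41.6*, 51 | ms | 40 ms [da] conventions; D,E,F (*) are placed on successive troughs of the rendered EFR so the transition morphology is self-consistent; O sits after the 50 ms F0-analysis cutoff, where an offset response (~11 ms after stimulus offset) belongs |
| peak amplitudes | +0.35, −0.30, −0.28, −0.25, −0.25, −0.22 | µV | typical adult deflection sizes; Gaussian shape, SD 0.5 ms |
| EFR amplitude / latency | 0.50 / 8.0 | µV / ms | robust envelope-following response at conversational level; brainstem group delay |
| aided advance / gain | 1.0 ms / ×1.3 | | aiding advances every peak and scales amplitudes (including the EFR) |
| noise F0 delay | 1.7 | ms | background noise delays F0 encoding only; peak latencies and amplitudes untouched |
| noise SD | 4 | µV | per-sample EEG background; keeps raw epochs under the 30 µV rejection bound except for injected artifacts |
| artifact rate | 0.02 | | occasional >30 µV transients (blink-like Gaussian bumps, 40–80 µV) |
| polarity-locked amplitude | 0.5 | µV | 1 kHz tone over the token's duration that flips sign with stimulus polarity (stimulus artifact / cochlear microphonic stand-in) |
| acquisition plan | 2 × 2500 × 2 polarities | epochs | 10,000 per condition at 9.1/s (40 ms token + 70 ms interval) |

The EFR is rendered as a delayed, scaled copy of the stimulus's F0-locked
fundamental waveform, obtained by synchronous demodulation
(`reference_fundamental()`: heterodyne at the known F0 phase, Gaussian
smoothing with SD 1.5 ms). Rendering the EFR as a *copy* — carrier and
envelope shifting rigidly with the group delay — is what a response that
follows the stimulus envelope at F0 looks like, and it is what makes the
F0-encoding latency a well-defined recoverable parameter. A fixed-gate
chirp (envelope pinned to the analysis window) makes the measured latency
insensitive to the simulated one; that failure mode is worth knowing about
when interpreting published F0 latencies. The demodulation reference is
deliberately a different construction from the analysis-side EMD
extraction, so recovery tests do not test a method against itself.

`generate_study()` adds per-subject jitter: a common latency shift
(SD 0.3 ms), log-normal amplitude scaling (SD 0.15), EFR-latency jitter
(SD 0.3 ms), and subject-specific effect sizes (advance SD 0.15 ms, gain
SD 0.1, noise delay SD 0.25 ms, truncated away from sign reversal). The
within-subject paired design is respected: one draw per subject feeds all
four conditions. These dispersions are simulator choices; no within-subject
variance components are published for this design.

## Preprocessing conventions

* **Rejection**: an epoch is dropped when its maximum absolute amplitude
  exceeds 30 µV; equality is kept.
* **Averaging**: per-block per-polarity means; the b-th positive and
  negative block means are averaged into one subaverage per block pair,
  each baseline-corrected by subtracting its full-epoch mean (de-meaning,
  not prestimulus-window subtraction); the final average is the mean of the
  subaverages. Averaging polarity means with equal weight cancels
  polarity-locked components exactly, independent of retained counts.
* **Filtering**: zero-phase FIR (forward–backward, i.e. squared Hamming
  response), order five periods of the lowest cutoff so the squared
  passband stays within 1%. 1500 Hz low-pass for peak analysis, 300 Hz for
  the F0 path. Zero-phase means an impulse stays at its sample; epoch edges
  (half a kernel) are attenuated, which is benign for baseline noise.
* **Time corrections**: the loudspeaker distance correction (3.3 ms) and,
  for aided recordings, the hearing-aid processing delay (7.9 ms) relabel
  the time axis; samples are not moved, so nothing is truncated. Double
  application is an error.

## Peak detection

Automated picking replaces visual identification: V is the maximum and
A, D, E, F, O the minima within configurable windows (defaults V 6–11,
A 8–14, D 20–28, E 28–36, F 37–46, O 46–56 ms; ties break to the earliest
latency; extrema on a window edge are flagged). Detection needs two
criteria:

1. **Bootstrap**: noise-floor replicates are sign-flipped epoch averages
   (destroying phase-locked content), de-meaned and filtered like the
   average. The pointwise 95% band describes the noise floor; the
   *decision*, however, compares the candidate against the 95% quantile of
   the noise floor's **window extremum** — because the candidate is itself
   the extremum over a 5–10 ms window, a pointwise band would be exceeded
   by pure noise in a third to a half of windows, while the
   window-extremum reference holds the per-window false-positive rate at
   the nominal level by construction.
2. **Repeatability**: within ±1 ms of the candidate, both subaverages must
   show a dominant deflection of the peak's sign (same-sign extremum larger
   in magnitude than the opposite one) — an explicit operationalisation of
   "repeatable in subaverages".

Amplitudes are peak-to-trough: V−A on the V row; for D, E, F, O the
highest point between the previous labelled trough and the current one,
down to the trough.

## F0 encoding

`extract_fundamental()` zeroes the onset burst, concatenates ten token
repetitions (the token alone is too short for stable sifting), runs EMD
(cubic-spline envelopes through maxima/minima with two-point mirror
extension, Cauchy stop at 0.05, 60 sifting iterations maximum, residual
declared when fewer than two extrema remain), selects the IMF whose
spectral peak falls in a configurable F0 band (80–150 Hz; ties resolved by
in-band power), averages the ten segments back into one token-length
waveform, and re-zeroes the onset (sifting spreads a little energy across
the zeroed region). Verification reports the zero-padded periodogram peak
and the mean interwave (inter-maximum) interval.

`complex_xcorr()` low-passes the averaged response at 300 Hz, zeroes the
first 20 ms, drops everything after 50 ms (isolating the transition-period
EFR from onset/offset peaks), and correlates with the fundamental waveform
(real part) and its FFT Hilbert transform (imaginary part); sums of
products are divided by the waveform length, so amplitudes are comparable
across equal-length conditions and scale with µV. The envelope (modulus)
maximum over 0–20 ms positive lags gives latency and amplitude.

`hotelling_t2()` splits the retained epochs into ten contiguous segments
with an equal polarity split (remainder dropped), processes each segment
exactly like the full response, reads the (real, imaginary) pair at the
full-response latency, and tests against (0, 0):
T² = n·x̄ᵀS⁻¹x̄, F = ((n−p)/(p(n−1)))·T² on (2, n−2) degrees of freedom;
the response is absent when p ≥ .05. All-zero segments are trivially
absent; identical non-zero segments raise a degenerate-covariance error.

## Statistical behaviour, numerical choices, limitations

* **Lag-selection inflation.** The composed procedure extracts segment
  values at the lag that maximises the envelope of the full response — the
  mean of the very segments being tested. Under the null this selection
  makes the procedure anti-conservative (roughly twice the nominal level
  in the package's null simulations; the test suite asserts the
  inflation). At a latency independent of the tested segments the test is
  exactly calibrated, which is how the package measures the test's type-I
  error: the latency is taken from the full response of an independent,
  identically processed noise-only recording. For present responses the
  latency is signal-dominated and the issue is immaterial; for
  borderline-absent responses the p ≥ .05 absence rule is optimistic.
* **Latency compression.** The F0-band cross-correlation envelope is broad
  (the token is a 30 ms shallow chirp), so the envelope-peak latency has a
  condition-independent offset and, because the fixed D/E/F deflections
  also correlate with the fundamental waveform, condition *differences*
  are compressed toward zero by on the order of 10–20% (visible in the
  recovery report). Group-level signs and magnitudes within the package's
  acceptance tolerance survive; exact per-subject latencies should not be
  over-interpreted — in real data either.
* **Noise model.** White Gaussian by default (a `"pink"` 1/f option
  exists). Real EEG is coloured and non-stationary; passing recovery tests
  here demonstrates the pipeline's correctness, not robustness to every
  physiological noise structure.
* **EMD boundaries.** Concatenation joins are genuine discontinuities when
  the token does not contain a whole number of F0 cycles; mirror extension
  handles the outer ends, and the onset re-zeroing plus ten-segment
  averaging suppress most interior artifacts, but the first/last cycles of
  the extracted waveform are the least reliable.
* **Problem sizes.** The test suite and the acceptance script use the full
  10,000-epoch plan for the 20-subject recovery study, a reduced
  1,000-epoch variant (10 segments of 100) for the 1000-replicate
  Hotelling null, and 200-epoch sets for the 100-replicate band-coverage
  study — sizes chosen so the whole validation runs on a laptop in
  minutes while keeping every estimate's sampling error well inside its
  assertion tolerance.
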