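---
title: "Detecting pulse-synchronous sound in the ear canal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pulse-synchronous sound in the ear canal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcoherence)
```

## The problem

Pulsatile tinnitus (PT) is tinnitus perceived in rhythm with the heartbeat,
usually of vascular origin. Whether the pulsatile sound is *objective* —
physically present in the ear canal, measurable by a microphone — matters
clinically: an objective PT raises the likelihood of underlying vascular
pathology and guides the choice of imaging. The traditional test,
auscultation or a clinician listening to an in-canal recording, is
subjective and depends on the examiner's hearing and experience.

`ptcoherence` implements an automated detector. Two channels are recorded
simultaneously: a sensitive microphone sealed in the ear canal (calibrated
to pascals against a 94 dB SPL / 1 kHz tone) and a fingertip
photoplethysmogram (PPG) that serves purely as a heartbeat timing
reference. The detector asks a precise question: *does the sound carry an
amplitude modulation coherent with the heartbeat?*

## The detection algorithm

### Pre-processing

1. The PPG is low-pass filtered at 5 Hz (zero-phase, 5th-order
   Butterworth) to remove measurement noise while preserving the pulse
   waveform.
2. Systolic peaks are detected in the filtered PPG and used as reference
   points to cut the sound recording into beat-by-beat segments
   (half-open inter-peak intervals; samples before the first and after
   the last peak are excluded).
3. Each segment's RMS level is measured in dB SPL. Segments whose level
   exceeds the median of all segments by more than a margin (default
   6 dB) are rejected as artifacts — swallowing, coughing and similar
   transients are tens of dB above the noise floor. Both channels are
   then restricted to the kept segments and concatenated, preserving
   sample alignment.

### The coherence index

The artifact-free sound is band-pass filtered (zero-phase 5th-order
Butterworth) into six one-octave bands centred at 125, 250, 500, 1000,
2000 and 4000 Hz (edges $f_c/\sqrt2 \ldots f_c\sqrt2$). For each band the
Hilbert envelope is computed, smoothed with a 5 Hz low-pass, and compared
with the (equally smoothed) PPG through the Welch magnitude-squared
coherence

$$C_{xy}(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

estimated on 6 s Hamming windows with 3 s overlap — the frequency-domain
analogue of a squared correlation coefficient, on a grid spaced
$1/6\;\mathrm{Hz}$.

The heart rate is the frequency of the predominant peak, within
0.8–2 Hz, of the full-length FFT of the mean-removed PPG. The per-band
**PTCI** is the maximum coherence within ±0.15 Hz of that heart rate, and
the detector score **PTCI~max~** is the maximum PTCI across the six
bands. A high PTCI~max~ indicates a sound component locked to the
heartbeat; the score lives on a continuous 0–1 scale per band, so the
modulated frequency region is identified as a by-product.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| PPG / envelope low-pass | 5 | Hz | passes pulse morphology and its first harmonics, removes noise |
| band-pass order | 5 | – | steep octave-band selectivity without ringing |
| coherence window / overlap | 6 / 3 | s | resolves 0.17 Hz; enough averages in a ~1 min recording |
| heart-rate band | 0.8–2 | Hz | 48–120 bpm, the plausible resting range |
| PTCI search half-width | 0.15 | Hz | ≈ one coherence bin; absorbs the mismatch between the fine heart-rate grid and the coarse coherence grid |
| artifact margin | 6 | dB | transients are far above the beat-to-beat RMS spread (see below) |
| envelope rate | 100 | Hz | both coherence inputs are band-limited to 5 Hz, so any rate well above 10 Hz is equivalent |

## Design choices where the design was open

**Artifact margin.** The literal rule "reject every segment whose RMS
exceeds the median" removes roughly half of *any* recording, including
perfectly clean ones (the median splits the data). We therefore expose
`marginDb` with default 6 dB — rejection means exceeding the median *by a
margin* — and keep `marginDb = 0` available for the literal rule. The
6 dB default rejects under 5% of clean synthetic beats while catching
every injected +20 dB transient (both are tested).

**Peak detection.** The systolic-peak method is rate-informed: the heart
rate estimated from the PPG spectrum sets a minimum peak separation of
half a beat interval, and candidate local maxima must have a prominence
of at least 0.3× the median prominence. This keeps dicrotic bumps and
noise ripples out without any absolute amplitude threshold (the PPG is
uncalibrated).

**PTCI readout.** "Maximum coherence at the heart rate" is read as a
maximum over a ±0.15 Hz neighbourhood. The heart-rate estimate comes from
a full-length transform with millihertz resolution while the coherence
grid is 0.17 Hz coarse; a single-bin readout would be at the mercy of
where the heart rate falls between bins.

**Resampling before coherence.** Envelopes and PPG are resampled (linear
interpolation) to 100 Hz. Both are band-limited to 5 Hz, so this loses
nothing; estimating 6 s windows at 44.1 kHz would waste four orders of
magnitude of computation. Invariance of the PTCI (within 0.02) over
envelope rates 50–200 Hz is asserted in the tests.

**Zero-phase filtering everywhere.** Coherence magnitude is invariant to
pure delays, so filter phase cannot bias the score; forward–backward
filtering keeps envelopes visually aligned with the PPG for plots.

**Argmax ties** go to the lowest band center. **Partial final windows**
are dropped rather than zero-padded. **Excision discontinuities**: the
concatenation across removed segments introduces step discontinuities;
they are accepted because coherence is estimated on 6 s windows and the
envelopes are smoothed at 5 Hz, both long against a one-beat gap.

## Numerical choices

*Filtering.* Narrow low-frequency octave bands at audio rates (the
125 Hz band at 44.1 kHz has normalized edges near 0.002) are numerically
unstable in expanded transfer-function form — the classic polynomial
filter representation overflows under forward–backward filtering. All
filters here are therefore designed analytically in zero-pole-gain form
and run as cascaded second-order sections (biquads, compiled code), with
odd-reflection padding and steady-state initial conditions at the signal
edges. The section responses match an independent reference design to
~1e-10 across the band (tested).

*FFT lengths.* Hilbert transforms and the heart-rate spectrum are
zero-padded to the next 5-smooth length: after artifact excision a signal
length can have a large prime factor, for which a mixed-radix FFT
degrades to quadratic cost. Padding perturbs only the signal edge (for
the envelope) or refines the frequency grid (for the heart rate).

*Degenerate inputs.* An all-zero segment has RMS −Inf dB, which sorts
below any threshold and is always kept by the rejection rule (it is
quiet, not an artifact). A PPG with no usable peaks, a recording shorter
than 10 s, fewer than 5 detected beats, zero kept segments, or a
coherence input shorter than one window all raise errors rather than
returning a silently meaningless score.

## The synthetic-recording generator

No clinical recordings ship with the package, so validation rests on a
generator whose defaults *are* the study conditions the detector targets:

- **PPG**: per beat, a systolic Gaussian pulse (amplitude 1, width
  0.08 × the beat interval) plus a dicrotic bump (0.3, offset 0.25,
  width 0.12), 1% additive noise; beat times follow
  $t_{i+1} = t_i + \mathrm{IBI}\,(1 + \varepsilon_i)$ with 3% truncated
  Gaussian jitter at a configurable heart rate.
- **Sound**: per octave band, white noise band-passed to the band and
  scaled to 30 dB SPL, amplitude-modulated by $1 + m_b\,g(t)$ where $g$
  is a raised-cosine pulse of width 0.3 × the beat interval centred
  0.15 s *after* the beat (a pulse-transit delay — deliberately nonzero
  so that any correct implementation must be delay-invariant, as
  coherence magnitude is); plus a 20 dB SPL broadband noise floor, a
  0.25 Hz breathing amplitude modulation (default depth 0.2, a confound
  the detector must not key on), and optional +20 dB transient bursts.
- A recording is *pulsatile* iff any band's modulation depth $m_b > 0$;
  cohorts draw the heart rate uniformly from 0.9–1.8 Hz and give each
  pulsatile member depth 0.5 in one uniformly chosen band.

The carrier/floor levels (30/20 dB SPL) and depth 0.5 describe a clearly
audible objective PT against a quiet sealed-canal noise floor; they were
fixed once as the reference condition for all tests. At the default test
rate of 8 kHz the 4 kHz band's upper edge would cross Nyquist, so it is
clipped at 3900 Hz with a warning; full-band work should use ≥ 16 kHz.

**What the generator does not emulate**: 1/f microphone noise, ear-canal
acoustics and the probe's frequency response, PPG motion artifacts,
intermittent pulsatility (the hardest clinical case: a pulsatile sound
present only part of the time drags the averaged coherence down), and
etiology-specific spectra. Passing tests therefore demonstrate that the
algorithm recovers heartbeat-locked modulation under realistic noise,
jitter and confounds — not that clinical sensitivity/specificity will
match the synthetic cohort's near-perfect separation, which is an
easier problem than 36 heterogeneous patients.

## Evaluation layer

Observer judgments (three blinded raters, binary) are combined by
majority vote; inter-rater agreement uses Fleiss's kappa with its
large-sample standard error for a Wald confidence interval (the CI
method is a convention choice; kappa itself is the standard formula).
Detector performance against the majority label uses the empirical ROC
with trapezoidal AUC — equal, by construction, to the midrank
Mann–Whitney probability, which the tests verify exhaustively — and
sensitivity/specificity tables at chosen PTCI~max~ cutoffs with the
positive call `score >= cutoff` (higher score = pulsatile).

The package ships a *reconstructed* 36 × 3 rating table
(`ratingsFixture()`, also under `inst/extdata/`) matching a published
vote histogram: 20 recordings with three "present" votes, 1 with two, 7
with one, 8 with none. Which rater dissents in a split case is
arbitrary — majority counts and kappa are invariant to it. On this table
the Fleiss formula gives κ = 0.679 (observed agreement 85.2%); the study
that reported the histogram printed κ = 0.64 and 83.33% agreement, values
not reproducible from its own published counts. We implement the standard
formulas and document the discrepancy rather than reverse-engineering it.

## Problem sizes used in the test suite

Unit tests run on 20–60 s recordings at 8 kHz (500 Hz for PPG-only
tests). The cohort-level checks use 40 recordings of 60 s (20 pulsatile
at depth 0.5, 20 null), 50 null seeds for the false-positive rate, and
20 seeds per depth for the monotonicity of PTCI~max~ in modulation
depth — sizes chosen so the full statistical suite completes in minutes
on one core while keeping Monte-Carlo margins comfortable.

## Known limitations

- The artifact rule assumes artifacts are *loud*; a quiet artifact
  (probe slip lowering the level) passes the filter.
- A single fixed calibration per session is assumed; microphone gain
  drift between calibration and measurement is not modelled.
- Intermittent PT yields a diluted PTCI~max~ (segment masks are exposed
  so a user can re-select segments, but no interactive tool is
  provided).
- The breathing confound is rejected by design (coherence is evaluated
  at the heart rate, and respiration at ~0.25 Hz lies outside the
  0.8–2 Hz band), but heart rates at exactly double the breathing rate
  of a deeply breathing subject would require care.
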