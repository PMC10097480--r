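# ptcoherence

Automated detection of **objective pulsatile tinnitus** from paired
ear-canal sound and photoplethysmogram (PPG) recordings.

Pulsatile tinnitus (PT) — tinnitus perceived in rhythm with the heartbeat —
is often of vascular origin, and establishing that the pulsatile sound is
*objectively* present in the ear canal (rather than only perceived) guides
the imaging work-up. The conventional check, a clinician listening to the
recording, is subjective. This package implements an automated detector:
the **Pulsatile-Tinnitus Coherence Index (PTCI)**.

A sensitive microphone sealed in the ear canal (calibrated to pascals
against a 94 dB SPL / 1 kHz tone) and a fingertip PPG are recorded
simultaneously. After beat-by-beat artifact rejection keyed on the PPG
systolic peaks, the sound is split into six octave bands
(f_c = 125 … 4000 Hz), each band's 5 Hz-smoothed Hilbert envelope `e_b(t)`
is compared with the PPG `p(t)` via Welch magnitude-squared coherence
(6 s Hamming windows, 3 s overlap),

    C_b(f) = |S_ep(f)|^2 / (S_ee(f) S_pp(f))  in [0, 1],

and the per-band index is the coherence at the heart rate f_hr (the
dominant 0.8–2 Hz peak of the PPG spectrum):

    PTCI_b = max_{|f - f_hr| <= 0.15 Hz} C_b(f),     PTCI_max = max_b PTCI_b.

A PTCI_max near 1 means a sound component locked to the heartbeat; the
band identifies where in frequency it lives.

The package also provides the evaluation layer used to validate such a
detector (majority vote over blinded observers, Fleiss kappa, ROC/AUC,
sensitivity/specificity tables) and a synthetic paired-recording
generator with full ground truth, so every stage is testable without
clinical data.

## Worked example

Generate a synthetic recording with a known heartbeat-locked modulation
(depth 0.5) confined to the 500 Hz octave band, pre-process it, and score
it:

```r
library(ptcoherence)

gen <- genRecording(synthConfig(modDepth = c("500" = 0.5), seed = 3))
rec <- gen$recording
rec
#> Recording: synth-seed3 (unknown ear)
#>   480000 samples at 8000 Hz (60.00 s)
#>   sound RMS: 38.1 dB SPL
#>   label: pulsatile

seg <- segmentRecording(rec, marginDb = 6)
seg
#> BeatSegmentation: 72 peaks, 71 segments (71 kept, 0 rejected)
#>   RMS threshold: 44.08 dB SPL (median + 6 dB margin)

res <- computePtci(excise(rec, seg))
res
#> PTCIResult
#>   heart rate: 1.200 Hz (72 bpm)
#>   PTCI per octave band:
#>       125 Hz: 0.116
#>       250 Hz: 0.130
#>       500 Hz: 0.963
#>      1000 Hz: 0.469
#>      2000 Hz: 0.070
#>      4000 Hz: 0.033
#>   PTCI_max: 0.963 (band 500 Hz)
```

The detector recovers the heart rate (1.2 Hz = 72 bpm), scores near-unity
coherence exactly in the modulated band (the 1000 Hz value is leakage
through the adjacent filter skirt), and stays near the estimator's noise
floor everywhere else. A non-pulsatile recording
(`synthConfig(seed = 4)`) scores `PTCI_max = 0.14` on the same pipeline.

Observer-rating utilities work on plain binary matrices:

```r
fleissKappa(ratingsFixture())$kappa   # 0.679 (three raters, 36 recordings)
sum(majorityVote(ratingsFixture()))   # 21 of 36 majority-present
```

## Command line

An installed `exec/ptci` script exposes the pipeline:

```sh
PTCI=$(Rscript -e 'cat(system.file("exec", "ptci", package = "ptcoherence"))')
Rscript $PTCI synth    --config cohort.json --out-dir wav/
Rscript $PTCI analyze  --out-dir out/ --calibration wav/calibration.json wav/*.wav
Rscript $PTCI evaluate --scores out/summary.csv --manifest wav/manifest.csv \
                       --out report.json
Rscript $PTCI calibrate --tone caltone.wav --level 94 --out calibration.json
```

`analyze` writes, per recording, a segmentation CSV, the per-band
coherence spectra, and a PTCI JSON embedding the resolved configuration
and package version, plus a cohort `summary.csv`.

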