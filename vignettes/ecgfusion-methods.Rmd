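---
title: "Methods: two-stage ECG anomaly detection with spectrogram/feature fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage ECG anomaly detection with spectrogram/feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the method it implements:
the model, its assumptions, the tunable parameters, the synthetic data it
is validated on, and the numerical choices made where the design was
genuinely open. It states no result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The two-stage detector

Ambulatory ECG anomalies split into *rhythm* anomalies spanning several
beats and *heartbeat* anomalies visible in one beat. `detect_anomalies()`
runs two stages: stage 1 slides a 3-s window (step 1 s) over the record
and classifies each window; stage 2 classifies every beat whose central R
peak lies outside all fused-abnormal windows. Membership of a beat in
abnormal rhythm is decided by its central R sample alone — the simplest
total rule when a beat excerpt straddles an interval boundary; every beat
is dispatched to exactly one stage.

## Preprocessing

All signals are brought to 250 Hz. The 360 Hz case uses rational 25/36
polyphase resampling with a Kaiser-window FIR anti-aliasing low-pass
(`signal::resample`), the standard construction for this rate pair;
output length is `ceiling(N * 25/36)`. Each lead is then min–max
normalized to [0, 1] *per record per lead* — the only scope on which the
normalization is well defined for streaming records; a constant lead has
zero range and is rejected rather than silently passed through.

Rhythm windows are labeled abnormal when they overlap *any* part of an
abnormal rhythm interval (rhythm annotations are onsets valid until the
next onset, the standard aux-note convention). Any-overlap was chosen
over majority-overlap to favor sensitivity; the labeling is localized in
one helper should a different rule be needed. Heartbeats span
`[R(i-1), R(i+1))`, half-open so consecutive excerpts never share a
sample; the first and last annotated beats have no bounding pair and are
skipped. Class balancing undersamples the majority class to parity
(seeded), and the test split takes `floor(0.1 * total)` items, stratified
so both splits stay 50–50 within one item.

## R-peak detection: two detectors, two features

The pipeline deliberately carries the R-peak counts of two independent
detectors; they fail differently on distorted beats and the disagreement
is itself informative, so the counts are never merged.

* `pan_tompkins()`: zero-phase 5–15 Hz Butterworth band-pass,
  derivative, squaring, 150 ms moving-window integration, adaptive dual
  thresholds with search-back, 200 ms refractory period.
* `seeht()`: 4–20 Hz band-pass, first difference, amplitude
  normalization, Shannon energy `-d² ln d²`, ~150 ms zero-phase envelope
  smoothing, Hilbert transform of the mean-removed envelope; R
  candidates sit at the negative-to-positive zero crossings of the
  transform (the Hilbert kernel makes the transform of a positive
  envelope bump negative before and positive after its apex).

Both detectors refine each detection to the local raw-signal maximum
within ±50 ms, so positions are comparable; both normalize amplitude
first, so detection is invariant to positive rescaling. The band edges,
integrator length, threshold coefficients and refractory period are not
dictated by the method itself; the values above are the classic ones and
are function arguments.

## Delineation and intervals

`delineate_beat()` locates P-QRS-T fiducials in the ecgpuwave style. QRS
boundaries walk outward from the known R until the smoothed derivative
stays below 5% of the complex's peak derivative (search capped at
250 ms); Q and S are the signal minima flanking R inside the boundaries.
P is searched in a 200 ms window ending 40 ms before QRS onset; T from
80 ms after QRS offset, capped at 0.6 of the right RR interval. Within a
window the wave apex is the zero crossing of the smoothed (5-sample
moving average) first derivative between the derivative maximum and the
*following* minimum — an upright wave rises then falls; pairing with a
preceding minimum would lock onto the previous wave's tail. An inverted
wave is handled by the symmetric fallback pairing.

A window whose peak derivative magnitude is below 2% of the excerpt's
peak derivative is declared empty and the wave missing. Two percent,
not higher: a physiologic P wave is ~10% of the R amplitude but about
three times wider, putting its derivative near 4% of the R derivative —
a stricter floor would structurally reject real P waves.

Intervals follow the peak-based conventions of the delineator: PR is
P-peak→R-peak, QT is Q→T-peak (clinical PR/QT use wave onsets; with a
peak detector the peak-based reading is the faithful one). Any interval
or amplitude whose defining fiducial is missing is exactly 0 — the
zero-is-sentinel rule — so feature vectors are total, and interval
averages over a window include the zeroed beats rather than skipping
them.

## Statistical moments

Skewness and kurtosis are population moments (`μ₃/σ³`, `μ₄/σ⁴`, kurtosis
non-excess so a Gaussian gives 3, with an `excess = TRUE` switch);
variance alone uses the `N−1` sample denominator. The conventions are
mixed deliberately: each matches its defining formula. Inside feature
assembly a zero-variance excerpt yields 0 for the standardized moments so
that flat segments still produce a complete vector; called directly, the
functions raise an error instead.

## Spectrograms

The STFT uses a symmetric Hann taper (endpoints exactly 0, range [0, 1],
matching the normalized signal's range), window length 167 samples
(0.668 s) for rhythm windows and 28 samples (0.112 s) for beats — short
enough for time resolution across a 3-s window, long enough for useful
frequency resolution. Hop defaults to `floor(L/2)` (50% overlap) and the
DFT length to `L` (no zero padding); both are arguments. Power is the
squared magnitude of the one-sided DFT; per-column energy obeys Parseval
once the one-sided fold is accounted for (tested to 1e-6 relative).

Rendering converts power to dB with a floor at −100 dB (so empty bins
never produce −∞), rescales linearly to 8-bit intensities, and resizes
bilinearly; frequency increases upward and time runs left to right.
Grayscale writes intensity directly; RGB uses a fixed jet-like lookup
table built in code. The reference image geometry is 656 × 875
(height × width, the time axis being the longer one); model training uses
a smaller configurable size (below).

## The feature-merging network

The backbone (VGG-16/19, ResNet-18/34 in their standard layouts, or the
two-block `tiny-test` backbone) ends in global average pooling, so the
merge always uses the post-pooling feature vector (512-dim for the large
backbones, 16 for tiny-test) and the input size is free. The CNN features
pass through an elementwise sigmoid so they occupy [0, 1] like the
min–max-scaled handcrafted features — neither source dominates the merged
vector by scale. Dropout (default rate 0.5) is applied to the merged
vector, then a single dense sigmoid unit produces the score. Batch
normalization is omitted from the residual blocks; at the training scales
this package targets, gradient-norm clipping (below) fills the
stabilizing role.

Decision rules are implemented exactly as defined, including their
boundary asymmetry: a single-lead score of exactly 0.5 is *normal*, while
a fused `Y = Y₁ + Y₂ − 0.5` of exactly 0.5 is *abnormal*. The asymmetry
is preserved rather than "fixed"; both rules are enumeration-tested on a
0.01 grid.

## Training

The loss is binary cross-entropy — the natural choice for a scalar
sigmoid output. The optimizer is minibatch SGD with momentum 0.9 and a
global gradient-norm clip of 5, which keeps the large initial learning
rate (0.1, halving every `decay_every` epochs, default 10) stable.
Training holds out 20% of the supplied data as an inner validation split
and stops early when validation accuracy strictly decreases in two
consecutive epochs (the patience is configurable); the weights at the
stopping epoch are kept. The feature scaler is fitted on the training
data only and stored in the fitted object. All randomness —
initialization, the inner split, shuffling, dropout — derives from the
configuration seed, and refitting with the same seed reproduces the
history bit for bit.

The network engine is written in base R (im2col convolution backed by
BLAS matrix multiplication, explicit backward passes); the large
backbones are structurally complete and forward/backward capable, while
desk-scale training and the test suite use `tiny-test`.

## The synthetic generator

`generate_record()` emulates the structure of annotated two-lead
ambulatory records: each beat is a sum of Gaussian bumps with physiologic
defaults (P: 0.1 units, 80 ms wide, 160 ms before R; a Q-R-S triplet
around R; T: 0.3 units, 120 ms wide, 250 ms after R; widths are FWHM),
R apexes exactly on their annotated samples, lead 2 a 0.7-scaled copy
with independent noise. Anomalies: *premature* shortens the preceding RR
by 0.6 and drops the P wave; *wide_qrs* stretches the whole QRS complex
to twice its duration with no P wave (PVC-like); *absent_p* and *tall_t*
modify single waves. Rhythm plans change annotations only. Per-record
seeds derive from the master seed by a fixed affine hash, so datasets
reproduce across platforms.

The study corpus (`synth_study_records()`) contrasts normal sinus rhythm
at 60–81 bpm against tachycardic (150–171 bpm), wide-QRS records labeled
as ventricular tachycardia, with additive noise of 0.01 normalized units
— enough to avoid degenerate bit-identical windows, small enough that
morphology dominates. With the default 27-s records, 8 per class give the
400-window balanced corpus (200 per class) used by the package's
end-to-end test, which trains the tiny backbone on 32 × 32 grayscale
spectrograms for at most 20 epochs per lead — sizes chosen so a full run
completes in about a minute on one CPU.

What the generator does *not* emulate: baseline wander, electrode motion
artifacts, biphasic or inverted waves, beat-to-beat morphology variation,
or clinically faithful arrhythmia dynamics. Passing tests therefore show
that the pipeline's mechanics — extraction, features, spectrograms,
training, fusion, bookkeeping — are correct and that the method separates
classes whose differences mirror its feature design; they do not certify
clinical performance on real recordings, which requires the annotated
ambulatory databases the full-scale results are defined on.

## Degenerate inputs and tie-breaks

Constant signals: rejected by normalization, silent for detectors, zero
feature vectors in assembly. Delineation never throws on degenerate
windows — it returns missing. Max-pooling ties take the first operand in
scan order; detector refractory conflicts keep the taller raw peak. The
balanced test split gives the extra item of an odd test size to the
abnormal class. WFDB quantization uses gain 1000 (quantization step
1e-3 of the normalized range) by default.

## Known limitations

The WFDB codec covers headers, format 16 and 212 signals, and the beat /
rhythm annotation stream including SKIP and AUX records — sufficient for
the two target databases' structure — but not the full format family
(multi-segment records, other signal formats). Delineation assumes
upright R and predominantly upright P/T (an inverted-wave fallback
exists but is not the tuned path). Full-size VGG/ResNet training at the
875 × 656 image scale is computationally impractical in pure R; those
backbones are provided for architectural fidelity and small-scale use.
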