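---
title: "Methods: phonocardiogram screening with hand-crafted features and weighted KNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phonocardiogram screening with hand-crafted features and weighted KNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgdx)
```

## Scope and model

`pcgdx` screens short heart-sound recordings for four valve pathologies
(aortic stenosis AS, mitral stenosis MS, mitral regurgitation MR,
mitral valve prolapse MVP) against normal (N). The diagnostic model is
deliberately classical: a fixed bank of 26 hand-crafted features, a
chi-square filter keeping the 15 most class-associated features, and a
1/distance-weighted k-nearest-neighbour vote. Its assumptions are
correspondingly modest: recordings long enough to contain a few cardiac
cycles, a sample rate reducible to 8000 Hz, and murmurs whose timing and
frequency band carry the class information. No segmentation into
S1/systole/S2/diastole is attempted — the features are computed over the
whole recording, which makes the pipeline robust to segmentation error at
the cost of diluting cycle-localized evidence.

## Signal canonicalization

All stages assume a mono signal at 8000 Hz. Resampling is a polyphase
upfirdn: the rational ratio p/q is reduced, a linear-phase Kaiser-windowed
FIR low-pass (cutoff at the tighter of the two Nyquist limits, ~80 dB
stopband, half-length 10 zero-crossings per polyphase branch) is applied
to the conceptually zero-stuffed stream, and only the requested output
phases are evaluated. Plain decimation is never used; aliasing would fold
wideband noise into the 40–400 Hz murmur bands. A 44.1 kHz → 8 kHz → 44.1 kHz
round trip of a band-limited sine reconstructs with relative RMS error
about 5×10⁻⁵ (the package tests assert < 10⁻³).

Amplitude normalization is the z-score `(x − μ)/σ`. The deviation uses the
sample (N−1) convention, switchable to population via `sd_type`; at
recording lengths of thousands of samples the two differ negligibly, the
switch exists for exact compatibility with either convention. The
normalization is applied in both the feature path and the scalogram path
(configurable off): it removes recorder gain, which none of the
dimensionless features should see, and fixes the amplitude scale the CWT
ridge magnitudes are compared on.

## The 26 features

*Time domain (10).* RMS, shape factor rms/mean|x|, skewness m₃/m₂^{3/2}
and kurtosis m₄/m₂² with 1/N central moments — kurtosis is the raw fourth
standardized moment, so a Gaussian scores 3 and no 3 is subtracted — peak
max|x|, impulse factor peak/mean|x|, crest factor peak/rms, clearance
factor peak/mean(√|x|)², mean, and std (N−1). The ratio features are
dimensionless, hence gain-invariant; `crest = impulse / shape` is an
algebraic identity the test suite checks on random signals, along with
equality to naive-loop reference implementations at 10⁻⁹ relative
tolerance.

*Spectral quality (3).* SNR, SINAD and THD in dB from a one-sided
periodogram with a Kaiser β = 38 window. The fundamental is the largest
non-DC component; each spectral peak is grouped with ±16 bins to absorb
the window mainlobe; harmonics are the 6 orders above the fundamental,
re-centered on the local peak within the same half-width. Noise is
everything outside the DC, fundamental and harmonic zones. The estimator
conventions (window, β, harmonic count, half-width) are package defaults,
exposed as arguments: the defining ratios say nothing about estimation,
and any fixed, documented convention yields comparable features across
recordings. Constructed mixtures (a sine over −20 dB white noise; a
−20 dB second harmonic) are recovered within 1 dB and 0.5 dB
respectively in the tests.

*MFCC (13).* 25 ms Hamming frames with 10 ms hop, power FFT, 26
triangular filters equally spaced on the mel scale
`mel(f) = 2595 log₁₀(1 + f/700)` between 0 Hz and Nyquist, log filter
energies (floored at the smallest positive double), orthonormal DCT-II,
coefficients 0–12 retained, and the per-coefficient mean over frames as
the recording-level value. Frame/hop/filter counts follow common MFCC
practice for short audio and are configurable. Whether the 0th
(energy-like) coefficient should be kept is genuinely open; the default
keeps it (`include_c0 = FALSE` switches to 1–13). Keeping c0 preserves a
loudness-like channel that the z-score normalization has already made
meaningful rather than recorder-dependent. A gain g moves only c0, by
2√M·ln g for M filters — a property the tests assert.

## Chi-square selection

Continuous features enter the chi-square independence test through
equal-frequency binning: 10 bins bounded by type-1 (inverse-ECDF)
quantiles. Because type-1 quantiles are order statistics, bin membership
depends only on ranks, making scores exactly invariant under strictly
monotone feature transforms — an interpolating quantile definition would
break this. Empty bins are dropped; a constant feature scores 0 (p = 1)
rather than erroring. The statistic uses the independence-test degrees of
freedom (bins − 1)(classes − 1); the importance score is −ln p with p
floored at the smallest positive double so a perfectly separating feature
gets a large finite score. The top 15 features are kept, ties broken by
canonical feature order. Selection is fitted on the training split only:
fitting it on all data would leak label information into the holdout
evaluation.

## Weighted KNN

Features are z-scored with training statistics (constant columns get unit
deviation), distances are Euclidean, and each of the k = 10 nearest
neighbours votes with weight 1/d. The 1/d weighting is the point of the
classifier: a query surrounded by a few close recordings of one class and
many far recordings of another is assigned to the close class, where the
unweighted majority flips it — the package reproduces this flip on a
5-neighbour construction in its tests, and checks prediction-for-
prediction equality with a brute-force oracle. Exact-match queries
(d = 0) are decided by majority among the zero-distance neighbours alone;
vote ties go to the class appearing first among the nearest neighbours.
Neither k nor the metric is canonical; k = 10 is a common default at
training sizes of several hundred, and `wknn_choose_k()` offers
cross-validated selection. Brute-force distance evaluation is the
intended contract at n ≤ a few thousand recordings; no tree acceleration
is provided.

## Scalograms

The CWT uses an analytic generalized Morse wavelet with symmetry γ = 3
and time-bandwidth βγ = 60, 12 voices per octave, evaluated in the
frequency domain with peak-normalized (L∞) wavelets so a unit sinusoid
yields a unit-magnitude ridge exactly at its frequency (the tests locate
a 200 Hz ridge within half a voice spacing, and require a rising chirp's
ridge to be monotone). The default frequency axis runs from the lowest
frequency whose wavelet support fits twice into the recording up to
0.45 of the sample rate.

Images are produced by per-image min–max scaling, bilinear resize of the
magnitude matrix to 224×224, then quantization through a fixed 128-level
jet-style colormap into 3 channels. Resizing the scalar magnitude before
colormapping (rather than resizing an RGB cube) costs a third of the
memory and is visually indistinguishable; per-image (not global) scaling
matches scalogram-image classification practice but means absolute
loudness is not comparable across images — the main divergence one should
expect from any other rendering pipeline. Which colormap, and whether to
log-scale magnitudes first, has no canonical answer; the choices here are
fixed so exported datasets are internally consistent. Network training
itself (e.g. GoogLeNet fine-tuning on the exported tree) is out of scope:
it needs pretrained weights and non-desk compute; the class-folder PNG
tree plus manifest is the hand-off point.

## Metrics

All metrics are one-vs-rest on the 5×5 confusion matrix, in percent,
full precision internally and half-up rounding to 2 decimals only for
display. The F1 here is the harmonic mean of **specificity and
sensitivity** — implemented literally because the downstream tables are
defined that way — and differs from the conventional precision–recall F1,
which is provided under the separate name `f1_precision_recall()` to
prevent silent confusion. Macro-averages are unweighted means over the
four disease classes, excluding Normal (the all-class average is
available by passing `classes = PCG_CLASSES`). A sensitivity or
specificity with a zero denominator is returned as `NA` with an
`undefined` attribute, never as a silent 0. `ovr_counts()` inverts a
printed sensitivity/specificity pair back to integer TP/FN/FP/TN counts,
as a realizability check on any reported table.

## The synthetic generator

`synth_recording()` emulates the textbook phenomenology of each class at
8000 Hz: S1 and S2 are Gaussian-windowed tone bursts (90 and 140 Hz, 100
and 70 ms, S2 at 35% of the cycle), murmurs are band-passed white noise
shaped by a per-cycle envelope — AS: diamond envelope over mid-systole,
100–400 Hz; MR: plateau over the whole of systole, 100–350 Hz; MS:
decrescendo diastolic rumble, 40–100 Hz; MVP: a 300 Hz mid-systolic click
plus a late-systolic crescendo, 150–400 Hz — with additive white noise at
25 dB SNR and peak normalization to 0.9. Defaults are fixed constants;
datasets jitter heart rate ±10% and murmur amplitude ±20% within class,
with per-recording seeds derived from one master seed. Recordings default
to 3 s (a handful of cycles at 70 bpm), a typical auscultation clip
length.

What the generator does *not* model: hemodynamics, respiration and sensor
coupling, inter-patient anatomy, recording-chain coloration, and murmur
grade variation. Its classes are constructed to be separable, so the
end-to-end test — 40 recordings per class, stratified 80/20 holdout,
accuracy ≥ 90% over 5 seeds, typically 100% — validates the pipeline's
plumbing and the discriminative adequacy of the feature set on clean
inputs. It is a synthetic stand-in, not evidence about clinical
performance.

## Numerical choices and degenerate inputs

- Constant signals are rejected by normalization and the time-domain
  moments (degenerate-input errors), as are all-zero signals whose ratio
  denominators vanish; a flat spectrum aborts the SNR estimator.
- Log arguments are floored at the smallest positive double (MFCC filter
  energies, chi-square p-values).
- Quantile-bin and vote ties break deterministically (canonical feature
  order; first-seen neighbour class).
- Every stochastic step threads one integer seed; RNG state is restored
  after each seeded operation, so library calls never perturb caller
  randomness.

## Problem sizes

The shipped test and acceptance runs use 40 recordings per class (200
total, 3 s at 8000 Hz), 100-replicate selection experiments, 100-signal
oracle comparisons and 200-query classifier oracles — sizes at which every
property of interest is already stable and a full run completes in a few
minutes on one core. All sizes scale up through function arguments.

## Known limitations

- The WKNN path's k, metric and validation protocol have no canonical
  reference values; published results from comparable pipelines on
  clinical corpora are not numerically reproducible from synthetic data,
  and no attempt is made to do so.
- SNR/SINAD/THD depend on estimator conventions; cross-toolkit
  comparisons require matching windows and peak-grouping widths.
- The scalogram rendering (colormap, per-image scaling) is one of many
  defensible conventions; exported images are consistent within this
  toolkit only.
- `f1_spec_sens()` can exceed the precision–recall F1 substantially on
  imbalanced one-vs-rest collapses; users comparing against other
  systems must pick the convention explicitly.
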