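---
title: "Methods: frequency-tagged statistical learning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged statistical learning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(entrainSL)
```

## The paradigm and the measurement model

The package analyses a word-segmentation paradigm in which listeners hear a
continuous artificial language: four trisyllabic nonsense words, each
repeated 100 times in pseudorandom order (no immediate repetition), at
300 ms per syllable — 400 words in six minutes with no acoustic boundary
cues. Because each of the 12 syllables occupies a unique word position, the
transitional probability between adjacent syllables is exactly 1 inside a
word; at a word boundary the next word is one of the three non-repeating
alternatives, so boundary transitions run at about 1/3. Segmentation can
therefore only be achieved statistically, and learning is read out in three
ways: neural entrainment during listening, and the rating, 2AFC and
target-detection tasks afterwards.

The neural measure is inter-trial phase coherence (ITC). EEG is epoched
time-locked to every 12th word onset (12 words = 10.8 s per epoch), each
epoch is Fourier transformed without tapering or zero-padding, and for each
channel and frequency bin the unit phasors of the per-epoch phases are
averaged; the modulus of that average is the ITC. The statistic is
phase-only by construction: it is invariant to positive rescaling of the
data and to epoch order (both properties are asserted in the test suite).
The bins of interest are the word rate, 12/10.8 ≈ 1.111 Hz, and the
syllable rate, 36/10.8 ≈ 3.333 Hz — commonly labelled 1.1 and 3.3 Hz; the
analysis always selects the nearest bin and logs the exact frequency. The
Word Learning Index, WLI = ITC_word / ITC_syllable, normalises word-rate
phase locking by the obligatory acoustic response, and is the primary
learning index.

Two inferential devices accompany the point estimates. A surrogate null is
built per participant by shifting every word onset by an independent
integer draw from −900..900 ms (1801 values) and re-running epoching and
ITC identically; paired t-tests compare actual against surrogate values. A
sliding-bundle time course traces learning: bundle *k* holds epochs
*k..k+4* (54 s), shifted by one epoch, and per-bundle WLI/ITC series are
modelled with `response ~ bundle + (1 | participant)` by REML with
Satterthwaite F tests, optionally with group × bundle or age × bundle
terms, or a dataType × bundle term to contrast actual with surrogate
trajectories.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `syllableDuration` | 0.3 (exposure), 0.35 (child detection) | s | the paradigm's presentation rates |
| `repsPerWord` | 100 | — | 400-word, six-minute stream |
| `band` | 0.1–20 | Hz | passband containing both target rates with wide margin |
| `notch` | 60 | Hz | mains interference |
| `ptpThreshold` | 150 | µV | peak-to-peak screen for extracranial artifacts |
| `wordsPerEpoch` | 12 | words | 10.8 s epochs; bin spacing ≈ 0.093 Hz separates 1.111 from 3.333 Hz cleanly |
| `freqRange` | 0.6–5 | Hz | analysis window around both rates |
| `bundleSize`, `step` | 5, 1 | epochs | 54 s sliding window |
| `missingThreshold` | 0.5 | fraction | drop bundles missing in a majority of participants |
| `jitterRangeMs` | ±900 | ms | one word period of onset jitter, destroying stimulus phase while preserving epoch timing |

## The synthetic-data generator

`simulateRecording()` is a generative model of what the analysis assumes:
within analysis epoch *n* the deterministic signal is

A_s·cos(2πt/d + φ_s,n) + A_w·cos(2πt/(3d) + φ_w,n),

with d the syllable duration, φ_s,n ~ von Mises(0, κ_s), and
φ_w,n ~ von Mises(0, κ_w(n)) where κ_w interpolates linearly from
`kappaWordStart` to `kappaWordEnd` across epochs — the learning signal.
Region-of-interest channels carry the signal at gain 1, other scalp
channels at 0.3 (frontocentral topography), mastoids at 0; every channel
receives independent 1/f^α Gaussian noise (spectrally shaped white noise,
α = 1 by default). Ground truth is returned with each recording: the κ
schedule, the drawn phases, and the expected resultant length
R(κ) = I₁(κ)/I₀(κ), which is what noise-free ITC converges to. Under no
entrainment the expected ITC from N epochs is √π/(2√N); both expectations
anchor the calibration tests.

Two deliberate simplifications: phase offsets are drawn **per analysis
epoch** (12 words), not per word — this makes the ground-truth ITC
analytically tractable at the cost of not modelling within-epoch phase
drift; and the amplitudes are set for comfortable desk-scale statistical
power (the literature gives no effect-size anchor for human entrainment
amplitude in this paradigm), not to match human signal-to-noise ratios. The
generator also omits eye-blink/EMG artifact morphology (the artifact screen
is exercised with injected amplitude steps), volume conduction, and
age-related anatomical differences. Consequently, passing parameter
recovery demonstrates that the *pipeline* is correct and well calibrated —
not that real recordings of any particular population will show these
effect sizes.

`simulateBehaviour()` drives all three tasks from a single learning
strength L ∈ [0, 1]: per-trial 2AFC accuracy 0.5 + 0.4·L, familiarity
ratings as discretised Gaussians whose word/nonword means separate with L,
and detection RTs shortened by `rtFacilitation`·L per predictable syllable
position, with miss and false-alarm processes. At L = 0 everything
collapses to chance, which the tests verify.

## Numerical choices and edge cases

* **Epoch length and onset mapping.** The stimulus grid is not
  sample-aligned (0.9 s × 512 Hz = 460.8 samples per word). Epochs are
  `round(12 × 0.9 × fs)` = 5530 samples and onsets map to the nearest
  sample, keeping timing error under 1 ms; consecutive epoch start samples
  therefore alternate between 5529 and 5530 apart, i.e. neighbouring
  epochs may share a single boundary sample. The residual phase jitter is
  ≤ 0.01 rad at the word rate, visible only as ITC ≈ 1 − 10⁻⁵ for
  perfectly locked signals.
* **Filtering.** Zero-phase (forward–backward) Butterworth: 2nd-order
  high-pass, 4th-order low-pass, 2nd-order band-stop notch, applied as a
  cascade rather than one high-order band-pass because a 0.1 Hz edge at
  512 Hz makes direct band-pass designs numerically fragile. Zero-phase
  filtering is essential since the downstream statistic is phase.
* **No taper, no padding.** Phases are taken from raw FFT coefficients;
  tapers would alter bin leakage without helping a phase-only statistic.
* **Nearest-bin selection** with ties resolved to the lower frequency; the
  chosen bin frequency is always attached to the result.
* **Degenerate inputs.** ITC requires ≥ 2 retained epochs; WLI refuses a
  zero denominator rather than returning infinity; the paired test returns
  a degenerate-variance flag (not ±∞) when all differences are equal, and
  t = 0, p = 1 when the arrays are identical; constant-response ANOVA
  input returns F = 0, p = 1 rather than a 0/0 ratio of rounding errors;
  bundles with < 2 retained epochs yield missing values, never fabricated
  ones.
* **Von Mises sampling** uses the Best–Fisher rejection algorithm
  implemented in the package (no circular-statistics dependency), with
  κ = 0 and κ = ∞ handled exactly.

## Design decisions on open points

* **Bundle count.** From 33 epochs the sliding-window arithmetic gives
  33 − 5 + 1 = 29 bundles; reports of 28 in this paradigm likely reflect
  artifact-rejection bookkeeping. The package follows the arithmetic rule;
  the majority-missing exclusion then trims late bundles per dataset.
* **Quota enforcement.** "Pseudorandom" ordering with exact 100-fold
  quotas is implemented by sampling each next word proportionally to its
  remaining quota among the three non-predecessor words, with bounded
  retries; the original stimulus sequences are not reproduced.
* **Hit assignment.** Each press is assigned to the nearest preceding
  unconsumed target whose response window covers it (earliest press wins;
  each target consumes at most one press); a press at exactly 0 ms counts
  as a false alarm. Multi-press handling is not specified by the paradigm
  description, so the rule is documented and fixed.
* **Rating score** uses the pooled-foil mean; with 4 + 4 foils this equals
  the mean of the two foil-category means.
* **Single surrogate per participant** is the default (matching the
  paradigm's procedure); averaging several surrogates is available as an
  extension via repeated seeded calls.
* **Partwords/nonwords.** Partwords join an attested within-word bigram
  with one foreign syllable (exactly one attested pair each); nonwords
  combine final, medial and initial syllables of three different words, so
  no bigram is attested either within words or across stream boundaries.
* **EEG interchange** uses a documented plain-text format (JSON header +
  TSV samples + BIDS-style events TSV) behind `readRecording()` /
  `writeRecording()`; round trips are lossless to the written precision.
* **Interface.** The package's functions, `runPipeline()` and this
  vignette are the interface; no shell entry point is shipped.

## Problem sizes used in the test suite

Unit tests run on toy epochs and short streams (25–100 word repetitions).
The calibration suite uses 30–40 Monte-Carlo replicates per null check
(N ∈ {10, 33, 100} epochs); parameter recovery runs 20 simulated cohorts
of 24 participants with full six-minute streams, two simulated channels
per participant, bundles 1–26, testing that the injected word-rate
entrainment increase is detected at α = 0.05 in at least 90% of cohorts;
series-level recovery checks that an injected 0.01/bundle WLI slope falls
inside its 95% confidence interval and that zero-slope data trigger the
bundle effect at no more than the nominal α rate (100 fits). These sizes
were chosen as the smallest designs at which the checked expectations are
sharp.

## Known limitations

* ICA-based ocular artifact removal is out of scope; the amplitude screen
  will not catch low-amplitude structured artifacts.
* The generator's per-epoch phase model cannot express within-epoch
  learning dynamics; slopes are injected at epoch resolution.
* Time–frequency (wavelet) ITC, source localisation and random-slope
  growth models are not implemented.
* Re-analysis of real recordings is supported through the text interchange
  format, but no claims are made about recovering published human effect
  sizes: those depend on the deposited data, not on this implementation.
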