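---
title: "Measuring feedforward variability in vowel production: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring feedforward variability in vowel production: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vowelvar)
```

## The scientific question

When a speaker produces the same vowel many times, the formant frequencies
(the vocal-tract resonances F1 and F2 that define vowel quality) scatter
from trial to trial. The *initial* portion of each vowel — the first
50 ms — is produced before auditory feedback of the ongoing utterance can
influence articulation, so its trial-to-trial dispersion indexes the
variability of *feedforward* motor commands rather than online feedback
corrections. This package quantifies that dispersion in cohorts of adults
who stutter (AWS) and matched nonstuttering adults (ANS) speaking under
normal auditory feedback (NAF) or 100-ms delayed auditory feedback (DAF),
and tests the factorial hypotheses of interest: a group baseline difference
in feedforward variability and a group-by-condition crossover (DAF
increasing variability in fluent speakers while decreasing it in stuttering
speakers).

Because the original recordings of such studies are typically not
distributable, the package includes a first-class synthetic-cohort
generator with exact formant ground truth. Every downstream stage —
tracking, windowing, variability metrics, mixed-model inference — is
validated against that ground truth.

## The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` emulate the study design: 2 groups
× 12 participants × 2 conditions × 4 front vowels × 24 trials = 4,608
trials of mono 16-bit audio at 44,100 Hz.

**Source-filter synthesis.** Each trial is an impulse train at f0 = 120 Hz
passed through a cascade of four second-order resonators (unit DC gain,
pole radius `exp(-pi * B / fs)`), ramped on/off over 10 ms and
peak-normalized to −6 dBFS before intensity shifts. Formant frequencies are
held constant within each 5-ms block and the exact per-block values are
recorded as the trial's ground-truth track, which makes the synthesizer a
formant-tracking oracle. Default targets are canonical adult-male values:
/i/ (270, 2290), /ɪ/ (390, 1990), /ɛ/ (530, 1840), /æ/ (660, 1720) Hz for
F1/F2. F3 is 3010 Hz for /i/ and ~2500 Hz otherwise — /i/'s F2 sits high,
and a uniform F3 of 2500 Hz would leave only ~70 Mel of headroom, so
trial offsets could push F2 through F3; the per-vowel F3 follows the
standard reference pattern and keeps the formant ordering valid across the
whole offset distribution.

**Variability injection.** Per-trial formant offsets are drawn per formant
in Mel with SD `sigma_trial[group, condition]`, times a per-vowel scale
(0.8 for /i/ … 1.15 for /æ/, making /i/ the most stable vowel). The default
SDs are 12 Mel (ANS/NAF), 12·e^0.25 ≈ 15.4 (ANS/DAF and AWS/DAF), and
12·e^0.5 ≈ 19.8 (AWS/NAF): a higher stuttering-group baseline with
opposite-signed DAF shifts of ±0.25 log units — the crossover pattern the
statistical stage is meant to detect, at an effect size the design can
resolve. Within-trial drift is a smooth zero-mean quadratic (orthonormal
shifted-Legendre basis, coefficients standard normal) scaled so its
expected within-window SD is `sigma_within` = 8 Mel; drift is applied to F1
and F2, the formants entering the metrics. DAF is simulated by its measured
consequences — duration ×1.2 and intensity +3 dB — rather than by an audio
feedback loop, since the delay acts on the *speaker*, which a generator
models directly as effect sizes. Small lognormal duration jitter (5%) and
intensity jitter (0.5 dB) keep secondary measures from being degenerate.

**What the generator does not emulate.** Real consonant-vowel-consonant
context (trials are isolated vowels with silence margins), glottal source
variation (no jitter/shimmer, flat-spectrum pulses), room acoustics and
microphone coloration, disfluencies, and mispronunciations. Passing tests
therefore demonstrate correctness of the measurement and inference chain
under known ground truth — not robustness to every property of real
recordings.

## Formant tracking

`track_formants()` implements the classical offline LPC chain:

1. **Decimation** to 11,025 Hz (anti-aliased, `signal::decimate`), putting
   the four target formants below Nyquist; LPC order 17 (the standard
   male-speech order; use 15 for female speech) is appropriate at this rate.
2. **Pre-emphasis** with coefficient 0.8. This is milder than the ~0.97
   used for real speech deliberately: pre-emphasis compensates the falling
   (−12 dB/oct) glottal spectrum, and the synthetic source is spectrally
   flat, so 0.97 over-whitens and biases low F1 estimates upward by tens of
   Hz on /i/. With 0.8 the median recovery error across the four vowels is
   ~5 Hz (F1) and ~11 Hz (F2). The coefficient is a config field; raise it
   for real recordings.
3. **Framing**: 25-ms Hamming frames, 5-ms hop (≈10 frames inside the
   50-ms analysis window).
4. **All-pole fit** per frame by the autocorrelation method
   (Levinson–Durbin, written out in `lpc_coefficients()` and property-tested
   against a direct Toeplitz solve), guaranteeing minimum phase.
5. **Candidates**: complex pole angles/moduli → frequency/bandwidth pairs;
   candidates below 50 Hz or within 50 Hz of Nyquist are discarded.
6. **Slot assignment by dynamic programming** across frames: each state is
   an increasing assignment of candidates to slots F1..F4, with local cost
   `0.25·Σ (log f − log nominal)² + Σ B/f` and transition cost
   `Σ (Δ log f)²`; a `1e-9·ΣB` term breaks exact ties toward the
   lowest-bandwidth assignment, keeping the tracker deterministic. Frames
   with no usable fit (silence) or fewer candidates than slots are filled
   with the nominal frequencies and flagged.

The weights put the three terms on comparable scales for Mel-magnitude
log-frequency deviations; they are exposed in `tracker_config()`.

## Windowing and per-trial measures

Vowel onsets/offsets come from the annotation table (the synthetic
counterpart of manual selection); `detect_vowel_bounds()` provides an
energy-based fallback flagged `source = "auto"`. The feedforward window is
the half-open interval `[onset, onset + 50 ms)` over frame *centers* —
half-open so the frame count is a deterministic function of onset and hop
alone — and at least 3 frames are required, else the trial is excluded and
logged. Duration is `offset − onset` in ms; intensity is dB RMS re full
scale (no SPL calibration is assumed, so only differences are meaningful).

## Variability metrics

With `m1, m2` the window-mean Mel F1/F2 of each trial and `s1, s2` the
within-window Mel SDs, for the `n` trials of one participant × vowel ×
condition cell:

- **TTV** `= sqrt(mean(d1² + d2²))`, the RMS Euclidean deviation of the
  per-trial (F1, F2) point from the cell's grand average. The grand
  *average* is the default center (a median switch exists). For independent
  offsets of SD σ per formant, `E[TTV] ≈ σ·√2·√((n−1)/n)` — the estimator
  recovery test and the acceptance script verify this to within 2%.
- **WTV** `= sqrt(sum(s1² + s2²) / (2n))`, the RMS of the pooled
  within-window SDs; translation-invariant and independent of between-trial
  spread. Both are computed over the 50-ms window only.
- **Inter-vowel distance**: mean of the 6 pairwise Euclidean distances
  among the four vowel centroids per participant × condition, in Mel.

Variability is bounded below by zero, so both measures are natural-log
transformed before modeling (`log_ttv`, `log_wtv`); the log base only
rescales the linear model and leaves F-tests unchanged. Zero-variability
cells cannot be log-transformed and are dropped with a warning.

The grand average could in principle be taken per vowel across both
conditions rather than per cell; per-cell centering is the implemented
default, so condition effects on the *mean* formant position do not leak
into the dispersion measure.

## The split-plot mixed ANOVA

`fit_mixed_anova()` fits `y ~ group * condition * vowel` with a participant
random intercept (participants nested in groups) *from scratch* via the
classical balanced-design sums of squares. For one observation per
participant × vowel × condition cell this is exact and coincides with the
REML + Satterthwaite solution of a general mixed-model fitter — the test
suite checks agreement with `lmerTest` to 1e−6. Group (between-subject) is
tested against the participants-within-groups stratum; every within-subject
effect against the residual stratum. For the default design the denominator
df are 22 and 154. Variance components come from expected mean squares,
with the participant component truncated at zero (REML-consistent) under a
warning. Unbalanced input is refused with an explicit error rather than
silently approximated: exactness and testability were preferred over
generality, and a user with missing cells should decide the
imputation/subsetting policy themselves.

**Post-hocs** (`posthoc_pairwise()`) use cell-mean marginal means (exact
under balance) with studentized-range (Tukey) adjustment; the error stratum
follows the contrast: participant stratum (df 22) when a contrast spans
groups, residual stratum (df 154) otherwise; cross-group cell-mean
contrasts use the composite variance `(MS_participant + MS_residual)/(n·v)`.
The group × condition family is the 4 cell means, 6 contrasts.
**Simple effects** (`simple_effects_condition_within_group()`) estimate
DAF − NAF within each group against the residual stratum,
Bonferroni-adjusted over the family of two. **Correlations**
(`correlate_wtv_ttv()`) are participant-level Pearson correlations between
mean log WTV and mean log TTV within a group × condition, with the usual
two-sided t test.

## Numerical and calibration choices

- Monte-Carlo problem sizes: type-I calibration uses 4,000 null cohorts at
  the table level (no audio), giving the rejection-rate estimate a standard
  error of ~0.0035 around the nominal 0.05; crossover power uses 200
  simulated cohorts; tracker validation uses 100 synthesized vowels with
  uniform ±30 Hz F1/F2 perturbations; estimator recovery uses 1,000 cells.
- Null and power simulations inject participant intercept SD 0.1 and
  residual SD 0.2 on the log-TTV scale; the power scenario adds the
  generator-implied group baseline difference of 0.25 and condition shifts
  of ±0.25.
- p-values use R's `pf` and `ptukey`; agreement with `emmeans` is tested to
  1e−3 (the studentized-range CDF is itself numeric).
- All cohort randomness is drawn up front in `cohort_trial_plan()`, so a
  cohort is bit-reproducible from its seed and trials can be synthesized
  streamingly in any order.

Two emergent properties of the measured (as opposed to injected) values are
worth knowing. First, tracked TTV sits on a noise floor (tracking error plus
within-trial drift leaking into window means), so measured log-TTV condition
ratios are attenuated relative to the injected ±0.25 — the full-cohort run
recovers ≈ ±0.14 with the correct signs and a decisive interaction. Second,
the within-trial drift budget is defined over the whole vowel while WTV is
measured in the first 50 ms, so longer (DAF) vowels show slightly smaller
measured WTV; this small condition effect on WTV is a property of the
generator's drift parameterization, not of the metrics.

## Known limitations

- The ANOVA engine is deliberately balanced-only; real datasets with
  excluded trials remain balanced at the *cell* level (TTV/WTV are computed
  per cell from however many trials survive) but a participant missing an
  entire cell cannot be fitted.
- The tracker assumes adult-male formant ranges by default
  (`nominal_formants`, LPC order 17); other voices need config changes.
- dBFS intensity is relative; absolute SPL claims are out of scope.
- The generator's effect sizes are fixed study conditions, not estimates
  from any real dataset.
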