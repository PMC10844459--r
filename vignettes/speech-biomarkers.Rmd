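---
title: "Digital speech biomarkers for Huntington disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital speech biomarkers for Huntington disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdspeech)
```

## The problem

Huntington disease (HD) progressively impairs motor control of speech:
articulation slows, pauses lengthen and multiply, reading becomes
disfluent, and intelligibility drops. These changes are measurable from
short, standardized speech tasks — reading the first paragraph of the
Rainbow Passage, counting forward from 1 to 20, and counting backward from
50 toward 30 in steps of 3, each capped at 40 s — and they track clinical
severity as rated by the UHDRS (motor, functional and dysarthria sub-scores)
and the MoCA cognitive screen.

`hdspeech` implements the full analysis chain for such recordings:

1. **Feature extraction** from a mono WAV recording plus a word-level timed
   transcript (any ASR or forced aligner that emits `{text, start, end}`
   triples; ASR itself is deliberately out of scope).
2. **Cohort statistics**: pairwise group contrasts (pooled-variance t-tests
   with Cohen's d) and feature-clinical correlations.
3. **Prediction**: leave-one-subject-out (LOSO) random-forest
   classification of diagnostic group and dysarthria level, and regression
   of the four clinical scores.
4. **Synthetic data**: recordings with planted ground truth, a controllable
   transcript-corruption channel, and feature-level cohorts that reproduce
   the published distributional structure of an 18 HD / 7 prodromal HD
   (pHD) / 11 control cohort — which makes every stage testable without
   access to clinical audio.

## Timing model

Transcript word intervals are the source of truth for voicing. Merged word
spans form the voiced intervals; everything before the first word and after
the last word is discarded as irrelevant. Within the remaining span:

* total voiced time = sum of merged word-interval durations;
* total signal time = last word end − first word start;
* total pause time = signal − voiced, so the three are conserved exactly;
* speech-to-pause ratio = voiced / pause (reported missing when pause time
  is zero rather than infinite);
* articulatory rate = words per second of *voiced* time.

Counted pauses are inter-word gaps of at least `min_pause` seconds
(default **0.10 s**). Shorter gaps are treated as within-speech
articulation: they still count toward total pause time, but not toward the
pause count or mean pause length. The published control-group values
(total pause ≈ 6.01 s over ≈ 22.5 pauses with mean pause ≈ 0.26–0.27 s)
are consistent with a small threshold of this kind but cannot pin its
exact value down, so it is a configuration knob. Words of zero duration
count as words but contribute no voiced time. The 40 s task cap is
available as an optional truncation (off by default) since transcripts of
in-protocol recordings already respect it.

## Acoustic features

**Pitch.** F0 is estimated per 40 ms frame (10 ms hop) as the peak of the
normalized autocorrelation within 60–400 Hz, the standard adult speech
range. A frame is voiced when the peak exceeds 0.45 and the frame RMS
exceeds an energy floor (1e-4 full scale). Two numerical details matter:

* *Octave errors*: for strongly periodic frames the autocorrelation at the
  true period T and at 2T are numerically near-equal, and rounding can tip
  the maximum to 2T (halving the estimate). Candidate lags therefore pay a
  small penalty (0.01 per octave of lag), which resolves ties toward the
  shorter period without affecting unambiguous frames.
* *Sub-sample lag*: the peak lag is refined by parabolic interpolation,
  keeping the relative error well below 1% across 80–300 Hz.

Pitch mean and SD (sample SD, n−1) are computed over voiced frames whose
centers fall inside voiced intervals, so leading/trailing silence cannot
bias them. Fewer than two qualifying frames yields missing values.

**Loudness.** Per frame, the Hann-windowed magnitude spectrum is grouped
into the 24 Bark critical bands (Traunmüller transform
z = 26.81·f/(1960+f) − 0.53); the RMS of bin magnitudes within each band is
summed across bands, and the sum is compressed with the Stevens power law
(exponent 0.3) to a sone-like scale; frames inside voiced intervals are
averaged. Two caveats are deliberate: a plain waveform carries no
sound-pressure calibration, so the absolute scale is arbitrary and only
relative comparisons are meaningful; and whether band energies should be
summed before or after the psychoacoustic compression is ambiguous from the
verbal definition — summing before compression was chosen and documented,
not inferred from data. Full ISO-532/Zwicker loudness (specific-loudness
integration with masking) is out of scope.

## Similarity and intelligibility

Transcribed readings are compared with the reference passage at the
*letter* level, which captures partial-word errors that word-level
comparison misses. Text is normalized (lower-case, hyphens split,
apostrophes removed, everything outside a–z dropped) and encoded a = 1 …
z = 26 with 0 for inter-word spaces; the published description cites a
letter-coding scheme without giving the map, so the alphabetical ordinal —
the simplest reproducible choice — is used and is swappable via a
configuration table.

The **similarity DTW** feature is 1/(1 + DTW distance) between the encoded
reference and transcript, where the DTW uses local cost |aᵢ − bⱼ| and the
classic symmetric step set {(1,0), (0,1), (1,1)}. The step pattern and cost
are validated against exhaustive path enumeration rather than taken on
authority. The **intelligibility DTW** applies the same similarity to the
transcripts of a higher- and a lower-capacity recognizer of the same
recording: unclear speech degrades the weaker model more, lowering the
score. Within the package the lower-capacity channel is emulated by
`corruptTranscript()`, which substitutes, deletes or duplicates each word
independently with a configurable error rate.

**Extra/missing word ratios** come from a minimum-edit word alignment
(match 0, indel 1, substitution = insertion + deletion, i.e. a longest
common subsequence): insertions / reference length and deletions /
reference length. The reference length as common denominator keeps the
missing ratio within [0, 1] and the two ratios comparable; the published
definition does not state a denominator.

## Counting tasks

Number words (including two-word compounds such as "forty seven" and digit
strings) are parsed to integers; all other words, including leading
chatter, are ignored. Scoring follows a **chain rule**: the first value is
correct iff it equals the task start (1 or 50), and each later value is
correct iff it equals the *previously spoken* value plus the step (+1, or
−3). Participants were instructed to keep counting after mistakes, so a
single slip costs one error rather than cascading — e.g. 50, 47, 45, 42
scores 3 correct (42 = 45 − 3 is again correct), 1 incorrect. Position-wise
comparison against the canonical sequence is available as
`rule = "canonical"`. Values beyond the nominal stopping point (below 30)
are still chain-scored, not penalized. Counts per second divides the count
of parsed values by total signal time; articulatory rate keeps its
voiced-time denominator.

## Cohort statistics

Group contrasts use the two-sided independent two-sample t-test with pooled
variance and Cohen's d on the pooled SD,

d = (m₁ − m₂) / s_p,  s_p² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁+n₂−2).

The pooled (not Welch) form is used because it is the estimator consistent
with the pooled-SD effect sizes in the published tables (t = d·√(n₁n₂/(n₁+n₂)),
a relation the test suite asserts). **No multiple-testing correction** is
applied by default, matching the exploratory-analysis policy of the source
study; Benjamini–Hochberg adjustment is available behind a flag.
Correlations are Pearson for MoCA and the UHDRS functional/motor scales and
Spearman for the five-level dysarthria score, two-sided, on
pairwise-complete observations. When subjects contribute several visits the
default analysis unit is the visit; per-subject aggregation is left to the
caller, as the repeated-visit handling of the source tables is not stated.

## LOSO random forests

Each fold holds out *all* visits of one subject (hard-asserted: zero
subject overlap between train and test). Per fold a `ranger` random forest
is fitted — 500 trees, probability output, inverse-class-frequency case
weights for balance, impurity importance, a fold-derived seed and a single
thread so runs are bit-reproducible. Missing features are imputed with the
training-fold median only. Out-of-fold predictions are pooled to compute:
weighted accuracy (= overall accuracy, the support-weighted mean recall),
balanced accuracy (unweighted mean recall), per-class recall, the
macro-averaged one-vs-rest AUC (the published AUC's averaging scheme is
unstated; macro OvR on pooled probabilities was chosen and documented), a
confusion matrix, and fold-averaged normalized importances. Regressors
report MSE, MAE and explained variance 1 − var(residual)/var(target) on the
pooled out-of-fold predictions. Forest hyper-parameters beyond tree count
stay at `ranger` defaults; with 36 subjects, tuning would mostly fit noise.

Model feature sets default to the features with at least one contrast
p < 0.05 in the cohort under analysis, mirroring the "significant features"
selection of the source study as closely as its description allows.

## The synthetic cohort generator

The generator's defaults *are* the study conditions: 18/7/11 subjects, one
visit each, and the published per-group mean ± SD of all 14 passage
features. Three design choices deserve explanation:

* **Bound-censored normal sampling.** Ratios, times and similarity scores
  have physical bounds. Sampling truncated normals would be biased (the
  truncated moments differ from the targets) and — worse — cannot represent
  the control-group missing-word ratio at all: a lower-truncated normal
  cannot have SD three times its mean near the bound, as 0.01 ± 0.03
  requires. Draws are instead *clamped* to the bounds (censoring), which
  reproduces the point mass that real bounded features show (a perfect
  reading has exactly zero missing words; similarity can be exactly 1), and
  the underlying (μ, σ) are solved numerically so the censored distribution
  matches the target mean and SD. The solver's moment residuals are below
  1e-3 for every (feature, group) pair, which the suite checks.
* **Independent features.** The published tables carry no cross-feature
  covariance, so features are drawn independently (a covariance hook
  exists). Real speech features are substantially correlated, so synthetic
  classification metrics *bound* what the pipeline can do on data with this
  effect-size structure; they are calibration checks, not reproductions of
  the real-data AUC.
* **Latent severity.** Each subject gets a latent severity (group means 0 /
  0.05 / 1 for control / pHD / HD, SD 0.3); clinical scores are linear in
  severity with intercept and slope anchored at the published control and
  HD means (MoCA 27.9 → 23, functional 23.6 → 19.8, motor 0.7 → 41.1), plus
  Gaussian noise, rounded and clamped to their scales. The dysarthria level
  is assigned from the within-HD severity rank so that on average 5 of 18
  HD subjects score 2 and one scores 0, matching the published grouping;
  controls and pHD score 0. Group SDs of the clinical scores are
  approximate (a single homoscedastic noise term cannot match all three
  group SDs at once); the linkage is meant to give the right ordering,
  ranges and correlation sign structure, not exact second moments.

Synthetic recordings are harmonic pulse trains (1/k harmonic amplitudes,
5 ms onset/offset ramps) inside known word spans, silence elsewhere, with
the exact transcript attached — so planted pauses, F0 and word counts can
be recovered end to end and compared against ground truth.

### What the effect-size recovery checks — and a statistical subtlety

Validating the generator means recomputing the HD-vs-control Cohen's d from
generated cohorts and comparing with the d implied by the published
summaries. The naive estimate — average the per-cohort sample d over
replicates — is *biased away from zero*: sample d inflates |d| by the
Jensen effect of 1/s_pooled (the normal-theory Hedges factor is ≈ 3% at
n = 29, and censoring-induced skew adds more). `recoverCohensD()` therefore
aggregates the per-replicate group means and variances — both exactly
unbiased for any generating distribution — and computes d from those
averages, with a Monte-Carlo standard error from 20 batch means. Under the
default conditions (200 replicates) all eight targeted features recover
their published effect size within three Monte-Carlo SEs.

## Problem sizes used in the checks

The validation suite runs entirely on synthesized data at sizes chosen to
exercise the mathematics while staying light: exhaustive DTW path
enumeration on 1,000 code pairs of length ≤ 6; 1,000 random segmentations
for timing conservation; a 20-frequency × 3-gain pitch grid on 0.75 s
tones; 200 replicate cohorts for effect-size recovery; 20 label
permutations for the chance-level calibration of the LOSO classifier.
These sizes are stated here so the reported Monte-Carlo tolerances can be
interpreted; they are the package's chosen defaults, and all scale up via
function arguments.

## Known limitations

* Transcript quality is assumed: timestamps are the source of truth, and no
  energy-based voice-activity detection cross-checks them.
* The loudness scale is uncalibrated by construction; comparisons across
  recording setups reflect gain as much as speakers.
* The intelligibility channel is a simulation of recognizer degradation,
  not a second ASR; its error modes (uniform substitution/deletion/
  duplication) are simpler than real recognizer confusions.
* Independent-feature cohorts understate the redundancy of real speech
  features; regression explained-variance figures on synthetic cohorts
  depend on the latent-severity linkage and should be read as calibration,
  not as reproductions of real-data performance.
* English-only number parsing (0–99) in the counting tasks.
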