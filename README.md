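# hdspeech

Digital speech biomarkers for Huntington disease (HD).

HD dysarthria changes how people read and count aloud: pauses lengthen and
multiply, articulation slows, and intelligibility falls. `hdspeech` turns
short standardized speech tasks — reading the first paragraph of the
Rainbow Passage, counting 1→20, and counting 50→30 by threes — into
quantitative features, cohort statistics and subject-level predictions:

* **Feature extraction** from a mono WAV plus a word-level timed transcript
  (`{text, start, end}` from any ASR/forced aligner): voiced/pause timing
  (total voiced/pause/signal time, speech-to-pause ratio, pause count and
  mean length, articulatory rate), autocorrelation pitch mean/SD, Bark-band
  loudness, letter-encoded DTW similarity to the reference passage
  (`1 / (1 + DTW distance)` with codes a = 1 … z = 26, space = 0),
  dual-recognizer intelligibility, extra/missing word ratios, and
  chain-scored counting accuracy.
* **Cohort statistics**: pairwise pooled-variance t-tests with Cohen's d
  (`d = (m₁ − m₂)/s_pooled`), no multiple-testing correction by default;
  Pearson correlations with MoCA and UHDRS functional/motor, Spearman with
  the dysarthria score.
* **Prediction**: leave-one-subject-out random forests (balanced class
  weights, pooled out-of-fold metrics: per-class recall, weighted/balanced
  accuracy, macro one-vs-rest AUC, impurity importances; MSE/MAE/explained
  variance for clinical-score regression).
* **Synthetic data**: harmonic recordings with planted word spans and F0, a
  controllable transcript-corruption channel, and feature-level cohorts
  (18 HD / 7 prodromal / 11 control) whose per-group moments match the
  published summary tables — so the whole pipeline is testable without
  clinical audio.

## Worked example

Effect size from published-style group summaries (mean, SD, n per group):

```r
library(hdspeech)
cohensD(0.92, 0.51, 18, 1.91, 0.46, 11)
#> [1] -2.011892
```

A lower speech-to-pause ratio in the HD group of about two pooled standard
deviations — a large effect.

Extract features from a synthesized recording with a known transcript:

```r
words <- normalizeText(rainbowPassage())[1:10]
start <- seq(0.1, by = 0.55, length.out = 10)
rec   <- synthesizeRecording(words, start, start + 0.35, f0 = 140)
small <- corruptTranscript(rec$truth, 0.2, seed = 2)   # weak-recognizer channel
feats <- extractRecordingFeatures(rec$audio, rec$truth, small, "passage",
                                  referenceText = paste(words, collapse = " "))
str(feats[c("total_pause_time_s", "speech_to_pause_ratio", "pitch_mean_hz",
            "similarity_dtw", "intelligibility_dtw")])
#> List of 5
#>  $ total_pause_time_s   : num 1.8
#>  $ speech_to_pause_ratio: num 1.94
#>  $ pitch_mean_hz        : num 140
#>  $ similarity_dtw       : num 1
#>  $ intelligibility_dtw  : num 0.0217
```

The planted 140 Hz pitch and the 10 × 0.2 s inter-word gaps are recovered
exactly; the transcript matches the reference perfectly (similarity 1)
while the corrupted small-model transcript drags intelligibility down.

Cohort statistics and LOSO classification on a synthetic cohort drawn at
the published group sizes and feature distributions:

```r
cohort <- generateCohort(defaultCohortSpec(), seed = 7)
tab <- pairwiseGroupTable(cohort, c("speech_to_pause_ratio", "similarity_dtw"))
tab[tab$group_a == "HD" & tab$group_b == "CTR",
    c("feature", "mean_a", "mean_b", "d", "p")]
#>                 feature mean_a mean_b     d        p
#> 2 speech_to_pause_ratio  0.641  2.066 -3.72 2.61e-10
#> 5        similarity_dtw  0.407  0.901 -2.47 6.37e-07

cls <- classifyLoso(cohort, featureCatalogue("passage"), seed = 7)
round(cls$per_class_recall, 1)
#>   CTR    HD   pHD
#>  90.9 100.0  57.1
round(cls$auc, 3)
#> [1] 0.953
```

HD visits are recalled essentially perfectly while the prodromal group —
whose feature distributions sit between controls and HD — is hardest, the
ordering expected for this effect-size structure.

A thin CLI over the same functions ships in `inst/scripts/hdspeech`
(`extract`, `analyze`, `simulate` subcommands).

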