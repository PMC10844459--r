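test_that("cohort generation is deterministic under the seed", {
  c1 <- generateCohort(seed = 21)
  c2 <- generateCohort(seed = 21)
  expect_identical(c1, c2)
  c3 <- generateCohort(seed = 22)
  expect_false(identical(c1, c3))
})

test_that("the default cohort matches the study conditions", {
  coh <- generateCohort(seed = 2)
  expect_equal(unname(table(coh$group)[c("HD", "pHD", "CTR")]),
               c(18L, 7L, 11L), ignore_attr = TRUE)
  expect_true(all(coh$dysarthria[coh$group != "HD"] == 0))
  expect_true(all(coh$dysarthria %in% 0:4))
  expect_true(all(coh$moca >= 0 & coh$moca <= 30))
  # severity linkage: HD low MoCA / high motor relative to controls
  expect_lt(mean(coh$moca[coh$group == "HD"]),
            mean(coh$moca[coh$group == "CTR"]))
  expect_gt(mean(coh$uhdrs_motor[coh$group == "HD"]),
            mean(coh$uhdrs_motor[coh$group == "CTR"]))
  # physical bounds respected
  expect_true(all(coh$similarity_dtw > 0 & coh$similarity_dtw <= 1))
  expect_true(all(coh$ratio_missing_words >= 0 &
                    coh$ratio_missing_words <= 1))
  expect_true(all(coh$total_pause_time_s >= 0))
})

test_that("bound-censored sampling reproduces every target moment pair", {
  spec <- defaultCohortSpec()
  set.seed(83)
  for (g in colnames(spec@featureMean)) {
    for (f in rownames(spec@featureMean)) {
      par <- hdspeech:::.censNormParams(spec@featureMean[f, g],
                                        spec@featureSd[f, g],
                                        spec@featureLower[[f]],
                                        spec@featureUpper[[f]])
      mo <- hdspeech:::.censMoments(par[["mu"]], par[["sigma"]],
                                    spec@featureLower[[f]],
                                    spec@featureUpper[[f]])
      expect_equal(unname(mo[["mean"]]), spec@featureMean[f, g],
                   tolerance = 1e-3)
      expect_equal(unname(mo[["sd"]]), spec@featureSd[f, g],
                   tolerance = 1e-3)
    }
  }
})

test_that("replicate sample means track the published group means", {
  # generator self-consistency: HD speech-to-pause mean near 0.92
  means <- vapply(1:60, function(r)
    mean(generateCohort(seed = 400 + r)$speech_to_pause_ratio[1:18]),
    numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.92), 3 * se + 0.01)
})

test_that("equal group means give mostly small effect sizes", {
  spec <- defaultCohortSpec()
  spec@featureMean[] <- spec@featureMean[, "CTR"]
  spec@featureSd[] <- spec@featureSd[, "CTR"]
  ds <- unlist(lapply(1:30, function(r) {
    coh <- generateCohort(spec, seed = 600 + r)
    tab <- pairwiseGroupTable(coh, rownames(spec@featureMean))
    tab$d
  }))
  expect_gt(mean(abs(ds) < 0.8, na.rm = TRUE), 0.9)
})

test_that("synthesized recordings carry their planted structure", {
  rec <- synthesizeRecording(c("one", "two"), c(0.1, 0.9), c(0.7, 1.5),
                             f0 = 150, seed = 1)
  expect_s4_class(rec$audio, "AudioSignal")
  expect_gte(duration(rec$audio), 1.5)
  # planted pause and F0 recovered end to end
  seg <- segmentFromTranscript(rec$truth)
  tf <- timingFeatures(seg, 2)
  expect_equal(tf$total_pause_time_s, 0.2, tolerance = 0.01)
  ps <- pitchStats(estimatePitchTrack(rec$audio), seg)
  expect_lt(abs(ps$pitch_mean_hz - 150), 3)
  # silence in the gap, energy in the words
  x <- audioSamples(rec$audio)
  gap <- x[round(0.72 * 16000):round(0.88 * 16000)]
  expect_lt(max(abs(gap)), 1e-12)
  expect_error(synthesizeRecording(c("a", "b"), c(0, 0.3), c(0.5, 0.8)),
               "overlap")
})

test_that("zero gain gives zero loudness and no voiced frames", {
  rec <- synthesizeRecording("w", 0.05, 0.9, f0 = 150, gain = 0)
  expect_equal(loudnessSone(rec$audio), 0)
  pt <- estimatePitchTrack(rec$audio)
  expect_equal(sum(!is.na(pt@f0)), 0)
})

test_that("a canonical backward-count profile scores a perfect ratio", {
  tr <- synthesizeCountingTranscript(seq(50, 32, by = -3))
  cf <- countingFeatures(tr, "backward_50_30_by3")
  expect_equal(cf$correct_counts_ratio, 1.0)
})

test_that("the corruption channel is an identity at rate zero and total at one", {
  tr <- synthesizeCountingTranscript(1:10)
  same <- corruptTranscript(tr, 0, seed = 3)
  expect_equal(transcriptWords(same), transcriptWords(tr))
  expect_equal(sourceTag(same), "small")
  # rate 1: every token was substituted, deleted or duplicated -> no token
  # survives with both its text and exact span intact
  gone <- corruptTranscript(tr, 1, seed = 3)
  orig <- transcriptWords(tr)
  cor <- transcriptWords(gone)
  survivors <- merge(orig, cor, by = c("text", "start", "end"))
  expect_equal(nrow(survivors), 0)
  # determinism
  expect_identical(transcriptWords(corruptTranscript(tr, 0.5, seed = 11)),
                   transcriptWords(corruptTranscript(tr, 0.5, seed = 11)))
})

test_that("moment-aggregated effect-size recovery is close to the target", {
  # single-feature quick check; the full 8-feature run is in acceptance
  r <- recoverCohensD(defaultCohortSpec(), "total_pause_time_s",
                      nReplicates = 60, seed = 900)
  target <- cohensD(15.91, 6.94, 18, 6.01, 1.63, 11)
  expect_lt(abs(r$d - target), 3 * r$se)
})
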