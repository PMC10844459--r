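# Builds a small on-disk recording session (WAVs + transcript JSONs +
# clinical CSV) for pipeline tests. All content is synthesized.
writeSyntheticSession <- function(dir, subjects = c("S01", "S02", "S03"),
                                  rate = 8000, seed = 1) {
  audioDir <- file.path(dir, "audio")
  trDir <- file.path(dir, "transcripts")
  dir.create(audioDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(trDir, recursive = TRUE, showWarnings = FALSE)
  passage <- normalizeText(rainbowPassage())[1:12]

  for (i in seq_along(subjects)) {
    s <- subjects[i]
    f0 <- 120 + 25 * i
    # passage task
    dur <- 0.3
    gaps <- rep(c(0.05, 0.3), 6)[1:12]
    start <- cumsum(c(0.1, head(dur + gaps, -1)))
    rec <- synthesizeRecording(passage, start, start + dur, f0 = f0,
                               rate = rate, seed = seed + i)
    writeAudio(rec$audio, file.path(audioDir, paste0(s, "_v1_passage.wav")))
    writeTimedTranscript(rec$truth,
                         file.path(trDir, paste0(s, "_v1_passage_medium.json")))
    small <- corruptTranscript(rec$truth, 0.1 * i, seed = seed + i)
    writeTimedTranscript(small,
                         file.path(trDir, paste0(s, "_v1_passage_small.json")))
    # counting tasks
    for (task in c("counting_forward", "counting_backward")) {
      vals <- if (task == "counting_forward") 1:10 else seq(50, 38, by = -3)
      tr <- synthesizeCountingTranscript(vals, wordDur = 0.25, gap = 0.4)
      w <- transcriptWords(tr)
      recC <- synthesizeRecording(w$text, w$start, w$end, f0 = f0,
                                  rate = rate, seed = seed + 10 * i)
      writeAudio(recC$audio,
                 file.path(audioDir, sprintf("%s_v1_%s.wav", s, task)))
      writeTimedTranscript(recC$truth,
                           file.path(trDir,
                                     sprintf("%s_v1_%s_medium.json", s, task)))
    }
  }
  k <- seq_along(subjects)
  clin <- data.frame(subject_id = subjects, visit_id = "v1",
                     group = c("HD", "pHD", "CTR")[k],
                     moca = c(22, 27, 28)[k],
                     uhdrs_functional = c(19, 24, 24)[k],
                     uhdrs_motor = c(40, 2, 1)[k], dysarthria = c(1, 0, 0)[k])
  clinPath <- file.path(dir, "clinical.csv")
  writeFeatureTable(clin, clinPath)
  list(audioDir = audioDir, transcriptDir = trDir, clinicalCsv = clinPath)
}
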