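test_that("WAV loading yields a mono unit-scaled signal at the native rate", {
  # 1 s at 16 kHz
  f <- withr::local_tempfile(fileext = ".wav")
  writeAudio(AudioSignal(makeTone(150, 1.0), 16000), f)
  sig <- loadAudio(f)
  expect_s4_class(sig, "AudioSignal")
  expect_equal(length(audioSamples(sig)), 16000)
  expect_equal(sampleRate(sig), 16000)
  expect_lte(max(abs(audioSamples(sig))), 1)
})

test_that("multi-channel WAV is averaged to mono", {
  # interleave +0.5 / -0.5: channel mean must be exactly zero
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  x <- rep(c(0.5, -0.5), 100)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(x) * 2), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")       # 2 channels
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(x) * 2), con, size = 4, endian = "little")
  writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  close(con)
  sig <- loadAudio(f)
  expect_equal(length(audioSamples(sig)), 100)
  expect_true(all(abs(audioSamples(sig)) < 1e-4))
})

test_that("write-then-load round trip is exact within PCM quantization", {
  tone <- makeTone(200, 0.25, rate = 8000)
  f <- withr::local_tempfile(fileext = ".wav")
  writeAudio(AudioSignal(tone, 8000), f, bits = 16)
  back <- loadAudio(f)
  expect_equal(audioSamples(back), tone, tolerance = 1 / 32767 * 4)
  # float WAV round trip is exact to single precision
  writeAudio(AudioSignal(tone, 8000), f, bits = 32)
  back32 <- loadAudio(f)
  expect_equal(audioSamples(back32), tone, tolerance = 1e-6)
})

test_that("missing, corrupt and empty audio raise explicit errors", {
  expect_error(loadAudio(file.path(tempdir(), "nope.wav")), "not found")
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("this is not audio at all, just text padding", f)
  expect_error(loadAudio(f), "RIFF")
  expect_error(writeAudio(AudioSignal(numeric(0), 16000), f) |> loadAudio(),
               "empty")
})

test_that("transcript JSON round trip preserves normalized tokens", {
  tr <- TimedTranscript(c("The", "Rain-bow", "isn't"),
                        c(0, 0.5, 1.2), c(0.4, 1.1, 1.6),
                        sourceTag = "medium")
  # hyphen split: 4 tokens, lower-cased, apostrophe removed
  expect_equal(transcriptWords(tr)$text, c("the", "rain", "bow", "isnt"))
  f <- withr::local_tempfile(fileext = ".json")
  writeTimedTranscript(tr, f)
  back <- readTimedTranscript(f)
  expect_equal(transcriptWords(back), transcriptWords(tr))
  expect_equal(sourceTag(back), "medium")
})

test_that("single-token JSON transcript normalizes as specified", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(words = data.frame(text = "The", start = 0.0, end = 0.4)),
    f, auto_unbox = TRUE)
  tr <- readTimedTranscript(f)
  expect_equal(nWords(tr), 1L)
  expect_equal(transcriptWords(tr)$text, "the")
  expect_equal(transcriptWords(tr)$start, 0.0)
  expect_equal(transcriptWords(tr)$end, 0.4)
})

test_that("invalid transcripts are rejected with the offending index", {
  expect_error(TimedTranscript(c("a", "b"), c(1.0, 0.2), c(1.4, 0.6)),
               "out of order at token 2")
  expect_error(TimedTranscript(c("a", "b"), c(0.0, 0.3), c(0.5, 0.8)),
               "overlapping tokens at token 2")
  expect_error(TimedTranscript("a", -0.1, 0.5), "negative start")
  expect_error(TimedTranscript("a", 0.5, 0.2), "end < start")
})

test_that("token normalization is idempotent", {
  set.seed(42)
  for (i in 1:20) {
    raw <- paste(sample(c("Hello,", "world!", "re-do", "don't", "A1B2", "x"),
                        5, replace = TRUE), collapse = " ")
    once <- normalizeText(raw)
    twice <- normalizeText(paste(once, collapse = " "))
    expect_identical(once, twice)
  }
})

test_that("feature-table round trip is lossless to 12 significant digits", {
  df <- data.frame(subject_id = c("S1", "S2"), visit_id = c("v1", "v1"),
                   a = c(pi, exp(1) * 1e-7), b = c(123456.789012345, NA))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(df, f)
  back <- readFeatureTable(f)
  expect_equal(back$a, df$a, tolerance = 1e-12)
  expect_equal(back$b, df$b, tolerance = 1e-12)
  expect_identical(back$subject_id, df$subject_id)
})
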