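test_that("letter encoding maps a-z to 1-26 with 0 for spaces", {
  expect_equal(encodeLetters("abc"), c(1L, 2L, 3L))
  expect_equal(encodeLetters("a b"), c(1L, 0L, 2L))
  expect_equal(encodeLetters(""), integer(0))
  expect_equal(encodeLetters("Zed!"), c(26L, 5L, 4L))
})

test_that("dtw distance matches hand-checked values and is symmetric", {
  expect_equal(dtwDistance(c(1L, 2L, 3L), c(1L, 2L, 3L)), 0)
  expect_equal(dtwDistance(c(1L, 2L, 3L), c(1L, 2L, 4L)), 1)
  set.seed(5)
  for (i in 1:25) {
    a <- sample(0:26, sample(1:6, 1), replace = TRUE)
    b <- sample(0:26, sample(1:6, 1), replace = TRUE)
    expect_equal(dtwDistance(a, b), dtwDistance(b, a))
    expect_equal(dtwDistance(a, a), 0)
  }
  expect_error(dtwDistance(integer(0), 1L), "non-empty")
})

test_that("dtw distance equals brute-force enumeration of monotone paths", {
  set.seed(6)
  for (i in 1:150) {
    a <- sample(0:26, sample(1:6, 1), replace = TRUE)
    b <- sample(0:26, sample(1:6, 1), replace = TRUE)
    expect_equal(dtwDistance(a, b), bruteDtw(a, b))
  }
})

test_that("similarity is the reciprocal of distance plus one", {
  expect_identical(similarityDtw("abc", "abc"), 1.0)
  expect_identical(similarityDtw("abc", "abd"), 0.5)
  expect_true(is.na(similarityDtw("abc", "")))
  expect_error(similarityDtw("", "abc"), "empty")
  # 1 iff identical encodings: case and punctuation are invisible
  expect_identical(similarityDtw("Ab, c!", "ab c"), 1.0)
})

test_that("corrupting one word of a reference strictly lowers similarity", {
  ref <- paste(normalizeText(rainbowPassage())[1:20], collapse = " ")
  words <- strsplit(ref, " ")[[1]]
  words[10] <- "grmbl"
  corrupted <- paste(c(words, "extra"), collapse = " ")
  expect_lt(similarityDtw(ref, corrupted), similarityDtw(ref, ref))
})

test_that("intelligibility compares dual transcripts and needs distinct tags", {
  mk <- function(words, tag) {
    n <- length(words)
    TimedTranscript(words, seq(0, by = 0.5, length.out = n),
                    seq(0.4, by = 0.5, length.out = n), sourceTag = tag)
  }
  med <- mk(c("one", "two", "three"), "medium")
  expect_identical(intelligibilityDtw(med, mk(c("one", "two", "three"),
                                              "small")), 1.0)
  # hand-checkable pair via the brute-force oracle (short enough that path
  # enumeration is exhaustive in reasonable time)
  med2 <- mk(c("ab", "cd"), "medium")
  small2 <- mk(c("ab", "ce"), "small")
  d <- bruteDtw(encodeLetters("ab cd"), encodeLetters("ab ce"))
  expect_equal(intelligibilityDtw(med2, small2), 1 / (1 + d))
  expect_error(intelligibilityDtw(med, mk("one", "medium")), "distinct")
})

test_that("mean intelligibility decreases with the corruption error rate", {
  words <- normalizeText(rainbowPassage())[1:20]
  tr <- TimedTranscript(words, seq(0, by = 0.5, length.out = 20),
                        seq(0.4, by = 0.5, length.out = 20),
                        sourceTag = "medium")
  means <- sapply(c(0, 0.1, 0.2, 0.4), function(er)
    mean(sapply(1:60, function(r)
      intelligibilityDtw(tr, corruptTranscript(tr, er, seed = 7000 + r)))))
  expect_identical(means[1], 1.0)
  expect_true(all(diff(means) < 0))
})

test_that("word alignment counts matches, insertions and deletions", {
  al <- wordAlignment("the quick fox", "the quick fox")
  expect_equal(al[c("matches", "insertions", "deletions")],
               list(matches = 3, insertions = 0, deletions = 0))
  al2 <- wordAlignment("the quick fox", "the fox over")
  expect_equal(al2$matches, 2)
  expect_equal(al2$deletions, 1)
  expect_equal(al2$insertions, 1)
  al3 <- wordAlignment("the quick fox", "")
  expect_equal(al3$matches, 0)
  expect_equal(al3$deletions, 3)
})

test_that("word alignment equals the exhaustive subsequence oracle", {
  set.seed(11)
  vocab <- c("a", "b", "c", "d")
  for (i in 1:60) {
    ref <- sample(vocab, sample(1:6, 1), replace = TRUE)
    hyp <- sample(vocab, sample(0:6, 1), replace = TRUE)
    if (!length(hyp)) hyp <- character(0)
    al <- wordAlignment(paste(ref, collapse = " "),
                        paste(hyp, collapse = " "))
    m <- bruteLcs(ref, hyp)
    expect_equal(al$matches, m)
    expect_equal(al$deletions, length(ref) - m)
    expect_equal(al$insertions, length(hyp) - m)
  }
})

test_that("extra/missing ratios use the reference length as denominator", {
  expect_equal(extraMissingRatios(wordAlignment("a b c", "a b c")),
               list(ratio_extra_words = 0, ratio_missing_words = 0))
  r <- extraMissingRatios(wordAlignment("the quick fox", "the fox over"))
  expect_equal(r$ratio_extra_words, 1 / 3)
  expect_equal(r$ratio_missing_words, 1 / 3)
  # transcript = reference twice: every reference word matches once,
  # the second copy is all insertions
  r2 <- extraMissingRatios(wordAlignment("a b c", "a b c a b c"))
  expect_equal(r2$ratio_extra_words, 1.0)
  expect_equal(r2$ratio_missing_words, 0)
})
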