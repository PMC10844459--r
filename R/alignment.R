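# Letter-encoded DTW similarity, dual-transcript intelligibility, and
# word-level alignment ratios.

#' Encode text as letter codes
#'
#' Normalizes text ([normalizeText()]) and maps it character-wise to integer
#' codes: a = 1 ... z = 26, with 0 for the space between words. Alignment
#' over letters rather than words captures partial word errors.
#'
#' @param text character scalar or vector of words.
#' @param alphabet named integer vector mapping single characters to codes;
#'   the default is the alphabetical ordinal map.
#' @return integer vector of codes (length 0 for empty text).
#' @examples
#' encodeLetters("a b")  # 1 0 2
#' @export
encodeLetters <- function(text, alphabet = letterAlphabet()) {
  tokens <- normalizeText(text)
  # only characters in the map are encodable (digits etc. are dropped)
  keep <- setdiff(names(alphabet), " ")
  tokens <- gsub(sprintf("[^%s]", paste(keep, collapse = "")), "", tokens)
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(integer(0))
  chars <- strsplit(paste(tokens, collapse = " "), "")[[1]]
  unname(alphabet[chars])
}

#' @rdname encodeLetters
#' @export
letterAlphabet <- function() {
  setNames(c(0L, 1:26), c(" ", letters))
}

#' Dynamic time warping distance between code sequences
#'
#' Classic DTW with local cost `|a_i - b_j|`, step set
#' \{(1,0), (0,1), (1,1)\} and full-path cumulative cost. Symmetric in its
#' arguments; zero iff the sequences are identical.
#'
#' @param a,b integer code vectors (non-empty), e.g. from [encodeLetters()].
#' @return non-negative numeric distance.
#' @examples
#' dtwDistance(c(1L, 2L, 3L), c(1L, 2L, 4L))  # 1
#' @export
dtwDistance <- function(a, b) {
  if (!length(a) || !length(b)) stop("dtw_distance requires non-empty sequences")
  .dtwDistanceC(as.integer(a), as.integer(b))
}

#' Letter-DTW similarity between a reference and a transcript
#'
#' The reciprocal of the dynamic time warping distance plus one,
#' `1 / (1 + dtw)`, computed over the letter encodings of the two texts.
#' Values lie in (0, 1]; 1 indicates identical encodings and lower values
#' greater dissimilarity.
#'
#' @param reference reference text (e.g. the printed passage).
#' @param transcript transcribed reading.
#' @param alphabet letter-code map, see [encodeLetters()].
#' @return numeric in (0, 1\], or `NA` if the transcript is empty after
#'   normalization.
#' @examples
#' similarityDtw("abc", "abd")  # 0.5
#' @export
similarityDtw <- function(reference, transcript, alphabet = letterAlphabet()) {
  ref <- encodeLetters(reference, alphabet)
  if (!length(ref)) stop("reference text is empty after normalization")
  hyp <- encodeLetters(transcript, alphabet)
  if (!length(hyp)) return(NA_real_)
  1 / (1 + dtwDistance(ref, hyp))
}

#' Intelligibility from dual-model transcripts
#'
#' The letter-DTW similarity between the transcripts of the same recording
#' produced by a higher-capacity and a lower-capacity recognizer. Unclear
#' speech degrades the small model more, so less intelligible speech yields
#' a smaller value.
#'
#' @param medium,small [TimedTranscript-class] objects with distinct
#'   `sourceTag`s.
#' @return numeric in (0, 1\], or `NA` if either transcript is empty.
#' @export
intelligibilityDtw <- function(medium, small) {
  stopifnot(is(medium, "TimedTranscript"), is(small, "TimedTranscript"))
  if (identical(sourceTag(medium), sourceTag(small)))
    stop("intelligibility needs transcripts from two distinct models ",
         "(identical sourceTag '", sourceTag(medium), "')")
  a <- transcriptText(medium)
  b <- transcriptText(small)
  if (!nzchar(a) || !nzchar(b)) return(NA_real_)
  1 / (1 + dtwDistance(encodeLetters(a), encodeLetters(b)))
}

#' Word-level alignment of a transcript against a reference
#'
#' Minimum-edit alignment over whole words with match cost 0 and indel cost
#' 1; a substitution counts as one insertion plus one deletion (no separate
#' substitution class). Equivalent to a longest-common-subsequence match:
#' `matches + deletions = reference length`, `matches + insertions =
#' transcript length`.
#'
#' @param reference character vector of reference words (non-empty) or a
#'   string to be tokenized.
#' @param transcript character vector of transcript words or a string.
#' @return list with `matches`, `insertions`, `deletions`,
#'   `reference_length`.
#' @examples
#' wordAlignment("the quick fox", "the fox over")
#' @export
wordAlignment <- function(reference, transcript) {
  ref <- normalizeText(reference)
  hyp <- normalizeText(transcript)
  if (!length(ref)) stop("reference must contain at least one word")
  vocab <- unique(c(ref, hyp))
  m <- .lcsLengthC(match(ref, vocab), match(hyp, vocab))
  list(matches = m,
       insertions = length(hyp) - m,
       deletions = length(ref) - m,
       reference_length = length(ref))
}

#' Extra- and missing-word ratios
#'
#' From a word alignment: the ratio of extra words (transcript words not
#' matched to the reference) and of missing words (reference words not
#' matched), both normalized by the reference length so the missing ratio is
#' bounded by 1 and the two ratios are comparable.
#'
#' @param alignment result of [wordAlignment()].
#' @return list with `ratio_extra_words` and `ratio_missing_words`.
#' @export
extraMissingRatios <- function(alignment) {
  stopifnot(alignment$reference_length >= 1)
  list(ratio_extra_words = alignment$insertions / alignment$reference_length,
       ratio_missing_words = alignment$deletions / alignment$reference_length)
}

#' The reference reading passage
#'
#' Returns the text of the standard reading passage shipped with the package
#' (the first paragraph of the public-domain "Rainbow Passage", the
#' connected-speech elicitation text used by the reading task).
#'
#' @return single character string.
#' @export
rainbowPassage <- function() {
  path <- system.file("extdata", "rainbow_passage.txt", package = "hdspeech")
  paste(readLines(path, warn = FALSE), collapse = " ")
}
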