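# Token normalization and the external file formats: PCM WAV audio,
# timed-transcript JSON, and visit/feature CSV tables.

# Lower-case, split hyphenated forms, strip everything outside a-z0-9.
# Digits survive so spoken digit strings ("47") remain parseable; the
# letter encoder drops them later. Apostrophes are removed (not split):
# "don't" -> "dont". Idempotent.
normalizeWord <- function(word) {
  w <- tolower(word)
  w <- gsub("'", "", w, fixed = TRUE)
  parts <- strsplit(w, "-", fixed = TRUE)[[1]]
  if (!length(parts)) parts <- ""
  gsub("[^a-z0-9]", "", parts)
}

# Normalize a token vector; hyphenated tokens split into several tokens that
# share the original time span (split proportionally to character length).
.normalizeAndSplit <- function(text, start, end) {
  outText <- character(0); outStart <- numeric(0); outEnd <- numeric(0)
  for (i in seq_along(text)) {
    parts <- normalizeWord(text[i])
    k <- length(parts)
    if (k == 1L) {
      outText <- c(outText, parts)
      outStart <- c(outStart, start[i]); outEnd <- c(outEnd, end[i])
    } else {
      len <- nchar(parts); len[len == 0] <- 1L
      cuts <- start[i] + (end[i] - start[i]) * cumsum(c(0, len)) / sum(len)
      outText <- c(outText, parts)
      outStart <- c(outStart, cuts[seq_len(k)])
      outEnd <- c(outEnd, cuts[seq_len(k) + 1L])
    }
  }
  list(text = outText, start = outStart, end = outEnd)
}

#' Normalize free text to the transcript token convention
#'
#' Lower-cases, splits hyphens, removes apostrophes and any character outside
#' a-z, and drops empty tokens. Normalization is idempotent.
#'
#' @param text a character scalar (whitespace-separated words) or vector of
#'   words.
#' @return character vector of normalized tokens.
#' @examples
#' normalizeText("The rain-bow, isn't it?")
#' @export
normalizeText <- function(text) {
  tokens <- unlist(strsplit(paste(text, collapse = " "), "[[:space:]]+"))
  tokens <- unlist(lapply(tokens, normalizeWord))
  tokens[nzchar(tokens)]
}

# ---- WAV ----
# Minimal RIFF/WAVE reader and writer: PCM 8/16/24/32-bit and IEEE float32.

#' Load a WAV file as a mono AudioSignal
#'
#' Reads a RIFF/WAVE file (integer PCM 8/16/24/32-bit or IEEE float32).
#' Multi-channel audio is mixed down by averaging channels; integer samples
#' are scaled to \[-1, 1\]. The native sampling rate is preserved.
#'
#' @param path path to a WAV file.
#' @return An [AudioSignal-class].
#' @seealso [writeAudio()]
#' @export
loadAudio <- function(path) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt)) stop("corrupt WAV (no fmt chunk): ", path)
  if (is.null(data) || length(data) == 0) stop("empty audio signal: ", path)
  if (fmt$format == 65534L) fmt$format <- 1L  # WAVE_FORMAT_EXTENSIBLE, assume PCM

  x <- switch(as.character(fmt$format),
    "1" = {  # integer PCM
      bytes <- fmt$bits / 8
      n <- length(data) %/% bytes
      if (fmt$bits == 8) {
        (readBin(data, "integer", n, 1, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 24) {
        m <- matrix(as.integer(data[seq_len(n * 3)]), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        v[v >= 2^23] <- v[v >= 2^23] - 2^24
        v / 2^23
      } else {
        readBin(data, "integer", n, bytes, signed = TRUE, endian = "little") /
          2^(fmt$bits - 1)
      }
    },
    "3" = readBin(data, "double", length(data) %/% 4, 4, endian = "little"),
    stop("unsupported WAV format code: ", fmt$format)
  )
  if (!length(x)) stop("empty audio signal: ", path)
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  AudioSignal(x, fmt$rate)
}

#' Write an AudioSignal to a WAV file
#'
#' @param signal an [AudioSignal-class].
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeAudio <- function(signal, path, bits = 16) {
  stopifnot(is(signal, "AudioSignal"), bits %in% c(16, 32))
  x <- pmin(1, pmax(-1, signal@samples))
  con <- file(path, "wb")
  on.exit(close(con))
  fmtCode <- if (bits == 16) 1L else 3L
  bytes <- bits / 8
  dataSize <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmtCode, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(signal@rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal@rate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")  # block align
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- transcript JSON ----

#' Read a timed transcript from JSON
#'
#' The expected schema is an object with optional `"source_tag"` and a
#' `"words"` array of `{"text", "start", "end"}` objects (a bare array of
#' word objects is also accepted). Tokens are normalized on load and the
#' ordering/overlap invariants are validated.
#'
#' @param path path to a JSON file.
#' @param sourceTag override the transcriber tag stored in the file.
#' @return A [TimedTranscript-class].
#' @seealso [writeTimedTranscript()]
#' @export
readTimedTranscript <- function(path, sourceTag = NULL) {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(obj)) {
    words <- obj
    tag <- "unknown"
  } else {
    words <- obj$words
    tag <- if (!is.null(obj$source_tag)) obj$source_tag else "unknown"
  }
  if (!is.null(sourceTag)) tag <- sourceTag
  if (is.null(words) || !nrow(words))
    return(new("TimedTranscript", sourceTag = as.character(tag)))
  need <- c("text", "start", "end")
  if (!all(need %in% names(words)))
    stop("transcript JSON needs text/start/end fields: ", path)
  TimedTranscript(words$text, words$start, words$end, sourceTag = tag)
}

#' Write a timed transcript to JSON
#'
#' @param transcript a [TimedTranscript-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTimedTranscript <- function(transcript, path) {
  stopifnot(is(transcript, "TimedTranscript"))
  obj <- list(source_tag = transcript@sourceTag,
              words = transcriptWords(transcript))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- feature tables ----

#' Read/write visit-level feature tables
#'
#' Feature tables have one row per (subject, visit) with stable column names
#' drawn from the feature catalogue ([featureCatalogue()]), written as CSV.
#' The round trip preserves numeric values to at least 12 significant digits.
#'
#' @param x a data.frame with at least `subject_id` and `visit_id` columns.
#' @param path CSV path.
#' @return `readFeatureTable` returns a data.frame; `writeFeatureTable`
#'   returns `path` invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) {
    ifelse(is.na(v), NA, formatC(v, digits = 15, format = "g"))
  })
  write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  charCols <- c("subject_id", "visit_id", "group", "task", "sex")
  for (nm in setdiff(names(df), charCols)) {
    conv <- suppressWarnings(as.numeric(df[[nm]]))
    if (!anyNA(conv[!is.na(df[[nm]]) & nzchar(as.character(df[[nm]]))]))
      df[[nm]] <- conv
  }
  df
}

#' The fixed feature catalogue
#'
#' Column names of the features computed per task: 14 passage-reading
#' features (timing, acoustics, alignment, similarity) and the counting-task
#' scores and rates.
#'
#' @param task `"passage"`, `"counting_forward"` or `"counting_backward"`.
#' @return character vector of feature column names.
#' @export
featureCatalogue <- function(task = c("passage", "counting_forward",
                                      "counting_backward")) {
  task <- match.arg(task)
  timing <- c("total_voiced_time_s", "total_pause_time_s", "total_signal_time_s",
              "speech_to_pause_ratio", "number_of_pauses", "mean_pause_length_s",
              "articulatory_rate_wps")
  if (task == "passage") {
    c(timing, "pitch_mean_hz", "pitch_sd_hz", "loudness_sone",
      "similarity_dtw", "intelligibility_dtw",
      "ratio_extra_words", "ratio_missing_words")
  } else {
    c(timing, "pitch_mean_hz", "pitch_sd_hz", "loudness_sone",
      "correct_counts", "incorrect_counts", "correct_counts_ratio",
      "counts_per_second")
  }
}
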