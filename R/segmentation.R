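# Voiced/pause structure from word timestamps and the derived timing features.

#' Segment a recording from its timed transcript
#'
#' Word intervals become voiced intervals (abutting or overlapping words are
#' merged); inter-word gaps of at least `minPause` seconds become counted
#' pauses. Audio before the first word and after the last word is treated as
#' irrelevant and excluded from the analyzed span, so leading/trailing
#' silence never affects timing features.
#'
#' Gaps shorter than `minPause` are regarded as within-speech articulation:
#' they are excluded from the pause count and mean pause length, but their
#' duration still counts toward total pause (non-voiced) time in
#' [timingFeatures()].
#'
#' @param transcript a non-empty [TimedTranscript-class].
#' @param minPause minimum gap duration (s) counted as a pause. Default 0.10.
#' @param truncate optional cap (s): words starting after
#'   `signalStart + truncate` are dropped (task time limit); `NULL` disables.
#' @return A [Segmentation-class].
#' @examples
#' tr <- TimedTranscript(c("a", "b"), c(0, 0.7), c(0.5, 1.2))
#' segmentFromTranscript(tr, minPause = 0.1)
#' @export
segmentFromTranscript <- function(transcript, minPause = 0.10, truncate = NULL) {
  stopifnot(is(transcript, "TimedTranscript"))
  if (!length(transcript@text)) stop("no speech: transcript is empty")
  start <- transcript@start
  end <- transcript@end
  if (!is.null(truncate)) {
    keep <- start <= start[1] + truncate
    start <- start[keep]; end <- pmin(end[keep], start[1] + truncate)
  }

  # merge word intervals that abut or overlap
  voiced <- matrix(c(start[1], end[1]), ncol = 2)
  if (length(start) > 1) for (i in 2:length(start)) {
    last <- nrow(voiced)
    if (start[i] <= voiced[last, 2] + 1e-12) {
      voiced[last, 2] <- max(voiced[last, 2], end[i])
    } else {
      voiced <- rbind(voiced, c(start[i], end[i]))
    }
  }
  gapStart <- voiced[-nrow(voiced), 2]
  gapEnd <- voiced[-1, 1]
  isPause <- (gapEnd - gapStart) >= minPause
  pauses <- cbind(gapStart[isPause], gapEnd[isPause])
  if (!nrow(pauses)) pauses <- matrix(numeric(0), ncol = 2)
  colnames(voiced) <- colnames(pauses) <- c("start", "end")
  new("Segmentation", voiced = voiced, pauses = pauses,
      signalStart = unname(voiced[1, 1]),
      signalEnd = unname(voiced[nrow(voiced), 2]),
      minPause = minPause)
}

#' Timing features of a segmented recording
#'
#' Computes the voiced/pause timing features: total voiced time (sum of
#' voiced-interval durations), total signal time (last word end minus first
#' word start), total pause time (their difference, so voiced + pause =
#' signal exactly), speech-to-pause ratio (voiced / pause; reported `NA`
#' when the pause time is zero rather than infinity), number of counted
#' pauses, mean pause length (0 when there are none), and articulatory rate
#' (words per second of voiced time).
#'
#' @param seg a [Segmentation-class].
#' @param wordCount number of uttered words (>= 1).
#' @return Named list with elements `total_voiced_time_s`,
#'   `total_pause_time_s`, `total_signal_time_s`, `speech_to_pause_ratio`,
#'   `number_of_pauses`, `mean_pause_length_s`, `articulatory_rate_wps`.
#' @examples
#' tr <- TimedTranscript(c("a", "b"), c(0, 0.7), c(0.5, 1.2))
#' timingFeatures(segmentFromTranscript(tr), wordCount = 2)
#' @export
timingFeatures <- function(seg, wordCount) {
  stopifnot(is(seg, "Segmentation"), wordCount >= 1)
  voicedT <- sum(seg@voiced[, 2] - seg@voiced[, 1])
  signalT <- seg@signalEnd - seg@signalStart
  pauseT <- signalT - voicedT
  nPause <- nrow(seg@pauses)
  list(
    total_voiced_time_s = voicedT,
    total_pause_time_s = pauseT,
    total_signal_time_s = signalT,
    speech_to_pause_ratio = if (pauseT > 0) voicedT / pauseT else NA_real_,
    number_of_pauses = nPause,
    mean_pause_length_s = if (nPause) mean(seg@pauses[, 2] - seg@pauses[, 1]) else 0,
    articulatory_rate_wps = if (voicedT > 0) wordCount / voicedT else NA_real_
  )
}
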