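#' Accessors for hdspeech objects
#'
#' @param x an [AudioSignal-class], [TimedTranscript-class],
#'   [Segmentation-class] or [PitchTrack-class] object.
#' @name accessors
NULL

#' @describeIn accessors amplitude vector of an AudioSignal.
#' @export
setGeneric("audioSamples", function(x) standardGeneric("audioSamples"))

#' @describeIn accessors sampling rate (Hz).
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @describeIn accessors duration in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @describeIn accessors tokens as a data.frame with text/start/end columns.
#' @export
setGeneric("transcriptWords", function(x) standardGeneric("transcriptWords"))

#' @describeIn accessors normalized transcript text, space-joined.
#' @export
setGeneric("transcriptText", function(x) standardGeneric("transcriptText"))

#' @describeIn accessors transcriber tag of a TimedTranscript.
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))

#' @describeIn accessors number of word tokens.
#' @export
setGeneric("nWords", function(x) standardGeneric("nWords"))

#' @describeIn accessors voiced intervals of a Segmentation (matrix).
#' @export
setGeneric("voicedIntervals", function(x) standardGeneric("voicedIntervals"))

#' @describeIn accessors counted pause intervals of a Segmentation (matrix).
#' @export
setGeneric("pauseIntervals", function(x) standardGeneric("pauseIntervals"))

setMethod("audioSamples", "AudioSignal", function(x) x@samples)
setMethod("sampleRate", "AudioSignal", function(x) x@rate)
setMethod("duration", "AudioSignal", function(x) length(x@samples) / x@rate)

setMethod("transcriptWords", "TimedTranscript", function(x) {
  data.frame(text = x@text, start = x@start, end = x@end,
             stringsAsFactors = FALSE)
})
setMethod("transcriptText", "TimedTranscript", function(x) {
  paste(x@text[nzchar(x@text)], collapse = " ")
})
setMethod("sourceTag", "TimedTranscript", function(x) x@sourceTag)
setMethod("nWords", "TimedTranscript", function(x) length(x@text))
setMethod("duration", "TimedTranscript", function(x) {
  if (!length(x@text)) 0 else max(x@end) - min(x@start)
})

setMethod("voicedIntervals", "Segmentation", function(x) x@voiced)
setMethod("pauseIntervals", "Segmentation", function(x) x@pauses)
setMethod("duration", "Segmentation", function(x) x@signalEnd - x@signalStart)

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf("AudioSignal: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate,
              if (length(object@samples)) max(abs(object@samples)) else 0))
})

setMethod("show", "TimedTranscript", function(object) {
  n <- length(object@text)
  cat(sprintf("TimedTranscript [%s]: %d tokens", object@sourceTag, n))
  if (n) {
    cat(sprintf(", %.2f-%.2f s\n", min(object@start), max(object@end)))
    preview <- paste(head(object@text, 8), collapse = " ")
    if (n > 8) preview <- paste(preview, "...")
    cat("  ", preview, "\n", sep = "")
  } else cat("\n")
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d voiced, %d pause interval(s) in [%.2f, %.2f] s (min pause %.2g s)\n",
              nrow(object@voiced), nrow(object@pauses),
              object@signalStart, object@signalEnd, object@minPause))
})

setMethod("show", "PitchTrack", function(object) {
  nv <- sum(!is.na(object@f0))
  cat(sprintf("PitchTrack: %d frames, %d voiced (%.0f%%), search %g-%g Hz\n",
              length(object@f0), nv,
              if (length(object@f0)) 100 * nv / length(object@f0) else 0,
              object@fmin, object@fmax))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = ", "),
      sprintf("| %d feature(s), %d visit(s)/subject\n",
              nrow(object@featureMean), object@visitsPerSubject))
})
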