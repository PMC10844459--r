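#' @import methods
#' @importFrom stats sd cor cor.test t.test p.adjust rnorm runif qnorm pnorm dnorm optim var median complete.cases aggregate fft setNames predict
#' @importFrom utils read.csv write.csv head tail combn
#' @useDynLib hdspeech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' AudioSignal: a mono audio signal
#'
#' Container for a single-channel audio waveform. Amplitudes are dimensionless
#' and scaled to \[-1, 1\]; the sampling rate is in Hz.
#'
#' @slot samples numeric vector of amplitudes in \[-1, 1\].
#' @slot rate sampling rate in samples per second (Hz), > 0.
#'
#' @seealso [loadAudio()], [writeAudio()], [synthesizeRecording()]
#' @export
setClass("AudioSignal",
  representation(samples = "numeric", rate = "numeric"),
  prototype(samples = numeric(0), rate = 16000)
)

setValidity("AudioSignal", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioSignal
#'
#' @param samples numeric amplitude vector.
#' @param rate sampling rate in Hz.
#' @return An [AudioSignal-class] object.
#' @examples
#' sig <- AudioSignal(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), rate = 8000)
#' duration(sig)
#' @export
AudioSignal <- function(samples, rate) {
  new("AudioSignal", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' TimedTranscript: word tokens with start/end times
#'
#' An ordered sequence of word tokens, each with a start and end time in
#' seconds, as produced by any ASR or forced aligner. Token text is stored
#' normalized (lower-case, alphabetic characters and apostrophes only,
#' hyphens split). Word intervals must be non-overlapping and non-decreasing
#' in start time.
#'
#' @slot text character vector of normalized word tokens.
#' @slot start numeric vector, word start times (s), non-negative.
#' @slot end numeric vector, word end times (s), `end >= start`.
#' @slot sourceTag single string identifying the transcriber (e.g. `"medium"`,
#'   `"small"`); used by [intelligibilityDtw()].
#'
#' @seealso [readTimedTranscript()], [TimedTranscript()]
#' @export
setClass("TimedTranscript",
  representation(text = "character", start = "numeric", end = "numeric",
                 sourceTag = "character"),
  prototype(text = character(0), start = numeric(0), end = numeric(0),
            sourceTag = "unknown")
)

setValidity("TimedTranscript", function(object) {
  n <- length(object@text)
  if (length(object@start) != n || length(object@end) != n)
    return("text, start and end must have equal length")
  if (length(object@sourceTag) != 1L)
    return("sourceTag must be a single string")
  if (n == 0L) return(TRUE)
  if (any(object@start < 0))
    return(sprintf("negative start time at token %d", which(object@start < 0)[1]))
  if (any(object@end < object@start))
    return(sprintf("end < start at token %d", which(object@end < object@start)[1]))
  if (n > 1L) {
    ooo <- which(diff(object@start) < 0)
    if (length(ooo))
      return(sprintf("tokens out of order at token %d", ooo[1] + 1L))
    ovl <- which(object@start[-1] < object@end[-n] - 1e-9)
    if (length(ovl))
      return(sprintf("overlapping tokens at token %d", ovl[1] + 1L))
  }
  TRUE
})

#' Construct a TimedTranscript
#'
#' Token text is normalized on construction: lower-cased, hyphens split into
#' separate tokens, characters outside a-z and apostrophes dropped,
#' apostrophes removed. Tokens that normalize to the empty string are kept as
#' empty (they still occupy time) unless `dropEmpty = TRUE`.
#'
#' @param text character vector of word tokens.
#' @param start,end numeric vectors of token times in seconds.
#' @param sourceTag transcriber tag (single string).
#' @param dropEmpty drop tokens whose normalized text is empty.
#' @return A [TimedTranscript-class] object.
#' @examples
#' tr <- TimedTranscript(c("The", "rainbow"), c(0, 0.5), c(0.4, 1.0))
#' transcriptText(tr)
#' @export
TimedTranscript <- function(text, start, end, sourceTag = "unknown",
                            dropEmpty = FALSE) {
  stopifnot(length(text) == length(start), length(start) == length(end))
  res <- .normalizeAndSplit(as.character(text), as.numeric(start), as.numeric(end))
  if (dropEmpty && length(res$text)) {
    keep <- nzchar(res$text)
    res <- lapply(res, `[`, keep)
  }
  new("TimedTranscript", text = res$text, start = res$start, end = res$end,
      sourceTag = as.character(sourceTag))
}

#' Segmentation: voiced and pause intervals of a recording
#'
#' Derived from a timed transcript: voiced intervals are merged word spans,
#' pause intervals are inter-word gaps at least `minPause` seconds long.
#' Audio before the first word and after the last is treated as irrelevant
#' and excluded from the signal span.
#'
#' @slot voiced two-column matrix of (start, end) voiced intervals (s).
#' @slot pauses two-column matrix of (start, end) counted pause intervals (s).
#' @slot signalStart,signalEnd numeric, the analyzed span (s).
#' @slot minPause pause-duration threshold used (s).
#'
#' @seealso [segmentFromTranscript()], [timingFeatures()]
#' @export
setClass("Segmentation",
  representation(voiced = "matrix", pauses = "matrix",
                 signalStart = "numeric", signalEnd = "numeric",
                 minPause = "numeric")
)

setValidity("Segmentation", function(object) {
  for (nm in c("voiced", "pauses")) {
    m <- slot(object, nm)
    if (ncol(m) != 2L) return(sprintf("%s must have two columns", nm))
    if (nrow(m) && any(m[, 2] < m[, 1])) return(sprintf("%s has negative-length interval", nm))
    if (nrow(m) && (any(m < object@signalStart - 1e-9) || any(m > object@signalEnd + 1e-9)))
      return(sprintf("%s outside the signal span", nm))
  }
  TRUE
})

#' PitchTrack: framewise fundamental-frequency estimates
#'
#' @slot time frame-center times (s).
#' @slot f0 estimated F0 per frame (Hz); `NA` marks unvoiced frames.
#' @slot fmin,fmax F0 search bounds (Hz).
#'
#' @seealso [estimatePitchTrack()], [pitchStats()]
#' @export
setClass("PitchTrack",
  representation(time = "numeric", f0 = "numeric",
                 fmin = "numeric", fmax = "numeric")
)

setValidity("PitchTrack", function(object) {
  if (length(object@time) != length(object@f0))
    return("time and f0 must have equal length")
  v <- object@f0[!is.na(object@f0)]
  if (length(v) && (any(v < object@fmin - 1e-9) || any(v > object@fmax + 1e-9)))
    return("voiced f0 outside [fmin, fmax]")
  TRUE
})

#' CohortSpec: parameters of a synthetic speech cohort
#'
#' Describes the per-group feature distributions (mean and SD per feature and
#' group), group sizes, visits per subject, physical feature bounds, and the
#' latent-severity linkage that generates clinical scores. The default spec
#' ([defaultCohortSpec()]) encodes group sizes 18/7/11 (HD/pHD/CTR) and the
#' published passage-reading summary statistics.
#'
#' @slot groupSizes named integer vector (subjects per group).
#' @slot visitsPerSubject integer, visits simulated per subject.
#' @slot featureMean,featureSd numeric matrices, features x groups.
#' @slot featureLower,featureUpper named numeric vectors of truncation bounds.
#' @slot severityMean named numeric, latent severity mean per group.
#' @slot severitySd single numeric, within-group severity SD.
#' @slot clinicalIntercept,clinicalSlope,clinicalNoiseSd named numeric vectors
#'   (per clinical score) defining score = intercept + slope * severity + noise.
#'
#' @seealso [defaultCohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(groupSizes = "integer", visitsPerSubject = "integer",
                 featureMean = "matrix", featureSd = "matrix",
                 featureLower = "numeric", featureUpper = "numeric",
                 severityMean = "numeric", severitySd = "numeric",
                 clinicalIntercept = "numeric", clinicalSlope = "numeric",
                 clinicalNoiseSd = "numeric")
)

setValidity("CohortSpec", function(object) {
  if (any(object@groupSizes < 2L))
    return("each group needs at least 2 subjects")
  if (!identical(dim(object@featureMean), dim(object@featureSd)))
    return("featureMean and featureSd must have identical dimensions")
  if (any(object@featureSd < 0))
    return("feature SDs must be non-negative")
  if (!all(colnames(object@featureMean) %in% names(object@groupSizes)))
    return("featureMean columns must match group names")
  if (object@visitsPerSubject < 1L)
    return("visitsPerSubject must be >= 1")
  TRUE
})
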