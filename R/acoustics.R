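# Acoustic features: autocorrelation F0 tracking, pitch statistics, and
# Bark-band loudness.

# TRUE for each time whose point falls inside any [start, end] interval
.inIntervals <- function(times, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(times)))
  sapply(times, function(t) any(t >= intervals[, 1] & t <= intervals[, 2]))
}

# slice a signal into frames: matrix frameN x nFrames
.frameSignal <- function(x, frameN, hopN) {
  nFrames <- 1L + max(0L, (length(x) - frameN) %/% hopN)
  idx <- outer(seq_len(frameN), (seq_len(nFrames) - 1L) * hopN, `+`)
  matrix(x[idx], nrow = frameN)
}

#' Estimate a fundamental-frequency track
#'
#' Framewise F0 estimation by the peak of the normalized autocorrelation
#' (normalized cross-correlation between the frame and its lagged copy)
#' within the lag range corresponding to `[fmin, fmax]`. A frame is voiced
#' when its best normalized autocorrelation exceeds `voicingThreshold` and
#' its RMS energy exceeds `energyFloor`; unvoiced frames carry `NA`.
#' The peak lag is refined by parabolic interpolation. Candidate lags pay
#' a cost proportional to their log2 lag (`octaveCost`), which breaks the
#' near-ties between the true period and its multiples that strongly
#' periodic frames produce and would otherwise cause octave-down errors.
#'
#' @param signal an [AudioSignal-class].
#' @param frame analysis frame length (s). Default 0.04.
#' @param hop hop between frame starts (s). Default 0.01.
#' @param fmin,fmax F0 search bounds (Hz). Defaults 60 and 400, standard
#'   adult speech range.
#' @param voicingThreshold minimum normalized autocorrelation for a voiced
#'   frame. Default 0.45.
#' @param energyFloor minimum frame RMS (full-scale units). Default 1e-4.
#' @param octaveCost per-octave lag penalty on the peak score. Default 0.01.
#' @return A [PitchTrack-class] with one frame per hop.
#' @export
estimatePitchTrack <- function(signal, frame = 0.04, hop = 0.01,
                               fmin = 60, fmax = 400,
                               voicingThreshold = 0.45, energyFloor = 1e-4,
                               octaveCost = 0.01) {
  stopifnot(is(signal, "AudioSignal"), fmin < fmax)
  rate <- signal@rate
  frameN <- round(frame * rate)
  hopN <- max(1L, round(hop * rate))
  if (frameN < 2 * rate / fmin)
    warning("frame shorter than two periods at fmin; low-F0 estimates unreliable")
  x <- signal@samples
  if (length(x) < frameN) stop("signal shorter than one analysis frame")

  minLag <- max(2L, floor(rate / fmax))
  maxLag <- min(frameN - 2L, ceiling(rate / fmin))
  if (maxLag <= minLag) stop("frame too short for the requested F0 range")

  frames <- .frameSignal(x, frameN, hopN)
  nFrames <- ncol(frames)
  times <- ((seq_len(nFrames) - 1L) * hopN + frameN / 2) / rate
  f0 <- rep(NA_real_, nFrames)

  nfft <- 2^ceiling(log2(2L * frameN))
  for (j in seq_len(nFrames)) {
    fr <- frames[, j]
    fr <- fr - mean(fr)
    rms <- sqrt(mean(fr^2))
    if (rms < energyFloor) next
    # raw autocorrelation via FFT, then lag-wise energy normalization
    sp <- fft(c(fr, rep(0, nfft - frameN)))
    ac <- Re(fft(sp * Conj(sp), inverse = TRUE)) / nfft
    cs <- cumsum(fr^2)
    lags <- minLag:maxLag
    e0 <- cs[frameN - lags]                 # energy of x[1..N-tau]
    e1 <- cs[frameN] - cs[lags]             # energy of x[tau+1..N]
    ncc <- ac[lags + 1L] / sqrt(pmax(e0 * e1, 1e-30))
    score <- ncc - octaveCost * log2(lags / minLag)
    k <- which.max(score)
    if (ncc[k] < voicingThreshold) next
    lag <- lags[k]
    # parabolic refinement around the peak
    if (k > 1L && k < length(lags)) {
      y1 <- ncc[k - 1L]; y2 <- ncc[k]; y3 <- ncc[k + 1L]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / den
    }
    cand <- rate / lag
    if (cand >= fmin && cand <= fmax) f0[j] <- cand
  }
  new("PitchTrack", time = times, f0 = f0, fmin = fmin, fmax = fmax)
}

#' Pitch mean and standard deviation over voiced speech
#'
#' Summarizes a pitch track over the voiced frames whose centers fall inside
#' the segmentation's voiced intervals: the mean F0 and the sample standard
#' deviation (n - 1 denominator). Fewer than two qualifying frames yields
#' `NA` for both.
#'
#' @param track a [PitchTrack-class].
#' @param seg a [Segmentation-class], or `NULL` to use all voiced frames.
#' @return list with `pitch_mean_hz` and `pitch_sd_hz`.
#' @export
pitchStats <- function(track, seg = NULL) {
  stopifnot(is(track, "PitchTrack"))
  keep <- !is.na(track@f0)
  if (!is.null(seg)) {
    stopifnot(is(seg, "Segmentation"))
    keep <- keep & .inIntervals(track@time, seg@voiced)
  }
  v <- track@f0[keep]
  if (length(v) < 2)
    return(list(pitch_mean_hz = NA_real_, pitch_sd_hz = NA_real_))
  list(pitch_mean_hz = mean(v), pitch_sd_hz = sd(v))
}

#' Traunmüller Bark transform
#'
#' Maps frequency in Hz to the critical-band rate (Bark).
#'
#' @param f frequency in Hz.
#' @return Bark value(s).
#' @export
hzToBark <- function(f) 26.81 * f / (1960 + f) - 0.53

#' Bark-band loudness of voiced speech
#'
#' Per analysis frame, the Hann-windowed magnitude spectrum is grouped into
#' the 24 critical bands of the Bark scale (Traunmüller transform); the RMS
#' of the bin magnitudes within each band is taken and the band values are
#' summed. The frame sum is compressed by the Stevens power law (exponent
#' 0.3) to a sone-like scale and averaged over frames falling inside the
#' voiced intervals. The absolute calibration is arbitrary (no sound-pressure
#' reference is available from a plain waveform), so values support relative
#' comparison only; the measure is zero for silence and strictly increasing
#' in overall gain.
#'
#' @param signal an [AudioSignal-class].
#' @param seg optional [Segmentation-class]; only frames inside voiced
#'   intervals are averaged. `NULL` averages all frames.
#' @param frame,hop framing parameters (s), as in [estimatePitchTrack()].
#' @return single numeric, mean frame loudness (sone-like units).
#' @export
loudnessSone <- function(signal, seg = NULL, frame = 0.04, hop = 0.01) {
  stopifnot(is(signal, "AudioSignal"))
  rate <- signal@rate
  frameN <- round(frame * rate)
  hopN <- max(1L, round(hop * rate))
  x <- signal@samples
  if (length(x) < frameN) stop("signal shorter than one analysis frame")
  frames <- .frameSignal(x, frameN, hopN)
  nFrames <- ncol(frames)
  times <- ((seq_len(nFrames) - 1L) * hopN + frameN / 2) / rate

  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, frameN - 1) / (frameN - 1))  # Hann
  binHz <- (seq_len(frameN %/% 2 + 1L) - 1L) * rate / frameN
  band <- floor(hzToBark(binHz)) + 1L
  inBand <- band >= 1L & band <= 24L

  frameLoud <- apply(frames, 2, function(fr) {
    mag <- Mod(fft(fr * w))[seq_along(binHz)]
    bandRms <- tapply(mag[inBand]^2, band[inBand], function(p) sqrt(mean(p)))
    sum(bandRms)^0.3
  })

  if (!is.null(seg)) {
    stopifnot(is(seg, "Segmentation"))
    keep <- .inIntervals(times, seg@voiced)
    if (!any(keep)) return(0)
    frameLoud <- frameLoud[keep]
  }
  mean(frameLoud)
}
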