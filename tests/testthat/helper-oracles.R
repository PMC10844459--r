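# Independent oracles, deliberately written as plain recursions / straight-
# line code so they share nothing with the package implementations they
# check.

# Minimum cumulative |a_i - b_j| cost over all monotone warping paths from
# (1,1) to (n,m), by exhaustive recursive path enumeration (no memoization,
# no DP table). Exponential: keep inputs short.
bruteDtw <- function(a, b) {
  n <- length(a); m <- length(b)
  walk <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == n && j == m) return(cost)
    best <- Inf
    if (i < n) best <- min(best, walk(i + 1, j))
    if (j < m) best <- min(best, walk(i, j + 1))
    if (i < n && j < m) best <- min(best, walk(i + 1, j + 1))
    cost + best
  }
  walk(1, 1)
}

# Longest common subsequence by exhaustive recursion over both sequences.
bruteLcs <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  if (a[1] == b[1]) return(1 + bruteLcs(a[-1], b[-1]))
  max(bruteLcs(a[-1], b), bruteLcs(a, b[-1]))
}

# Straight-line reimplementation of the Bark band-RMS-sum loudness of a
# single frame (no windowing helpers shared with the package).
bruteFrameLoudness <- function(frame, rate) {
  n <- length(frame)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  spec <- abs(fft(frame * hann))[1:(n %/% 2 + 1)]
  freq <- (0:(n %/% 2)) * rate / n
  bark <- 26.81 * freq / (1960 + freq) - 0.53
  bandOf <- floor(bark) + 1
  total <- 0
  for (b in 1:24) {
    sel <- bandOf == b
    if (any(sel)) total <- total + sqrt(mean(spec[sel]^2))
  }
  total^0.3
}

# A harmonic test tone as a plain numeric vector.
makeTone <- function(f0, dur, rate = 16000, gain = 0.8, nHarm = 8) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- rowSums(sapply(seq_len(nHarm), function(k) sin(2 * pi * k * f0 * t) / k))
  gain * x / max(abs(x))
}

# Random well-formed timed transcript (monotone non-overlapping spans).
randomTranscript <- function(nWords, minGap = 0, maxGap = 0.6,
                             minDur = 0.1, maxDur = 0.5) {
  durs <- runif(nWords, minDur, maxDur)
  gaps <- runif(nWords, minGap, maxGap)
  start <- cumsum(gaps) + c(0, cumsum(durs))[seq_len(nWords)]
  TimedTranscript(replicate(nWords, paste(sample(letters, 3), collapse = "")),
                  start, start + durs, sourceTag = "medium")
}
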