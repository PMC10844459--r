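# Synthetic inputs for end-to-end validation: feature-level cohorts with the
# published distributional structure, harmonic recordings with known
# voiced/pause/F0 ground truth, and an ASR-error corruption channel.

# Passage-reading feature summaries (mean, SD) per group, and group sizes
# 18/7/11, as printed in the cohort's descriptive tables. These define the
# default simulation conditions.
.passageSummaries <- function() {
  f <- c("speech_to_pause_ratio", "similarity_dtw", "articulatory_rate_wps",
         "total_pause_time_s", "total_signal_time_s", "intelligibility_dtw",
         "mean_pause_length_s", "ratio_extra_words", "ratio_missing_words",
         "pitch_sd_hz", "loudness_sone", "number_of_pauses", "pitch_mean_hz",
         "total_voiced_time_s")
  mean <- cbind(
    HD  = c(0.92, 0.37, 1.73, 15.91, 27.53, 0.32, 0.60, 0.13, 0.20,
            26.42, 79.44, 28.39, 157.84, 11.62),
    pHD = c(1.84, 0.74, 2.72, 7.01, 18.60, 0.59, 0.27, 0.03, 0.04,
            36.32, 86.78, 26.00, 166.63, 11.60),
    CTR = c(1.91, 0.92, 3.16, 6.01, 16.90, 0.72, 0.26, 0.01, 0.01,
            22.00, 86.70, 22.50, 136.00, 10.90))
  sd <- cbind(
    HD  = c(0.51, 0.24, 0.75, 6.94, 7.00, 0.19, 0.32, 0.10, 0.18,
            9.06, 7.60, 9.11, 33.82, 3.72),
    pHD = c(0.64, 0.19, 0.44, 2.43, 2.43, 0.27, 0.04, 0.02, 0.03,
            12.10, 14.70, 6.24, 24.30, 1.41),
    CTR = c(0.46, 0.14, 0.31, 1.63, 2.19, 0.19, 0.03, 0.02, 0.03,
            12.10, 10.20, 3.91, 30.20, 1.07))
  rownames(mean) <- rownames(sd) <- f
  list(mean = mean, sd = sd)
}

#' Default synthetic cohort specification
#'
#' Encodes the study conditions of the reference cohort: 18 HD, 7 prodromal
#' HD and 11 control subjects, the published per-group mean/SD of the 14
#' passage-reading features, physical truncation bounds (times and counts
#' >= 0, similarity measures in (0, 1\], missing-word ratio <= 1), and a
#' latent-severity linkage that gives HD subjects high UHDRS motor and
#' dysarthria scores and low MoCA, matching the published participant
#' characteristics.
#'
#' @param visitsPerSubject visits simulated per subject. Default 1.
#' @return A [CohortSpec-class].
#' @export
defaultCohortSpec <- function(visitsPerSubject = 1L) {
  s <- .passageSummaries()
  f <- rownames(s$mean)
  lower <- setNames(rep(0, length(f)), f)
  upper <- setNames(rep(Inf, length(f)), f)
  upper[c("similarity_dtw", "intelligibility_dtw", "ratio_missing_words")] <- 1
  # similarity measures are 1/(1 + distance), hence strictly positive
  lower[c("similarity_dtw", "intelligibility_dtw")] <- 1e-6
  # clinical scores: score = intercept + slope * severity + N(0, noise),
  # anchored at control (severity 0) and HD (severity 1) published means
  new("CohortSpec",
      groupSizes = c(HD = 18L, pHD = 7L, CTR = 11L),
      visitsPerSubject = as.integer(visitsPerSubject),
      featureMean = s$mean, featureSd = s$sd,
      featureLower = lower, featureUpper = upper,
      severityMean = c(HD = 1, pHD = 0.05, CTR = 0),
      severitySd = 0.3,
      clinicalIntercept = c(moca = 27.9, uhdrs_functional = 23.6,
                            uhdrs_motor = 0.7),
      clinicalSlope = c(moca = -4.9, uhdrs_functional = -3.8,
                        uhdrs_motor = 40.4),
      clinicalNoiseSd = c(moca = 1.5, uhdrs_functional = 1.2,
                          uhdrs_motor = 8))
}

# Bounded features are sampled as censored (bound-clamped) normals: real
# bounded speech features carry point mass at their bounds (a perfect
# reading has exactly zero missing words, similarity exactly 1), and unlike
# truncation, censoring can represent distributions whose SD exceeds the
# distance to the bound (e.g. control missing-word ratio 0.01 +/- 0.03).
# The underlying (mu, sigma) are moment-matched so the censored draw has
# the target mean/SD. Identity when bounds are > 4 SD away. Solutions are
# cached; the solve is deterministic and reused across replicate cohorts.
.censParamCache <- new.env(parent = emptyenv())

# mean and sd of clamp(N(mu, sigma), lo, hi)
.censMoments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  pa <- pnorm(a); pb <- pnorm(b)
  da <- dnorm(a); db <- dnorm(b)
  loTerm <- if (is.finite(lo)) lo * pa else 0
  hiTerm <- if (is.finite(hi)) hi * (1 - pb) else 0
  m1 <- loTerm + hiTerm + mu * (pb - pa) + sigma * (da - db)
  lo2 <- if (is.finite(lo)) lo^2 * pa else 0
  hi2 <- if (is.finite(hi)) hi^2 * (1 - pb) else 0
  aTerm <- if (is.finite(a)) a * da else 0
  bTerm <- if (is.finite(b)) b * db else 0
  m2 <- lo2 + hi2 + (mu^2 + sigma^2) * (pb - pa) +
    2 * mu * sigma * (da - db) + sigma^2 * (aTerm - bTerm)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

.censNormParams <- function(m, s, lo, hi) {
  if (s == 0 || (lo <= m - 4 * s && hi >= m + 4 * s))
    return(c(mu = m, sigma = s))
  key <- paste(m, s, lo, hi, sep = "|")
  hit <- .censParamCache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mo <- .censMoments(par[1], exp(par[2]), lo, hi)
    (mo[["mean"]] - m)^2 + (mo[["sd"]] - s)^2
  }
  fit <- optim(c(m, log(s)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  if (fit$value > 1e-8)
    warning(sprintf(
      "censored-normal moment match imperfect for target %.3g +/- %.3g", m, s))
  .censParamCache[[key]] <- out
  out
}

.rcensnorm <- function(n, mu, sigma, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mu, sigma)))
}

#' Generate a synthetic visit-level cohort
#'
#' Draws per-visit features from per-group bound-censored normal
#' distributions whose moments match the spec's per-group mean/SD: draws
#' are clamped to the physical bounds, and the underlying parameters are
#' moment-corrected so the clamped distribution reproduces the target
#' summaries. Censoring (rather than truncation) both respects the bounds
#' and reproduces the point mass real bounded features show at their bounds
#' (a perfect reading has exactly zero missing words). Features are drawn
#' independently of each other. Clinical scores derive from a per-subject
#' latent severity factor: HD subjects get high motor/dysarthria and low
#' MoCA scores; the dysarthria score (0-4 scale, observed range 0-2) is
#' assigned from the within-HD severity rank so roughly 5/18 HD subjects
#' score 2 and one scores 0. With multiple visits per subject, half of each
#' feature's variance is a stable subject effect.
#'
#' @param spec a [CohortSpec-class]; default [defaultCohortSpec()].
#' @param seed integer seed; identical seed and spec give identical cohorts.
#' @return data.frame with one row per (subject, visit): `subject_id`,
#'   `visit_id`, `group`, `moca`, `uhdrs_functional`, `uhdrs_motor`,
#'   `dysarthria`, and one column per feature.
#' @export
generateCohort <- function(spec = defaultCohortSpec(), seed = 1) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(seed)
  groups <- names(spec@groupSizes)
  feats <- rownames(spec@featureMean)
  nVisits <- spec@visitsPerSubject

  # moment-corrected censoring parameters, once per (feature, group)
  parTab <- lapply(setNames(groups, groups), function(g)
    lapply(setNames(feats, feats), function(f)
      .censNormParams(spec@featureMean[f, g], spec@featureSd[f, g],
                       spec@featureLower[[f]], spec@featureUpper[[f]])))

  rows <- list()
  for (g in groups) {
    nSub <- spec@groupSizes[[g]]
    sev <- rnorm(nSub, spec@severityMean[[g]], spec@severitySd)
    # dysarthria from within-HD severity rank: lowest -> 0, top ~28% -> 2
    dys <- rep(0L, nSub)
    if (g == "HD") {
      thr0 <- qnorm(1 / 18, spec@severityMean[[g]], spec@severitySd)
      thr2 <- qnorm(1 - 5 / 18, spec@severityMean[[g]], spec@severitySd)
      dys <- ifelse(sev < thr0, 0L, ifelse(sev > thr2, 2L, 1L))
    }
    clin <- sapply(names(spec@clinicalIntercept), function(sc) {
      spec@clinicalIntercept[[sc]] + spec@clinicalSlope[[sc]] * sev +
        rnorm(nSub, 0, spec@clinicalNoiseSd[[sc]])
    })
    clin[, "moca"] <- pmin(30, pmax(0, round(clin[, "moca"])))
    clin[, "uhdrs_functional"] <- pmin(25, pmax(0, round(clin[, "uhdrs_functional"])))
    clin[, "uhdrs_motor"] <- pmin(124, pmax(0, round(clin[, "uhdrs_motor"])))

    # subject-level feature effects (half the variance when visits > 1)
    subjShare <- if (nVisits > 1L) 0.5 else 0
    for (i in seq_len(nSub)) {
      fmat <- matrix(NA_real_, nVisits, length(feats),
                     dimnames = list(NULL, feats))
      for (f in feats) {
        par <- parTab[[g]][[f]]
        subjOff <- if (subjShare > 0)
          rnorm(1, 0, par[["sigma"]] * sqrt(subjShare)) else 0
        visSigma <- par[["sigma"]] * sqrt(1 - subjShare)
        fmat[, f] <- .rcensnorm(nVisits, par[["mu"]] + subjOff, visSigma,
                                 spec@featureLower[[f]],
                                 spec@featureUpper[[f]])
      }
      for (v in seq_len(nVisits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%02d", g, i),
          visit_id = sprintf("v%d", v),
          group = g,
          moca = clin[i, "moca"],
          uhdrs_functional = clin[i, "uhdrs_functional"],
          uhdrs_motor = clin[i, "uhdrs_motor"],
          dysarthria = dys[i],
          as.list(fmat[v, ]),
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo recovery of a group effect size from replicate cohorts
#'
#' Generates `nReplicates` cohorts from `spec`, records the per-group sample
#' mean and variance of a feature in each, and recomputes Cohen's d from the
#' across-replicate averages of those moments. Because sample means and
#' sample variances are unbiased for any generating distribution, this
#' estimate converges to the population effect size implied by the spec,
#' free of the small-sample bias that inflates the plain average of
#' per-replicate d estimates. The Monte-Carlo standard error is estimated
#' by batching (20 batches).
#'
#' @param spec a [CohortSpec-class].
#' @param features character vector of feature names (all evaluated on the
#'   same replicate cohorts).
#' @param groupA,groupB group labels (d is groupA minus groupB).
#' @param nReplicates number of replicate cohorts. Default 200.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data.frame with one row per feature: `feature`, `d` (recovered
#'   effect size), `se` (Monte-Carlo SE from batch means), `nReplicates`.
#' @export
recoverCohensD <- function(spec, features, groupA = "HD", groupB = "CTR",
                           nReplicates = 200, seed = 1) {
  stopifnot(is(spec, "CohortSpec"),
            all(features %in% rownames(spec@featureMean)))
  nA <- spec@groupSizes[[groupA]]; nB <- spec@groupSizes[[groupB]]
  nf <- length(features)
  # per replicate and feature: group means and variances
  stats <- vapply(seq_len(nReplicates), function(r) {
    coh <- generateCohort(spec, seed = seed + r)
    a <- coh[coh$group == groupA, features, drop = FALSE]
    b <- coh[coh$group == groupB, features, drop = FALSE]
    rbind(vapply(a, mean, 0), vapply(a, var, 0),
          vapply(b, mean, 0), vapply(b, var, 0))
  }, matrix(0, 4, nf))
  dFrom <- function(reps, i) {
    m <- rowMeans(stats[, i, reps, drop = FALSE], dims = 2)
    sp <- sqrt(((nA - 1) * m[2] + (nB - 1) * m[4]) / (nA + nB - 2))
    (m[1] - m[3]) / sp
  }
  nBatch <- min(20L, nReplicates)
  batch <- split(seq_len(nReplicates),
                 rep(seq_len(nBatch), length.out = nReplicates))
  out <- lapply(seq_len(nf), function(i) {
    db <- vapply(batch, dFrom, numeric(1), i = i)
    data.frame(feature = features[i],
               d = dFrom(seq_len(nReplicates), i),
               se = sd(db) / sqrt(nBatch),
               nReplicates = nReplicates, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Synthesize a recording with known ground truth
#'
#' Builds a harmonic pulse train (harmonics of `f0` with 1/k amplitudes and
#' 5 ms raised-cosine onset/offset ramps) inside the given word spans and
#' silence (plus an optional noise floor) elsewhere, with the exact word
#' transcript attached. The planted F0, word spans and pause structure are
#' therefore known exactly, which makes the extraction pipeline testable
#' end to end.
#'
#' @param words character vector of word texts.
#' @param start,end numeric vectors of word spans (s), non-overlapping.
#' @param f0 fundamental frequency (Hz). Default 150.
#' @param gain peak amplitude in (0, 1\]. Default 0.8.
#' @param rate sampling rate (Hz). Default 16000.
#' @param noise noise-floor amplitude (adds white noise everywhere).
#'   Default 0.
#' @param task task label attached to the result.
#' @param sourceTag tag for the ground-truth transcript. Default "medium"
#'   (the reference transcriber).
#' @param seed optional seed for the noise floor.
#' @return list with `audio` ([AudioSignal-class]), `truth`
#'   ([TimedTranscript-class]), `true_f0`, `task`.
#' @export
synthesizeRecording <- function(words, start, end, f0 = 150, gain = 0.8,
                                rate = 16000, noise = 0, task = "passage",
                                sourceTag = "medium", seed = NULL) {
  stopifnot(length(words) == length(start), length(start) == length(end),
            all(end >= start), f0 > 0, gain >= 0)
  if (length(start) > 1 && any(start[-1] < end[-length(end)] - 1e-9))
    stop("word spans overlap")
  if (!is.null(seed)) set.seed(seed)
  total <- max(end) + 0.1
  n <- ceiling(total * rate)
  x <- if (noise > 0) rnorm(n, 0, noise) else numeric(n)
  t <- (seq_len(n) - 1) / rate
  nHarm <- max(1L, min(10L, floor(0.45 * rate / f0)))
  ramp <- 0.005
  for (i in seq_along(start)) {
    idx <- which(t >= start[i] & t < end[i])
    if (!length(idx)) next
    tt <- t[idx]
    tone <- rowSums(sapply(seq_len(nHarm), function(k)
      sin(2 * pi * k * f0 * tt) / k))
    env <- pmin(1, pmin(tt - start[i], end[i] - tt) / ramp)
    x[idx] <- x[idx] + tone * pmax(0, env)
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x * gain / peak
  truth <- TimedTranscript(words, start, end, sourceTag = sourceTag)
  list(audio = AudioSignal(x, rate), truth = truth, true_f0 = f0, task = task)
}

#' Synthesize a counting-task transcript
#'
#' Renders integer values as English number words (compounds become two
#' tokens sharing the value's span) with a fixed word duration and
#' inter-value gap. Useful as ground truth for the counting scorer.
#'
#' @param values integer vector of spoken values.
#' @param wordDur duration of each word token (s). Default 0.3.
#' @param gap silent gap between values (s). Default 0.5.
#' @param startAt start time of the first word (s). Default 0.
#' @param sourceTag transcriber tag.
#' @return A [TimedTranscript-class].
#' @export
synthesizeCountingTranscript <- function(values, wordDur = 0.3, gap = 0.5,
                                         startAt = 0, sourceTag = "medium") {
  words <- character(0); ws <- numeric(0); we <- numeric(0)
  tcur <- startAt
  for (v in values) {
    toks <- strsplit(numberToWords(v), " ")[[1]]
    for (tok in toks) {
      words <- c(words, tok); ws <- c(ws, tcur); we <- c(we, tcur + wordDur)
      tcur <- tcur + wordDur
    }
    tcur <- tcur + gap
  }
  TimedTranscript(words, ws, we, sourceTag = sourceTag)
}

#' Corrupt a transcript through a simulated ASR-error channel
#'
#' Emulates a lower-capacity recognizer: each word is independently left
#' intact with probability `1 - errorRate`, or (with equal shares of
#' `errorRate`) substituted (one letter replaced by a different random
#' letter), deleted, or duplicated. The result carries `sourceTag "small"`
#' and is deterministic under the seed. At `errorRate = 1` no word survives
#' unchanged.
#'
#' @param truth a [TimedTranscript-class].
#' @param errorRate per-word corruption probability in \[0, 1\].
#' @param seed integer seed.
#' @return A [TimedTranscript-class] tagged `"small"`.
#' @export
corruptTranscript <- function(truth, errorRate, seed = 1) {
  stopifnot(is(truth, "TimedTranscript"), errorRate >= 0, errorRate <= 1)
  set.seed(seed)
  words <- character(0); ws <- numeric(0); we <- numeric(0)
  for (i in seq_along(truth@text)) {
    w <- truth@text[i]; s <- truth@start[i]; e <- truth@end[i]
    if (runif(1) >= errorRate) {
      words <- c(words, w); ws <- c(ws, s); we <- c(we, e)
      next
    }
    op <- sample(c("substitute", "delete", "duplicate"), 1)
    if (op == "substitute") {
      chars <- strsplit(w, "")[[1]]
      if (length(chars)) {
        j <- sample.int(length(chars), 1)
        chars[j] <- sample(setdiff(letters, chars[j]), 1)
        w <- paste(chars, collapse = "")
      } else w <- sample(letters, 1)
      words <- c(words, w); ws <- c(ws, s); we <- c(we, e)
    } else if (op == "duplicate") {
      mid <- (s + e) / 2
      words <- c(words, w, w); ws <- c(ws, s, mid); we <- c(we, mid, e)
    }  # delete: drop the token
  }
  new("TimedTranscript", text = words, start = ws, end = we,
      sourceTag = "small")
}
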