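# Orchestration: per-recording feature extraction, directory-level
# extraction, and the cohort analysis bundle (tables + models).

#' Extract the full feature set for one recording
#'
#' Runs segmentation, timing, pitch, loudness and — for the passage task —
#' the reference-alignment and similarity features on one recording plus
#' its timed transcript(s). Counting tasks get the counting scores instead.
#'
#' @param audio an [AudioSignal-class], or `NULL` to skip the acoustic
#'   features (pitch and loudness are then `NA`).
#' @param medium the reference-model [TimedTranscript-class].
#' @param small optional lower-capacity-model transcript (enables
#'   intelligibility).
#' @param task `"passage"`, `"counting_forward"` or `"counting_backward"`.
#' @param referenceText reference passage text; default [rainbowPassage()].
#' @param minPause pause threshold (s). Default 0.10.
#' @param truncate optional task time cap (s); `NULL` (default) disables.
#' @param fmin,fmax pitch search bounds (Hz).
#' @return named list of features (columns of [featureCatalogue()]).
#' @export
extractRecordingFeatures <- function(audio, medium, small = NULL,
                                     task = c("passage", "counting_forward",
                                              "counting_backward"),
                                     referenceText = rainbowPassage(),
                                     minPause = 0.10, truncate = NULL,
                                     fmin = 60, fmax = 400) {
  task <- match.arg(task)
  stopifnot(is(medium, "TimedTranscript"))

  if (task == "passage") {
    seg <- segmentFromTranscript(medium, minPause = minPause,
                                 truncate = truncate)
    out <- timingFeatures(seg, wordCount = nWords(medium))
  } else {
    taskLabel <- if (task == "counting_forward") "forward_1_20" else
      "backward_50_30_by3"
    out <- countingFeatures(medium, taskLabel, minPause = minPause)
    seg <- segmentFromTranscript(medium, minPause = minPause)
  }

  acoustic <- list(pitch_mean_hz = NA_real_, pitch_sd_hz = NA_real_,
                   loudness_sone = NA_real_)
  if (!is.null(audio)) {
    stopifnot(is(audio, "AudioSignal"))
    track <- estimatePitchTrack(audio, fmin = fmin, fmax = fmax)
    acoustic[c("pitch_mean_hz", "pitch_sd_hz")] <- pitchStats(track, seg)
    acoustic$loudness_sone <- loudnessSone(audio, seg)
  }
  out <- c(out, acoustic)

  if (task == "passage") {
    out$similarity_dtw <- similarityDtw(referenceText, transcriptText(medium))
    out$intelligibility_dtw <- if (!is.null(small))
      intelligibilityDtw(medium, small) else NA_real_
    al <- wordAlignment(referenceText, transcriptText(medium))
    out <- c(out, extraMissingRatios(al))
  }
  out[featureCatalogue(task)]
}

#' Extract features for a directory of recordings
#'
#' Expects `<subject>_<visit>_<task>.wav` files in `audioDir` and matching
#' `<subject>_<visit>_<task>_medium.json` (and optionally `_small.json`)
#' transcripts in `transcriptDir`, with task one of `passage`,
#' `counting_forward`, `counting_backward`. Unreadable recordings are
#' skipped with a logged reason; the run fails only if nothing could be
#' extracted. Extraction never reads clinical labels.
#'
#' @param config list with `audioDir`, `transcriptDir`, `outDir` and
#'   optional parameters `minPause`, `truncate`, `fmin`, `fmax`,
#'   `referenceText`.
#' @return path of the written feature CSV (one row per subject, visit and
#'   task), invisibly.
#' @export
runExtract <- function(config) {
  for (key in c("audioDir", "transcriptDir", "outDir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  if (!dir.exists(config$audioDir))
    stop("audio directory does not exist: ", config$audioDir)
  wavs <- list.files(config$audioDir, pattern = "\\.wav$", full.names = TRUE)
  if (!length(wavs))
    stop("no WAV recordings found in ", config$audioDir)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  refText <- if (!is.null(config$referenceText)) config$referenceText else
    rainbowPassage()
  minPause <- if (!is.null(config$minPause)) config$minPause else 0.10

  rows <- list()
  for (wav in wavs) {
    stem <- sub("\\.wav$", "", basename(wav))
    parts <- strsplit(stem, "_")[[1]]
    task <- c("passage", "counting_forward", "counting_backward")[
      vapply(c("passage$", "counting_forward$", "counting_backward$"),
             function(p) grepl(p, stem), logical(1))][1]
    row <- tryCatch({
      if (is.na(task)) stop("cannot infer task from file name")
      subject <- parts[1]
      visit <- parts[2]
      medPath <- file.path(config$transcriptDir,
                           paste0(stem, "_medium.json"))
      smallPath <- file.path(config$transcriptDir,
                             paste0(stem, "_small.json"))
      medium <- readTimedTranscript(medPath, sourceTag = "medium")
      small <- if (file.exists(smallPath))
        readTimedTranscript(smallPath, sourceTag = "small") else NULL
      audio <- loadAudio(wav)
      feats <- extractRecordingFeatures(audio, medium, small, task,
                                        referenceText = refText,
                                        minPause = minPause,
                                        truncate = config$truncate,
                                        fmin = config$fmin %||% 60,
                                        fmax = config$fmax %||% 400)
      message("extracted: ", stem)
      data.frame(subject_id = subject, visit_id = visit, task = task,
                 as.list(unlist(feats)), stringsAsFactors = FALSE,
                 check.names = FALSE)
    }, error = function(e) {
      warning("skipped ", stem, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    rows[[length(rows) + 1L]] <- row
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("extraction failed for every recording")
  allCols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(allCols, names(r))] <- NA
    r[allCols]
  })
  out <- do.call(rbind, rows)
  path <- file.path(config$outDir, "features.csv")
  writeFeatureTable(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full cohort analysis bundle
#'
#' Runs the statistical and machine-learning layer on a visit-level feature
#' table: pairwise group contrasts, dysarthria-score contrasts,
#' clinical-score correlations, leave-one-subject-out random-forest
#' classification of group and of dysarthria score, and one regressor per
#' clinical score. Model feature sets default to the features with at least
#' one contrast p-value below `alpha` in the corresponding contrast table.
#'
#' @param visits data.frame as returned by [generateCohort()] (or built
#'   from extracted features merged with a clinical table).
#' @param features feature columns to analyze; default: every catalogue
#'   feature present in `visits`.
#' @param groups group labels. Default `c("HD", "pHD", "CTR")`.
#' @param alpha significance threshold used to pick model features.
#'   Default 0.05.
#' @param seed integer seed for the forests.
#' @param nTrees trees per forest.
#' @return list with `group_contrasts`, `dysarthria_contrasts`,
#'   `correlations`, `selected_features`, `classification_group`,
#'   `classification_dysarthria`, `regressions` (named by score), `seed`.
#' @export
analyzeCohort <- function(visits, features = NULL,
                          groups = c("HD", "pHD", "CTR"),
                          alpha = 0.05, seed = 1, nTrees = 500) {
  stopifnot(is.data.frame(visits))
  if (is.null(features))
    features <- intersect(unique(c(featureCatalogue("passage"),
                                   featureCatalogue("counting_forward"))),
                          names(visits))
  missingF <- setdiff(features, names(visits))
  if (length(missingF))
    stop("unknown feature column(s): ", paste(missingF, collapse = ", "))

  groupTab <- pairwiseGroupTable(visits, features, groups)
  sig <- unique(groupTab$feature[!is.na(groupTab$p) & groupTab$p < alpha])
  if (!length(sig)) sig <- features

  dysTab <- NULL; dysCls <- NULL
  if ("dysarthria" %in% names(visits)) {
    vd <- visits
    vd$dys_level <- as.character(vd$dysarthria)
    lv <- sort(unique(vd$dys_level), decreasing = TRUE)
    if (length(lv) >= 2) {
      dysTab <- pairwiseGroupTable(
        transform(vd, group = dys_level), features, lv)
      sigD <- unique(dysTab$feature[!is.na(dysTab$p) & dysTab$p < alpha])
      if (!length(sigD)) sigD <- features
      dysCls <- classifyLoso(vd, sigD, labelField = "dys_level",
                             nTrees = nTrees, seed = seed)
    }
  }

  scores <- intersect(c("moca", "uhdrs_functional", "uhdrs_motor",
                        "dysarthria"), names(visits))
  corrTab <- correlationTable(visits, features, scores)

  cls <- classifyLoso(visits, sig, labelField = "group",
                      nTrees = nTrees, seed = seed)
  regs <- lapply(setNames(scores, scores), function(sc)
    regressLoso(visits, sig, sc, nTrees = nTrees, seed = seed))

  list(group_contrasts = groupTab,
       dysarthria_contrasts = dysTab,
       correlations = corrTab,
       selected_features = sig,
       classification_group = cls,
       classification_dysarthria = dysCls,
       regressions = regs,
       seed = seed)
}

#' Run the analysis stage and write the report bundle
#'
#' File-level wrapper around [analyzeCohort()]: reads the extracted feature
#' CSV and the clinical CSV, merges them on (subject, visit), widens
#' per-task rows into one row per visit (counting features prefixed by
#' task), runs the analysis and writes Table-style CSVs plus JSON model
#' reports into `outDir`. Every JSON report embeds the seed and a hash of
#' the configuration.
#'
#' @param config list with `featureCsv`, `clinicalCsv`, `outDir` and
#'   optional `seed`, `nTrees`, `alpha`.
#' @return the in-memory bundle of [analyzeCohort()], invisibly.
#' @export
runAnalyze <- function(config) {
  for (key in c("featureCsv", "clinicalCsv", "outDir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  feats <- readFeatureTable(config$featureCsv)
  clin <- readFeatureTable(config$clinicalCsv)
  need <- c("subject_id", "visit_id", "group")
  missingC <- setdiff(need, names(clin))
  if (length(missingC))
    stop("clinical table is missing column(s): ",
         paste(missingC, collapse = ", "))

  wide <- NULL
  for (task in unique(feats$task)) {
    sub <- feats[feats$task == task, setdiff(names(feats), "task")]
    fcols <- setdiff(names(sub), c("subject_id", "visit_id"))
    if (task != "passage")
      names(sub)[match(fcols, names(sub))] <- paste(task, fcols, sep = "_")
    wide <- if (is.null(wide)) sub else
      merge(wide, sub, by = c("subject_id", "visit_id"), all = TRUE)
  }
  visits <- merge(clin, wide, by = c("subject_id", "visit_id"))
  if (!nrow(visits)) stop("no visits shared between feature and clinical tables")

  featCols <- setdiff(names(visits),
                      c(need, "moca", "uhdrs_functional", "uhdrs_motor",
                        "dysarthria", "sex", "age"))
  seed <- config$seed %||% 1
  bundle <- analyzeCohort(visits, features = featCols,
                          alpha = config$alpha %||% 0.05,
                          seed = seed, nTrees = config$nTrees %||% 500)

  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, force = TRUE)
  cfgHash <- unname(tools::md5sum(cfgFile))
  unlink(cfgFile)

  writeFeatureTable(bundle$group_contrasts,
                    file.path(config$outDir, "group_contrasts.csv"))
  if (!is.null(bundle$dysarthria_contrasts))
    writeFeatureTable(bundle$dysarthria_contrasts,
                      file.path(config$outDir, "dysarthria_contrasts.csv"))
  writeFeatureTable(bundle$correlations,
                    file.path(config$outDir, "correlations.csv"))

  .writeModelJson <- function(report, path, kind) {
    if (is.null(report)) return(invisible(NULL))
    obj <- list(kind = kind, seed = seed, config_hash = cfgHash)
    keep <- setdiff(names(report), c("predictions", "folds"))
    obj <- c(obj, lapply(report[keep], function(x)
      if (is.table(x)) as.data.frame.matrix(x) else x))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    writeFeatureTable(report$predictions,
                      sub("\\.json$", "_predictions.csv", path))
  }
  .writeModelJson(bundle$classification_group,
                  file.path(config$outDir, "classification_group.json"),
                  "classification")
  .writeModelJson(bundle$classification_dysarthria,
                  file.path(config$outDir, "classification_dysarthria.json"),
                  "classification")
  for (sc in names(bundle$regressions))
    .writeModelJson(bundle$regressions[[sc]],
                    file.path(config$outDir,
                              paste0("regression_", sc, ".json")),
                    "regression")
  invisible(bundle)
}
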