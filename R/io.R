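#' Write / read an EEG recording as plain text
#'
#' Interchange format: \code{<prefix>.json} (sampling rate, channel labels,
#' reference, metadata), \code{<prefix>_samples.tsv} (one column per
#' channel, one row per sample, fixed decimal precision) and
#' \code{<prefix>_events.tsv} (BIDS-style events). The round trip is
#' lossless to the written precision (`digits` decimal places, i.e. a
#' quantisation step of 10^-digits microvolts).
#'
#' @param rec an [EEGRecording-class].
#' @param prefix file path prefix (no extension).
#' @param digits decimal places for sample values (default 6).
#' @return (invisibly) the three file paths.
#' @export
writeRecording <- function(rec, prefix, digits = 6) {
  stopifnot(is(rec, "EEGRecording"))
  header <- list(samplingRate = samplingRate(rec),
                 channelLabels = channelLabels(rec),
                 reference = referenceState(rec),
                 nSamples = ncol(rec@samples),
                 meta = rec@meta)
  paths <- c(json = paste0(prefix, ".json"),
             samples = paste0(prefix, "_samples.tsv"),
             events = paste0(prefix, "_events.tsv"))
  jsonlite::write_json(header, paths["json"], auto_unbox = TRUE, digits = NA)
  m <- t(rec@samples)
  colnames(m) <- channelLabels(rec)
  utils::write.table(round(m, digits), paths["samples"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeEvents(recordingEvents(rec), paths["events"])
  invisible(paths)
}

#' @rdname writeRecording
#' @param prefix file path prefix used when writing.
#' @export
readRecording <- function(prefix) {
  jsonPath <- paste0(prefix, ".json")
  if (!file.exists(jsonPath))
    stop("missing recording header: ", jsonPath)
  header <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  sPath <- paste0(prefix, "_samples.tsv")
  if (!file.exists(sPath)) stop("missing samples file: ", sPath)
  m <- as.matrix(utils::read.table(sPath, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  events <- readEvents(paste0(prefix, "_events.tsv"))
  meta <- header$meta
  if (is.null(meta)) meta <- list()
  new("EEGRecording", samples = t(m), samplingRate = header$samplingRate,
      channelLabels = header$channelLabels, reference = header$reference,
      events = events, meta = as.list(meta))
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated events with at least \code{onset} (s); typically also
#' \code{duration}, \code{trial_type}, \code{label}. On read, unsorted
#' onsets are sorted with a warning.
#'
#' @param events data.frame.
#' @param path TSV file path.
#' @return \code{readEvents}: the events data.frame sorted by onset.
#' @export
writeEvents <- function(events, path) {
  stopifnot("onset" %in% names(events))
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("missing events file: ", path)
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"onset" %in% names(ev)) stop("events file lacks an 'onset' column")
  if (is.unsorted(ev$onset)) {
    warning("events were not sorted by onset; sorting on load")
    ev <- ev[order(ev$onset), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' Write a speech stream's events as BIDS-style TSV
#'
#' One row per word and per syllable: columns onset (s), duration (s),
#' trial_type ("word"/"syllable"), label, word_index, syllable_position.
#'
#' @param stream a [SpeechStream-class].
#' @param path TSV file path.
#' @return (invisibly) the path.
#' @export
writeStreamEvents <- function(stream, path) {
  stopifnot(is(stream, "SpeechStream"))
  d <- syllableDuration(stream)
  n <- length(tokens(stream))
  wordRows <- data.frame(onset = wordOnsets(stream), duration = 3 * d,
                         trial_type = "word", label = tokens(stream),
                         word_index = seq_len(n), syllable_position = NA)
  sylRows <- data.frame(onset = syllableOnsets(stream), duration = d,
                        trial_type = "syllable",
                        label = syllableSequence(stream),
                        word_index = rep(seq_len(n), each = 3L),
                        syllable_position = rep(1:3, times = n))
  ev <- rbind(wordRows, sylRows)
  ev <- ev[order(ev$onset, ev$trial_type == "word"), ]
  writeEvents(ev, path)
}

#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end analysis: stream build,
#' simulation, preprocessing, entrainment, surrogate and time-course
#' settings. Round-trips through JSON.
#'
#' @param lexiconVersion "A", "B" or "C".
#' @param repsPerWord,syllableDurationSec stream parameters.
#' @param nParticipants simulated participants.
#' @param band,notch,ptpThreshold preprocessing parameters.
#' @param roi ROI channel labels (NULL = montage default).
#' @param wordFreq,syllableFreq nominal target frequencies, Hz.
#' @param bundleSize,bundleStep,missingThreshold time-course parameters.
#' @param jitterRangeMs surrogate jitter range.
#' @param eegConfig base [syntheticEEGConfig()]; per-participant seeds are
#'   derived from \code{seed}.
#' @param seed master seed.
#' @param outputDir optional directory for CSV/JSON outputs.
#' @return named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(lexiconVersion = "A", repsPerWord = 100,
                      syllableDurationSec = 0.3, nParticipants = 6,
                      band = c(0.1, 20), notch = 60, ptpThreshold = 150,
                      roi = NULL, wordFreq = 1.1, syllableFreq = 3.3,
                      bundleSize = 5L, bundleStep = 1L,
                      missingThreshold = 0.5,
                      jitterRangeMs = c(-900, 900),
                      eegConfig = syntheticEEGConfig(), seed = 1L,
                      outputDir = NULL) {
  structure(list(lexiconVersion = lexiconVersion, repsPerWord = repsPerWord,
                 syllableDurationSec = syllableDurationSec,
                 nParticipants = as.integer(nParticipants), band = band,
                 notch = notch, ptpThreshold = ptpThreshold, roi = roi,
                 wordFreq = wordFreq, syllableFreq = syllableFreq,
                 bundleSize = as.integer(bundleSize),
                 bundleStep = as.integer(bundleStep),
                 missingThreshold = missingThreshold,
                 jitterRangeMs = jitterRangeMs, eegConfig = eegConfig,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "RunConfig")
}

#' Run the full analysis pipeline on simulated participants
#'
#' simulate -> filter -> re-reference -> epoch -> artifact screen -> overall
#' ITC/WLI -> surrogate comparison -> bundle time course (+ LMM slope test
#' when enough participants) -> behavioural scores. Fully reproducible from
#' the config seed; when \code{outputDir} is set, summary tables are written
#' as CSV/JSON.
#'
#' @param config a [runConfig()] list.
#' @param applyFilter set FALSE to skip band-pass/notch filtering (faster
#'   for simulation studies; the simulated signal is already in-band).
#' @return list: \code{summaries} (per-participant overall ITC/WLI, actual
#'   and surrogate), \code{surrogateTests} (paired tests at both
#'   frequencies), \code{bundleSeries}, \code{surrogateBundleSeries},
#'   \code{lmm} (WLI slope report or NULL), \code{behaviour} (scores),
#'   \code{config}.
#' @export
runPipeline <- function(config = runConfig(), applyFilter = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  lex <- buildLexicon(config$lexiconVersion)
  montage <- config$eegConfig$montage
  roi <- if (is.null(config$roi)) montage$roi else config$roi

  summaries <- list(); surrSummaries <- list()
  series <- list(); surrSeries <- list()
  for (p in seq_len(config$nParticipants)) {
    pseed <- config$seed + 7919L * p
    stream <- generateStream(lex, config$repsPerWord,
                             config$syllableDurationSec, seed = pseed)
    cfg <- config$eegConfig
    cfg$seed <- pseed
    sim <- simulateRecording(stream, cfg)
    rec <- sim$recording
    if (applyFilter) rec <- filterRecording(rec, config$band, config$notch)
    rec <- rereferenceMastoids(rec, montage$mastoids)
    ep <- epochByWords(rec)
    ep <- rejectArtifacts(ep, config$ptpThreshold, channels = roi)
    sm <- entrainmentSummary(ep, roi, config$wordFreq, config$syllableFreq)
    sm$participant <- p
    summaries[[p]] <- sm
    surr <- surrogateITC(rec, jitterRangeMs = config$jitterRangeMs,
                         seed = pseed + 1L,
                         ptpThreshold = config$ptpThreshold)
    sw <- roiAverage(extractFrequency(surr$itc, config$wordFreq), roi)
    ss <- roiAverage(extractFrequency(surr$itc, config$syllableFreq), roi)
    surrSummaries[[p]] <- data.frame(participant = p, itcWord = sw,
                                     itcSyllable = ss,
                                     wli = wordLearningIndex(sw, ss))
    bs <- bundleITCSeries(ep, roi, config$bundleSize, config$bundleStep,
                          config$wordFreq, config$syllableFreq)
    bs$participant <- p
    series[[p]] <- bs
    sEp <- epochByWords(rec,
                        onsets = sort(recordingEvents(rec)$onset +
                                      surr$jitterMs / 1000))
    sEp <- rejectArtifacts(sEp, config$ptpThreshold, channels = roi)
    sb <- bundleITCSeries(sEp, roi, config$bundleSize, config$bundleStep,
                          config$wordFreq, config$syllableFreq)
    sb$participant <- p
    surrSeries[[p]] <- sb
  }
  summaries <- do.call(rbind, summaries)
  surrSummaries <- do.call(rbind, surrSummaries)
  series <- do.call(rbind, series)
  surrSeries <- do.call(rbind, surrSeries)

  surrogateTests <- if (config$nParticipants >= 3L) list(
    word = compareActualSurrogate(summaries$itcWord, surrSummaries$itcWord),
    syllable = compareActualSurrogate(summaries$itcSyllable,
                                      surrSummaries$itcSyllable)) else NULL

  series <- excludeSparseBundles(series, config$missingThreshold)
  lmm <- if (config$nParticipants >= 5L) fitLearningLMM(series, "wli") else NULL

  behSim <- simulateBehaviour(
    behaviourSimConfig(nParticipants = config$nParticipants,
                       seed = config$seed), lex)
  behaviour <- list(rating = scoreRating(behSim$rating),
                    afc = scoreAFC(behSim$afc),
                    detection = scoreDetection(behSim$detectionTargets,
                                               behSim$detectionPresses,
                                               behSim$mode))

  out <- list(summaries = summaries, surrogateSummaries = surrSummaries,
              surrogateTests = surrogateTests, bundleSeries = series,
              surrogateBundleSeries = surrSeries, lmm = lmm,
              behaviour = behaviour, config = config)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries,
                     file.path(config$outputDir, "entrainment_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(series,
                     file.path(config$outputDir, "bundle_series.csv"),
                     row.names = FALSE)
    utils::write.csv(behaviour$detection,
                     file.path(config$outputDir, "detection_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(surrogateTests,
                         file.path(config$outputDir, "surrogate_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
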