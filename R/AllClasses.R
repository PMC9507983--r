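#' @import methods
NULL

#' Artificial-language lexicon
#'
#' Four unique trisyllabic words drawn from a 12-syllable inventory. Each
#' syllable is used in exactly one word position across the lexicon, so the
#' within-word transitional probability of the exposure stream is 1 by
#' construction while word-boundary transitions are unpredictable.
#'
#' @slot version single character, one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @slot words named list of four character vectors of length 3 (syllables).
#' @slot syllables character vector of the 12 distinct syllable labels.
#'
#' @seealso [buildLexicon()]
#' @export
setClass("Lexicon",
  representation(version = "character", words = "list", syllables = "character"))

setValidity("Lexicon", function(object) {
  msg <- character()
  if (length(object@words) != 4L)
    msg <- c(msg, "a lexicon must contain exactly 4 words")
  if (!all(lengths(object@words) == 3L))
    msg <- c(msg, "every word must have exactly 3 syllables")
  syl <- unlist(object@words, use.names = FALSE)
  if (anyDuplicated(syl))
    msg <- c(msg, "each syllable may be used in only one word position")
  if (length(object@syllables) != 12L || !setequal(object@syllables, syl))
    msg <- c(msg, "syllable inventory must list the 12 distinct syllables")
  if (length(msg)) msg else TRUE
})

#' Continuous artificial-language speech stream
#'
#' An ordered sequence of word tokens presented back-to-back at a fixed
#' syllable rate, with nominal (stimulus-grid) syllable and word onset times.
#' The stream starts at t = 0; onsets are not sample-aligned.
#'
#' @slot tokens character vector of word labels in presentation order.
#' @slot syllableSeq character vector of the syllable sequence (3 per token).
#' @slot syllableOnsets numeric, seconds from stream start.
#' @slot wordOnsets numeric, seconds from stream start.
#' @slot syllableDuration numeric scalar, seconds (0.3 in the exposure task).
#' @slot totalDuration numeric scalar, seconds.
#' @slot lexiconVersion single character.
#' @slot seed integer used to generate the ordering.
#'
#' @seealso [generateStream()], [transitionalProbabilities()]
#' @export
setClass("SpeechStream",
  representation(tokens = "character", syllableSeq = "character",
    syllableOnsets = "numeric", wordOnsets = "numeric",
    syllableDuration = "numeric", totalDuration = "numeric",
    lexiconVersion = "character", seed = "integer"))

setValidity("SpeechStream", function(object) {
  msg <- character()
  n <- length(object@tokens)
  if (n > 1L && any(object@tokens[-1L] == object@tokens[-n]))
    msg <- c(msg, "a word may not repeat twice in a row")
  if (length(object@syllableSeq) != 3L * n)
    msg <- c(msg, "syllable sequence must hold 3 syllables per token")
  d <- object@syllableDuration
  if (length(d) != 1L || d <= 0)
    msg <- c(msg, "syllableDuration must be a positive scalar")
  expect_w <- 3 * d * (seq_len(n) - 1L)
  if (n && max(abs(object@wordOnsets - expect_w)) > 1e-9)
    msg <- c(msg, "word onsets must sit on the 3 * syllableDuration grid")
  if (abs(object@totalDuration - 3 * d * n) > 1e-9)
    msg <- c(msg, "totalDuration must equal 3 * syllableDuration * n tokens")
  if (length(msg)) msg else TRUE
})

#' Target-detection speech stream
#'
#' A short stream of 16 word tokens (4 words x 4 repetitions, no immediate
#' repeats) with one designated target syllable; the listener presses a key
#' at every occurrence of the target. Child mode slows the syllable rate to
#' 350 ms; adult mode keeps the 300 ms exposure rate.
#'
#' @slot tokens character, the 16 word tokens.
#' @slot targetSyllable single character.
#' @slot targetPosition integer in 1..3, position of the target within its word.
#' @slot syllableDuration numeric scalar, seconds.
#' @slot targetOnsets numeric, onset times (s) of the 4 target occurrences.
#'
#' @seealso [generateDetectionStreams()]
#' @export
setClass("DetectionStream",
  representation(tokens = "character", targetSyllable = "character",
    targetPosition = "integer", syllableDuration = "numeric",
    targetOnsets = "numeric"))

setValidity("DetectionStream", function(object) {
  msg <- character()
  n <- length(object@tokens)
  if (n > 1L && any(object@tokens[-1L] == object@tokens[-n]))
    msg <- c(msg, "no immediate word repeats allowed")
  if (length(object@targetOnsets) != 4L)
    msg <- c(msg, "a detection stream must contain exactly 4 targets")
  if (!object@targetPosition %in% 1:3)
    msg <- c(msg, "targetPosition must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' Channels-by-samples matrix in microvolts with its sampling rate, channel
#' labels, reference state, a word-onset event table, and free-form metadata
#' (applied filters, simulation seeds).
#'
#' @slot samples numeric matrix, channels x time, microvolts.
#' @slot samplingRate numeric scalar, Hz.
#' @slot channelLabels character, unique, one per row of \code{samples}.
#' @slot reference single character, \code{"raw"} or \code{"mastoid_avg"}.
#' @slot events data.frame with at least \code{onset} (s) and \code{label},
#'   sorted by onset.
#' @slot meta list.
#'
#' @seealso [simulateRecording()], [filterRecording()], [epochByWords()]
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", samplingRate = "numeric",
    channelLabels = "character", reference = "character",
    events = "data.frame", meta = "list"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "one channel label per sample row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (!object@reference %in% c("raw", "mastoid_avg"))
    msg <- c(msg, "reference must be 'raw' or 'mastoid_avg'")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (nrow(object@events) && is.unsorted(object@events$onset))
    msg <- c(msg, "events must be sorted by onset")
  if (length(msg)) msg else TRUE
})

#' Word-locked epoch set
#'
#' Non-overlapping epochs time-locked to every 12th word onset, each holding
#' \code{wordsPerEpoch} words, stored as an epochs x channels x samples array
#' together with a per-epoch retention mask set by artifact screening.
#'
#' @slot epochs numeric array, n_epochs x channels x samples_per_epoch.
#' @slot epochOnsets numeric, epoch start times in recording seconds.
#' @slot wordsPerEpoch integer (12 in the standard analysis; 10.8 s epochs).
#' @slot retainedMask logical, length n_epochs.
#' @slot samplingRate numeric scalar, Hz.
#' @slot channelLabels character.
#'
#' @seealso [epochByWords()], [rejectArtifacts()], [computeITC()]
#' @export
setClass("EpochSet",
  representation(epochs = "array", epochOnsets = "numeric",
    wordsPerEpoch = "integer", retainedMask = "logical",
    samplingRate = "numeric", channelLabels = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "epochs must be a 3-d array (epoch x channel x sample)")
  else {
    if (length(object@retainedMask) != d[1L])
      msg <- c(msg, "retainedMask must have one entry per epoch")
    if (length(object@epochOnsets) != d[1L])
      msg <- c(msg, "epochOnsets must have one entry per epoch")
    if (length(object@channelLabels) != d[2L])
      msg <- c(msg, "one channel label per channel required")
  }
  if (length(object@epochOnsets) > 1L && is.unsorted(object@epochOnsets))
    msg <- c(msg, "epochs must be in temporal order")
  if (length(msg)) msg else TRUE
})

#' Inter-trial phase coherence spectrum
#'
#' Per-channel, per-frequency-bin resultant length of unit phasors of the
#' per-epoch FFT phase: 0 means random phase across epochs, 1 means strict
#' phase locking. Bin spacing is 1 / epoch duration (about 0.093 Hz for
#' 10.8 s epochs).
#'
#' @slot values numeric matrix, channels x bins, all in [0, 1].
#' @slot binFrequencies numeric, Hz, strictly increasing, constant spacing.
#' @slot nEpochsUsed integer, number of retained epochs entering the average.
#' @slot channelLabels character.
#'
#' @seealso [computeITC()], [extractFrequency()], [wordLearningIndex()]
#' @export
setClass("ITCSpectrum",
  representation(values = "matrix", binFrequencies = "numeric",
    nEpochsUsed = "integer", channelLabels = "character"))

setValidity("ITCSpectrum", function(object) {
  msg <- character()
  v <- object@values
  if (any(v < -1e-12 | v > 1 + 1e-12))
    msg <- c(msg, "ITC values must lie in [0, 1]")
  bf <- object@binFrequencies
  if (ncol(v) != length(bf))
    msg <- c(msg, "one bin frequency per value column required")
  if (length(bf) > 1L) {
    if (any(diff(bf) <= 0))
      msg <- c(msg, "bin frequencies must be strictly increasing")
    if (max(abs(diff(bf) - diff(bf)[1L])) > 1e-9)
      msg <- c(msg, "bin frequencies must be evenly spaced")
  }
  if (nrow(v) != length(object@channelLabels))
    msg <- c(msg, "one channel label per value row required")
  if (length(msg)) msg else TRUE
})
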