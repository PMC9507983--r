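#' Accessors for entrainSL containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an entrainSL S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tokens", function(object) standardGeneric("tokens"))
#' @rdname accessors
#' @export
setGeneric("syllableSequence", function(object) standardGeneric("syllableSequence"))
#' @rdname accessors
#' @export
setGeneric("wordOnsets", function(object) standardGeneric("wordOnsets"))
#' @rdname accessors
#' @export
setGeneric("syllableOnsets", function(object) standardGeneric("syllableOnsets"))
#' @rdname accessors
#' @export
setGeneric("syllableDuration", function(object) standardGeneric("syllableDuration"))
#' @rdname accessors
#' @export
setGeneric("lexiconWords", function(object) standardGeneric("lexiconWords"))
#' @rdname accessors
#' @export
setGeneric("syllableInventory", function(object) standardGeneric("syllableInventory"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("recordingEvents", function(object) standardGeneric("recordingEvents"))
#' @rdname accessors
#' @export
setGeneric("referenceState", function(object) standardGeneric("referenceState"))
#' @rdname accessors
#' @export
setGeneric("recordingSamples", function(object) standardGeneric("recordingSamples"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("retainedMask", function(object) standardGeneric("retainedMask"))
#' @rdname accessors
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))
#' @rdname accessors
#' @export
setGeneric("itcValues", function(object) standardGeneric("itcValues"))
#' @rdname accessors
#' @export
setGeneric("binFrequencies", function(object) standardGeneric("binFrequencies"))

#' @rdname accessors
#' @export
setMethod("tokens", "SpeechStream", function(object) object@tokens)
#' @rdname accessors
#' @export
setMethod("tokens", "DetectionStream", function(object) object@tokens)
#' @rdname accessors
#' @export
setMethod("syllableSequence", "SpeechStream", function(object) object@syllableSeq)
#' @rdname accessors
#' @export
setMethod("wordOnsets", "SpeechStream", function(object) object@wordOnsets)
#' @rdname accessors
#' @export
setMethod("syllableOnsets", "SpeechStream", function(object) object@syllableOnsets)
#' @rdname accessors
#' @export
setMethod("syllableDuration", "SpeechStream", function(object) object@syllableDuration)
#' @rdname accessors
#' @export
setMethod("syllableDuration", "DetectionStream", function(object) object@syllableDuration)
#' @rdname accessors
#' @export
setMethod("lexiconWords", "Lexicon", function(object) object@words)
#' @rdname accessors
#' @export
setMethod("syllableInventory", "Lexicon", function(object) object@syllables)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "ITCSpectrum", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("recordingEvents", "EEGRecording", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("referenceState", "EEGRecording", function(object) object@reference)
#' @rdname accessors
#' @export
setMethod("recordingSamples", "EEGRecording", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1L])
#' @rdname accessors
#' @export
setMethod("retainedMask", "EpochSet", function(object) object@retainedMask)
#' @rdname accessors
#' @export
setMethod("epochArray", "EpochSet", function(object) object@epochs)
#' @rdname accessors
#' @export
setMethod("itcValues", "ITCSpectrum", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("binFrequencies", "ITCSpectrum", function(object) object@binFrequencies)

setMethod("show", "Lexicon", function(object) {
  cat("Lexicon version", object@version, "\n")
  for (w in names(object@words))
    cat(" ", w, "=", paste(object@words[[w]], collapse = "-"), "\n")
})

setMethod("show", "SpeechStream", function(object) {
  cat("SpeechStream:", length(object@tokens), "word tokens,",
      sprintf("%.1f s total (%.0f ms/syllable), lexicon %s, seed %d\n",
              object@totalDuration, 1000 * object@syllableDuration,
              object@lexiconVersion, object@seed))
})

setMethod("show", "DetectionStream", function(object) {
  cat("DetectionStream: target", object@targetSyllable,
      sprintf("(position %d), %d tokens, %.0f ms/syllable\n",
              object@targetPosition, length(object@tokens),
              1000 * object@syllableDuration))
})

setMethod("show", "EEGRecording", function(object) {
  d <- dim(object@samples)
  cat(sprintf("EEGRecording: %d channels x %d samples (%.1f s at %g Hz), reference %s, %d events\n",
              d[1L], d[2L], d[2L] / object@samplingRate, object@samplingRate,
              object@reference, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs (%d retained) x %d channels x %d samples, %d words/epoch\n",
              d[1L], sum(object@retainedMask), d[2L], d[3L],
              object@wordsPerEpoch))
})

setMethod("show", "ITCSpectrum", function(object) {
  bf <- object@binFrequencies
  cat(sprintf("ITCSpectrum: %d channels x %d bins (%.3f-%.3f Hz, spacing %.4f Hz), %d epochs\n",
              nrow(object@values), length(bf), min(bf), max(bf),
              if (length(bf) > 1L) diff(bf)[1L] else NA_real_,
              object@nEpochsUsed))
})
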