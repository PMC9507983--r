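#' Zero-phase band-pass and notch filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass — a 2nd
#' order high-pass at the low edge cascaded with a 4th order low-pass at the
#' high edge — plus an optional 2nd order Butterworth band-stop notch.
#' Zero-phase filtering matters here because the downstream statistic is
#' phase-based: a causal filter would rotate the phase at the frequencies of
#' interest. Filter parameters are recorded in the recording metadata.
#'
#' @param rec an [EEGRecording-class].
#' @param band numeric length-2, pass band in Hz (default c(0.1, 20)).
#' @param notch notch centre frequency in Hz (default 60; \code{NULL} or 0
#'   disables), applied as a 4 Hz-wide band-stop.
#' @return the filtered [EEGRecording-class].
#' @export
filterRecording <- function(rec, band = c(0.1, 20), notch = 60) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  nyq <- fs / 2
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
      band[2L] >= nyq)
    stop("band must satisfy 0 < low < high < Nyquist")
  hp <- signal::butter(2, band[1L] / nyq, type = "high")
  lp <- signal::butter(4, band[2L] / nyq, type = "low")
  useNotch <- !is.null(notch) && notch > 0
  if (useNotch) {
    if (notch >= nyq) stop("notch frequency must be below Nyquist")
    bs <- signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")
  }
  x <- rec@samples
  for (ch in seq_len(nrow(x))) {
    y <- signal::filtfilt(hp, x[ch, ])
    y <- signal::filtfilt(lp, y)
    if (useNotch) y <- signal::filtfilt(bs, y)
    x[ch, ] <- y
  }
  rec@samples <- x
  rec@meta$filter <- list(band = band, notch = if (useNotch) notch else NA,
                          design = "butterworth zero-phase (hp2 + lp4 + stop2)")
  validObject(rec)
  rec
}

#' Re-reference to the mastoid average
#'
#' Subtracts the mean of the left and right mastoid channels from every
#' channel. Refuses to re-reference twice.
#'
#' @param rec an [EEGRecording-class] with \code{reference == "raw"}.
#' @param mastoidLabels character length-2 (default \code{c("M1", "M2")}).
#' @return the re-referenced [EEGRecording-class]
#'   (\code{reference == "mastoid_avg"}).
#' @export
rereferenceMastoids <- function(rec, mastoidLabels = c("M1", "M2")) {
  stopifnot(is(rec, "EEGRecording"))
  if (referenceState(rec) != "raw")
    stop("recording is already re-referenced")
  if (length(mastoidLabels) != 2L ||
      !all(mastoidLabels %in% channelLabels(rec)))
    stop("both mastoid channels must be present: ",
         paste(mastoidLabels, collapse = ", "))
  m <- colMeans(rec@samples[mastoidLabels, , drop = FALSE])
  rec@samples <- sweep(rec@samples, 2L, m, "-")
  rec@reference <- "mastoid_avg"
  validObject(rec)
  rec
}

#' Extract non-overlapping word-locked epochs
#'
#' Time-locks the recording to every \code{wordsPerEpoch}-th word onset and
#' cuts fixed-length epochs: epoch k starts at word onset index
#' \code{wordsPerEpoch * (k - 1) + 1} and spans
#' \code{round(wordsPerEpoch * wordDuration * fs)} samples (5530 samples for
#' 12 x 0.9 s words at 512 Hz). Onsets are mapped to the nearest sample
#' (max timing error under 1 ms); epochs running past the end of the
#' recording are dropped. With the standard 400-word stream this yields
#' floor(400 / 12) = 33 epochs of 10.8 s.
#'
#' @param rec an [EEGRecording-class].
#' @param onsets word onset times in recording seconds; defaults to the
#'   recording's word events.
#' @param wordsPerEpoch words per epoch (default 12).
#' @param wordDuration seconds per word; defaults to
#'   \code{rec@meta$syllableDuration * 3} or 0.9.
#' @return an [EpochSet-class]; zero epochs (with a warning) if fewer than
#'   \code{wordsPerEpoch} onsets are available.
#' @export
epochByWords <- function(rec, onsets = NULL, wordsPerEpoch = 12L,
                         wordDuration = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  wordsPerEpoch <- as.integer(wordsPerEpoch)
  if (is.null(onsets)) {
    ev <- recordingEvents(rec)
    onsets <- if (is.null(ev$trial_type)) ev$onset else
      ev$onset[ev$trial_type == "word"]
  }
  if (is.unsorted(onsets)) stop("word onsets must be sorted")
  if (is.null(wordDuration)) {
    d <- rec@meta$syllableDuration
    wordDuration <- if (is.null(d)) 0.9 else 3 * d
  }
  fs <- samplingRate(rec)
  nSampEpoch <- round(wordsPerEpoch * wordDuration * fs)
  nFull <- floor(length(onsets) / wordsPerEpoch)
  nTotal <- ncol(rec@samples)
  starts <- integer(0); keptOnsets <- numeric(0)
  for (k in seq_len(nFull)) {
    onset <- onsets[wordsPerEpoch * (k - 1L) + 1L]
    s0 <- round(onset * fs) + 1L              # nearest sample, 1-based
    if (s0 >= 1L && s0 + nSampEpoch - 1L <= nTotal) {
      starts <- c(starts, s0)
      keptOnsets <- c(keptOnsets, onset)
    }
  }
  nE <- length(starts)
  if (nE == 0L) {
    warning("fewer than one full epoch available; returning empty EpochSet")
    return(new("EpochSet",
               epochs = array(0, c(0L, nrow(rec@samples), nSampEpoch)),
               epochOnsets = numeric(0), wordsPerEpoch = wordsPerEpoch,
               retainedMask = logical(0), samplingRate = fs,
               channelLabels = channelLabels(rec)))
  }
  arr <- array(0, c(nE, nrow(rec@samples), nSampEpoch))
  for (k in seq_len(nE))
    arr[k, , ] <- rec@samples[, starts[k]:(starts[k] + nSampEpoch - 1L)]
  new("EpochSet", epochs = arr, epochOnsets = keptOnsets,
      wordsPerEpoch = wordsPerEpoch, retainedMask = rep(TRUE, nE),
      samplingRate = fs, channelLabels = channelLabels(rec))
}

#' Automated peak-to-peak artifact rejection
#'
#' Marks epochs whose maximum peak-to-peak amplitude across the screened
#' channels exceeds a threshold as not retained. An automated stand-in for
#' manual artifact inspection; the default 150 microvolt threshold catches
#' large extracranial artifacts while sparing typical cortical signal.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold peak-to-peak limit in microvolts (default 150).
#' @param channels labels to screen (default: all).
#' @return the [EpochSet-class] with an updated retention mask; warns if
#'   every epoch is rejected.
#' @export
rejectArtifacts <- function(epochs, threshold = 150, channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (threshold <= 0) stop("threshold must be positive")
  chIdx <- if (is.null(channels)) seq_along(channelLabels(epochs)) else {
    idx <- match(channels, channelLabels(epochs))
    if (anyNA(idx)) stop("unknown channel labels in 'channels'")
    idx
  }
  nE <- nEpochs(epochs)
  keep <- epochs@retainedMask
  for (k in seq_len(nE)) {
    seg <- epochs@epochs[k, chIdx, , drop = FALSE]
    ptp <- apply(seg[1L, , , drop = TRUE], 1L, function(v) max(v) - min(v))
    if (length(chIdx) == 1L) ptp <- max(seg) - min(seg)
    if (max(ptp) > threshold) keep[k] <- FALSE
  }
  nRej <- sum(epochs@retainedMask & !keep)
  if (nRej) message(nRej, " epoch(s) rejected at ", threshold, " uV peak-to-peak")
  if (!any(keep)) warning("all epochs rejected; retention mask is empty")
  epochs@retainedMask <- keep
  epochs
}
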