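# unit phasors of per-epoch FFT phase: retained-epoch x channel x bin array,
# restricted to bins inside freqRange. Shared by computeITC and the bundle
# time course so per-epoch FFTs are computed once.
.epochPhasors <- function(epochs, freqRange = c(0.6, 5), retainedOnly = TRUE) {
  stopifnot(is(epochs, "EpochSet"))
  keep <- if (retainedOnly) which(retainedMask(epochs)) else
    seq_len(nEpochs(epochs))
  d <- dim(epochs@epochs)
  nSamp <- d[3L]
  fs <- samplingRate(epochs)
  binF <- (seq_len(nSamp) - 1L) * fs / nSamp
  sel <- which(binF >= freqRange[1L] & binF <= freqRange[2L])
  ph <- array(complex(real = 0), c(length(keep), d[2L], length(sel)))
  for (i in seq_along(keep)) {
    for (ch in seq_len(d[2L])) {
      X <- stats::fft(epochs@epochs[keep[i], ch, ])[sel]
      ph[i, ch, ] <- exp(1i * Arg(X))
    }
  }
  list(phasors = ph, binFrequencies = binF[sel], epochIndex = keep)
}

.itcFromPhasors <- function(ph, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(dim(ph)[1L])
  m <- apply(ph[rows, , , drop = FALSE], c(2L, 3L), mean)
  Mod(m)
}

#' Inter-trial phase coherence spectrum
#'
#' For every channel and frequency bin, computes the resultant length of the
#' unit phasors of the per-epoch FFT phase over the retained epochs:
#' \deqn{ITC(f) = | (1/N) \sum_n e^{i \phi_n(f)} |.}
#' Amplitude is discarded (unit phasors), so the statistic is invariant to
#' any positive rescaling of the data and to epoch order. Raw FFT
#' coefficients are used without tapering or zero-padding; bin spacing is
#' 1 / epoch duration. Only bins inside \code{freqRange} are returned.
#'
#' @param epochs an [EpochSet-class] with at least 2 retained epochs.
#' @param freqRange numeric length-2, Hz (default c(0.6, 5)).
#' @return an [ITCSpectrum-class].
#' @export
computeITC <- function(epochs, freqRange = c(0.6, 5)) {
  stopifnot(is(epochs, "EpochSet"))
  nRet <- sum(retainedMask(epochs))
  if (nRet < 2L)
    stop("ITC requires at least 2 retained epochs (got ", nRet, ")")
  pp <- .epochPhasors(epochs, freqRange)
  vals <- .itcFromPhasors(pp$phasors)
  new("ITCSpectrum", values = vals, binFrequencies = pp$binFrequencies,
      nEpochsUsed = as.integer(nRet), channelLabels = channelLabels(epochs))
}

#' Extract per-channel ITC at a target frequency
#'
#' Selects the bin whose centre frequency is closest to the target; ties
#' resolve to the lower frequency. With 10.8 s epochs the nominal 1.1 Hz
#' word rate maps to the bin at 12/10.8 = 1.111 Hz and the nominal 3.3 Hz
#' syllable rate to 36/10.8 = 3.333 Hz; the selected bin frequency is
#' attached as attribute \code{"selectedFrequency"}.
#'
#' @param itc an [ITCSpectrum-class].
#' @param target frequency in Hz, inside the computed range.
#' @return named numeric vector (one value per channel) with attribute
#'   \code{selectedFrequency}.
#' @export
extractFrequency <- function(itc, target) {
  stopifnot(is(itc, "ITCSpectrum"))
  bf <- binFrequencies(itc)
  if (target < min(bf) || target > max(bf))
    stop(sprintf("target %.3f Hz outside computed range [%.3f, %.3f]",
                 target, min(bf), max(bf)))
  idx <- .nearestBin(bf, target)
  out <- itcValues(itc)[, idx]
  names(out) <- channelLabels(itc)
  attr(out, "selectedFrequency") <- bf[idx]
  out
}

#' Average channel values over a region of interest
#'
#' Unweighted mean over the named ROI channels (frontocentral electrodes in
#' the standard analysis, where auditory entrainment is maximal).
#'
#' @param values named numeric vector of per-channel values.
#' @param roi character vector of channel labels, nonempty subset of
#'   \code{names(values)}.
#' @return scalar mean.
#' @export
roiAverage <- function(values, roi) {
  if (!length(roi)) stop("ROI must be nonempty")
  missing <- setdiff(roi, names(values))
  if (length(missing) == length(roi))
    stop("no ROI channels found in the data")
  if (length(missing))
    stop("ROI channels absent from data: ", paste(missing, collapse = ", "))
  mean(values[roi])
}

#' Word Learning Index
#'
#' WLI = word-frequency ITC / syllable-frequency ITC. Values above the
#' no-learning baseline indicate relatively stronger phase locking at the
#' (hidden) word rate than at the (acoustically given) syllable rate.
#'
#' @param itcWord scalar word-rate ITC.
#' @param itcSyllable scalar syllable-rate ITC, must be > 0.
#' @return scalar ratio.
#' @export
wordLearningIndex <- function(itcWord, itcSyllable) {
  if (any(itcSyllable <= 0))
    stop("WLI undefined: syllable ITC must be positive")
  itcWord / itcSyllable
}

#' Surrogate ITC by word-onset jitter
#'
#' Builds the null distribution of non-entrained activity: every word onset
#' is shifted by an independently drawn integer number of milliseconds,
#' uniform over the 1801 values in the jitter range (default -900..900 ms),
#' destroying the consistent stimulus-EEG phase relation while preserving
#' the epoch's position in the exposure period. Epoching (same epoch length,
#' same words-per-epoch, same artifact threshold) and ITC are then
#' recomputed exactly as for the actual data. With a zero jitter range the
#' surrogate reproduces the actual ITC bit for bit.
#'
#' @param rec an [EEGRecording-class] (already filtered/re-referenced as for
#'   the actual analysis).
#' @param onsets actual word onsets in recording seconds; defaults to the
#'   recording's word events.
#' @param jitterRangeMs integer length-2 (default c(-900, 900)).
#' @param seed integer seed for the jitter draws.
#' @param wordsPerEpoch,wordDuration,freqRange as in [epochByWords()] /
#'   [computeITC()].
#' @param ptpThreshold peak-to-peak artifact threshold applied to the
#'   surrogate epochs; \code{NULL} disables screening.
#' @return list with \code{itc} (an [ITCSpectrum-class]), \code{jitterMs}
#'   (the drawn shifts), \code{nEpochsDropped} (jittered epochs falling
#'   outside the recording).
#' @export
surrogateITC <- function(rec, onsets = NULL, jitterRangeMs = c(-900, 900),
                         seed = 1L, wordsPerEpoch = 12L, wordDuration = NULL,
                         freqRange = c(0.6, 5), ptpThreshold = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  if (is.null(onsets)) {
    ev <- recordingEvents(rec)
    onsets <- if (is.null(ev$trial_type)) ev$onset else
      ev$onset[ev$trial_type == "word"]
  }
  set.seed(as.integer(seed))
  vals <- seq(jitterRangeMs[1L], jitterRangeMs[2L])
  jit <- if (length(vals) == 1L) rep(vals, length(onsets)) else
    sample(vals, length(onsets), replace = TRUE)
  jittered <- onsets + jit / 1000
  # epoching requires sorted onsets; epoch anchors (every 12th onset) remain
  # ordered for the +-0.9 s jitter against the 10.8 s epoch spacing, but sort
  # defensively and keep the epoch-anchor correspondence by sorting onsets.
  ord <- order(jittered)
  jittered <- jittered[ord]
  ep <- epochByWords(rec, onsets = jittered, wordsPerEpoch = wordsPerEpoch,
                     wordDuration = wordDuration)
  nExpected <- floor(length(onsets) / wordsPerEpoch)
  nDropped <- nExpected - nEpochs(ep)
  if (nDropped > 0)
    message(nDropped, " surrogate epoch(s) outside recording bounds dropped")
  if (!is.null(ptpThreshold))
    ep <- rejectArtifacts(ep, threshold = ptpThreshold)
  list(itc = computeITC(ep, freqRange), jitterMs = jit,
       nEpochsDropped = nDropped)
}

#' Paired comparison of actual and surrogate values
#'
#' Paired-samples t-test (two-sided) of per-participant actual vs surrogate
#' ITC values, with Cohen's d computed as mean difference / SD of
#' differences. Identical arrays give t = 0, p = 1; a nonzero constant
#' difference has zero variance and is returned with a degenerate-variance
#' flag rather than an infinite statistic.
#'
#' @param actual,surrogate numeric vectors of equal length (n >= 3), paired
#'   by participant.
#' @return list: \code{t}, \code{df}, \code{p}, \code{cohenD},
#'   \code{meanDifference}, \code{degenerateVariance}.
#' @export
compareActualSurrogate <- function(actual, surrogate) {
  if (length(actual) != length(surrogate))
    stop("actual and surrogate must be paired (equal length)")
  n <- length(actual)
  if (n < 3L) stop("paired comparison requires n >= 3")
  d <- actual - surrogate
  md <- mean(d)
  sdd <- stats::sd(d)
  eps <- 1e-12 * max(1, abs(md))
  if (sdd <= eps) {
    if (abs(md) <= eps)
      return(list(t = 0, df = n - 1L, p = 1, cohenD = 0, meanDifference = 0,
                  degenerateVariance = TRUE))
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, cohenD = NA_real_,
                meanDifference = md, degenerateVariance = TRUE))
  }
  tval <- md / (sdd / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1L),
       cohenD = md / sdd, meanDifference = md, degenerateVariance = FALSE)
}

#' Correlate neural entrainment with behavioural performance
#'
#' Pearson correlations between each entrainment summary column and each
#' behavioural score column, participants matched by id and dropped
#' pairwise when missing.
#'
#' @param summaries data.frame with \code{participant} and entrainment
#'   columns (e.g. wli, itcWord, itcSyllable).
#' @param scores data.frame with \code{participant} and behavioural columns
#'   (e.g. ratingScore, rtPriming, afcAccuracy).
#' @param entrainCols,behaviourCols column names to correlate; default all
#'   non-id numeric columns.
#' @return data.frame with columns \code{entrainment}, \code{behaviour},
#'   \code{n}, \code{r}, \code{df}, \code{p}.
#' @export
correlateEntrainmentBehaviour <- function(summaries, scores,
                                          entrainCols = NULL,
                                          behaviourCols = NULL) {
  stopifnot("participant" %in% names(summaries),
            "participant" %in% names(scores))
  if (is.null(entrainCols))
    entrainCols <- setdiff(names(summaries)[vapply(summaries, is.numeric,
                                                   logical(1L))],
                           "participant")
  if (is.null(behaviourCols))
    behaviourCols <- setdiff(names(scores)[vapply(scores, is.numeric,
                                                  logical(1L))],
                             "participant")
  merged <- merge(summaries, scores, by = "participant")
  out <- list()
  for (e in entrainCols) for (b in behaviourCols) {
    ok <- stats::complete.cases(merged[, c(e, b)])
    n <- sum(ok)
    if (n < 3L)
      stop("fewer than 3 complete pairs for ", e, " vs ", b)
    ct <- stats::cor.test(merged[[e]][ok], merged[[b]][ok],
                          method = "pearson")
    out[[length(out) + 1L]] <-
      data.frame(entrainment = e, behaviour = b, n = n,
                 r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Overall entrainment summary for one participant
#'
#' Convenience wrapper: ROI-averaged word-rate and syllable-rate ITC and the
#' WLI from an epoch set.
#'
#' @param epochs an [EpochSet-class].
#' @param roi channel labels to average over.
#' @param wordFreq,syllableFreq target frequencies in Hz (nominal labels;
#'   nearest bins are used and logged via attributes).
#' @param freqRange passed to [computeITC()].
#' @return data.frame row: itcWord, itcSyllable, wli, nEpochs.
#' @export
entrainmentSummary <- function(epochs, roi, wordFreq = 1.1,
                               syllableFreq = 3.3, freqRange = c(0.6, 5)) {
  itc <- computeITC(epochs, freqRange)
  w <- roiAverage(extractFrequency(itc, wordFreq), roi)
  s <- roiAverage(extractFrequency(itc, syllableFreq), roi)
  data.frame(itcWord = w, itcSyllable = s, wli = wordLearningIndex(w, s),
             nEpochs = sum(retainedMask(epochs)))
}
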