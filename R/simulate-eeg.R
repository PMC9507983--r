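#' Configuration for the synthetic EEG generator
#'
#' Parameters of the generative model behind [simulateRecording()]: a
#' syllable-rate (1/0.3 s = 3.33 Hz) and a word-rate (1/0.9 s = 1.11 Hz)
#' sinusoidal component whose per-epoch phase offsets are drawn from von
#' Mises distributions, embedded in 1/f^alpha Gaussian background noise.
#' The word-rate concentration interpolates linearly from
#' \code{kappaWordStart} to \code{kappaWordEnd} across the 12-word analysis
#' epochs, emulating growing phase alignment to the hidden word structure as
#' it is learned; syllable-rate concentration is constant (the syllable
#' rhythm is acoustically given, not learned).
#'
#' @param samplingRate Hz (default 512, the recording rate).
#' @param nChannels 32 or 64 scalp channels (mastoids added on top).
#' @param roiChannels labels carrying the entrained signal at gain 1;
#'   non-ROI scalp channels carry it at gain 0.3 (frontocentral topography).
#'   Defaults to the montage ROI.
#' @param syllableAmp,wordAmp component amplitudes, microvolts.
#' @param kappaSyllable von Mises concentration of the syllable component.
#' @param kappaWordStart,kappaWordEnd word-component concentration at the
#'   first and last epoch; values in between are linearly interpolated.
#' @param noiseSigma background noise standard deviation, microvolts.
#' @param noiseExponent spectral slope alpha of the 1/f^alpha noise.
#' @param padSeconds silent padding before/after the stream so that
#'   jittered surrogate epochs stay inside the recording.
#' @param seed integer seed; all randomness of one simulated recording
#'   funnels through it.
#' @return a named list of class \code{"SyntheticEEGConfig"}.
#' @export
syntheticEEGConfig <- function(samplingRate = 512, nChannels = 32,
                               roiChannels = NULL,
                               syllableAmp = 1.5, wordAmp = 1,
                               kappaSyllable = 8,
                               kappaWordStart = 0.5, kappaWordEnd = 4,
                               noiseSigma = 2, noiseExponent = 1,
                               padSeconds = 1, seed = 1L) {
  if (samplingRate <= 2 * 3.34)
    stop("samplingRate must exceed twice the syllable rate")
  stopifnot(kappaSyllable >= 0, kappaWordStart >= 0, kappaWordEnd >= 0,
            syllableAmp >= 0, wordAmp >= 0, noiseSigma >= 0, padSeconds >= 0)
  montage <- defaultMontage(nChannels)
  if (is.null(roiChannels)) roiChannels <- montage$roi
  if (!length(roiChannels) || !all(roiChannels %in% montage$labels))
    stop("roiChannels must be a nonempty subset of the montage labels")
  structure(list(samplingRate = samplingRate, nChannels = nChannels,
                 montage = montage, roiChannels = roiChannels,
                 syllableAmp = syllableAmp, wordAmp = wordAmp,
                 kappaSyllable = kappaSyllable,
                 kappaWordStart = kappaWordStart,
                 kappaWordEnd = kappaWordEnd,
                 noiseSigma = noiseSigma, noiseExponent = noiseExponent,
                 padSeconds = padSeconds, seed = as.integer(seed)),
            class = "SyntheticEEGConfig")
}

#' Simulate an entrained EEG recording for an exposure stream
#'
#' Generates a multichannel recording whose deterministic part is, within
#' analysis epoch n (12 words = 10.8 s at the standard rate),
#' \deqn{A_s cos(2 pi t / d + phi_{s,n}) + A_w cos(2 pi t / (3 d) + phi_{w,n})}
#' with d the syllable duration, \eqn{phi_{s,n} ~ vonMises(0, kappa_s)} and
#' \eqn{phi_{w,n} ~ vonMises(0, kappa_w(n))}, where kappa_w(n) interpolates
#' linearly across epochs. ROI channels carry the signal at gain 1, other
#' scalp channels at 0.3, mastoids at 0; every channel receives independent
#' 1/f^alpha noise. Word-onset events are written into the recording's event
#' table (shifted by the padding).
#'
#' @param stream a [SpeechStream-class].
#' @param config a [syntheticEEGConfig()] list.
#' @param channels optional subset of montage labels to simulate (e.g. just
#'   the ROI for large simulation studies); default: the whole montage.
#' @return list with elements \code{recording} ([EEGRecording-class]) and
#'   \code{groundTruth} (per-epoch kappa values, expected resultant lengths
#'   \code{vonMisesResultant(kappa)}, drawn phases, injected WLI slope sign,
#'   seed).
#' @export
simulateRecording <- function(stream, config = syntheticEEGConfig(),
                              channels = NULL) {
  stopifnot(is(stream, "SpeechStream"), inherits(config, "SyntheticEEGConfig"))
  fs <- config$samplingRate
  d <- syllableDuration(stream)
  epochDur <- 12 * 3 * d                      # 12 words x 3 syllables x d
  pad <- config$padSeconds
  totalDur <- stream@totalDuration + 2 * pad
  nSamp <- ceiling(totalDur * fs)
  nEpoch <- ceiling(stream@totalDuration / epochDur)
  set.seed(config$seed)
  kapW <- if (nEpoch == 1L || config$kappaWordStart == config$kappaWordEnd)
    rep(config$kappaWordEnd, nEpoch)
  else
    config$kappaWordStart +
      (config$kappaWordEnd - config$kappaWordStart) *
      (seq_len(nEpoch) - 1L) / (nEpoch - 1L)
  phiW <- vapply(kapW, function(k) rVonMises(1L, 0, k), numeric(1L))
  phiS <- rVonMises(nEpoch, 0, config$kappaSyllable)

  t <- (seq_len(nSamp) - 1L) / fs - pad       # stimulus time; stream at t=0
  epochIdx <- pmin(pmax(floor(t / epochDur), 0), nEpoch - 1L) + 1L
  fWord <- 1 / (3 * d)                        # word period = 3 syllables
  fSyll <- 1 / d
  sig <- config$wordAmp * cos(2 * pi * fWord * t + phiW[epochIdx]) +
         config$syllableAmp * cos(2 * pi * fSyll * t + phiS[epochIdx])
  sig[t < 0 | t >= stream@totalDuration] <- 0

  labels <- config$montage$labels
  if (!is.null(channels)) {
    if (!all(channels %in% labels))
      stop("'channels' must be a subset of the montage labels")
    labels <- channels
  }
  gain <- ifelse(labels %in% config$roiChannels, 1,
                 ifelse(labels %in% config$montage$mastoids, 0, 0.3))
  samples <- matrix(0, length(labels), nSamp, dimnames = list(labels, NULL))
  for (ch in seq_along(labels)) {
    samples[ch, ] <- gain[ch] * sig +
      pinkNoise(nSamp, config$noiseExponent, config$noiseSigma)
  }
  events <- data.frame(onset = wordOnsets(stream) + pad,
                       duration = 3 * d,
                       trial_type = "word",
                       label = tokens(stream),
                       stringsAsFactors = FALSE)
  rec <- new("EEGRecording", samples = samples, samplingRate = fs,
             channelLabels = labels, reference = "raw", events = events,
             meta = list(simulated = TRUE, seed = config$seed,
                         padSeconds = pad, syllableDuration = d))
  gt <- list(kappaWord = kapW, kappaSyllable = rep(config$kappaSyllable, nEpoch),
             expectedResultantWord = vonMisesResultant(kapW),
             expectedResultantSyllable = vonMisesResultant(config$kappaSyllable),
             phaseWord = phiW, phaseSyllable = phiS,
             wliSlopeSign = sign(config$kappaWordEnd - config$kappaWordStart),
             seed = config$seed)
  list(recording = rec, groundTruth = gt)
}

#' Configuration for the behavioural simulator
#'
#' A single learning-strength parameter L in [0, 1] drives all three tasks:
#' 2AFC accuracy is p(L) = 0.5 + 0.4 L per trial; familiarity ratings are
#' discretised Gaussians whose means separate with L (words up, nonwords
#' down, partwords in between); detection reaction times shorten by
#' \code{rtFacilitation * L} ms per predictable syllable position.
#'
#' @param nParticipants number of simulated participants.
#' @param learningStrength L in [0, 1].
#' @param ratingBase mean rating at L = 0 (1-4 scale).
#' @param ratingSeparation word-vs-nonword mean separation at L = 1.
#' @param ratingSD Gaussian SD before discretisation.
#' @param rtBaseline mean RT to word-initial targets, ms.
#' @param rtFacilitation RT reduction per position step at L = 1, ms.
#' @param rtNoiseSD RT noise SD, ms.
#' @param missRate probability a target is missed.
#' @param faRate expected false alarms per stream.
#' @param mode "child" or "adult" detection protocol (stream count, rate,
#'   response window).
#' @param seed integer seed.
#' @return a named list of class \code{"BehaviourSimConfig"}.
#' @export
behaviourSimConfig <- function(nParticipants = 24, learningStrength = 0.5,
                               ratingBase = 2.5, ratingSeparation = 1.6,
                               ratingSD = 0.8,
                               rtBaseline = 600, rtFacilitation = 120,
                               rtNoiseSD = 80, missRate = 0.15,
                               faRate = 0.5, mode = c("child", "adult"),
                               seed = 1L) {
  mode <- match.arg(mode)
  if (learningStrength < 0 || learningStrength > 1)
    stop("learningStrength must lie in [0, 1]")
  stopifnot(rtBaseline > 0, nParticipants >= 1)
  structure(list(nParticipants = as.integer(nParticipants),
                 learningStrength = learningStrength,
                 ratingBase = ratingBase,
                 ratingSeparation = ratingSeparation, ratingSD = ratingSD,
                 rtBaseline = rtBaseline, rtFacilitation = rtFacilitation,
                 rtNoiseSD = rtNoiseSD, missRate = missRate, faRate = faRate,
                 mode = mode, seed = as.integer(seed)),
            class = "BehaviourSimConfig")
}

#' Simulate behavioural task data
#'
#' Produces trial tables for the three post-exposure tasks: a 12-trial
#' familiarity rating task (4 words, 4 partwords, 4 nonwords on a 1-4
#' scale), a 16-trial two-alternative forced choice task (each word against
#' two partwords and two nonwords), and the speeded target-detection task
#' (24 streams child mode / 36 adult mode) with hits, misses,
#' position-dependent reaction times, and false alarms.
#'
#' @param config a [behaviourSimConfig()] list.
#' @param lexicon a [Lexicon-class].
#' @return list with data.frames \code{rating} (participant, item, category,
#'   rating), \code{afc} (participant, trial, word, foil, foilType, correct),
#'   \code{detectionTargets} (participant, stream, position, onset, pressTime
#'   with NA for misses) and \code{detectionPresses} (participant, stream,
#'   time: every press, hit or stray), plus \code{mode}.
#' @export
simulateBehaviour <- function(config = behaviourSimConfig(), lexicon = buildLexicon("A")) {
  stopifnot(inherits(config, "BehaviourSimConfig"), is(lexicon, "Lexicon"))
  set.seed(config$seed)
  L <- config$learningStrength
  foils <- makeFoils(lexicon, seed = config$seed)
  wordNames <- names(lexiconWords(lexicon))
  pwNames <- apply(foils$partwords, 1L, paste, collapse = "")
  nwNames <- apply(foils$nonwords, 1L, paste, collapse = "")
  half <- config$ratingSeparation / 2

  ratingMeans <- c(word = config$ratingBase + half * L,
                   partword = config$ratingBase,
                   nonword = config$ratingBase - half * L)
  nP <- config$nParticipants
  rating <- do.call(rbind, lapply(seq_len(nP), function(p) {
    items <- c(wordNames, pwNames, nwNames)
    cat <- rep(c("word", "partword", "nonword"), each = 4L)
    r <- round(stats::rnorm(12L, ratingMeans[cat], config$ratingSD))
    data.frame(participant = p, item = items, category = cat,
               rating = pmin(pmax(r, 1L), 4L), stringsAsFactors = FALSE)
  }))

  pAcc <- 0.5 + 0.4 * L
  afc <- do.call(rbind, lapply(seq_len(nP), function(p) {
    foilType <- rep(rep(c("partword", "nonword"), each = 2L), times = 4L)
    foilIdx <- rep(c(1L, 2L, 1L, 2L), times = 4L)
    word <- rep(wordNames, each = 4L)
    foil <- ifelse(foilType == "partword", pwNames[foilIdx], nwNames[foilIdx])
    data.frame(participant = p, trial = seq_len(16L), word = word,
               foil = foil, foilType = foilType,
               correct = stats::runif(16L) < pAcc, stringsAsFactors = FALSE)
  }))

  nStreams <- if (config$mode == "child") 24L else 36L
  targets <- list(); presses <- list()
  for (p in seq_len(nP)) {
    streams <- generateDetectionStreams(lexicon, nStreams, mode = config$mode,
                                        seed = config$seed + 1000L * p)
    streamDur <- 3 * syllableDuration(streams[[1L]]) * 16L
    for (s in seq_along(streams)) {
      st <- streams[[s]]
      onsets <- st@targetOnsets
      posn <- st@targetPosition
      rtMean <- config$rtBaseline - config$rtFacilitation * L * (posn - 1L)
      hit <- stats::runif(4L) >= config$missRate
      rt <- pmax(stats::rnorm(4L, rtMean, config$rtNoiseSD), 100)
      pressT <- ifelse(hit, onsets + rt / 1000, NA_real_)
      targets[[length(targets) + 1L]] <-
        data.frame(participant = p, stream = s, position = posn,
                   onset = onsets, pressTime = pressT)
      nFA <- stats::rpois(1L, config$faRate)
      faT <- if (nFA) sort(stats::runif(nFA, 0, streamDur)) else numeric(0)
      allPress <- sort(c(pressT[!is.na(pressT)], faT))
      if (length(allPress))
        presses[[length(presses) + 1L]] <-
          data.frame(participant = p, stream = s, time = allPress)
    }
  }
  list(rating = rating, afc = afc,
       detectionTargets = do.call(rbind, targets),
       detectionPresses = if (length(presses)) do.call(rbind, presses) else
         data.frame(participant = integer(), stream = integer(),
                    time = numeric()),
       mode = config$mode)
}
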