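# shared fixtures built in code

# epoch set of pure sinusoids at `freq` with given per-epoch phase offsets;
# single channel unless more labels given
toyEpochs <- function(phases, freq, fs = 100, durSec = 10, amp = 1,
                      labels = "Cz") {
  nSamp <- round(durSec * fs)
  t <- (seq_len(nSamp) - 1L) / fs
  nE <- length(phases)
  arr <- array(0, c(nE, length(labels), nSamp))
  for (k in seq_len(nE))
    for (ch in seq_along(labels))
      arr[k, ch, ] <- amp * cos(2 * pi * freq * t + phases[k])
  new("EpochSet", epochs = arr, epochOnsets = durSec * (seq_len(nE) - 1L),
      wordsPerEpoch = 12L, retainedMask = rep(TRUE, nE),
      samplingRate = fs, channelLabels = labels)
}

# epoch set from an arbitrary epochs x channels x samples array
epochsFromArray <- function(arr, fs = 100, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(arr)[2L]))
  new("EpochSet", epochs = arr,
      epochOnsets = (seq_len(dim(arr)[1L]) - 1L) * dim(arr)[3L] / fs,
      wordsPerEpoch = 12L, retainedMask = rep(TRUE, dim(arr)[1L]),
      samplingRate = fs, channelLabels = labels)
}

# toy recording with given channel matrix
toyRecording <- function(samples, fs = 100, labels = NULL,
                         events = data.frame(onset = numeric(0),
                                             label = character(0))) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  rownames(samples) <- labels
  new("EEGRecording", samples = samples, samplingRate = fs,
      channelLabels = labels, reference = "raw", events = events,
      meta = list())
}

# a small simulated participant: stream + recording + ROI epochs, few
# channels for speed
simParticipant <- function(seed, reps = 25, kappaWordStart = 0.5,
                           kappaWordEnd = 4, noiseSigma = 2, wordAmp = 1,
                           channels = c("Fz", "Cz", "FC1", "FC2", "M1", "M2")) {
  lex <- buildLexicon("A")
  st <- generateStream(lex, reps, 0.3, seed = seed)
  cfg <- syntheticEEGConfig(seed = seed, kappaWordStart = kappaWordStart,
                            kappaWordEnd = kappaWordEnd,
                            noiseSigma = noiseSigma, wordAmp = wordAmp)
  sim <- simulateRecording(st, cfg, channels = channels)
  list(stream = st, recording = sim$recording, groundTruth = sim$groundTruth,
       roi = setdiff(channels, c("M1", "M2")))
}
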