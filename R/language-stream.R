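#' Build one of the three artificial-language lexicons
#'
#' Each lexicon holds four unique trisyllabic nonsense words built from 12
#' distinct syllables, so that syllable-to-syllable transitions inside a word
#' are fully predictable while transitions across word boundaries are not.
#' Version A was used for children, B and C for the two adult samples; B and
#' C differ from A only in a swap of word-final or word-medial syllables.
#'
#' @param version "A", "B" or "C".
#' @return a [Lexicon-class] object.
#' @examples
#' buildLexicon("A")
#' @export
buildLexicon <- function(version = c("A", "B", "C")) {
  if (length(version) != 1L || !version %in% c("A", "B", "C"))
    stop("unknown lexicon version: must be one of 'A', 'B', 'C'")
  words <- switch(version,
    A = list(pautone = c("pau", "to", "ne"),
             nurafi  = c("nu", "ra", "fi"),
             gabalu  = c("ga", "ba", "lu"),
             mailoki = c("mai", "lo", "ki")),
    B = list(pautoki = c("pau", "to", "ki"),
             nurafi  = c("nu", "ra", "fi"),
             gabalu  = c("ga", "ba", "lu"),
             mailone = c("mai", "lo", "ne")),
    C = list(pautone = c("pau", "to", "ne"),
             nurafi  = c("nu", "ra", "fi"),
             gamilu  = c("ga", "mi", "lu"),
             maipuki = c("mai", "pu", "ki")))
  new("Lexicon", version = version, words = words,
      syllables = unlist(words, use.names = FALSE))
}

# pseudorandom token order: exact per-word quotas, no immediate repeats.
# Samples the next word with probability proportional to its remaining quota
# among non-predecessor words; bounded retries guard against dead ends.
.orderTokens <- function(wordNames, repsPerWord, maxRetries = 1000L) {
  n <- length(wordNames) * repsPerWord
  for (try in seq_len(maxRetries)) {
    counts <- stats::setNames(rep(repsPerWord, length(wordNames)), wordNames)
    out <- character(n)
    prev <- ""
    ok <- TRUE
    for (i in seq_len(n)) {
      cand <- names(counts)[counts > 0L & names(counts) != prev]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = counts[cand])
      out[i] <- pick
      counts[pick] <- counts[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("could not arrange tokens without immediate repeats after ",
       maxRetries, " retries")
}

#' Generate a continuous exposure stream
#'
#' Concatenates the four lexicon words in pseudorandom order, with exact
#' per-word repetition quotas and the restriction that the same word never
#' occurs twice in a row. Syllables fall on a fixed grid (300 ms each by
#' default), so a standard stream of 4 x 100 words lasts six minutes.
#'
#' @param lexicon a [Lexicon-class].
#' @param repsPerWord repetitions of each word (default 100 -> 400 tokens).
#' @param syllableDuration seconds per syllable (default 0.3).
#' @param seed integer seed; the ordering is reproducible given the seed.
#' @return a [SpeechStream-class].
#' @examples
#' st <- generateStream(buildLexicon("A"), repsPerWord = 5, seed = 1)
#' tokens(st)
#' @export
generateStream <- function(lexicon, repsPerWord = 100, syllableDuration = 0.3,
                           seed = 1L) {
  stopifnot(is(lexicon, "Lexicon"))
  if (repsPerWord < 1) stop("repsPerWord must be >= 1")
  if (syllableDuration <= 0) stop("syllableDuration must be positive")
  seed <- as.integer(seed)
  set.seed(seed)
  toks <- .orderTokens(names(lexiconWords(lexicon)), as.integer(repsPerWord))
  n <- length(toks)
  syl <- unlist(lexiconWords(lexicon)[toks], use.names = FALSE)
  sylOn <- syllableDuration * (seq_along(syl) - 1L)
  wordOn <- 3 * syllableDuration * (seq_len(n) - 1L)
  new("SpeechStream", tokens = toks, syllableSeq = syl,
      syllableOnsets = sylOn, wordOnsets = wordOn,
      syllableDuration = syllableDuration,
      totalDuration = 3 * syllableDuration * n,
      lexiconVersion = lexicon@version, seed = seed)
}

#' Empirical transitional probabilities of a stream
#'
#' Tallies all adjacent syllable bigrams of the stream and forms the
#' conditional probabilities P(next | current). Each transition is classified
#' as within-word (positions 1->2 and 2->3 of a token) or between-word
#' (position 3 -> position 1 of the next token); the summary means average
#' the conditional probability over the transition instances of each class.
#' For a standard stream the within-word mean is exactly 1 and the
#' between-word mean is close to 1/3 (the successor is drawn from the three
#' non-repeating words).
#'
#' @param stream a [SpeechStream-class].
#' @param lexicon the [Lexicon-class] the stream was drawn from.
#' @return data.frame with columns \code{from}, \code{to}, \code{count},
#'   \code{p}, \code{type}; attributes \code{withinWordMean} and
#'   \code{betweenWordMean}.
#' @export
transitionalProbabilities <- function(stream, lexicon) {
  stopifnot(is(stream, "SpeechStream"), is(lexicon, "Lexicon"))
  syl <- syllableSequence(stream)
  if (length(syl) < 2L) stop("stream too short for transitional probabilities")
  if (!all(syl %in% syllableInventory(lexicon)))
    stop("stream contains syllables outside the lexicon")
  from <- syl[-length(syl)]
  to <- syl[-1L]
  pos <- rep(1:3, length.out = length(syl))       # syllable position in word
  type <- ifelse(pos[-length(syl)] == 3L, "between", "within")
  tab <- as.data.frame(table(from = from, to = to), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  names(tab)[3L] <- "count"
  fromTotals <- tapply(tab$count, tab$from, sum)
  tab$p <- tab$count / as.numeric(fromTotals[tab$from])
  pairType <- tapply(type, paste(from, to), function(x) x[1L])
  tab$type <- as.character(pairType[paste(tab$from, tab$to)])
  tab <- tab[order(tab$from, tab$to), ]
  rownames(tab) <- NULL
  key <- paste(from, to)
  pLookup <- stats::setNames(tab$p, paste(tab$from, tab$to))
  attr(tab, "withinWordMean") <- mean(pLookup[key][type == "within"])
  attr(tab, "betweenWordMean") <- mean(pLookup[key][type == "between"])
  tab
}

#' Generate target-detection streams
#'
#' Builds short streams of 16 tokens (each word 4 times, no immediate
#' repeats). Each stream designates one target syllable; (word, position)
#' targets are assigned round-robin over the 4 x 3 combinations after a
#' seeded shuffle, so with a multiple of 12 streams every syllable position
#' receives \code{nStreams * 4 / 3} targets. Child mode slows the syllable
#' rate to 350 ms; adult mode uses the exposure rate of 300 ms.
#'
#' @param lexicon a [Lexicon-class].
#' @param nStreams number of streams (24 child protocol, 36 adult protocol).
#' @param mode "child" (0.35 s syllables) or "adult" (0.30 s).
#' @param seed integer seed.
#' @return list of [DetectionStream-class] objects.
#' @export
generateDetectionStreams <- function(lexicon, nStreams, mode = c("child", "adult"),
                                     seed = 1L) {
  stopifnot(is(lexicon, "Lexicon"))
  mode <- match.arg(mode)
  if (nStreams < 1) stop("nStreams must be >= 1")
  dur <- if (mode == "child") 0.35 else 0.30
  set.seed(as.integer(seed))
  combos <- expand.grid(word = names(lexiconWords(lexicon)), position = 1:3,
                        stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), ]
  assign <- combos[((seq_len(nStreams) - 1L) %% nrow(combos)) + 1L, ]
  lapply(seq_len(nStreams), function(s) {
    toks <- .orderTokens(names(lexiconWords(lexicon)), 4L)
    word <- assign$word[s]
    posn <- as.integer(assign$position[s])
    targetSyl <- lexiconWords(lexicon)[[word]][posn]
    hits <- which(toks == word)
    onsets <- 3 * dur * (hits - 1L) + dur * (posn - 1L)
    new("DetectionStream", tokens = toks, targetSyllable = targetSyl,
        targetPosition = posn, syllableDuration = dur, targetOnsets = onsets)
  })
}

#' Build partword and nonword foils
#'
#' Partwords append a foreign syllable to an attested syllable pair (the
#' final syllable of one word after the first two syllables of another, or
#' the first syllable of one word before the final two of another), so each
#' partword contains exactly one attested within-word bigram. Nonwords
#' combine syllables that never occur adjacently in the stream (final,
#' medial, initial syllables of three different words), so they contain no
#' attested bigram at all.
#'
#' @param lexicon a [Lexicon-class].
#' @param seed integer seed controlling which words donate which syllables.
#' @return list with character-matrix elements \code{partwords} and
#'   \code{nonwords} (4 rows x 3 syllable columns each).
#' @export
makeFoils <- function(lexicon, seed = 1L) {
  stopifnot(is(lexicon, "Lexicon"))
  set.seed(as.integer(seed))
  w <- lexiconWords(lexicon)
  ord <- sample.int(4L)            # donor order for partwords
  partwords <- matrix("", 4L, 3L)
  for (k in 1:4) {
    i <- ord[k]
    j <- ord[(k %% 4L) + 1L]       # a different word
    if (k <= 2L) {
      # first two syllables of word i + final syllable of word j
      partwords[k, ] <- c(w[[i]][1:2], w[[j]][3L])
    } else {
      # first syllable of word j + final two syllables of word i
      partwords[k, ] <- c(w[[j]][1L], w[[i]][2:3])
    }
  }
  # nonwords: (final of word a, medial of word b, initial of word c) with
  # a, b, c all different; finals are only ever followed by initials in the
  # stream and medials only by finals, so no bigram is ever attested.
  p <- sample.int(4L)
  nonwords <- matrix("", 4L, 3L)
  for (k in 1:4) {
    a <- p[k]
    b <- p[(k %% 4L) + 1L]
    cc <- p[((k + 1L) %% 4L) + 1L]
    nonwords[k, ] <- c(w[[a]][3L], w[[b]][2L], w[[cc]][1L])
  }
  list(partwords = partwords, nonwords = nonwords)
}

#' Within-word bigram set of a lexicon
#'
#' The attested syllable pairs (positions 1-2 and 2-3 of each word), used to
#' validate foils.
#'
#' @param lexicon a [Lexicon-class].
#' @return character vector of "from>to" bigram keys.
#' @export
wordInternalBigrams <- function(lexicon) {
  stopifnot(is(lexicon, "Lexicon"))
  unlist(lapply(lexiconWords(lexicon), function(s)
    c(paste(s[1L], s[2L], sep = ">"), paste(s[2L], s[3L], sep = ">"))),
    use.names = FALSE)
}
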