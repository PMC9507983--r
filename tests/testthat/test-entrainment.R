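test_that("ITC is 1 for identical epochs and 0 for antiphase pairs", {
  ep <- toyEpochs(rep(0.3, 10), freq = 2)
  itc <- computeITC(ep, freqRange = c(0.6, 5))
  bin <- which.min(abs(binFrequencies(itc) - 2))
  expect_equal(itcValues(itc)[1L, bin], 1.0, tolerance = 1e-9)

  anti <- toyEpochs(c(0, pi), freq = 2)
  itcA <- computeITC(anti, freqRange = c(0.6, 5))
  expect_lt(itcValues(itcA)[1L, bin], 1e-9)

  expect_error(computeITC(toyEpochs(0, freq = 2)), "at least 2 retained")
})

test_that("uniform random phase gives the sqrt(pi)/(2 sqrt(N)) floor", {
  set.seed(7)
  vals <- replicate(40, {
    ep <- toyEpochs(runif(100, -pi, pi), freq = 2, durSec = 5)
    itc <- computeITC(ep, freqRange = c(0.6, 5))
    itcValues(itc)[1L, which.min(abs(binFrequencies(itc) - 2))]
  })
  # 40-run Monte-Carlo mean within 3 SEs of 0.0886
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - uniformPhaseITC(100)), 3 * se + 0.003)
})

test_that("ITC is amplitude-invariant, order-invariant and bounded", {
  set.seed(3)
  arr <- array(rnorm(8 * 2 * 300), c(8, 2, 300))
  ep <- epochsFromArray(arr)
  itc1 <- computeITC(ep, c(0.6, 5))
  expect_true(all(itcValues(itc1) >= 0 & itcValues(itc1) <= 1))

  scaled <- epochsFromArray(arr * 73.1)
  expect_equal(itcValues(computeITC(scaled, c(0.6, 5))), itcValues(itc1),
               tolerance = 1e-12)

  perm <- epochsFromArray(arr[sample(8), , , drop = FALSE])
  expect_identical(itcValues(computeITC(perm, c(0.6, 5))),
                   itcValues(itc1))
})

test_that("frequency extraction picks the nearest bin with tie-to-lower", {
  # 10.8 s epochs at 512 Hz: 5530-sample epochs, bin spacing 512/5530 Hz
  ep <- toyEpochs(rep(0, 3), freq = 1.111, fs = 512, durSec = 5530 / 512)
  itc <- computeITC(ep, c(0.6, 5))
  w <- extractFrequency(itc, 1.1)
  expect_equal(attr(w, "selectedFrequency"), 12 * 512 / 5530,
               tolerance = 1e-9)              # the 12/10.8 ~ 1.111 Hz bin
  s <- extractFrequency(itc, 3.3)
  expect_equal(attr(s, "selectedFrequency"), 36 * 512 / 5530,
               tolerance = 1e-9)              # the 36/10.8 ~ 3.333 Hz bin

  # a target exactly on a bin returns that bin
  onbin <- extractFrequency(itc, binFrequencies(itc)[5L])
  expect_equal(attr(onbin, "selectedFrequency"), binFrequencies(itc)[5L])

  # equidistant target resolves to the lower bin
  bf <- binFrequencies(itc)
  mid <- (bf[10L] + bf[11L]) / 2
  expect_equal(attr(extractFrequency(itc, mid), "selectedFrequency"),
               bf[10L])
  expect_error(extractFrequency(itc, 12), "outside computed range")
})

test_that("ROI averaging and the WLI follow their definitions", {
  v <- c(Fz = 0.4, Cz = 0.2, Pz = 0.9, Oz = 0.1)
  expect_equal(roiAverage(v, c("Fz", "Cz")), 0.3)
  expect_equal(roiAverage(v, "Pz"), 0.9)
  expect_equal(roiAverage(v, names(v)), mean(v))
  expect_error(roiAverage(v, character(0)), "nonempty")
  expect_error(roiAverage(v, c("XX", "YY")), "no ROI channels")

  expect_equal(wordLearningIndex(0.2, 0.4), 0.5)
  expect_equal(wordLearningIndex(0.37, 0.37), 1.0)
  expect_error(wordLearningIndex(0.2, 0), "undefined")
})

test_that("paired actual-vs-surrogate test matches the closed-form computation", {
  a <- c(0.52, 0.61, 0.44, 0.58, 0.49)
  s <- c(0.41, 0.52, 0.47, 0.46, 0.42)
  res <- compareActualSurrogate(a, s)
  d <- a - s
  tOracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, tOracle, tolerance = 1e-12)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 2 * pt(-abs(tOracle), 4), tolerance = 1e-12)
  expect_equal(res$cohenD, mean(d) / sd(d), tolerance = 1e-12)
  # cross-check against stats::t.test
  tt <- t.test(a, s, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)

  ident <- compareActualSurrogate(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_true(ident$degenerateVariance)

  shifted <- compareActualSurrogate(a + 0.1, a)
  expect_true(shifted$degenerateVariance)
  expect_true(is.na(shifted$t))

  expect_error(compareActualSurrogate(a, s[-1L]), "paired")
  expect_error(compareActualSurrogate(a[1:2], s[1:2]), "n >= 3")
})

test_that("entrainment-behaviour correlations match the closed-form Pearson oracle", {
  x <- c(0.8, 1.1, 0.9, 1.4, 1.2, 0.7)
  y <- c(1.2, 1.9, 1.4, 2.4, 2.1, 1.1)
  summaries <- data.frame(participant = 1:6, wli = x)
  scores <- data.frame(participant = 1:6, ratingScore = y)
  res <- correlateEntrainmentBehaviour(summaries, scores)
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, rOracle, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$n, 6L)

  # y = x gives r = 1
  resId <- correlateEntrainmentBehaviour(
    data.frame(participant = 1:5, wli = 1:5),
    data.frame(participant = 1:5, score = 1:5))
  expect_equal(resId$r, 1)

  # independent large-n null
  set.seed(2)
  resNull <- correlateEntrainmentBehaviour(
    data.frame(participant = 1:1000, wli = rnorm(1000)),
    data.frame(participant = 1:1000, score = rnorm(1000)))
  expect_lt(abs(resNull$r), 0.1)

  expect_error(correlateEntrainmentBehaviour(
    data.frame(participant = 1:2, wli = 1:2),
    data.frame(participant = 1:2, score = 1:2)), "fewer than 3")
})

test_that("zero jitter reproduces the actual ITC bit for bit", {
  p <- simParticipant(seed = 31, reps = 25)
  rec <- p$recording
  ep <- epochByWords(rec)
  actual <- computeITC(ep)
  surr0 <- surrogateITC(rec, jitterRangeMs = c(0, 0), seed = 123)
  expect_identical(itcValues(surr0$itc), itcValues(actual))
  expect_identical(binFrequencies(surr0$itc), binFrequencies(actual))
})

test_that("jitter destroys word-rate phase locking in entrained data", {
  hits <- vapply(1:8, function(s) {
    p <- simParticipant(seed = 600 + s, reps = 25, kappaWordStart = 6,
                        kappaWordEnd = 6, noiseSigma = 1)
    ep <- epochByWords(p$recording)
    aw <- roiAverage(extractFrequency(computeITC(ep), 1.1), p$roi)
    surr <- surrogateITC(p$recording, seed = 900 + s)
    sw <- roiAverage(extractFrequency(surr$itc, 1.1), p$roi)
    aw > sw
  }, logical(1L))
  expect_gte(sum(hits), 7L)
})
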