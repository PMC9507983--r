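test_that("bundle construction follows the sliding-window arithmetic", {
  arr <- array(rnorm(33 * 1 * 50), c(33, 1, 50))
  ep <- epochsFromArray(arr)
  b <- makeBundles(ep, bundleSize = 5L)
  expect_equal(nrow(b), 29L)                  # 33 - 5 + 1
  expect_equal(b$bundle, 1:29)
  # adjacent bundles share exactly 4 epoch positions
  for (k in 1:28)
    expect_length(intersect(b$epochs[[k]], b$epochs[[k + 1L]]), 4L)
  # bundle duration: 5 epochs x 10.8 s worth of samples
  expect_equal(5 * 10.8, 54)

  b1 <- makeBundles(epochsFromArray(array(0, c(5, 1, 10))), 5L)
  expect_equal(nrow(b1), 1L)
  expect_warning(b0 <- makeBundles(epochsFromArray(array(0, c(3, 1, 10))), 5L),
                 "fewer epochs")
  expect_equal(nrow(b0), 0L)

  # rejected epochs are excluded and sparse bundles flagged unusable
  ep2 <- epochsFromArray(arr)
  ep2@retainedMask[2:5] <- FALSE
  b2 <- makeBundles(ep2, 5L)
  expect_equal(b2$epochs[[1L]], 1L)
  expect_false(b2$usable[1L])
  expect_true(b2$usable[6L])
})

test_that("single-bundle series equals the overall ITC and flat signals stay flat", {
  set.seed(5)
  arr <- array(rnorm(5 * 2 * 200), c(5, 2, 200))
  ep <- epochsFromArray(arr, fs = 100, labels = c("Fz", "Cz"))
  series <- bundleITCSeries(ep, roi = c("Fz", "Cz"), bundleSize = 5L,
                            wordFreq = 1, syllableFreq = 3,
                            freqRange = c(0.6, 5))
  expect_equal(nrow(series), 1L)
  itc <- computeITC(ep, c(0.6, 5))
  expect_equal(series$itcWord,
               roiAverage(extractFrequency(itc, 1), c("Fz", "Cz")),
               tolerance = 1e-12)
  expect_equal(series$itcSyllable,
               roiAverage(extractFrequency(itc, 3), c("Fz", "Cz")),
               tolerance = 1e-12)
  expect_equal(series$wli, series$itcWord / series$itcSyllable)
})

test_that("an increasing word-phase concentration yields a rising bundle series", {
  p <- simParticipant(seed = 77, reps = 100, kappaWordStart = 0.2,
                      kappaWordEnd = 8, noiseSigma = 1)
  ep <- epochByWords(p$recording)
  series <- bundleITCSeries(ep, p$roi)
  expect_equal(nrow(series), 29L)
  ct <- cor.test(series$bundle, series$itcWord, method = "spearman",
                 exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("sparse bundles are excluded by the majority-missing rule", {
  series <- expand.grid(participant = 1:10, bundle = 1:29)
  series$wli <- 1
  series$wli[series$bundle == 29 & series$participant <= 6] <- NA  # 60% missing
  series$wli[series$bundle == 28 & series$participant <= 5] <- NA  # 50% missing
  out <- suppressMessages(excludeSparseBundles(series, threshold = 0.5))
  expect_equal(attr(out, "droppedBundles"), 29)
  expect_true(28 %in% out$bundle)             # exactly 50% is not "more than"

  # brute-force fraction-count oracle on a random missingness pattern
  set.seed(8)
  series2 <- expand.grid(participant = 1:20, bundle = 1:15)
  series2$wli <- ifelse(runif(nrow(series2)) < 0.3, NA, 1)
  out2 <- suppressMessages(excludeSparseBundles(series2, threshold = 0.5))
  oracle <- sapply(1:15, function(b) {
    mean(is.na(series2$wli[series2$bundle == b])) > 0.5
  })
  expect_setequal(attr(out2, "droppedBundles"), (1:15)[oracle])

  # no missing data: nothing dropped
  out3 <- excludeSparseBundles(transform(series, wli = 1), 0.5)
  expect_length(attr(out3, "droppedBundles"), 0L)
})

# direct series-level generator: known slope + participant intercepts + noise
simSlopeSeries <- function(nP = 24, nB = 26, slope = 0.01, sdIntercept = 0.1,
                           sdNoise = 0.05, groupOffset = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nP), function(p) {
    grp <- if (p <= nP / 2) "g1" else "g2"
    b <- slope + if (grp == "g2") groupOffset else 0
    data.frame(participant = p, group = grp, bundle = 1:nB,
               wli = 1 + rnorm(1, 0, sdIntercept) + b * (1:nB) +
                 rnorm(nB, 0, sdNoise))
  }))
}

test_that("the mixed model recovers an injected bundle slope", {
  series <- simSlopeSeries(nP = 24, nB = 26, slope = 0.01, seed = 1)
  fit <- fitLearningLMM(series, response = "wli")
  est <- fit$estimates
  b <- est$estimate[est$term == "bundle"]
  se <- est$se[est$term == "bundle"]
  expect_lt(abs(b - 0.01), 1.96 * se)         # truth inside the 95% CI
  expect_false(fit$singular)
  expect_lt(fit$ftests$p[fit$ftests$term == "bundle"], 0.05)
  expect_match(fit$method, "Satterthwaite")

  # mean estimate across 20 seeds within 20% of the injected slope
  ests <- vapply(1:20, function(s) {
    f <- fitLearningLMM(simSlopeSeries(seed = s), "wli")
    f$estimates$estimate[f$estimates$term == "bundle"]
  }, numeric(1L))
  expect_lt(abs(mean(ests) - 0.01) / 0.01, 0.2)
})

test_that("zero-slope data rarely trigger the bundle effect", {
  ps <- vapply(1:100, function(s) {
    f <- fitLearningLMM(simSlopeSeries(slope = 0, seed = 100 + s), "wli")
    f$ftests$p[f$ftests$term == "bundle"]
  }, numeric(1L))
  expect_gte(sum(ps >= 0.05), 90L)            # at most ~alpha false alarms
})

test_that("a group slope difference shows up in the interaction with the right sign", {
  series <- simSlopeSeries(nP = 30, nB = 26, slope = 0.005,
                           groupOffset = 0.012, seed = 4)
  fit <- fitLearningLMM(series, response = "wli", groupTerm = TRUE)
  est <- fit$estimates
  inter <- est$estimate[grepl("bundle:group", est$term)]
  expect_gt(inter, 0)
  expect_lt(fit$ftests$p[grepl("bundle:group", fit$ftests$term)], 0.05)

  # negative offset flips the sign
  fit2 <- fitLearningLMM(simSlopeSeries(nP = 30, nB = 26, slope = 0.01,
                                        groupOffset = -0.012, seed = 5),
                         "wli", groupTerm = TRUE)
  expect_lt(fit2$estimates$estimate[grepl("bundle:group",
                                          fit2$estimates$term)], 0)
})

test_that("actual-vs-surrogate time course isolates the learning trend", {
  actual <- simSlopeSeries(nP = 20, nB = 20, slope = 0.01, seed = 6)
  surrogateNull <- simSlopeSeries(nP = 20, nB = 20, slope = 0, seed = 7)
  names(actual)[names(actual) == "wli"] <- "itcWord"
  names(surrogateNull)[names(surrogateNull) == "wli"] <- "itcWord"
  cmp <- surrogateTimecourse(actual, surrogateNull, response = "itcWord")
  expect_gt(cmp$interaction$estimate, 0)
  expect_lt(cmp$interaction$p, 0.05)

  # surrogate = copy of actual: interaction vanishes
  cmp0 <- surrogateTimecourse(actual, actual, response = "itcWord")
  expect_lt(abs(cmp0$interaction$estimate), 1e-8)

  bad <- surrogateNull[surrogateNull$participant <= 10, ]
  expect_error(surrogateTimecourse(actual, bad, "itcWord"), "same participant")
})
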