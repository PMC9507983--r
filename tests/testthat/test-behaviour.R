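test_that("rating scores follow the word-minus-foils arithmetic", {
  mk <- function(p, ratings) data.frame(
    participant = p,
    category = rep(c("word", "partword", "nonword"), each = 4L),
    rating = ratings)
  # toy table: words 4,3,4,3; partwords 2,2,3,1; nonwords 1,2,1,2
  toy <- mk(1L, c(4, 3, 4, 3, 2, 2, 3, 1, 1, 2, 1, 2))
  sc <- scoreRating(toy)
  expect_equal(sc$ratingScore, 3.5 - 1.75)    # hand-computed oracle
  expect_equal(sc$meanWord, 3.5)
  expect_equal(sc$meanPartword, 2)
  expect_equal(sc$meanNonword, 1.5)
  expect_false(sc$zeroVariance)

  # all ratings equal -> score 0 and the single-key flag
  flat <- scoreRating(mk(1L, rep(3, 12)))
  expect_equal(flat$ratingScore, 0)
  expect_true(flat$zeroVariance)

  # extremes -> the maximum score of 3 (bounded by the 1-4 scale)
  ext <- scoreRating(mk(1L, c(rep(4, 4), rep(1, 8))))
  expect_equal(ext$ratingScore, 3)

  expect_warning(scoreRating(toy[1:10, ]), "complete 12-trial")
  expect_error(scoreRating(mk(1L, c(rep(5, 4), rep(1, 8)))), "1-4 scale")
})

test_that("2AFC accuracy and the chance-level test behave", {
  one <- data.frame(participant = 1L, correct = rep(TRUE, 16L))
  expect_equal(scoreAFC(one)$scores$accuracy, 100)
  eleven <- data.frame(participant = 1L, correct = c(rep(TRUE, 11), rep(FALSE, 5)))
  expect_equal(scoreAFC(eleven)$scores$accuracy, 68.75)

  # simulated guessers: group mean within 2 SEs of 50%
  set.seed(12)
  guess <- do.call(rbind, lapply(1:1000, function(p)
    data.frame(participant = p, correct = runif(16) < 0.5)))
  res <- scoreAFC(guess)
  se <- res$testVsChance$sd / sqrt(1000)
  expect_lt(abs(res$testVsChance$mean - 50), 2 * se + 0.5)
  expect_gt(res$testVsChance$p, 0.001)

  # above-chance group: t matches a direct one-sample computation
  set.seed(13)
  good <- do.call(rbind, lapply(1:30, function(p)
    data.frame(participant = p, correct = runif(16) < 0.75)))
  resG <- scoreAFC(good)
  acc <- resG$scores$accuracy
  expect_equal(resG$testVsChance$t,
               (mean(acc) - 50) / (sd(acc) / sqrt(30)), tolerance = 1e-12)
  expect_equal(resG$testVsChance$cohenD, (mean(acc) - 50) / sd(acc))
  expect_error(scoreAFC(one[0, ]), "no 2AFC trials")
})

test_that("detection scoring matches a brute-force event matcher on a toy stream", {
  # 4 targets; presses: 3 in-window hits, 2 strays
  targets <- data.frame(participant = 1L, stream = 1L,
                        position = c(1L, 2L, 3L, 1L),
                        onset = c(1.0, 4.0, 7.0, 10.0))
  presses <- data.frame(participant = 1L, stream = 1L,
                        time = c(1.5, 4.6, 7.4, 2.9, 12.5))
  sc <- scoreDetection(targets, presses, mode = "child")
  expect_equal(sc$hits, 3L)
  expect_equal(sc$hitRate, 0.75)
  expect_equal(sc$falseAlarms, 2L)
  expect_equal(sc$normalisedFA, 0.5)
  # RTs per position in ms
  expect_equal(sc$rtS1, 500)                  # only the 1.5 s press hits a P1
  expect_equal(sc$rtS2, 600)
  expect_equal(sc$rtS3, 400)
  expect_equal(sc$rtPriming, (500 - 400) / 500)

  # every press classified exactly once; hits + misses = total targets
  expect_equal(sc$hits + (sc$nTargets - sc$hits), sc$nTargets)
  expect_equal(sc$hits + sc$falseAlarms, nrow(presses))
})

test_that("response windows differ by mode and a press at exactly 0 ms is a false alarm", {
  targets <- data.frame(participant = 1L, stream = 1L, position = 1L,
                        onset = 1.0)
  # press 1.3 s after onset: inside the child window (1.4 s), outside adult (1.2 s)
  late <- data.frame(participant = 1L, stream = 1L, time = 2.3)
  expect_equal(suppressWarnings(
    scoreDetection(targets, late, "child"))$hits, 1L)
  expect_equal(suppressWarnings(
    scoreDetection(targets, late, "adult"))$hits, 0L)
  zero <- data.frame(participant = 1L, stream = 1L, time = 1.0)
  sc0 <- suppressWarnings(scoreDetection(targets, zero, "child"))
  expect_equal(sc0$hits, 0L)
  expect_equal(sc0$falseAlarms, 1L)
})

test_that("each target consumes one press and overlaps resolve to the nearest target", {
  # two targets 0.5 s apart; one press in both windows goes to the nearer
  targets <- data.frame(participant = 1L, stream = 1L,
                        position = c(1L, 3L), onset = c(1.0, 1.5))
  press <- data.frame(participant = 1L, stream = 1L, time = 2.0)
  sc <- suppressWarnings(scoreDetection(targets, press, "child"))
  expect_equal(sc$hits, 1L)
  expect_true(is.na(sc$rtS1))                 # nearest target was position 3
  expect_equal(sc$rtS3, 500)

  # two presses, two targets: earliest press consumes the near target first
  press2 <- data.frame(participant = 1L, stream = 1L, time = c(1.9, 2.1))
  sc2 <- suppressWarnings(scoreDetection(targets, press2, "child"))
  expect_equal(sc2$hits, 2L)
  expect_equal(sc2$rtS3, 400)                 # 1.9 s press -> 1.5 s target
  expect_equal(sc2$rtS1, 1100)                # 2.1 s press -> 1.0 s target
})

test_that("RT priming is scale-invariant and the formula matches the definition", {
  targets <- data.frame(participant = 1L, stream = rep(1:3, each = 2L),
                        position = rep(c(1L, 3L), 3L),
                        onset = rep(c(1.0, 4.0), 3L))
  presses <- data.frame(participant = 1L, stream = rep(1:3, each = 2L),
                        time = c(1.6, 4.45, 1.6, 4.45, 1.6, 4.45))
  sc <- suppressWarnings(scoreDetection(targets, presses, "child"))
  expect_equal(sc$rtPriming, (600 - 450) / 600)
  expect_equal(sc$rtPriming, 0.25)

  # multiply all RTs by 1.7: priming unchanged
  presses2 <- transform(presses,
                        time = rep(c(1.0, 4.0), 3L) +
                          1.7 * (time - rep(c(1.0, 4.0), 3L)))
  sc2 <- suppressWarnings(scoreDetection(targets, presses2, "adult"))
  expect_equal(sc2$rtPriming, 0.25, tolerance = 1e-12)

  # S1 = S3 -> zero priming
  pressesEq <- transform(presses, time = rep(c(1.5, 4.5), 3L))
  scEq <- suppressWarnings(scoreDetection(targets, pressesEq, "child"))
  expect_equal(scEq$rtPriming, 0)
})

test_that("repeated-measures ANOVA flags a simulated category gradient", {
  simGradient <- function(seed, effect = 0.5) {
    set.seed(seed)
    do.call(rbind, lapply(1:24, function(p) {
      base <- rnorm(1, 2.5, 0.3)
      data.frame(participant = p,
                 category = c("word", "partword", "nonword"),
                 rating = base + effect * c(1, 0, -1) + rnorm(3, 0, 0.3))
    }))
  }
  hits <- vapply(1:20, function(s) {
    res <- rmAnova(simGradient(s), dv = "rating", within = "category",
                   id = "participant",
                   withinOrder = c("nonword", "partword", "word"))
    res$linearContrast$p < 0.05
  }, logical(1L))
  expect_gte(sum(hits), 18L)

  # identical scores -> all effects null
  flat <- simGradient(1, effect = 0)
  flat$rating <- 2.5
  resFlat <- rmAnova(flat, dv = "rating", within = "category",
                     id = "participant",
                     withinOrder = c("nonword", "partword", "word"))
  expect_true(all(is.na(resFlat$effects$F) | resFlat$effects$F < 1e-6))

  # two groups with an RT offset but equal position slopes
  set.seed(99)
  rt <- do.call(rbind, lapply(1:40, function(p) {
    grp <- if (p <= 20) "child" else "adult"
    offset <- if (grp == "child") 650 else 450
    data.frame(participant = p, group = grp, position = c("S1", "S2", "S3"),
               rt = offset - 60 * (0:2) + rnorm(3, 0, 30))
  }))
  res <- rmAnova(rt, dv = "rt", within = "position", id = "participant",
                 between = "group", withinOrder = c("S1", "S2", "S3"))
  eff <- res$effects
  expect_lt(eff$p[eff$term == "group"], 0.001)
  expect_gt(eff$p[eff$term == "position:group"], 0.05)
  expect_lt(eff$p[eff$term == "position"], 0.001)
  expect_true(all(eff$partialEta2 >= 0 & eff$partialEta2 <= 1))
})

test_that("t-test reports carry Cohen's d", {
  set.seed(4)
  x <- rnorm(30, 0.5)
  one <- tTestReport(x, mu = 0)
  expect_equal(one$cohenD, mean(x) / sd(x))
  expect_equal(one$t, unname(t.test(x)$statistic))
  y <- rnorm(25, 0)
  two <- tTestReport(x, y)
  sp <- sqrt((29 * var(x) + 24 * var(y)) / 53)
  expect_equal(two$cohenD, (mean(x) - mean(y)) / sp)
  expect_equal(two$df, 53)
})
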