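#' Sliding bundles of consecutive epochs
#'
#' Bundle k collects epoch positions k .. k + bundleSize - 1 (default 5
#' non-overlapping 12-word epochs = 54 s of exposure), shifted by one epoch
#' per bundle, giving B = n_epochs - bundleSize + 1 bundles. Only retained
#' epochs inside a bundle enter later ITC computation; bundles with fewer
#' than 2 retained epochs are flagged unusable (ITC over one epoch is not a
#' coherence).
#'
#' @param epochs an [EpochSet-class].
#' @param bundleSize epochs per bundle (default 5, >= 2).
#' @param step shift between consecutive bundles (default 1).
#' @return data.frame with \code{bundle}, \code{epochs} (list column of
#'   retained epoch indices), \code{nRetained}, \code{usable}; zero rows
#'   (with warning) if too few epochs.
#' @export
makeBundles <- function(epochs, bundleSize = 5L, step = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  bundleSize <- as.integer(bundleSize)
  if (bundleSize < 2L) stop("bundleSize must be >= 2")
  nE <- nEpochs(epochs)
  if (nE < bundleSize) {
    warning("fewer epochs (", nE, ") than bundleSize (", bundleSize,
            "); zero bundles")
    return(data.frame(bundle = integer(0), nRetained = integer(0),
                      usable = logical(0)))
  }
  starts <- seq(1L, nE - bundleSize + 1L, by = as.integer(step))
  keep <- retainedMask(epochs)
  idx <- lapply(starts, function(s) {
    pos <- s:(s + bundleSize - 1L)
    pos[keep[pos]]
  })
  out <- data.frame(bundle = seq_along(starts),
                    nRetained = lengths(idx),
                    usable = lengths(idx) >= 2L)
  out$epochs <- idx
  out
}

#' Per-bundle ITC and WLI series
#'
#' Computes ITC within each bundle exactly as the overall analysis does
#' (per-epoch FFT phases are computed once and reused across bundles),
#' ROI-averages the word- and syllable-frequency bins, and forms the WLI per
#' bundle. Unusable bundles yield missing values, never fabricated numbers.
#'
#' @param epochs an [EpochSet-class].
#' @param roi channel labels to average over.
#' @param bundleSize,step as in [makeBundles()].
#' @param wordFreq,syllableFreq nominal target frequencies, Hz.
#' @param freqRange frequency window for the spectra.
#' @return data.frame: \code{bundle}, \code{itcWord}, \code{itcSyllable},
#'   \code{wli}, \code{nEpochs}.
#' @export
bundleITCSeries <- function(epochs, roi, bundleSize = 5L, step = 1L,
                            wordFreq = 1.1, syllableFreq = 3.3,
                            freqRange = c(0.6, 5)) {
  bundles <- makeBundles(epochs, bundleSize, step)
  if (!nrow(bundles))
    return(data.frame(bundle = integer(0), itcWord = numeric(0),
                      itcSyllable = numeric(0), wli = numeric(0),
                      nEpochs = integer(0)))
  pp <- .epochPhasors(epochs, freqRange, retainedOnly = FALSE)
  roiIdx <- match(roi, channelLabels(epochs))
  if (anyNA(roiIdx)) stop("ROI channels absent from epoch set")
  wBin <- .nearestBin(pp$binFrequencies, wordFreq)
  sBin <- .nearestBin(pp$binFrequencies, syllableFreq)
  res <- lapply(seq_len(nrow(bundles)), function(i) {
    if (!bundles$usable[i])
      return(c(itcWord = NA_real_, itcSyllable = NA_real_, wli = NA_real_))
    rows <- bundles$epochs[[i]]
    itcW <- mean(Mod(apply(pp$phasors[rows, roiIdx, wBin, drop = FALSE],
                           2L, mean)))
    itcS <- mean(Mod(apply(pp$phasors[rows, roiIdx, sBin, drop = FALSE],
                           2L, mean)))
    c(itcWord = itcW, itcSyllable = itcS,
      wli = if (itcS > 0) itcW / itcS else NA_real_)
  })
  res <- do.call(rbind, res)
  data.frame(bundle = bundles$bundle, itcWord = res[, "itcWord"],
             itcSyllable = res[, "itcSyllable"], wli = res[, "wli"],
             nEpochs = bundles$nRetained)
}

#' Drop bundles missing in too many participants
#'
#' A bundle number is excluded for everyone when more than
#' \code{threshold} of participants have no usable value there (late
#' bundles typically thin out as artifact-rejected epochs accumulate).
#'
#' @param series multi-participant data.frame with \code{participant},
#'   \code{bundle} and at least one response column; missing = absent row or
#'   NA in \code{responseCol}.
#' @param threshold missing fraction above which a bundle is dropped
#'   (default 0.5).
#' @param responseCol column used to judge missingness (default "wli").
#' @return the filtered series; attribute \code{"droppedBundles"} lists the
#'   removed bundle numbers. Errors if nothing survives.
#' @export
excludeSparseBundles <- function(series, threshold = 0.5,
                                 responseCol = "wli") {
  stopifnot(all(c("participant", "bundle", responseCol) %in% names(series)))
  participants <- unique(series$participant)
  nP <- length(participants)
  if (nP < 1L) stop("at least one participant required")
  bundles <- sort(unique(series$bundle))
  present <- !is.na(series[[responseCol]])
  nPresent <- tapply(present, series$bundle, sum)
  missingFrac <- 1 - as.numeric(nPresent[as.character(bundles)]) / nP
  dropped <- bundles[missingFrac > threshold]
  out <- series[!(series$bundle %in% dropped), , drop = FALSE]
  if (!nrow(out)) stop("all bundles excluded by the missingness rule")
  if (length(dropped))
    message("bundles dropped (> ", 100 * threshold, "% missing): ",
            paste(dropped, collapse = ", "))
  attr(out, "droppedBundles") <- dropped
  out
}

.lmmReport <- function(fit, data, formulaText) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  av <- stats::anova(fit)                 # lmerTest: Satterthwaite F tests
  list(formula = formulaText,
       estimates = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), stringsAsFactors = FALSE),
       ftests = data.frame(term = rownames(av),
                           F = av[["F value"]],
                           df1 = av[["NumDF"]], df2 = av[["DenDF"]],
                           p = av[["Pr(>F)"]], stringsAsFactors = FALSE),
       singular = lme4::isSingular(fit),
       method = "REML, Satterthwaite denominator df",
       nObs = nrow(data), fit = fit)
}

#' Mixed-effects model of learning across bundles
#'
#' Fits \code{response ~ bundle (+ group * bundle) (+ age * bundle)} with a
#' participant random intercept, by REML, and reports slope estimates with
#' standard errors plus Satterthwaite F tests. Bundle number enters as a
#' numeric covariate (1-based); the bundle coefficient is the change in the
#' response per bundle (one epoch = 10.8 s of exposure shift). Singular fits
#' are flagged, not hidden. Missing responses are dropped (complete case).
#'
#' @param series data.frame with \code{participant}, \code{bundle} and the
#'   response column; optionally \code{group} and/or \code{age}.
#' @param response one of "wli", "itcWord", "itcSyllable" (or any column).
#' @param groupTerm if TRUE (or a column name), add group and
#'   group:bundle fixed effects.
#' @param ageTerm if TRUE (or a column name), add age and age:bundle.
#' @return list: \code{formula}, \code{estimates} (term/estimate/se),
#'   \code{ftests} (term/F/df1/df2/p), \code{singular}, \code{method},
#'   \code{nObs}, and the underlying \code{fit}.
#' @export
fitLearningLMM <- function(series, response = "wli", groupTerm = NULL,
                           ageTerm = NULL) {
  stopifnot(all(c("participant", "bundle", response) %in% names(series)))
  data <- series[!is.na(series[[response]]), , drop = FALSE]
  data$participant <- factor(data$participant)
  rhs <- "bundle"
  if (isTRUE(groupTerm) || is.character(groupTerm)) {
    gcol <- if (is.character(groupTerm)) groupTerm else "group"
    stopifnot(gcol %in% names(data))
    data$group <- factor(data[[gcol]])
    rhs <- paste(rhs, "* group")
  }
  if (isTRUE(ageTerm) || is.character(ageTerm)) {
    acol <- if (is.character(ageTerm)) ageTerm else "age"
    stopifnot(acol %in% names(data))
    data$age <- data[[acol]]
    rhs <- paste(rhs, "* age")
  }
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | participant)"))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  .lmmReport(fit, data, deparse(fml))
}

#' Actual vs surrogate learning time course
#'
#' Stacks matched actual and surrogate bundle series and fits
#' \code{response ~ bundle * dataType + (1 | participant)} with the
#' surrogate as reference level, so a positive bundle:dataType interaction
#' means the actual data gain coherence over exposure faster than the
#' jittered null.
#'
#' @param actualSeries,surrogateSeries data.frames with \code{participant},
#'   \code{bundle}, response column; designs must match on
#'   participant-bundle pairs.
#' @param response response column name (default "itcWord").
#' @return as [fitLearningLMM()], plus \code{interaction} (estimate, se, p of
#'   bundle:dataType).
#' @export
surrogateTimecourse <- function(actualSeries, surrogateSeries,
                                response = "itcWord") {
  need <- c("participant", "bundle", response)
  stopifnot(all(need %in% names(actualSeries)),
            all(need %in% names(surrogateSeries)))
  keyA <- paste(actualSeries$participant, actualSeries$bundle)
  keyS <- paste(surrogateSeries$participant, surrogateSeries$bundle)
  if (!setequal(keyA, keyS))
    stop("actual and surrogate series must cover the same participant x bundle design")
  both <- rbind(
    cbind(actualSeries[need], dataType = "actual"),
    cbind(surrogateSeries[need], dataType = "surrogate"))
  both$dataType <- stats::relevel(factor(both$dataType), ref = "surrogate")
  both$participant <- factor(both$participant)
  data <- both[!is.na(both[[response]]), , drop = FALSE]
  fml <- stats::as.formula(paste(response,
                                 "~ bundle * dataType + (1 | participant)"))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  rep <- .lmmReport(fit, data, deparse(fml))
  co <- summary(fit)$coefficients
  irow <- grep("^bundle:dataType", rownames(co))
  rep$interaction <- list(estimate = co[irow, "Estimate"],
                          se = co[irow, "Std. Error"],
                          p = co[irow, "Pr(>|t|)"])
  rep
}
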