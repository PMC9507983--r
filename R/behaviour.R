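#' Score the familiarity rating task
#'
#' Per participant: mean rating per category and the composite rating score,
#' mean(word ratings) minus the mean of the pooled partword and nonword
#' ratings (with 4 + 4 foils this equals the mean of the two foil-category
#' means). The score is bounded in [-3, 3] on the 1-4 scale. Participants
#' who pressed a single key throughout are flagged via zero response
#' variance. Incomplete 12-trial sets are scored with a warning.
#'
#' @param trials data.frame: \code{participant}, \code{category}
#'   ("word"/"partword"/"nonword"), \code{rating} (integer 1-4).
#' @return data.frame per participant: \code{meanWord}, \code{meanPartword},
#'   \code{meanNonword}, \code{ratingScore}, \code{zeroVariance}.
#' @export
scoreRating <- function(trials) {
  stopifnot(all(c("participant", "category", "rating") %in% names(trials)))
  if (any(trials$rating < 1 | trials$rating > 4))
    stop("ratings must lie on the 1-4 scale")
  bad <- names(which(table(trials$participant) != 12L))
  if (length(bad))
    warning("participant(s) without a complete 12-trial set: ",
            paste(bad, collapse = ", "))
  out <- lapply(split(trials, trials$participant), function(d) {
    mw <- mean(d$rating[d$category == "word"])
    mp <- mean(d$rating[d$category == "partword"])
    mn <- mean(d$rating[d$category == "nonword"])
    data.frame(participant = d$participant[1L], meanWord = mw,
               meanPartword = mp, meanNonword = mn,
               ratingScore = mw - mean(d$rating[d$category != "word"]),
               zeroVariance = stats::var(d$rating) == 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score the 2AFC recognition task
#'
#' Per-participant accuracy (percent correct) and, across participants, a
#' one-sample t-test of mean accuracy against the 50% chance level with
#' Cohen's d.
#'
#' @param trials data.frame: \code{participant}, \code{correct} (logical).
#' @return list: \code{scores} (participant, nTrials, accuracy in %) and
#'   \code{testVsChance} (t, df, p, cohenD, mean, sd) — the group test is
#'   NULL with fewer than 2 participants.
#' @export
scoreAFC <- function(trials) {
  stopifnot(all(c("participant", "correct") %in% names(trials)))
  if (!nrow(trials)) stop("no 2AFC trials to score")
  scores <- do.call(rbind, lapply(split(trials, trials$participant),
    function(d) data.frame(participant = d$participant[1L],
                           nTrials = nrow(d),
                           accuracy = 100 * mean(d$correct))))
  rownames(scores) <- NULL
  test <- NULL
  if (nrow(scores) >= 2L && stats::sd(scores$accuracy) > 0) {
    tt <- stats::t.test(scores$accuracy, mu = 50)
    test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 cohenD = (mean(scores$accuracy) - 50) / stats::sd(scores$accuracy),
                 mean = mean(scores$accuracy), sd = stats::sd(scores$accuracy))
  }
  list(scores = scores, testVsChance = test)
}

# match presses to targets within one (participant, stream):
# a press within (0, window] s after a target onset is a hit for the nearest
# preceding unconsumed target (each target consumes at most one press, the
# earliest in-window press wins); all other presses are false alarms.
.matchPresses <- function(targetOnsets, pressTimes, windowSec) {
  nT <- length(targetOnsets)
  assigned <- rep(NA_integer_, nT)           # press index per target
  isFA <- logical(length(pressTimes))
  for (ip in seq_along(pressTimes)) {
    p <- pressTimes[ip]
    cand <- which(is.na(assigned) &
                  p - targetOnsets > 0 & p - targetOnsets <= windowSec)
    if (length(cand)) {
      tgt <- cand[which.max(targetOnsets[cand])]   # nearest preceding target
      assigned[tgt] <- ip
    } else {
      isFA[ip] <- TRUE
    }
  }
  list(assigned = assigned, isFA = isFA)
}

#' Score the target-detection task
#'
#' Classifies every press as a hit (within the response window after an
#' unconsumed target; 0-1400 ms in child mode, 0-1200 ms in adult mode,
#' exclusive of 0) or a false alarm, then summarises per participant: mean
#' RT of correct responses per target syllable position (S1, S2, S3), the RT
#' priming effect (S1 - S3) / S1 (proportional facilitation, invariant to
#' baseline RT scale), the hit rate (hits / total targets) and the
#' normalised false-alarm rate (false alarms / total targets, equating task
#' lengths across protocols).
#'
#' @param targets data.frame: \code{participant}, \code{stream},
#'   \code{position} (1-3), \code{onset} (s).
#' @param presses data.frame: \code{participant}, \code{stream}, \code{time}
#'   (s); every press, target-related or stray.
#' @param mode "child" (1400 ms window) or "adult" (1200 ms).
#' @return data.frame per participant: \code{nTargets}, \code{hits},
#'   \code{hitRate}, \code{falseAlarms}, \code{normalisedFA},
#'   \code{rtS1}, \code{rtS2}, \code{rtS3} (ms; NA with a warning if a
#'   position has no hits), \code{rtPriming}.
#' @export
scoreDetection <- function(targets, presses, mode = c("child", "adult")) {
  mode <- match.arg(mode)
  windowSec <- if (mode == "child") 1.4 else 1.2
  stopifnot(all(c("participant", "stream", "position", "onset") %in%
                names(targets)),
            all(c("participant", "stream", "time") %in% names(presses)))
  if (any(presses$time < 0)) stop("press times must be non-negative")
  out <- lapply(split(targets, targets$participant), function(tp) {
    pid <- tp$participant[1L]
    pp <- presses[presses$participant == pid, , drop = FALSE]
    hitsByPos <- list(`1` = numeric(0), `2` = numeric(0), `3` = numeric(0))
    nHit <- 0L; nFA <- 0L
    for (s in unique(tp$stream)) {
      ts <- tp[tp$stream == s, , drop = FALSE]
      ps <- sort(pp$time[pp$stream == s])
      m <- .matchPresses(ts$onset, ps, windowSec)
      hit <- !is.na(m$assigned)
      nHit <- nHit + sum(hit)
      nFA <- nFA + sum(m$isFA)
      for (i in which(hit)) {
        rt <- 1000 * (ps[m$assigned[i]] - ts$onset[i])
        key <- as.character(ts$position[i])
        hitsByPos[[key]] <- c(hitsByPos[[key]], rt)
      }
    }
    rts <- vapply(hitsByPos, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1L))
    if (anyNA(rts))
      warning("participant ", pid, ": no hits in position(s) ",
              paste(names(rts)[is.na(rts)], collapse = ", "))
    nT <- nrow(tp)
    priming <- if (!is.na(rts[1L]) && !is.na(rts[3L]) && rts[1L] > 0)
      (rts[1L] - rts[3L]) / rts[1L] else NA_real_
    data.frame(participant = pid, nTargets = nT, hits = nHit,
               hitRate = nHit / nT, falseAlarms = nFA,
               normalisedFA = nFA / nT,
               rtS1 = rts[1L], rtS2 = rts[2L], rtS3 = rts[3L],
               rtPriming = priming)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeated-measures ANOVA with linear contrast
#'
#' One within-subject factor, optional between-subject factors, fit with
#' \code{stats::aov} error strata. Reports F, dfs, p and partial eta squared
#' per effect, plus the linear contrast across the ordered within-factor
#' levels computed from per-participant contrast scores (one-sample t,
#' reported as F with 1 numerator df).
#'
#' @param data long data.frame, one row per participant x within-level (cell
#'   means).
#' @param dv response column name.
#' @param within within-subject factor column; \code{withinOrder} gives the
#'   ordered levels for the linear contrast (default: factor level order).
#' @param id participant column.
#' @param between optional character vector of between-subject factor
#'   columns.
#' @param withinOrder optional character vector ordering the within levels.
#' @return list: \code{effects} (data.frame term/F/df1/df2/p/partialEta2),
#'   \code{linearContrast} (F, df1, df2, p, partialEta2) or NULL when the
#'   within factor has fewer than 3 levels.
#' @export
rmAnova <- function(data, dv, within, id, between = NULL,
                    withinOrder = NULL) {
  stopifnot(all(c(dv, within, id, between) %in% names(data)))
  d <- data
  d$.id <- factor(d[[id]])
  d$.w <- factor(d[[within]],
                 levels = if (is.null(withinOrder)) unique(d[[within]])
                          else withinOrder)
  for (b in between) d[[b]] <- factor(d[[b]])
  # listwise deletion of participants with missing cells
  complete <- tapply(!is.na(d[[dv]]), d$.id, all)
  dropIds <- names(complete)[!complete]
  if (length(dropIds)) {
    message("participants dropped for missing cells: ",
            paste(dropIds, collapse = ", "))
    d <- d[!(as.character(d$.id) %in% dropIds), , drop = FALSE]
    d$.id <- droplevels(d$.id)
  }
  if (stats::var(d[[dv]]) == 0) {
    # constant response: every effect is exactly null, avoid 0/0 F ratios
    terms <- c(within, between,
               if (length(between)) paste(within, between, sep = ":"))
    return(list(effects = data.frame(term = terms, F = 0, df1 = NA, df2 = NA,
                                     p = 1, partialEta2 = 0,
                                     stringsAsFactors = FALSE),
                linearContrast = list(F = 0, df1 = 1L, df2 = NA, p = 1,
                                      partialEta2 = 0)))
  }
  bterm <- if (length(between)) paste(between, collapse = " * ") else NULL
  rhs <- if (is.null(bterm)) ".w" else paste0(".w * ", bterm)
  fml <- stats::as.formula(paste(dv, "~", rhs, "+ Error(.id/.w)"))
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)
  eff <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    resIdx <- which(terms == "Residuals")
    if (!length(resIdx)) next
    ssErr <- tab[resIdx, "Sum Sq"]
    dfErr <- tab[resIdx, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), resIdx)) {
      eff[[length(eff) + 1L]] <- data.frame(
        term = gsub("\\.w", within, terms[i]),
        F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = dfErr,
        p = tab[i, "Pr(>F)"],
        partialEta2 = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ssErr),
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, eff)
  linear <- NULL
  lev <- levels(d$.w)
  if (length(lev) >= 3L) {
    w <- seq_along(lev) - mean(seq_along(lev))   # ordered linear weights
    wide <- tapply(d[[dv]], list(d$.id, d$.w), mean)
    ell <- as.numeric(wide[, lev, drop = FALSE] %*% w)
    ell <- ell[!is.na(ell)]
    tt <- stats::t.test(ell, mu = 0)
    Fv <- unname(tt$statistic)^2
    df2 <- unname(tt$parameter)
    linear <- list(F = Fv, df1 = 1L, df2 = df2, p = tt$p.value,
                   partialEta2 = Fv / (Fv + df2))
  }
  list(effects = effects, linearContrast = linear)
}

#' t-test report with Cohen's d
#'
#' One-sample (against \code{mu}) or independent two-sample
#' (pooled-variance) t-test with effect size.
#'
#' @param x numeric vector.
#' @param y optional second group.
#' @param mu null value for the one-sample case (default 0).
#' @return list: t, df, p, cohenD, means.
#' @export
tTestReport <- function(x, y = NULL, mu = 0) {
  if (is.null(y)) {
    tt <- stats::t.test(x, mu = mu)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         cohenD = (mean(x) - mu) / stats::sd(x), means = mean(x))
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    n1 <- length(x); n2 <- length(y)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         cohenD = (mean(x) - mean(y)) / sp, means = c(mean(x), mean(y)))
  }
}
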