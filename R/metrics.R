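## Per-session and cohort behavioral metrics for two-stimulus tests:
## binned investigation curves, bout-duration categories, RDI,
## transitions, center/periphery occupancy, contact metrics. All metrics
## are deterministic functions of their inputs. Sessions are expected to
## have passed the 0.5-s gap merge (mergeInvestigationGaps) first, the
## same preprocessing applied to experimental and simulated logs.

.binStarts <- function(testDuration, binWidth) {
  nBins <- ceiling(testDuration / binWidth)
  (seq_len(nBins) - 1) * binWidth
}

## Internal: per-bin overlap of intervals [onset, offset) with half-open
## bins [t, t + binWidth).
.binOverlap <- function(onset, offset, binWidth, nBins) {
  vals <- numeric(nBins)
  for (j in seq_along(onset)) {
    i1 <- max(1L, floor(onset[j] / binWidth) + 1L)
    i2 <- min(nBins, floor((offset[j] - 1e-12) / binWidth) + 1L)
    if (i2 < i1) next
    for (i in i1:i2) {
      lo <- (i - 1L) * binWidth
      vals[i] <- vals[i] +
        max(0, min(offset[j], lo + binWidth) - max(onset[j], lo))
    }
  }
  vals
}

#' Binned investigation time per stimulus
#'
#' Total investigation time of each stimulus falling inside consecutive
#' half-open time bins `[t, t + binWidth)` covering the test. The
#' per-stimulus sum over bins equals the total investigation time.
#'
#' @param session a gap-merged [BehaviorSession-class].
#' @param binWidth bin width in seconds (default 20, the convention for
#'   investigation-time curves).
#' @return `data.frame` with columns `stimulus`, `binStart`, `value`
#'   (seconds of investigation in the bin), covering every bin and both
#'   stimuli.
#' @examples
#' s <- behaviorSession("m1", data.frame(stimulus = "stim1",
#'                                       onset = 10, offset = 50))
#' binnedInvestigationTime(s)  # 10, 20, 10 s in the first three bins
#' @export
binnedInvestigationTime <- function(session, binWidth = 20) {
  stopifnot(is(session, "BehaviorSession"), binWidth > 0)
  starts <- .binStarts(testDuration(session), binWidth)
  ev <- events(session)
  out <- lapply(.STIMULI, function(stim) {
    sub <- ev[ev$stimulus == stim, , drop = FALSE]
    data.frame(stimulus = stim, binStart = starts,
               value = .binOverlap(sub$onset, sub$offset, binWidth,
                                   length(starts)))
  })
  do.call(rbind, out)
}

#' Catalog investigation bouts with duration categories
#'
#' Labels every investigation bout as short (duration < `shortMax`),
#' intermediate (`shortMax` to `longMin`, boundaries inclusive), or long
#' (duration > `longMin`). Bouts starting during the final minute of the
#' test are dropped by default, because the test end truncates them
#' toward artificially short durations.
#'
#' @param session a gap-merged [BehaviorSession-class].
#' @param shortMax upper bound (exclusive) of the short category, seconds
#'   (default 6).
#' @param longMin lower bound (exclusive) of the long category, seconds
#'   (default 19).
#' @param excludeLastMinute drop bouts with onset in the final 60 s
#'   (default `TRUE`).
#' @return `data.frame` with columns `stimulus`, `onset`, `duration`,
#'   `category` (factor short/intermediate/long).
#' @export
boutCatalog <- function(session, shortMax = 6, longMin = 19,
                        excludeLastMinute = TRUE) {
  stopifnot(is(session, "BehaviorSession"),
            shortMax > 0, longMin > 0, shortMax <= longMin)
  ev <- events(session)
  dur <- ev$offset - ev$onset
  cat <- ifelse(dur < shortMax, "short",
                ifelse(dur > longMin, "long", "intermediate"))
  out <- data.frame(stimulus = ev$stimulus, onset = ev$onset,
                    duration = dur,
                    category = factor(cat, levels = c("short",
                                      "intermediate", "long")))
  if (excludeLastMinute)
    out <- out[out$onset < testDuration(session) - 60, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled investigation time per bout category
#'
#' Credits each bout's full duration to the bin containing its onset,
#' separately per duration category and stimulus — the quantity shown as
#' per-minute pooled short/intermediate/long investigation time.
#'
#' @param catalog output of [boutCatalog()].
#' @param testDuration test length in seconds (fixes the bin count).
#' @param binWidth bin width in seconds (default 60).
#' @return `data.frame` with columns `category`, `stimulus`, `binStart`,
#'   `value`, complete over all combinations.
#' @export
pooledCategoryTime <- function(catalog, testDuration = 300, binWidth = 60) {
  starts <- .binStarts(testDuration, binWidth)
  grid <- expand.grid(category = c("short", "intermediate", "long"),
                      stimulus = .STIMULI, binStart = starts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- 0
  if (nrow(catalog)) {
    bin <- pmin(length(starts) - 1L, floor(catalog$onset / binWidth))
    key <- paste(catalog$category, catalog$stimulus, bin * binWidth)
    sums <- tapply(catalog$duration, key, sum)
    gkey <- paste(grid$category, grid$stimulus, grid$binStart)
    hit <- match(gkey, names(sums))
    grid$value[!is.na(hit)] <- as.numeric(sums[hit[!is.na(hit)]])
  }
  grid[order(grid$category, grid$stimulus, grid$binStart), ]
}

#' Relative differential investigation (RDI)
#'
#' The absolute difference in investigation time between the two stimuli
#' divided by their sum: 0 for equal investigation, 1 for exclusive
#' investigation of one stimulus. Symmetric under stimulus relabeling.
#'
#' @param timeStim1,timeStim2 total investigation times in seconds.
#' @return Value in `[0, 1]`; `NA` with a warning when both times are
#'   zero (the index is undefined).
#' @examples
#' rdi(30, 10)  # 0.5
#' @export
rdi <- function(timeStim1, timeStim2) {
  stopifnot(timeStim1 >= 0, timeStim2 >= 0)
  tot <- timeStim1 + timeStim2
  if (length(tot) == 1L && tot == 0) {
    warning("RDI undefined: no investigation of either stimulus")
    return(NA_real_)
  }
  out <- abs(timeStim1 - timeStim2) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Stimulus-transition times
#'
#' A transition is the onset of a bout directed at a different stimulus
#' than the previous bout. By convention the first bout of the session
#' counts as a transition (the beginning of investigation of a new
#' stimulus); set `countFirstBout = FALSE` to count only switches.
#'
#' @param session a gap-merged [BehaviorSession-class].
#' @param countFirstBout include the first bout (default `TRUE`).
#' @return Numeric vector of transition onset times in seconds.
#' @export
transitionTimes <- function(session, countFirstBout = TRUE) {
  ev <- events(session)
  if (!nrow(ev)) return(numeric())
  switch_ <- c(countFirstBout,
               ev$stimulus[-1L] != ev$stimulus[-nrow(ev)])
  ev$onset[switch_]
}

#' Binned stimulus-transition rate
#'
#' Number of stimulus transitions per time bin (transitions/bin).
#'
#' @param session a gap-merged [BehaviorSession-class].
#' @param binWidth bin width in seconds (default 20).
#' @param countFirstBout passed to [transitionTimes()].
#' @return `data.frame` with columns `binStart`, `count`.
#' @export
transitionRate <- function(session, binWidth = 20, countFirstBout = TRUE) {
  stopifnot(binWidth > 0)
  starts <- .binStarts(testDuration(session), binWidth)
  tt <- transitionTimes(session, countFirstBout)
  bin <- pmin(length(starts) - 1L, floor(tt / binWidth))
  counts <- tabulate(bin + 1L, nbins = length(starts))
  data.frame(binStart = starts, count = counts)
}

#' Mean bout duration per bin
#'
#' Per bin, the mean duration of bouts whose onset falls in that bin.
#' Bins without any bout onset are `NA` (undefined), not zero, and
#' propagate as missing into cohort means.
#'
#' @param session a gap-merged [BehaviorSession-class].
#' @param binWidth bin width in seconds (default 60).
#' @return `data.frame` with columns `binStart`, `meanDuration`.
#' @export
meanBoutDurationPerBin <- function(session, binWidth = 60) {
  starts <- .binStarts(testDuration(session), binWidth)
  ev <- events(session)
  out <- data.frame(binStart = starts, meanDuration = NA_real_)
  if (nrow(ev)) {
    bin <- pmin(length(starts) - 1L, floor(ev$onset / binWidth))
    m <- tapply(ev$offset - ev$onset, bin, mean)
    out$meanDuration[as.integer(names(m)) + 1L] <- as.numeric(m)
  }
  out
}

## Internal: mean and SEM (sample SD / sqrt(n)) across rows of a matrix,
## NA-aware (mean over available subjects).
.meanSem <- function(mat) {
  n <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(mat, 2, sd, na.rm = TRUE)
  list(mean = mu, sem = sdv / sqrt(pmax(n, 1)))
}

#' Cohort summary curves
#'
#' Mean and SEM across subjects of the binned investigation-time curves
#' (per stimulus), the binned transition-rate curve, the per-category
#' pooled-time series, and the subjects-by-bins investigation heatmap
#' matrices (rows ordered by subject identifier). These summary curves
#' are the cohort-level description of the test and the target surface
#' for model fitting.
#'
#' @param sessions list of gap-merged [BehaviorSession-class] objects
#'   sharing one `testDuration`.
#' @param binWidth investigation/transition bin width in seconds
#'   (default 20).
#' @param categoryBinWidth pooled-category bin width (default 60).
#' @param countFirstBout passed to [transitionRate()].
#' @param categories compute the per-category pooled-time curves
#'   (default `TRUE`; the curves are skipped when only the
#'   investigation and transition surfaces are needed, e.g. inside
#'   fitting loops).
#' @param ... passed to [boutCatalog()].
#' @return A list of class `"SummaryCurves"`: `investigation` and
#'   `transitionRate` (`mean`/`sem` per bin), `categoryTime`, `heatmap`
#'   (list of matrices per stimulus), `rdi` (per-subject values), `n`,
#'   `binWidth`, `testDuration`.
#' @export
cohortSummary <- function(sessions, binWidth = 20, categoryBinWidth = 60,
                          countFirstBout = TRUE, categories = TRUE, ...) {
  stopifnot(length(sessions) >= 1)
  durs <- vapply(sessions, testDuration, numeric(1))
  if (length(unique(durs)) != 1L)
    stop("sessions have mixed test durations")
  td <- durs[[1L]]
  ids <- vapply(sessions, subjectId, character(1))
  ord <- order(ids)
  sessions <- sessions[ord]; ids <- ids[ord]
  n <- length(sessions)
  starts <- .binStarts(td, binWidth)

  inv <- lapply(sessions, binnedInvestigationTime, binWidth = binWidth)
  heat <- lapply(setNames(.STIMULI, .STIMULI), function(stim) {
    m <- t(vapply(inv, function(d) d$value[d$stimulus == stim],
                  numeric(length(starts))))
    dimnames(m) <- list(ids, starts)
    m
  })
  invCurves <- do.call(rbind, lapply(.STIMULI, function(stim) {
    ms <- .meanSem(heat[[stim]])
    data.frame(stimulus = stim, binStart = starts,
               mean = ms$mean, sem = ms$sem)
  }))

  trMat <- t(vapply(sessions, function(s)
    transitionRate(s, binWidth, countFirstBout)$count,
    numeric(length(starts))))
  trMS <- .meanSem(trMat)
  trCurve <- data.frame(binStart = starts, mean = trMS$mean,
                        sem = trMS$sem)

  catCurve <- NULL
  if (categories) {
    catTabs <- lapply(sessions, function(s)
      pooledCategoryTime(boutCatalog(s, ...), testDuration = td,
                         binWidth = categoryBinWidth))
    catMat <- vapply(catTabs, function(d) d$value,
                     numeric(nrow(catTabs[[1L]])))
    catMS <- .meanSem(t(catMat))
    catCurve <- catTabs[[1L]][, c("category", "stimulus", "binStart")]
    catCurve$mean <- catMS$mean
    catCurve$sem <- catMS$sem
  }

  totals <- vapply(sessions, function(s) {
    ev <- events(s)
    c(sum(ev$offset[ev$stimulus == "stim1"] -
            ev$onset[ev$stimulus == "stim1"]),
      sum(ev$offset[ev$stimulus == "stim2"] -
            ev$onset[ev$stimulus == "stim2"]))
  }, numeric(2))
  rdis <- suppressWarnings(rdi(totals[1, ], totals[2, ]))

  structure(list(investigation = invCurves, transitionRate = trCurve,
                 categoryTime = catCurve, heatmap = heat,
                 rdi = setNames(rdis, ids), n = n, binWidth = binWidth,
                 testDuration = td),
            class = "SummaryCurves")
}

#' @export
print.SummaryCurves <- function(x, ...) {
  cat(sprintf("SummaryCurves: n = %d subjects, %.0f-s test, %g-s bins\n",
              x$n, x$testDuration, x$binWidth))
  cat(sprintf("  mean RDI %.3f; peak mean transition rate %.2f/bin at %g s\n",
              mean(x$rdi, na.rm = TRUE), max(x$transitionRate$mean),
              x$transitionRate$binStart[which.max(x$transitionRate$mean)]))
  invisible(x)
}

#' Center/periphery occupancy ratio
#'
#' Time spent in the arena's center region divided by time spent in the
#' periphery, with each inter-sample interval credited to the zone of
#' its starting sample. The center is the concentric region holding
#' `centerFraction` of the arena area (see [arenaSpec()]); a higher
#' ratio reflects lower anxiety.
#'
#' @param positions `data.frame` with columns `time`, `x`, `y`, arena
#'   coordinates with origin at the arena corner.
#' @param arena an [arenaSpec()].
#' @return Non-negative ratio; `Inf` with a warning when the trajectory
#'   never leaves the center (the ratio is unbounded).
#' @export
centerPeripheryRatio <- function(positions, arena) {
  stopifnot(inherits(arena, "ArenaSpec"), nrow(positions) >= 2)
  scale <- sqrt(arena$centerFraction)
  hw <- arena$width * scale / 2
  hh <- arena$height * scale / 2
  cx <- arena$width / 2; cy <- arena$height / 2
  inCenter <- abs(positions$x - cx) <= hw & abs(positions$y - cy) <= hh
  dt <- diff(positions$time)
  centerT <- sum(dt[inCenter[-length(inCenter)]])
  periT <- sum(dt) - centerT
  if (periT == 0) {
    warning("trajectory never leaves the center: ratio unbounded")
    return(Inf)
  }
  centerT / periT
}

#' Free-interaction contact metrics
#'
#' Total contact time and its split into short and long interactions.
#' A contact of duration below `threshold` is short; at or above it,
#' long (so the two classes always sum to the total).
#'
#' @param contacts gap-merged contact `data.frame` with columns
#'   `onset`, `offset` (see [readContactLog()]).
#' @param threshold class boundary in seconds (default 6).
#' @return List with elements `total`, `short`, `long` (seconds) and
#'   `nContacts`.
#' @export
contactMetrics <- function(contacts, threshold = 6) {
  dur <- contacts$offset - contacts$onset
  stopifnot(all(dur > 0) || !length(dur))
  list(total = sum(dur),
       short = sum(dur[dur < threshold]),
       long = sum(dur[dur >= threshold]),
       nContacts = length(dur))
}
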