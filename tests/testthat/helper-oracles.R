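## Independent brute-force oracles and fixture builders used across the
## suite. Oracles deliberately share no code with the implementation
## paths they check.

## A random valid session with times on a 1-ms grid (so discretization
## oracles are exact), sorted, non-overlapping across stimuli.
randomSession <- function(seed, nEvents = 20, testDuration = 300,
                          maxGapS = 8, maxDurS = 12) {
  set.seed(seed)
  onset <- numeric(nEvents); offset <- numeric(nEvents)
  stim <- character(nEvents)
  t <- 0
  n <- 0L
  for (i in seq_len(nEvents)) {
    t <- t + round(runif(1, 0.001, maxGapS), 3)
    dur <- round(runif(1, 0.05, maxDurS), 3)
    if (t + dur > testDuration) break
    n <- n + 1L
    onset[n] <- t; offset[n] <- t + dur
    stim[n] <- sample(c("stim1", "stim2"), 1)
    t <- t + dur
  }
  behaviorSession(sprintf("rand%03d", seed),
                  data.frame(stimulus = stim[seq_len(n)],
                             onset = onset[seq_len(n)],
                             offset = offset[seq_len(n)]),
                  testDuration = testDuration)
}

## O(n^2) pairwise-fusion gap-merge oracle, run to fixpoint: repeatedly
## scan all same-stimulus pairs and fuse the first immediate-neighbour
## pair whose gap is below the threshold and free of other-stimulus
## events.
oracleMerge <- function(ev, maxGap = 0.5) {
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  repeat {
    fused <- FALSE
    for (i in seq_len(nrow(ev))) {
      if (fused) break
      for (j in seq_len(nrow(ev))) {
        if (i == j || ev$stimulus[i] != ev$stimulus[j]) next
        if (ev$onset[j] < ev$offset[i]) next
        gap <- ev$onset[j] - ev$offset[i]
        ## immediate same-stimulus neighbour only
        between <- ev$stimulus == ev$stimulus[i] &
          ev$onset >= ev$offset[i] & ev$offset <= ev$onset[j]
        between[c(i, j)] <- FALSE
        if (any(between)) next
        other <- ev$stimulus != ev$stimulus[i] &
          ev$onset < ev$onset[j] & ev$offset > ev$offset[i]
        if (gap < maxGap && !any(other)) {
          ev$offset[i] <- ev$offset[j]
          ev <- ev[-j, , drop = FALSE]
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## 1-ms discretization oracle for binned investigation time: samples
## the session on a millisecond grid and accumulates per-bin coverage.
oracleBinnedTime <- function(session, binWidth = 20, dt = 0.001) {
  td <- testDuration(session)
  grid <- seq(0, td - dt, by = dt) + dt / 2
  ev <- events(session)
  nBins <- ceiling(td / binWidth)
  out <- list()
  for (stim in c("stim1", "stim2")) {
    sub <- ev[ev$stimulus == stim, , drop = FALSE]
    covered <- rep(FALSE, length(grid))
    for (k in seq_len(nrow(sub)))
      covered <- covered |
        (grid >= sub$onset[k] & grid < sub$offset[k])
    bin <- pmin(nBins - 1L, floor(grid / binWidth))
    out[[stim]] <- vapply(seq_len(nBins) - 1L, function(b)
      sum(covered[bin == b]) * dt, numeric(1))
  }
  out
}

## Run-length-encoding oracle for the transition count.
oracleTransitionCount <- function(session, countFirstBout = TRUE) {
  stim <- events(session)$stimulus
  if (!length(stim)) return(0L)
  length(rle(stim)$values) - 1L + as.integer(countFirstBout)
}

## Build a SummaryCurves skeleton directly (for objective tests).
makeCurves <- function(stim1, stim2, trans, binWidth = 20) {
  nb <- length(stim1)
  starts <- (seq_len(nb) - 1) * binWidth
  structure(list(
    investigation = data.frame(
      stimulus = rep(c("stim1", "stim2"), each = nb),
      binStart = rep(starts, 2), mean = c(stim1, stim2),
      sem = 0),
    transitionRate = data.frame(binStart = starts, mean = trans,
                                sem = 0),
    categoryTime = NULL, heatmap = NULL, rdi = NULL, n = 1L,
    binWidth = binWidth, testDuration = nb * binWidth),
    class = "SummaryCurves")
}

## First-minute cohort summaries used by the regime-contrast checks.
firstMinuteContrast <- function(cohort) {
  rdis <- vapply(cohort, function(s) {
    b <- binnedInvestigationTime(s)
    t1 <- sum(b$value[b$stimulus == "stim1" & b$binStart < 60])
    t2 <- sum(b$value[b$stimulus == "stim2" & b$binStart < 60])
    if (t1 + t2 == 0) NA_real_ else abs(t1 - t2) / (t1 + t2)
  }, numeric(1))
  trans <- vapply(cohort, function(s)
    sum(transitionTimes(s) < 60), numeric(1))
  list(meanRdi = mean(rdis, na.rm = TRUE), meanTransitions = mean(trans))
}
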