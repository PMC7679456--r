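## Seeded synthetic-data generators. Every generator is a pure function
## of (parameters, seed) and returns its ground truth alongside the
## data, so each pipeline stage can be tested against known answers
## without animal recordings. Event logs come from alternating renewal
## processes — a deliberately different mechanism from the Markov model,
## so metric tests are not circular with simulator tests.

#' Synthetic-session regime specification
#'
#' Loads one of the shipped two-phase renewal regimes (`"mouse_like"`,
#' `"rat_like"`, `"uniform"`), or builds a custom one. A regime gives,
#' per phase (early = first 60 s, late = remainder) and per stimulus, a
#' bout-initiation hazard (bouts/s of non-investigation time) and a mean
#' bout duration (s). The default numeric values live in the shipped
#' `regimes.json` configuration.
#'
#' @param name shipped regime name, or `NULL` when `phases` is given.
#' @param phases custom regime: a list with elements `early` and `late`,
#'   each `list(hazard = c(stim1=, stim2=), meanBout = c(stim1=, stim2=))`.
#' @return A list of class `"RegimeSpec"` with elements `name`, `early`,
#'   `late`, `phaseBoundary` (60 s).
#' @export
regimeSpec <- function(name = c("mouse_like", "rat_like", "uniform"),
                       phases = NULL) {
  if (is.null(phases)) {
    name <- match.arg(name)
    cfg <- jsonlite::read_json(system.file("extdata", "regimes.json",
                                           package = "socialMarkov"),
                               simplifyVector = TRUE)
    phases <- cfg[[name]]
  } else {
    name <- if (is.character(name) && length(name) == 1L) name else "custom"
  }
  for (ph in c("early", "late")) {
    stopifnot(all(unlist(phases[[ph]]$hazard) >= 0),
              all(unlist(phases[[ph]]$meanBout) > 0))
  }
  structure(list(name = name, early = phases$early, late = phases$late,
                 phaseBoundary = 60),
            class = "RegimeSpec")
}

## Internal: one stimulus's bout stream over [0, duration) as an
## alternating renewal process with phase-dependent rates: exponential
## waits at the phase hazard, exponential bout durations at the phase
## mean. A zero hazard in a phase skips the phase.
.renewalStream <- function(regime, stim, duration) {
  onset <- numeric(); offset <- numeric()
  t <- 0
  repeat {
    phase <- if (t < regime$phaseBoundary) regime$early else regime$late
    hz <- unlist(phase$hazard)[[stim]]
    mb <- unlist(phase$meanBout)[[stim]]
    if (hz <= 0) {
      ## no initiations this phase: jump to next phase or stop
      if (t < regime$phaseBoundary) { t <- regime$phaseBoundary; next }
      break
    }
    wait <- rexp(1, rate = hz)
    ## phase change during the wait: re-draw from the boundary
    if (t < regime$phaseBoundary && t + wait > regime$phaseBoundary) {
      t <- regime$phaseBoundary
      next
    }
    t <- t + wait
    if (t >= duration) break
    dur <- rexp(1, rate = 1 / mb)
    off <- min(t + dur, duration)
    onset <- c(onset, t); offset <- c(offset, off)
    t <- off
  }
  data.frame(stimulus = rep(stim, length(onset)), onset = onset,
             offset = offset)
}

#' Generate a synthetic investigation session
#'
#' Draws one two-stimulus session from a two-phase alternating renewal
#' process (see [regimeSpec()]): per stimulus, exponential inter-bout
#' waits at the phase hazard and exponential bout durations at the phase
#' mean. Cross-stimulus overlaps are resolved by truncating the
#' later-starting bout to begin at the earlier bout's offset (dropping
#' it if nothing remains), since the subject investigates one chamber at
#' a time.
#'
#' @param regime a [regimeSpec()].
#' @param testDuration session length in seconds (default 300).
#' @param seed integer seed.
#' @param subjectId identifier for the session.
#' @return List with elements `session` (a [BehaviorSession-class]) and
#'   `groundTruth` (the generating regime, seed, and the expected
#'   per-stimulus occupancy fraction `hazard * meanBout /
#'   (1 + hazard * meanBout)` per phase).
#' @export
genEventLog <- function(regime, testDuration = 300, seed = 1,
                        subjectId = "synth1") {
  stopifnot(inherits(regime, "RegimeSpec"))
  ev <- withSeed(seed, {
    s1 <- .renewalStream(regime, "stim1", testDuration)
    s2 <- .renewalStream(regime, "stim2", testDuration)
    rbind(s1, s2)
  })
  ev <- ev[order(ev$onset, ev$offset), , drop = FALSE]
  ## resolve cross-stimulus overlap by truncation
  if (nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    lastOff <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$onset[i] < lastOff) ev$onset[i] <- lastOff
      if (ev$offset[i] - ev$onset[i] <= 1e-9) { keep[i] <- FALSE; next }
      lastOff <- ev$offset[i]
    }
    ev <- ev[keep, , drop = FALSE]
  }
  occ <- lapply(list(early = regime$early, late = regime$late),
                function(ph) {
    hz <- unlist(ph$hazard); mb <- unlist(ph$meanBout)
    hz * mb / (1 + hz * mb)
  })
  session <- behaviorSession(subjectId, ev, testDuration = testDuration,
                             groupTag = regime$name,
                             rngSeed = as.integer(seed))
  list(session = session,
       groundTruth = list(regime = regime, seed = seed,
                          expectedOccupancy = occ))
}

#' Generate a synthetic piezo trace with injected movement bursts
#'
#' White Gaussian noise plus Gaussian-windowed 40-Hz bursts (inside the
#' 10-100 Hz analysis passband) at stated times and amplitude, sampled
#' at the acquisition rate.
#'
#' @param duration trace length in seconds.
#' @param burstTimes burst center times in seconds.
#' @param burstAmplitude peak amplitude of each burst (sensor units).
#' @param noiseSd standard deviation of the background noise.
#' @param seed integer seed.
#' @param samplingRate Hz (default 20000).
#' @param burstWidth Gaussian envelope SD in seconds (default 0.05).
#' @return List with `trace` (a [PiezoTrace-class]) and `groundTruth`
#'   (burst times, amplitude, noise level, seed).
#' @export
genPiezoTrace <- function(duration, burstTimes = numeric(),
                          burstAmplitude = 0.6, noiseSd = 0.05,
                          seed = 1, samplingRate = 20000,
                          burstWidth = 0.05) {
  stopifnot(all(burstTimes >= 0), all(burstTimes <= duration))
  n <- round(duration * samplingRate)
  x <- withSeed(seed, if (noiseSd > 0) rnorm(n, sd = noiseSd)
                      else numeric(n))
  tt <- (seq_len(n) - 1) / samplingRate
  for (bt in burstTimes) {
    idx <- which(abs(tt - bt) < 4 * burstWidth)
    env <- exp(-((tt[idx] - bt)^2) / (2 * burstWidth^2))
    x[idx] <- x[idx] +
      burstAmplitude * env * sin(2 * pi * 40 * (tt[idx] - bt))
  }
  list(trace = piezoTrace(x, samplingRate),
       groundTruth = list(burstTimes = burstTimes,
                          burstAmplitude = burstAmplitude,
                          noiseSd = noiseSd, seed = seed))
}

#' Generate a synthetic arena trajectory with known center occupancy
#'
#' A two-zone dwell process: the animal alternates between the arena
#' center and the periphery with exponential dwell times whose means are
#' chosen so the expected fraction of time in the center equals the
#' target. Positions are sampled on a regular grid at fixed
#' representative points of each zone.
#'
#' @param arena an [arenaSpec()].
#' @param centerFractionTarget expected center-occupancy fraction in
#'   `[0, 1]`.
#' @param duration trajectory length in seconds.
#' @param seed integer seed.
#' @param dt sampling interval in seconds (default 0.1).
#' @param meanCycle mean center + periphery cycle length in seconds
#'   (default 10).
#' @return List with `positions` (`data.frame` of `time`, `x`, `y`) and
#'   `groundTruth` (target fraction, realized fraction, seed).
#' @export
genPositions <- function(arena, centerFractionTarget, duration,
                         seed = 1, dt = 0.1, meanCycle = 10) {
  stopifnot(inherits(arena, "ArenaSpec"),
            centerFractionTarget >= 0, centerFractionTarget <= 1)
  tt <- seq(0, duration, by = dt)
  cx <- arena$width / 2; cy <- arena$height / 2
  peri <- c(arena$width * 0.02, arena$height * 0.02)
  zone <- withSeed(seed, {
    if (centerFractionTarget == 0) rep(FALSE, length(tt))
    else if (centerFractionTarget == 1) rep(TRUE, length(tt))
    else {
      mC <- meanCycle * centerFractionTarget
      mP <- meanCycle * (1 - centerFractionTarget)
      z <- logical(length(tt)); t0 <- 0
      inC <- runif(1) < centerFractionTarget
      while (t0 < duration) {
        dwell <- rexp(1, rate = 1 / (if (inC) mC else mP))
        z[tt >= t0 & tt < t0 + dwell] <- inC
        t0 <- t0 + dwell
        inC <- !inC
      }
      z
    }
  })
  pos <- data.frame(time = tt,
                    x = ifelse(zone, cx, peri[1]),
                    y = ifelse(zone, cy, peri[2]))
  realized <- mean(zone[-length(zone)])
  list(positions = pos,
       groundTruth = list(centerFractionTarget = centerFractionTarget,
                          realizedFraction = realized, seed = seed))
}

#' Generate a synthetic dyadic contact log
#'
#' Renewal contact process: exponential waits between contacts at the
#' stated hazard, exponential contact durations at the stated mean.
#'
#' @param duration session length in seconds.
#' @param hazard contact-initiation rate per second (of non-contact
#'   time).
#' @param meanContact mean contact duration in seconds.
#' @param seed integer seed.
#' @return List with `contacts` (`data.frame` of `onset`, `offset`) and
#'   `groundTruth` (parameters, seed, expected total contact fraction
#'   `hazard * meanContact / (1 + hazard * meanContact)`).
#' @export
genContactLog <- function(duration, hazard, meanContact, seed = 1) {
  stopifnot(hazard >= 0, meanContact > 0)
  con <- withSeed(seed, {
    onset <- numeric(); offset <- numeric(); t <- 0
    if (hazard > 0) repeat {
      t <- t + rexp(1, rate = hazard)
      if (t >= duration) break
      off <- min(t + rexp(1, rate = 1 / meanContact), duration)
      onset <- c(onset, t); offset <- c(offset, off)
      t <- off
    }
    data.frame(onset = onset, offset = offset)
  })
  list(contacts = con,
       groundTruth = list(hazard = hazard, meanContact = meanContact,
                          seed = seed,
                          expectedFraction =
                            hazard * meanContact / (1 + hazard * meanContact)))
}
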