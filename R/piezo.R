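## Piezoelectric stimulus-movement pipeline: anti-aliased downsampling,
## 10-100 Hz Butterworth band-pass, session-max normalization, threshold
## detection of major movements, per-minute counts, and
## movement-triggered investigation analysis.

#' Preprocess a raw piezo trace
#'
#' Anti-aliased decimation of the raw recording to the analysis rate,
#' followed by a Butterworth band-pass applied forward-backward
#' (zero-phase). The band 10-100 Hz isolates body-movement energy from
#' drift and high-frequency noise.
#'
#' @param trace a [PiezoTrace-class]; its sampling rate must be an
#'   integer multiple of `targetRate` and at least twice the band's
#'   upper edge after decimation.
#' @param targetRate analysis sampling rate in Hz (default 2000).
#' @param band band-pass edges in Hz (default `c(10, 100)`).
#' @param order Butterworth design order (default 4).
#' @return A filtered [PiezoTrace-class] at `targetRate`.
#' @export
preprocessPiezo <- function(trace, targetRate = 2000,
                            band = c(10, 100), order = 4) {
  stopifnot(is(trace, "PiezoTrace"))
  fs <- samplingRate(trace)
  if (fs < 2 * targetRate)
    stop("sampling rate too low to decimate to ", targetRate, " Hz")
  q <- fs / targetRate
  if (abs(q - round(q)) > 1e-9)
    stop("sampling rate must be an integer multiple of targetRate")
  x <- signal::decimate(samples(trace), round(q), ftype = "iir")
  bf <- signal::butter(order, band / (targetRate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  piezoTrace(y, targetRate, subjectId = trace@subjectId)
}

#' Normalize a piezo trace to its session maximum
#'
#' Divides the trace by its maximum absolute value, so amplitudes are
#' fractions of the session's largest deflection; idempotent, sign
#' preserving.
#'
#' @param trace a [PiezoTrace-class]; must not be all-zero.
#' @return A [PiezoTrace-class] with maximum absolute value 1.
#' @export
normalizePiezo <- function(trace) {
  stopifnot(is(trace, "PiezoTrace"))
  m <- max(abs(samples(trace)))
  if (m == 0) stop("cannot normalize an all-zero trace")
  piezoTrace(samples(trace) / m, samplingRate(trace),
             subjectId = trace@subjectId)
}

#' Detect major movements in a normalized piezo trace
#'
#' A major movement is an excursion beyond a fraction of the session's
#' maximum absolute signal. Contiguous suprathreshold runs separated by
#' less than `minSeparation` are fused into one event. Each event is
#' reported with its peak time (`time`, the sample of largest absolute
#' amplitude — the alignment point used downstream), its first
#' threshold crossing (`onset`), and the peak amplitude.
#'
#' @param trace a normalized [PiezoTrace-class] (see [normalizePiezo()]).
#' @param threshold detection threshold as a fraction of the maximum
#'   absolute value, in (0, 1) (default 0.20; results are insensitive
#'   between 0.20 and 0.40 when movements are much larger than that).
#' @param minSeparation fusion window in seconds (default 0.5).
#' @return `data.frame` with columns `time` (s, peak), `onset` (s,
#'   first crossing), `peakAmplitude`.
#' @export
detectMajorMovements <- function(trace, threshold = 0.20,
                                 minSeparation = 0.5) {
  stopifnot(is(trace, "PiezoTrace"),
            threshold > 0, threshold < 1, minSeparation >= 0)
  x <- abs(samples(trace))
  fs <- samplingRate(trace)
  above <- x > threshold
  if (!any(above))
    return(data.frame(time = numeric(), onset = numeric(),
                      peakAmplitude = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  ## fuse runs whose gap is shorter than minSeparation
  gapSamp <- minSeparation * fs
  fusedStart <- runs$start[1L]; fusedEnd <- runs$end[1L]
  outS <- integer(); outE <- integer()
  for (i in seq_len(nrow(runs))[-1L]) {
    if (runs$start[i] - fusedEnd < gapSamp) {
      fusedEnd <- runs$end[i]
    } else {
      outS <- c(outS, fusedStart); outE <- c(outE, fusedEnd)
      fusedStart <- runs$start[i]; fusedEnd <- runs$end[i]
    }
  }
  outS <- c(outS, fusedStart); outE <- c(outE, fusedEnd)
  peakIdx <- vapply(seq_along(outS), function(i)
    outS[i] - 1L + which.max(x[outS[i]:outE[i]]), integer(1))
  data.frame(time = (peakIdx - 1L) / fs,
             onset = (outS - 1L) / fs,
             peakAmplitude = x[peakIdx])
}

#' Major movements per minute
#'
#' Counts of detected movement events in 1-min bins across the session.
#'
#' @param movements output of [detectMajorMovements()].
#' @param duration session length in seconds.
#' @param binWidth bin width in seconds (default 60).
#' @return `data.frame` with columns `binStart`, `count`.
#' @export
movementsPerMinute <- function(movements, duration, binWidth = 60) {
  stopifnot(all(movements$time <= duration))
  starts <- .binStarts(duration, binWidth)
  bin <- pmin(length(starts) - 1L, floor(movements$time / binWidth))
  data.frame(binStart = starts,
             count = tabulate(bin + 1L, nbins = length(starts)))
}

#' Movement-triggered investigation analysis
#'
#' For every detected stimulus movement preceded by a quiet pre-window —
#' no investigation by the subject and no other major movement for at
#' least `quietWindow` seconds — measures the per-stimulus investigation
#' time within `responseWindow` seconds after the movement. Matched
#' control epochs (same quiet pre-window, but no movement anywhere in
#' the epoch) are sampled deterministically earliest-first, one per
#' qualifying movement where available, giving the no-movement
#' comparison.
#'
#' @param movements output of [detectMajorMovements()].
#' @param session a gap-merged [BehaviorSession-class] on the same time
#'   base.
#' @param quietWindow required quiet time before the trigger, seconds
#'   (default 3.5; results are insensitive between 2 and 8 s for
#'   well-separated events).
#' @param responseWindow measurement window after the trigger, seconds
#'   (default 3.5).
#' @return `data.frame` with columns `type` (`"movement"`/`"control"`),
#'   `time` (trigger time), `stim1Time`, `stim2Time` (investigation
#'   seconds within the response window).
#' @export
movementTriggeredInvestigation <- function(movements, session,
                                           quietWindow = 3.5,
                                           responseWindow = 3.5) {
  stopifnot(is(session, "BehaviorSession"),
            quietWindow > 0, responseWindow > 0)
  ev <- events(session)
  td <- testDuration(session)
  mv <- sort(movements$time)

  overlapIn <- function(stim, lo, hi) {
    sub <- ev[ev$stimulus == stim, , drop = FALSE]
    sum(pmax(0, pmin(sub$offset, hi) - pmax(sub$onset, lo)))
  }
  anyInvestigation <- function(lo, hi)
    any(ev$onset < hi & ev$offset > lo)
  anyMovement <- function(lo, hi, exclude = NULL) {
    m <- mv
    if (!is.null(exclude)) m <- m[m != exclude]
    any(m >= lo & m < hi)
  }

  rows <- list()
  for (t0 in mv) {
    if (t0 - quietWindow < 0) next
    if (anyInvestigation(t0 - quietWindow, t0)) next
    if (anyMovement(t0 - quietWindow, t0, exclude = t0)) next
    rows[[length(rows) + 1L]] <- data.frame(
      type = "movement", time = t0,
      stim1Time = overlapIn("stim1", t0, t0 + responseWindow),
      stim2Time = overlapIn("stim2", t0, t0 + responseWindow))
  }
  nQual <- length(rows)

  ## control epochs: earliest-first non-overlapping stretches with no
  ## movement over [trigger - quiet, trigger + response] and no
  ## investigation in the pre-window, matched in number to the
  ## qualifying movements
  if (nQual > 0) {
    bounds <- sort(unique(c(0, mv, td)))
    free <- data.frame(lo = bounds[-length(bounds)], hi = bounds[-1L])
    ## movement instants split the session into movement-free intervals
    nCtl <- 0L
    for (k in seq_len(nrow(free))) {
      lo <- free$lo[k]
      if (lo %in% mv) lo <- lo + 1e-9
      t0 <- lo + quietWindow
      while (nCtl < nQual && t0 + responseWindow <= free$hi[k]) {
        ovl <- ev[ev$onset < t0 & ev$offset > t0 - quietWindow, ,
                  drop = FALSE]
        if (nrow(ovl)) {
          t0 <- max(ovl$offset) + quietWindow
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          type = "control", time = t0,
          stim1Time = overlapIn("stim1", t0, t0 + responseWindow),
          stim2Time = overlapIn("stim2", t0, t0 + responseWindow))
        nCtl <- nCtl + 1L
        t0 <- t0 + quietWindow + responseWindow
      }
      if (nCtl >= nQual) break
    }
  }
  if (!length(rows))
    return(data.frame(type = character(), time = numeric(),
                      stim1Time = numeric(), stim2Time = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write a piezo trace as delimited text
#'
#' One sample per line, with a JSON sidecar `<file>.json` holding
#' `{"sampling_rate_hz": ..., "n_samples": ...}`.
#'
#' @param file path of the sample file.
#' @return `readPiezoTrace`: a [PiezoTrace-class].
#' @export
readPiezoTrace <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"))
  x <- scan(file, quiet = TRUE)
  if (length(x) != side$n_samples)
    stop("sample count does not match sidecar")
  piezoTrace(x, side$sampling_rate_hz)
}

#' @rdname readPiezoTrace
#' @param trace a [PiezoTrace-class].
#' @export
writePiezoTrace <- function(trace, file) {
  writeLines(formatC(samples(trace), digits = 10, format = "g"), file)
  jsonlite::write_json(list(sampling_rate_hz = samplingRate(trace),
                            n_samples = length(samples(trace))),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
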