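## Investigation event-log I/O and preprocessing.
##
## Event-log format: UTF-8 CSV with header
##   [session_id,]subject_id,stimulus,onset_s,offset_s
## stimulus is "stim1" or "stim2"; times are decimal seconds from test
## start. A file holds one session, or several keyed by session_id.

.STIMULI <- c("stim1", "stim2")

## Internal: invariant violations of a BehaviorSession, as messages.
sessionViolations <- function(session) {
  v <- character()
  ev <- session@events
  if (length(session@subjectId) != 1L || !nzchar(session@subjectId))
    v <- c(v, "subjectId must be a single non-empty string")
  if (!(length(session@testDuration) == 1L && session@testDuration >= 0))
    v <- c(v, "testDuration must be a single non-negative number")
  if (!all(c("stimulus", "onset", "offset") %in% names(ev)))
    return(c(v, "events must have columns stimulus, onset, offset"))
  if (nrow(ev)) {
    bad <- !ev$stimulus %in% .STIMULI
    if (any(bad))
      v <- c(v, sprintf("unknown stimulus label(s): %s",
                        paste(unique(ev$stimulus[bad]), collapse = ", ")))
    if (anyNA(ev$onset) || anyNA(ev$offset) ||
        !all(is.finite(ev$onset)) || !all(is.finite(ev$offset))) {
      v <- c(v, "event times must be finite")
      return(v)
    }
    if (any(ev$onset < 0)) v <- c(v, "event onsets must be >= 0")
    if (any(ev$offset <= ev$onset))
      v <- c(v, sprintf("%d event(s) with offset <= onset",
                        sum(ev$offset <= ev$onset)))
    if (any(ev$offset > session@testDuration + 1e-9))
      v <- c(v, sprintf("%d event(s) end after testDuration",
                        sum(ev$offset > session@testDuration + 1e-9)))
    if (is.unsorted(ev$onset)) v <- c(v, "events not sorted by onset")
    for (stim in .STIMULI) {
      sub <- ev[ev$stimulus == stim, , drop = FALSE]
      if (nrow(sub) > 1L &&
          any(sub$onset[-1L] < sub$offset[-nrow(sub)] - 1e-9))
        v <- c(v, sprintf("overlapping %s events", stim))
    }
    ## an animal investigates one chamber at a time: intervals of
    ## different stimuli must not overlap either
    if (nrow(ev) > 1L) {
      o <- order(ev$onset, ev$offset)
      if (any(ev$onset[o][-1L] < ev$offset[o][-nrow(ev)] - 1e-9) &&
          !any(grepl("^overlapping", v)))
        v <- c(v, "overlapping events across stimuli")
    }
  }
  if (!is.null(session@positions)) {
    pos <- session@positions
    if (!all(c("time", "x", "y") %in% names(pos)))
      v <- c(v, "positions must have columns time, x, y")
    else if (nrow(pos) > 1L && any(diff(pos$time) <= 0))
      v <- c(v, "position times must be strictly increasing")
  }
  v
}

#' Validate a session against its invariants
#'
#' Checks the structural invariants of a [BehaviorSession-class]: event
#' times finite, `offset > onset`, events inside `[0, testDuration]`,
#' sorted by onset, non-overlapping (within and across stimuli — the
#' animal investigates one chamber at a time), known stimulus labels, and
#' strictly increasing position times. Violations are returned as data,
#' not raised as errors.
#'
#' @param session a [BehaviorSession-class].
#' @return Character vector of violation messages; empty when valid.
#' @examples
#' s <- behaviorSession("m1", data.frame(stimulus = "stim1",
#'                                       onset = 0, offset = 2))
#' validateSession(s)  # character(0)
#' @export
validateSession <- function(session) {
  stopifnot(is(session, "BehaviorSession"))
  sessionViolations(session)
}

#' Merge sub-threshold gaps between same-stimulus investigation events
#'
#' Raw tracker output fragments investigation into events separated by
#' very short gaps. Any gap strictly shorter than `maxGap` between two
#' consecutive events directed at the same stimulus is treated as part of
#' one continuous investigation bout, and the two events are fused into a
#' single bout spanning both. A gap exactly equal to `maxGap` is not
#' merged. Merging is applied independently per stimulus, except that a
#' gap containing an investigation event of the other stimulus is never
#' bridged (the other-stimulus bout is a genuine interruption, and
#' bridging it would make the two stimuli's bouts overlap). The
#' operation is idempotent.
#'
#' @param x a [BehaviorSession-class] or an event `data.frame` with
#'   columns `stimulus`, `onset`, `offset` (sorted by onset,
#'   per-stimulus non-overlapping).
#' @param maxGap merge threshold in seconds (default 0.5).
#' @return Object of the same type as `x` with merged events.
#' @examples
#' ev <- data.frame(stimulus = "stim1", onset = c(0, 2.4), offset = c(2, 5))
#' mergeInvestigationGaps(ev)  # one bout from 0 to 5
#' @export
mergeInvestigationGaps <- function(x, maxGap = 0.5) {
  stopifnot(is.numeric(maxGap), length(maxGap) == 1L, maxGap >= 0)
  if (is(x, "BehaviorSession")) {
    merged <- mergeInvestigationGaps(x@events, maxGap)
    out <- x
    out@events <- merged
    return(out)
  }
  ev <- as.data.frame(x)
  stopifnot(all(c("stimulus", "onset", "offset") %in% names(ev)))
  if (!nrow(ev)) return(ev[, c("stimulus", "onset", "offset"), drop = FALSE])
  if (is.unsorted(ev$onset)) stop("events must be sorted by onset")
  pieces <- lapply(split(ev, ev$stimulus), function(sub) {
    if (any(sub$onset[-1L] < sub$offset[-nrow(sub)]))
      stop("per-stimulus events must not overlap")
    other <- ev[ev$stimulus != sub$stimulus[1L], , drop = FALSE]
    mergeIntervals(sub$onset, sub$offset, maxGap = maxGap,
                   stimulus = sub$stimulus[1L],
                   blockerOnset = other$onset,
                   blockerOffset = other$offset)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$onset, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Internal: fuse sorted, non-overlapping intervals whose gap < maxGap.
## A gap overlapped by any blocker interval is never fused.
mergeIntervals <- function(onset, offset, maxGap, stimulus = NULL,
                           blockerOnset = numeric(),
                           blockerOffset = numeric()) {
  n <- length(onset)
  if (n == 0L)
    return(data.frame(stimulus = character(), onset = numeric(),
                      offset = numeric()))
  blocked <- function(lo, hi)
    any(blockerOnset < hi & blockerOffset > lo)
  mOn <- onset[1L]; mOff <- offset[1L]
  outOn <- numeric(); outOff <- numeric()
  for (i in seq_len(n)[-1L]) {
    if (onset[i] - mOff < maxGap && !blocked(mOff, onset[i])) {
      mOff <- max(mOff, offset[i])
    } else {
      outOn <- c(outOn, mOn); outOff <- c(outOff, mOff)
      mOn <- onset[i]; mOff <- offset[i]
    }
  }
  outOn <- c(outOn, mOn); outOff <- c(outOff, mOff)
  if (is.null(stimulus))
    data.frame(onset = outOn, offset = outOff)
  else
    data.frame(stimulus = stimulus, onset = outOn, offset = outOff)
}

#' Read investigation event logs
#'
#' Reads a CSV event log with header columns `subject_id`, `stimulus`,
#' `onset_s`, `offset_s` and an optional leading `session_id` key.
#' Single-session files yield one session; long-format files keyed by
#' `session_id` yield one session per key. Malformed rows (unknown
#' stimulus, non-numeric times, `offset <= onset`) are reported with
#' their file row numbers.
#'
#' @param file path or connection.
#' @param testDuration test length in seconds applied to every session
#'   (default 300).
#' @param merge apply the 0.5-s investigation gap merge after reading
#'   (default `FALSE`: the file is taken verbatim).
#' @param validate reject sessions violating the structural invariants
#'   (default `TRUE`); with `FALSE`, violations are left for
#'   [validateSession()] to report.
#' @return A named list of [BehaviorSession-class] objects (one element
#'   for a single-session file).
#' @seealso [writeEventLog()]
#' @export
readEventLog <- function(file, testDuration = 300, merge = FALSE,
                         validate = TRUE) {
  raw <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "stimulus", "onset_s", "offset_s")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("event log is missing column(s): ", paste(miss, collapse = ", "))
  rowno <- seq_len(nrow(raw)) + 1L  # header is line 1
  for (col in c("onset_s", "offset_s")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(vals) & !is.na(raw[[col]])
    if (any(bad) || anyNA(vals))
      stop(sprintf("non-numeric %s on row(s) %s", col,
                   paste(rowno[is.na(vals)], collapse = ", ")))
    raw[[col]] <- vals
  }
  bad <- raw$offset_s <= raw$onset_s
  if (any(bad))
    stop("offset_s <= onset_s on row(s) ",
         paste(rowno[bad], collapse = ", "))
  bad <- !raw$stimulus %in% .STIMULI
  if (any(bad))
    stop("unknown stimulus on row(s) ", paste(rowno[bad], collapse = ", "))
  key <- if ("session_id" %in% names(raw)) as.character(raw$session_id)
         else rep("session1", nrow(raw))
  if (!nrow(raw)) key <- character()
  sessions <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    sub <- raw[idx, , drop = FALSE]
    sid <- unique(sub$subject_id)
    if (length(sid) != 1L)
      stop("multiple subject_id values within one session")
    s <- behaviorSession(sid,
           data.frame(stimulus = sub$stimulus, onset = sub$onset_s,
                      offset = sub$offset_s),
           testDuration = testDuration, validate = validate)
    if (merge) s <- mergeInvestigationGaps(s)
    s
  })
  if (!length(sessions)) {
    warning("empty event log")
    return(list())
  }
  sessions
}

#' Write investigation event logs
#'
#' Writes one or more sessions as CSV with a stable column order
#' (`session_id,subject_id,stimulus,onset_s,offset_s`) and full numeric
#' precision, so write-then-read reproduces the sessions exactly.
#'
#' @param sessions a [BehaviorSession-class] or list of them.
#' @param file path or connection.
#' @return `file`, invisibly.
#' @seealso [readEventLog()]
#' @export
writeEventLog <- function(sessions, file) {
  if (is(sessions, "BehaviorSession")) sessions <- list(sessions)
  ids <- names(sessions)
  if (is.null(ids)) ids <- vapply(sessions, subjectId, character(1))
  rows <- lapply(seq_along(sessions), function(i) {
    ev <- events(sessions[[i]])
    if (!nrow(ev))
      return(data.frame(session_id = character(), subject_id = character(),
                        stimulus = character(), onset_s = numeric(),
                        offset_s = numeric()))
    data.frame(session_id = ids[i], subject_id = subjectId(sessions[[i]]),
               stimulus = ev$stimulus, onset_s = ev$onset,
               offset_s = ev$offset)
  })
  tab <- do.call(rbind, rows)
  ## full precision: format times with 17 significant digits
  tab$onset_s <- formatC(tab$onset_s, digits = 17, format = "g")
  tab$offset_s <- formatC(tab$offset_s, digits = 17, format = "g")
  write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read or write a dyadic contact log
#'
#' Contact logs record free-interaction body-contact intervals as CSV
#' with header `onset_s,offset_s`.
#'
#' @param file path or connection.
#' @param merge apply the 0.5-s gap rule after reading (default `TRUE`,
#'   matching how interaction gaps are neglected in analysis).
#' @return `readContactLog`: `data.frame` with columns `onset`, `offset`.
#' @export
readContactLog <- function(file, merge = TRUE) {
  raw <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s") %in% names(raw)))
    stop("contact log needs columns onset_s, offset_s")
  con <- data.frame(onset = as.numeric(raw$onset_s),
                    offset = as.numeric(raw$offset_s))
  if (any(con$offset <= con$onset)) stop("contact with offset <= onset")
  con <- con[order(con$onset), , drop = FALSE]
  if (merge && nrow(con))
    con <- mergeIntervals(con$onset, con$offset, maxGap = 0.5)
  rownames(con) <- NULL
  con
}

#' @rdname readContactLog
#' @param contacts `data.frame` with columns `onset`, `offset`.
#' @export
writeContactLog <- function(contacts, file) {
  tab <- data.frame(onset_s = contacts$onset, offset_s = contacts$offset)
  write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a position trajectory
#'
#' CSV with header `time_s,x,y`; times must be strictly increasing.
#'
#' @param file path or connection.
#' @return `data.frame` with columns `time`, `x`, `y`.
#' @export
readTrajectory <- function(file) {
  raw <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("time_s", "x", "y") %in% names(raw)))
    stop("trajectory needs columns time_s, x, y")
  pos <- data.frame(time = as.numeric(raw$time_s),
                    x = as.numeric(raw$x), y = as.numeric(raw$y))
  if (nrow(pos) > 1L && any(diff(pos$time) <= 0))
    stop("trajectory times must be strictly increasing")
  pos
}

#' Specify a rectangular arena and its center region
#'
#' The center region is a concentric rectangle similar in shape to the
#' arena and scaled so that its area is `centerFraction` of the total
#' (linear scale `sqrt(centerFraction)`); the default 0.30 matches the
#' usual "inner 30%" open-field convention.
#'
#' @param width,height arena dimensions (any consistent length unit).
#' @param centerFraction fraction of arena area forming the center,
#'   in (0, 1).
#' @return A list with class `"ArenaSpec"`.
#' @export
arenaSpec <- function(width, height, centerFraction = 0.30) {
  stopifnot(width > 0, height > 0,
            centerFraction > 0, centerFraction < 1)
  structure(list(shape = "rectangle", width = width, height = height,
                 centerFraction = centerFraction),
            class = "ArenaSpec")
}
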