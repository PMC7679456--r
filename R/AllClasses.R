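#' @import methods
#' @importFrom stats rexp runif rnorm sd setNames approx
#' @importFrom utils read.csv write.csv head tail packageVersion
#' @useDynLib socialMarkov, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' BehaviorSession: one subject's investigation record for one test
#'
#' Container for a single two-stimulus test session: the chronologically
#' sorted investigation events (bouts) of one subject, plus optional arena
#' positions. Times are decimal seconds from test start; every event is a
#' half-open interval `[onset, offset)` labelled with the stimulus it was
#' directed at (`"stim1"` or `"stim2"`).
#'
#' @slot subjectId single character identifier.
#' @slot groupTag free-text group label (strain, paradigm, ...).
#' @slot testDuration test length in seconds (300 for the standard 5-min
#'   test, 900 for the extended test).
#' @slot events `data.frame` with columns `stimulus`, `onset`, `offset`.
#' @slot positions optional `data.frame` with columns `time`, `x`, `y`
#'   (strictly increasing `time`), or `NULL`.
#' @slot rngSeed integer seed for simulated sessions, `NA` otherwise.
#'
#' @seealso [behaviorSession()], [validateSession()], [mergeInvestigationGaps()]
#' @exportClass BehaviorSession
setClass("BehaviorSession",
  slots = c(
    subjectId    = "character",
    groupTag     = "character",
    testDuration = "numeric",
    events       = "data.frame",
    positions    = "data.frameOrNULL",
    rngSeed      = "integer"
  ),
  prototype = prototype(
    subjectId = "subject", groupTag = "", testDuration = 300,
    events = data.frame(stimulus = character(), onset = numeric(),
                        offset = numeric()),
    positions = NULL, rngSeed = NA_integer_
  )
)

## Class validity is structural only (slot shapes and column names);
## the behavioral invariants — ordering, bounds, non-overlap — are
## reported as data by validateSession(), so invalid recordings can be
## represented, inspected, and repaired rather than erroring on
## construction.
setValidity("BehaviorSession", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@testDuration) != 1L)
    msg <- c(msg, "testDuration must be a single number")
  if (!all(c("stimulus", "onset", "offset") %in% names(object@events)))
    msg <- c(msg, "events needs columns stimulus, onset, offset")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a BehaviorSession
#'
#' @param subjectId subject identifier.
#' @param events `data.frame` with columns `stimulus` (`"stim1"`/`"stim2"`),
#'   `onset`, `offset` in seconds. Rows are sorted by onset on construction.
#' @param testDuration test length in seconds.
#' @param groupTag optional free-text group label.
#' @param positions optional `data.frame` with `time`, `x`, `y` columns.
#' @param rngSeed optional integer seed recorded for simulated sessions.
#' @param validate check invariants (default `TRUE`).
#' @return A [BehaviorSession-class] object.
#' @examples
#' ev <- data.frame(stimulus = c("stim1", "stim2"),
#'                  onset = c(1, 10), offset = c(4, 12))
#' behaviorSession("m1", ev, testDuration = 300)
#' @export
behaviorSession <- function(subjectId, events, testDuration = 300,
                            groupTag = "", positions = NULL,
                            rngSeed = NA_integer_, validate = TRUE) {
  events <- as.data.frame(events)
  if (nrow(events)) {
    events <- events[order(events$onset, events$offset), , drop = FALSE]
    rownames(events) <- NULL
  }
  events$stimulus <- as.character(events$stimulus)
  obj <- new("BehaviorSession",
             subjectId = as.character(subjectId), groupTag = as.character(groupTag),
             testDuration = as.numeric(testDuration),
             events = events[, c("stimulus", "onset", "offset"), drop = FALSE],
             positions = positions, rngSeed = as.integer(rngSeed))
  if (validate) {
    v <- sessionViolations(obj)
    if (length(v)) stop("invalid session: ", paste(v, collapse = "; "))
  }
  obj
}

#' ModelParams: parameters of the four-state behavioral Markov model
#'
#' All fixed parameters of the discrete-time Markov model of social
#' investigation, together with the time calibration that converts model
#' steps to behavioral seconds. Rewards grow (`s = +1`, mice) or decay
#' (`s = -1`, rats) exponentially with cumulative investigation time;
#' anxiety decays exponentially from `a0` and is reduced by the absolute
#' reward difference between the stimuli.
#'
#' @slot a0 initial anxiety (dimensionless).
#' @slot r10,r20 initial reward values of stimulus 1 and 2.
#' @slot tauR reward time constant, in model time units (steps).
#' @slot tauA anxiety time constant, in model time units (steps).
#' @slot beta1r,beta1a weights of reward and anxiety on the decision to
#'   continue investigating the current stimulus.
#' @slot beta2r,beta2a weights of reward and anxiety on the decision taken
#'   from stillness / to remain exploring.
#' @slot S0 stillness coefficient.
#' @slot E0 exploration coefficient.
#' @slot s reward sign: `+1` (growth, mice) or `-1` (decay, rats).
#' @slot secondsPerStep behavioral seconds represented by one Markov step.
#' @slot testDuration simulated test length in seconds.
#' @slot initialState state occupied at t = 0 (default `"stillness"`).
#' @slot clampAnxiety if `TRUE`, anxiety is clamped at 0 from below
#'   (sensitivity switch; default `FALSE`, the formula may go negative).
#'
#' @seealso [modelPreset()], [simulateSession()], [transitionProbabilities()]
#' @exportClass ModelParams
setClass("ModelParams",
  slots = c(
    a0 = "numeric", r10 = "numeric", r20 = "numeric",
    tauR = "numeric", tauA = "numeric",
    beta1r = "numeric", beta2r = "numeric",
    beta1a = "numeric", beta2a = "numeric",
    S0 = "numeric", E0 = "numeric", s = "numeric",
    secondsPerStep = "numeric", testDuration = "numeric",
    initialState = "character", clampAnxiety = "logical"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (!(object@s %in% c(-1, 1))) msg <- c(msg, "s must be +1 or -1")
  for (nm in c("tauR", "tauA", "secondsPerStep"))
    if (!(slot(object, nm) > 0)) msg <- c(msg, paste(nm, "must be > 0"))
  if (object@testDuration < 0) msg <- c(msg, "testDuration must be >= 0")
  if (!object@initialState %in% behavioralStates())
    msg <- c(msg, "unknown initialState")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' The four behavioral states
#'
#' State labels of the Markov model, in transition-matrix order:
#' investigating stimulus 1, investigating stimulus 2, stillness, and
#' arena exploration. Direct moves between the two investigation states,
#' or between investigation and exploration, are structurally forbidden;
#' they are always routed through stillness.
#'
#' @return Character vector of the four state names.
#' @export
behavioralStates <- function() {
  c("investigate_stim1", "investigate_stim2", "stillness", "exploration")
}

#' PiezoTrace: a piezoelectric movement-sensor recording
#'
#' A uniformly sampled voltage trace from the piezoelectric floor sensors
#' under the stimulus chamber, used to detect stimulus movements.
#'
#' @slot samplingRate sampling rate in Hz.
#' @slot samples numeric sample vector (sensor units; normalized traces
#'   have maximum absolute value 1).
#' @slot subjectId identifier linking the trace to a session.
#'
#' @seealso [piezoTrace()], [preprocessPiezo()], [detectMajorMovements()]
#' @exportClass PiezoTrace
setClass("PiezoTrace",
  slots = c(samplingRate = "numeric", samples = "numeric",
            subjectId = "character"),
  prototype = prototype(samplingRate = 20000, samples = numeric(),
                        subjectId = "")
)

setValidity("PiezoTrace", function(object) {
  if (!(object@samplingRate > 0)) return("samplingRate must be > 0")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    return("samples must be finite")
  TRUE
})

#' Construct a PiezoTrace
#'
#' @param samples numeric sample vector.
#' @param samplingRate sampling rate in Hz (default 20000, the acquisition
#'   rate of the recording system).
#' @param subjectId optional identifier.
#' @return A [PiezoTrace-class] object.
#' @export
piezoTrace <- function(samples, samplingRate = 20000, subjectId = "") {
  new("PiezoTrace", samplingRate = as.numeric(samplingRate),
      samples = as.numeric(samples), subjectId = as.character(subjectId))
}

## ---- accessors ----

#' @describeIn behaviorSession-accessors event table of a session
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @describeIn behaviorSession-accessors test duration in seconds
#' @export
setGeneric("testDuration", function(x) standardGeneric("testDuration"))

#' @describeIn behaviorSession-accessors subject identifier
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @describeIn behaviorSession-accessors arena positions (or NULL)
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Accessors for BehaviorSession
#'
#' @param x a [BehaviorSession-class].
#' @return `events()` the event `data.frame`; `testDuration()` seconds;
#'   `subjectId()` character; `positions()` the position `data.frame` or
#'   `NULL`.
#' @name behaviorSession-accessors
#' @aliases events testDuration subjectId positions
NULL

#' @rdname behaviorSession-accessors
#' @export
setMethod("events", "BehaviorSession", function(x) x@events)

#' @rdname behaviorSession-accessors
#' @export
setMethod("testDuration", "BehaviorSession", function(x) x@testDuration)

#' @rdname behaviorSession-accessors
#' @export
setMethod("subjectId", "BehaviorSession", function(x) x@subjectId)

#' @rdname behaviorSession-accessors
#' @export
setMethod("positions", "BehaviorSession", function(x) x@positions)

#' @describeIn piezoTrace-accessors sample vector
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @describeIn piezoTrace-accessors sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Accessors for PiezoTrace
#'
#' @param x a [PiezoTrace-class].
#' @name piezoTrace-accessors
#' @aliases samples samplingRate
NULL

#' @rdname piezoTrace-accessors
#' @export
setMethod("samples", "PiezoTrace", function(x) x@samples)

#' @rdname piezoTrace-accessors
#' @export
setMethod("samplingRate", "PiezoTrace", function(x) x@samplingRate)

setMethod("show", "BehaviorSession", function(object) {
  ev <- object@events
  tot <- vapply(split(ev$offset - ev$onset, ev$stimulus), sum, numeric(1))
  cat(sprintf("BehaviorSession '%s'%s: %d events over %.0f s\n",
              object@subjectId,
              if (nzchar(object@groupTag))
                sprintf(" [%s]", object@groupTag) else "",
              nrow(ev), object@testDuration))
  for (nm in names(tot))
    cat(sprintf("  %s: %.1f s investigation\n", nm, tot[[nm]]))
  if (!is.null(object@positions))
    cat(sprintf("  positions: %d samples\n", nrow(object@positions)))
  invisible(NULL)
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(paste0(
    "ModelParams (s = %+d): a0=%.3g r0=(%.3g, %.3g) tauR=%.6g tauA=%.6g\n",
    "  beta1=(r %.3g, a %.3g) beta2=(r %.3g, a %.3g) S0=%.3g E0=%.3g\n",
    "  %.0f s test at %.4g s/step, start in %s\n"),
    as.integer(object@s), object@a0, object@r10, object@r20,
    object@tauR, object@tauA, object@beta1r, object@beta1a,
    object@beta2r, object@beta2a, object@S0, object@E0,
    object@testDuration, object@secondsPerStep, object@initialState))
  invisible(NULL)
})

setMethod("show", "PiezoTrace", function(object) {
  cat(sprintf("PiezoTrace: %d samples at %.0f Hz (%.1f s)%s\n",
              length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate,
              if (nzchar(object@subjectId))
                sprintf(", subject '%s'", object@subjectId) else ""))
  invisible(NULL)
})
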