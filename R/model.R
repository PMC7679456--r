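## The four-state discrete-time Markov model of social investigation.
##
## States: investigating stimulus 1 (S1), investigating stimulus 2 (S2),
## stillness (S3), arena exploration (S4). Transition probabilities are
## dynamic: they depend on the current rewards r1, r2 of the two stimuli
## and on anxiety a, which evolve with elapsed time and accumulated
## investigation. Leaving an investigation or exploration state always
## passes through stillness; from stillness the next behavior is chosen
## by a softmax over the two stimulus rewards, a stillness drive
## proportional to anxiety, and a fixed exploration drive.

## Table of strain/test presets. tauR and tauA are in model time units
## (Markov steps); secondsPerStep converts to behavioral seconds and is
## fixed by calibrateTimeScale() (see the methods vignette).
.PRESETS <- list(
  mice_SP  = list(r10 = 4.98, r20 = 4.72, tauR = 100406, s = +1),
  mice_SNP = list(r10 = 4.70, r20 = 4.90, tauR = 100406, s = +1),
  rats_SP  = list(r10 = 5.80, r20 = 4.72, tauR = 33406,  s = -1),
  rats_SNP = list(r10 = 5.05, r20 = 5.30, tauR = 33406,  s = -1)
)

## Calibrated step length in behavioral seconds (see calibrateTimeScale
## and the methods vignette); with this value the anxiety time constant
## spans ~104 s of a 300-s test.
.DEFAULT_SECONDS_PER_STEP <- 0.01

#' Strain/test parameter presets for the behavioral Markov model
#'
#' Returns the fixed model parameters for one of the four fitted
#' regimes: mouse or rat, social-preference (SP) or
#' social-novelty-preference (SNP) test. All presets share the anxiety
#' parameters and decision weights; they differ in the initial rewards,
#' the reward time constant, and the reward sign (`s = +1` for mice,
#' reward grows with exposure; `s = -1` for rats, reward decays). In the
#' SNP presets stimulus 2 is the novel animal.
#'
#' @param name one of `"mice_SP"`, `"mice_SNP"`, `"rats_SP"`,
#'   `"rats_SNP"`.
#' @param secondsPerStep behavioral seconds per Markov step (default:
#'   the calibrated value, see [calibrateTimeScale()]).
#' @param testDuration simulated test length in seconds (default 300).
#' @param initialState starting state (default `"stillness"`).
#' @param clampAnxiety clamp anxiety at zero from below (default
#'   `FALSE`).
#' @return A [ModelParams-class] object.
#' @examples
#' modelPreset("mice_SP")
#' @export
modelPreset <- function(name = c("mice_SP", "mice_SNP", "rats_SP",
                                 "rats_SNP"),
                        secondsPerStep = defaultSecondsPerStep(),
                        testDuration = 300,
                        initialState = "stillness",
                        clampAnxiety = FALSE) {
  name <- match.arg(name)
  p <- .PRESETS[[name]]
  new("ModelParams",
      a0 = 7.66, r10 = p$r10, r20 = p$r20,
      tauR = p$tauR, tauA = 10355.62,
      beta1r = 1.1, beta2r = 1.12, beta1a = -0.08, beta2a = 0.71,
      S0 = 2.72, E0 = 5.19, s = p$s,
      secondsPerStep = secondsPerStep, testDuration = testDuration,
      initialState = initialState, clampAnxiety = clampAnxiety)
}

#' @rdname modelPreset
#' @export
defaultSecondsPerStep <- function() .DEFAULT_SECONDS_PER_STEP

#' Anxiety value of the model
#'
#' Anxiety decays exponentially from its initial value with time
#' constant `tauA` and is reduced by the absolute reward difference
#' between the two stimuli (the motivational-conflict term), using the
#' current, time-varying rewards. The formula may go negative; set
#' `clampAnxiety` in the parameters to clamp at zero.
#'
#' @param t elapsed time in model time units (steps).
#' @param r1,r2 current rewards of the two stimuli.
#' @param params a [ModelParams-class].
#' @return Anxiety value (dimensionless).
#' @examples
#' p <- modelPreset("mice_SP")
#' anxiety(0, p@r10, p@r20, p)  # 7.66 - |4.98 - 4.72| = 7.40
#' @export
anxiety <- function(t, r1, r2, params) {
  stopifnot(all(t >= 0))
  a <- params@a0 * exp(-t / params@tauA) - abs(r1 - r2)
  if (params@clampAnxiety) a <- pmax(a, 0)
  a
}

#' Reward value of a stimulus
#'
#' A stimulus's reward changes exponentially with the cumulative time
#' the subject has spent investigating it: growth for mice (`s = +1`),
#' decay for rats (`s = -1`).
#'
#' @param T cumulative investigation time of the stimulus, in model time
#'   units (steps).
#' @param r0 initial reward of the stimulus.
#' @param params a [ModelParams-class].
#' @return Reward value.
#' @export
reward <- function(T, r0, params) {
  stopifnot(all(T >= 0))
  r0 * exp(params@s * T / params@tauR)
}

#' One-step transition probabilities of the behavioral Markov chain
#'
#' The probability row out of a state given the current anxiety and
#' rewards. From an investigation state the subject stays with
#' probability `sigmoid(beta1r * r + beta1a * a)` and otherwise falls to
#' stillness. From stillness the next state is a softmax choice over the
#' four logits `beta2r * r1`, `beta2r * r2`, `S0 * beta2a * a`, `E0`
#' (stimulus 1, stimulus 2, stay still, explore). From exploration the
#' subject keeps exploring with probability
#' `sigmoid(S0 + E0 - beta2a * a)` and otherwise falls to stillness.
#' Structural zeros (direct investigation-to-investigation or
#' investigation-to-exploration moves) are exactly 0.
#'
#' @param state one of [behavioralStates()], or its 1-based index.
#' @param a anxiety value.
#' @param r1,r2 current rewards.
#' @param params a [ModelParams-class].
#' @return Named numeric vector of four probabilities summing to 1.
#' @export
transitionProbabilities <- function(state, a, r1, r2, params) {
  if (is.character(state)) state <- match(state, behavioralStates())
  stopifnot(state %in% 1:4, is.finite(a), is.finite(r1), is.finite(r2))
  sig <- function(x) 1 / (1 + exp(-x))
  p <- numeric(4)
  if (state == 1) {
    stay <- sig(params@beta1r * r1 + params@beta1a * a)
    p[1] <- stay; p[3] <- 1 - stay
  } else if (state == 2) {
    stay <- sig(params@beta1r * r2 + params@beta1a * a)
    p[2] <- stay; p[3] <- 1 - stay
  } else if (state == 3) {
    l <- c(params@beta2r * r1, params@beta2r * r2,
           params@S0 * params@beta2a * a, params@E0)
    e <- exp(l - max(l))
    p <- e / sum(e)
  } else {
    stay <- sig(params@S0 + params@E0 - params@beta2a * a)
    p[4] <- stay; p[3] <- 1 - stay
  }
  setNames(p, behavioralStates())
}

#' Simulate the raw behavioral state path
#'
#' Runs the chain for `nSteps` occupancy steps and returns the state
#' sequence itself (before any conversion to investigation events) —
#' the view needed to study the chain's dynamics directly, e.g. to
#' compare empirical transition frequencies with
#' [transitionProbabilities()].
#'
#' @param params a [ModelParams-class]; set `tauR`/`tauA` to `Inf` to
#'   freeze the reward and anxiety dynamics at their initial values.
#' @param nSteps number of steps (default: `testDuration /
#'   secondsPerStep`).
#' @param seed integer seed.
#' @return Integer vector of states in 1:4, ordered as
#'   [behavioralStates()].
#' @export
simulateStates <- function(params, nSteps = NULL, seed = 1) {
  stopifnot(is(params, "ModelParams"))
  if (is.null(nSteps))
    nSteps <- floor(params@testDuration / params@secondsPerStep)
  withSeed(seed, .simulateStatePath(
    as.integer(nSteps), params@a0, params@r10, params@r20,
    params@tauR, params@tauA,
    params@beta1r, params@beta2r, params@beta1a, params@beta2a,
    params@S0, params@E0, params@s,
    match(params@initialState, behavioralStates()),
    params@clampAnxiety))
}

#' Simulate one test session
#'
#' Runs the Markov chain for `testDuration / secondsPerStep` steps from
#' the initial state, recomputing rewards and anxiety every step.
#' Contiguous runs of the two investigation states become investigation
#' events (duration = steps × `secondsPerStep`), and the standard 0.5-s
#' investigation gap merge is then applied, so simulated logs are
#' processed identically to experimental ones.
#'
#' @param params a [ModelParams-class].
#' @param seed integer seed; the session is a pure function of
#'   `(params, seed)`.
#' @param subjectId identifier for the resulting session.
#' @param merge apply the 0.5-s gap merge (default `TRUE`).
#' @return A [BehaviorSession-class].
#' @examples
#' s <- simulateSession(modelPreset("mice_SP"), seed = 1)
#' s
#' @export
simulateSession <- function(params, seed, subjectId = "sim1",
                            merge = TRUE) {
  stopifnot(is(params, "ModelParams"))
  nSteps <- floor(params@testDuration / params@secondsPerStep)
  path <- withSeed(seed, .simulateStatePath(
    nSteps, params@a0, params@r10, params@r20, params@tauR, params@tauA,
    params@beta1r, params@beta2r, params@beta1a, params@beta2a,
    params@S0, params@E0, params@s,
    match(params@initialState, behavioralStates()),
    params@clampAnxiety))
  ev <- statePathToEvents(path, params@secondsPerStep)
  s <- behaviorSession(subjectId, ev,
                       testDuration = params@testDuration,
                       groupTag = "simulated",
                       rngSeed = as.integer(seed))
  if (merge) s <- mergeInvestigationGaps(s)
  s
}

## Internal: contiguous runs of states 1/2 in an occupancy path become
## investigation events; step k occupies [(k-1)*dt, k*dt).
statePathToEvents <- function(path, dt) {
  empty <- data.frame(stimulus = character(), onset = numeric(),
                      offset = numeric())
  if (!length(path)) return(empty)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values %in% c(1L, 2L)
  if (!any(keep)) return(empty)
  data.frame(stimulus = .STIMULI[r$values[keep]],
             onset = starts[keep] * dt, offset = ends[keep] * dt)
}

## Internal: evaluate expr-like function under a temporary RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a cohort of test sessions
#'
#' Simulates `n` independent subjects under one parameter set, with
#' per-subject seeds derived deterministically from the master seed, so
#' the whole cohort is reproducible end-to-end.
#'
#' @param params a [ModelParams-class].
#' @param n number of subjects (default 60, the simulated cohort size).
#' @param masterSeed integer master seed.
#' @param ... passed to [simulateSession()].
#' @return Named list of [BehaviorSession-class] objects
#'   (`sim001`, `sim002`, ...).
#' @export
simulateCohort <- function(params, n = 60, masterSeed = 1, ...) {
  stopifnot(n >= 1)
  seeds <- deriveSeeds(masterSeed, n)
  ids <- sprintf("sim%03d", seq_len(n))
  setNames(lapply(seq_len(n), function(i)
    simulateSession(params, seed = seeds[i], subjectId = ids[i], ...)),
    ids)
}

## Internal: n child seeds derived deterministically from a master seed,
## kept within 32-bit integer range.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

#' Calibrate the step length of the model
#'
#' The model's time constants are expressed in Markov steps; the step
#' length in behavioral seconds is a free calibration. This routine
#' simulates a mouse SP cohort at each candidate step length and scores
#' how well the resulting behavior looks like a real session on two
#' requirements: (i) investigation bouts should mostly last between 1
#' and 40 s, and (ii) the cohort-mean transition-rate curve should rise
#' to an early peak and then decline to a lower stable late-test level
#' (peak value above the final-2-minute mean, peak not in the final two
#' minutes). The score is the fraction of bout mass inside 1-40 s, with
#' candidates failing requirement (ii) disqualified.
#'
#' @param candidates step lengths to try, in seconds (default
#'   `c(0.001, 0.01, 0.1, 1)`).
#' @param n cohort size per candidate (default 20).
#' @param masterSeed seed shared across candidates.
#' @param preset preset name to simulate (default `"mice_SP"`).
#' @return The winning step length (seconds), with the per-candidate
#'   score table in attribute `"scores"`.
#' @export
calibrateTimeScale <- function(candidates = c(0.001, 0.01, 0.1, 1),
                               n = 20, masterSeed = 20260101,
                               preset = "mice_SP") {
  stopifnot(length(candidates) >= 1)
  scores <- vapply(candidates, function(spp) {
    params <- modelPreset(preset, secondsPerStep = spp)
    cohort <- simulateCohort(params, n = n, masterSeed = masterSeed)
    dur <- unlist(lapply(cohort, function(s) {
      ev <- events(s); ev$offset - ev$onset
    }))
    if (!length(dur)) return(-Inf)
    mass <- sum(dur[dur >= 1 & dur <= 40]) / sum(dur)
    tr <- cohortSummary(cohort)$transitionRate
    lastTwoMin <- tr$binStart >= max(tr$binStart) - 100
    peakBin <- which.max(tr$mean)
    shapeOK <- max(tr$mean) > mean(tr$mean[lastTwoMin]) &&
      !lastTwoMin[peakBin] && max(tr$mean) > 0
    if (!shapeOK) return(-Inf)
    mass
  }, numeric(1))
  best <- candidates[which.max(scores)]
  structure(best, scores = data.frame(secondsPerStep = candidates,
                                      score = scores))
}
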