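## Evolutionary multiobjective fitting of model parameters to cohort
## summary curves: a compact NSGA-II (fast non-dominated sorting,
## crowding distance, binary tournament, blend crossover, bounded
## uniform mutation) with an external archive of all non-dominated
## solutions found. Objective evaluation uses common random numbers —
## fixed per-replicate seeds shared by every candidate — so fronts are
## reproducible and candidate comparisons are not swamped by simulation
## noise.

#' Objective vector between two summary-curve sets
#'
#' Root-mean-square discrepancies between simulated and target cohort
#' mean curves: the stimulus-1 investigation curve, the stimulus-2
#' investigation curve, and the transition-rate curve; optionally the
#' per-category pooled-time curves as a fourth objective.
#'
#' @param simulated,target [cohortSummary()] objects with identical bin
#'   structure.
#' @param includeCategories add the pooled-category RMS objective
#'   (default `FALSE`).
#' @return Named numeric vector of RMS discrepancies.
#' @export
summaryObjectives <- function(simulated, target,
                              includeCategories = FALSE) {
  stopifnot(inherits(simulated, "SummaryCurves"),
            inherits(target, "SummaryCurves"))
  if (!identical(simulated$investigation$binStart,
                 target$investigation$binStart) ||
      simulated$binWidth != target$binWidth)
    stop("bin structures differ between simulated and target curves")
  rms <- function(x) sqrt(mean(x^2))
  obj <- c(
    investigation_stim1 = rms(
      simulated$investigation$mean[simulated$investigation$stimulus ==
                                     "stim1"] -
        target$investigation$mean[target$investigation$stimulus ==
                                    "stim1"]),
    investigation_stim2 = rms(
      simulated$investigation$mean[simulated$investigation$stimulus ==
                                     "stim2"] -
        target$investigation$mean[target$investigation$stimulus ==
                                    "stim2"]),
    transition_rate = rms(simulated$transitionRate$mean -
                            target$transitionRate$mean))
  if (includeCategories) {
    if (is.null(simulated$categoryTime) || is.null(target$categoryTime))
      stop("category curves requested but not present")
    obj <- c(obj, category_time = rms(simulated$categoryTime$mean -
                                        target$categoryTime$mean))
  }
  obj
}

## Internal: TRUE if objective vector a dominates b (<= everywhere,
## < somewhere).
.dominates <- function(a, b) all(a <= b) && any(a < b)

## Internal: fast non-dominated sorting; returns integer rank per row.
.ndRank <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dominatedBy <- integer(n)
  dominates <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (.dominates(obj[i, ], obj[j, ]))
        dominates[[i]] <- c(dominates[[i]], j)
      else if (.dominates(obj[j, ], obj[i, ]))
        dominatedBy[i] <- dominatedBy[i] + 1L
    }
  }
  current <- which(dominatedBy == 0L)
  r <- 1L
  while (length(current)) {
    rank[current] <- r
    nxt <- integer()
    for (i in current) {
      for (j in dominates[[i]]) {
        dominatedBy[j] <- dominatedBy[j] - 1L
        if (dominatedBy[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- unique(nxt)
    r <- r + 1L
  }
  rank
}

## Internal: crowding distance within one front.
.crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / rng
  }
  d
}

#' Fit model parameters to target summary curves
#'
#' Generational NSGA-II search over a subset of model parameters,
#' minimizing the [summaryObjectives()] between simulated and target
#' cohort curves. Each candidate is evaluated by simulating
#' `replicates` cohorts of `cohortSize` subjects with per-replicate
#' seeds shared across all candidates (common random numbers) and
#' averaging the objective vectors. The returned front is the archive
#' of all mutually non-dominated solutions encountered, so the best
#' achievable weighted objective never worsens across generations.
#'
#' @param target a [cohortSummary()] of the cohort to match.
#' @param free named list of `c(low, high)` bounds for the free
#'   parameters; names must be [ModelParams-class] slot names (e.g.
#'   `r10`, `r20`, `a0`).
#' @param base a [ModelParams-class] supplying every fixed parameter.
#' @param popSize population size (default 64).
#' @param generations number of generations (default 50); 0 evaluates
#'   and archives only the initial population.
#' @param replicates simulated cohorts per evaluation (default 10).
#' @param cohortSize subjects per simulated cohort (default 20).
#' @param masterSeed integer seed governing the whole run.
#' @param includeCategories passed to [summaryObjectives()].
#' @param crossoverProb,mutationProb,blendAlpha variation settings:
#'   blend (BLX-alpha) crossover probability per pair, per-gene uniform
#'   mutation probability (default `1/d`), and blend width.
#' @return A list of class `"ParetoFront"`: `parameters` (matrix),
#'   `objectives` (matrix), `generation` (first generation each
#'   solution appeared), `history` (best equal-weight objective sum per
#'   generation), `free`, `masterSeed`.
#' @seealso [selectSolution()]
#' @export
fitParameters <- function(target, free, base, popSize = 64,
                          generations = 50, replicates = 10,
                          cohortSize = 20, masterSeed = 1,
                          includeCategories = FALSE,
                          crossoverProb = 0.9, mutationProb = NULL,
                          blendAlpha = 0.5) {
  stopifnot(inherits(target, "SummaryCurves"), is(base, "ModelParams"),
            length(free) >= 1, popSize >= 2)
  lo <- vapply(free, `[`, numeric(1), 1L)
  hi <- vapply(free, `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("infeasible bounds: need finite low < high per parameter")
  d <- length(free)
  if (is.null(mutationProb)) mutationProb <- 1 / d
  evalSeeds <- deriveSeeds(masterSeed, replicates)

  evalCandidate <- function(theta) {
    params <- base
    for (k in seq_len(d)) slot(params, names(free)[k]) <- theta[k]
    objs <- vapply(evalSeeds, function(s) {
      cohort <- simulateCohort(params, n = cohortSize, masterSeed = s)
      summaryObjectives(
        cohortSummary(cohort, binWidth = target$binWidth,
                      categories = includeCategories),
        target, includeCategories = includeCategories)
    }, numeric(if (includeCategories) 4L else 3L))
    rowMeans(objs)
  }

  withSeed(masterSeed + 1L, {
    pop <- matrix(runif(popSize * d, rep(lo, each = popSize),
                        rep(hi, each = popSize)),
                  nrow = popSize, dimnames = list(NULL, names(free)))
    obj <- t(apply(pop, 1, evalCandidate))

    archP <- pop; archO <- obj; archG <- rep(0L, popSize)
    pruneArchive <- function() {
      keep <- !vapply(seq_len(nrow(archO)), function(i)
        any(vapply(seq_len(nrow(archO)), function(j)
          i != j && (.dominates(archO[j, ], archO[i, ]) ||
                       (j < i && all(archO[j, ] == archO[i, ]))),
          logical(1))), logical(1))
      archP <<- archP[keep, , drop = FALSE]
      archO <<- archO[keep, , drop = FALSE]
      archG <<- archG[keep]
    }
    pruneArchive()
    history <- data.frame(generation = 0L,
                          bestWeighted = min(rowMeans(archO)))

    for (gen in seq_len(generations)) {
      rank <- .ndRank(obj)
      crowd <- numeric(popSize)
      for (r in unique(rank)) {
        idx <- which(rank == r)
        crowd[idx] <- .crowding(obj[idx, , drop = FALSE])
      }
      tournament <- function() {
        ij <- sample.int(popSize, 2)
        i <- ij[1]; j <- ij[2]
        if (rank[i] < rank[j]) i
        else if (rank[j] < rank[i]) j
        else if (crowd[i] >= crowd[j]) i else j
      }
      child <- matrix(NA_real_, popSize, d,
                      dimnames = list(NULL, names(free)))
      for (k in seq(1, popSize, by = 2)) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (runif(1) < crossoverProb) {
          cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
          span <- cmax - cmin
          c1 <- runif(d, cmin - blendAlpha * span,
                      cmax + blendAlpha * span)
          c2 <- runif(d, cmin - blendAlpha * span,
                      cmax + blendAlpha * span)
        } else {
          c1 <- p1; c2 <- p2
        }
        child[k, ] <- c1
        if (k + 1 <= popSize) child[k + 1, ] <- c2
      }
      mut <- matrix(runif(popSize * d) < mutationProb, popSize, d)
      if (any(mut)) {
        draws <- matrix(runif(popSize * d, rep(lo, each = popSize),
                              rep(hi, each = popSize)), popSize, d)
        child[mut] <- draws[mut]
      }
      child <- pmin(pmax(child, rep(lo, each = popSize)),
                    rep(hi, each = popSize))
      childObj <- t(apply(child, 1, evalCandidate))

      archP <- rbind(archP, child); archO <- rbind(archO, childObj)
      archG <- c(archG, rep(gen, popSize))
      pruneArchive()
      history <- rbind(history,
                       data.frame(generation = gen,
                                  bestWeighted = min(rowMeans(archO))))

      ## elitist (mu + lambda) environmental selection
      allP <- rbind(pop, child); allO <- rbind(obj, childObj)
      r <- .ndRank(allO)
      sel <- integer()
      for (fr in sort(unique(r))) {
        idx <- which(r == fr)
        if (length(sel) + length(idx) <= popSize) {
          sel <- c(sel, idx)
        } else {
          cd <- .crowding(allO[idx, , drop = FALSE])
          sel <- c(sel, idx[order(cd, decreasing = TRUE)
                            [seq_len(popSize - length(sel))]])
          break
        }
      }
      pop <- allP[sel, , drop = FALSE]
      obj <- allO[sel, , drop = FALSE]
    }

    structure(list(parameters = archP, objectives = archO,
                   generation = archG, history = history,
                   free = free, masterSeed = masterSeed),
              class = "ParetoFront")
  })
}

#' @export
print.ParetoFront <- function(x, ...) {
  cat(sprintf("ParetoFront: %d non-dominated solutions over %s, seed %d\n",
              nrow(x$parameters),
              paste(names(x$free), collapse = ", "), x$masterSeed))
  cat(sprintf("  best equal-weight objective: %.4f\n",
              min(rowMeans(x$objectives))))
  invisible(x)
}

#' Select one solution from a Pareto front
#'
#' Minimizer of the weighted objective sum; ties are broken by
#' lexicographic comparison of the objective vectors.
#'
#' @param front a `"ParetoFront"` from [fitParameters()].
#' @param weights per-objective weights (default equal).
#' @return List with `parameters`, `objectives`, `index`.
#' @export
selectSolution <- function(front, weights = NULL) {
  stopifnot(inherits(front, "ParetoFront"),
            nrow(front$objectives) >= 1)
  m <- ncol(front$objectives)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m)
  score <- as.numeric(front$objectives %*% weights)
  best <- which(score == min(score))
  if (length(best) > 1L) {
    o <- do.call(order,
                 c(lapply(seq_len(m),
                          function(j) front$objectives[best, j]),
                   list(method = "radix")))
    best <- best[o[1L]]
  }
  list(parameters = front$parameters[best, ],
       objectives = front$objectives[best, ],
       index = best)
}
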