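presetTable <- list(
  mice_SP  = c(r10 = 4.98, r20 = 4.72, tauR = 100406, s = 1),
  mice_SNP = c(r10 = 4.70, r20 = 4.90, tauR = 100406, s = 1),
  rats_SP  = c(r10 = 5.80, r20 = 4.72, tauR = 33406,  s = -1),
  rats_SNP = c(r10 = 5.05, r20 = 5.30, tauR = 33406,  s = -1)
)

test_that("presets carry the fitted parameter values bit-faithfully", {
  for (nm in names(presetTable)) {
    p <- modelPreset(nm)
    expect_identical(p@a0, 7.66)
    expect_identical(p@tauA, 10355.62)
    expect_identical(p@beta1r, 1.1)
    expect_identical(p@beta2r, 1.12)
    expect_identical(p@beta1a, -0.08)
    expect_identical(p@beta2a, 0.71)
    expect_identical(p@S0, 2.72)
    expect_identical(p@E0, 5.19)
    want <- presetTable[[nm]]
    expect_identical(p@r10, unname(want["r10"]))
    expect_identical(p@r20, unname(want["r20"]))
    expect_identical(p@tauR, unname(want["tauR"]))
    expect_identical(p@s, unname(want["s"]))
  }
})

test_that("anxiety decays from its initial value minus the reward conflict", {
  p <- modelPreset("mice_SP")
  expect_equal(anxiety(0, p@r10, p@r20, p), 7.40)
  ## strictly decreasing in t for fixed rewards
  ts <- seq(0, 5e4, length.out = 40)
  a <- anxiety(ts, p@r10, p@r20, p)
  expect_true(all(diff(a) < 0))
  ## long-time limit is minus the absolute reward difference
  expect_equal(anxiety(1e9, 5, 3, p), -2, tolerance = 1e-12)
  ## clamped variant never goes negative
  pc <- modelPreset("mice_SP", clampAnxiety = TRUE)
  expect_gte(anxiety(1e9, 5, 3, pc), 0)
})

test_that("reward grows or decays exponentially with investigation time", {
  p <- modelPreset("mice_SP")
  expect_identical(reward(0, 4.98, p), 4.98)
  expect_equal(reward(p@tauR, 4.98, p), 4.98 * exp(1))
  r <- modelPreset("rats_SP")
  Ts <- seq(0, 1e5, length.out = 30)
  expect_true(all(diff(reward(Ts, 5.8, r)) <= 0))
})

test_that("transition rows are stochastic with the forbidden moves at zero", {
  p <- modelPreset("mice_SP")
  set.seed(9)
  for (i in 1:50) {
    a <- runif(1, -5, 10); r1 <- runif(1, 0, 8); r2 <- runif(1, 0, 8)
    for (state in 1:4) {
      pr <- transitionProbabilities(state, a, r1, r2, p)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr >= 0))
      zeros <- switch(state, c(2, 4), c(1, 4), integer(), c(1, 2))
      expect_identical(unname(pr[zeros]), rep(0, length(zeros)))
    }
  }
})

test_that("symmetric inputs give the sigmoid midpoint and uniform softmax", {
  p <- modelPreset("mice_SP")
  ## zero logit in an investigation state: stay probability one half
  pr <- transitionProbabilities(1, a = 0, r1 = 0, r2 = 1, p)
  expect_identical(unname(pr[1]), 0.5)
  ## all four stillness logits equal: uniform choice
  rEq <- p@E0 / p@beta2r
  aEq <- p@E0 / (p@S0 * p@beta2a)
  pr <- transitionProbabilities(3, aEq, rEq, rEq, p)
  expect_equal(unname(pr), rep(0.25, 4), tolerance = 1e-12)
  ## exploration stay probability at zero anxiety
  pr <- transitionProbabilities(4, 0, 1, 1, p)
  expect_equal(unname(pr[4]), 1 / (1 + exp(-(2.72 + 5.19))),
               tolerance = 1e-12)
})

test_that("the simulated chain is reproducible and honors degenerate rows", {
  p <- modelPreset("mice_SP")
  expect_identical(simulateStates(p, 5000, seed = 3),
                   simulateStates(p, 5000, seed = 3))
  ## saturated exploration logit pins the chain in place
  stuck <- p
  stuck@S0 <- 400; stuck@E0 <- 400
  stuck@initialState <- "exploration"
  expect_true(all(simulateStates(stuck, 2000, seed = 1) == 4L))
})

test_that("with frozen dynamics the simulator matches the analytic chain", {
  p <- modelPreset("mice_SP")
  p@tauR <- Inf; p@tauA <- Inf
  path <- simulateStates(p, 2e5, seed = 77)
  a0 <- anxiety(0, p@r10, p@r20, p)
  counts <- table(factor(head(path, -1), levels = 1:4),
                  factor(tail(path, -1), levels = 1:4))
  for (state in 1:4) {
    nFrom <- sum(counts[state, ])
    want <- transitionProbabilities(state, a0, p@r10, p@r20, p)
    phat <- as.numeric(counts[state, ]) / nFrom
    se <- sqrt(want * (1 - want) / nFrom)
    expect_true(all(abs(phat - want) <= 3 * se + 1e-12),
                label = sprintf("state %d frequencies", state))
  }
})

test_that("simulated sessions are valid and cohort simulation is reproducible", {
  p <- modelPreset("mice_SP")
  zero <- modelPreset("mice_SP", testDuration = 0)
  expect_equal(nrow(events(simulateSession(zero, 1))), 0L)
  for (seed in c(1, 23)) {
    s <- simulateSession(p, seed)
    expect_length(validateSession(s), 0L)
    expect_true(all(events(s)$offset <= 300))
  }
  co <- simulateCohort(p, n = 3, masterSeed = 5)
  co2 <- simulateCohort(p, n = 3, masterSeed = 5)
  expect_equal(lapply(co, events), lapply(co2, events))
  ## n = 1 cohort equals a single session at the derived seed
  one <- simulateCohort(p, n = 1, masterSeed = 5)
  seed1 <- socialMarkov:::deriveSeeds(5, 1)
  expect_equal(events(one[[1]]),
               events(simulateSession(p, seed1, subjectId = "sim001")))
  ## cohorts feed the metrics pipeline directly
  expect_s3_class(cohortSummary(co), "SummaryCurves")
})

test_that("time-scale calibration is deterministic and favors realistic dynamics", {
  expect_equal(as.numeric(calibrateTimeScale(candidates = 0.02, n = 2)),
               0.02)
  a <- calibrateTimeScale(candidates = c(0.005, 0.02), n = 4)
  b <- calibrateTimeScale(candidates = c(0.005, 0.02), n = 4)
  expect_identical(attr(a, "scores"), attr(b, "scores"))
  expect_error(calibrateTimeScale(candidates = numeric()))
  ## at the calibrated default the mouse transition-rate curve peaks
  ## early and settles lower late in the test
  co <- simulateCohort(modelPreset("mice_SP"), n = 30, masterSeed = 8)
  tr <- cohortSummary(co)$transitionRate
  peak <- which.max(tr$mean)
  expect_lt(tr$binStart[peak], 150)
  lateMean <- mean(tr$mean[tr$binStart >= 180])
  expect_gt(max(tr$mean), lateMean)
})
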