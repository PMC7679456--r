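test_that("event logs round-trip through write/read exactly", {
  for (seed in c(2, 17, 91)) {
    sessions <- list(a = randomSession(seed), b = randomSession(seed + 100))
    f <- withr::local_tempfile(fileext = ".csv")
    writeEventLog(sessions, f)
    back <- readEventLog(f)
    expect_named(back, c("a", "b"))
    for (k in names(sessions)) {
      expect_identical(subjectId(back[[k]]), subjectId(sessions[[k]]))
      expect_equal(events(back[[k]]), events(sessions[[k]]),
                   tolerance = 1e-12)
    }
  }
  ## two writes of the same sessions are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  s <- randomSession(5)
  writeEventLog(s, f1); writeEventLog(s, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty session writes a header-only file", {
  s <- behaviorSession("empty", data.frame(stimulus = character(),
                                           onset = numeric(),
                                           offset = numeric()))
  f <- withr::local_tempfile()
  writeEventLog(s, f)
  expect_length(readLines(f), 1L)
})

test_that("malformed event logs are rejected with row numbers", {
  f <- withr::local_tempfile()
  writeLines(c("subject_id,stimulus,onset_s,offset_s",
               "m1,stim1,0,2", "m1,stim2,3,4", "m1,stim1,6,5"), f)
  expect_error(readEventLog(f), "row\\(s\\) 4")
  writeLines(c("subject_id,stimulus,onset_s,offset_s",
               "m1,stim1,x,2"), f)
  expect_error(readEventLog(f), "non-numeric")
  writeLines(c("subject_id,stimulus,onset_s",
               "m1,stim1,0"), f)
  expect_error(readEventLog(f), "missing column")
  writeLines(c("subject_id,stimulus,onset_s,offset_s",
               "m1,object,0,2"), f)
  expect_error(readEventLog(f), "unknown stimulus")
})

test_that("sub-threshold same-stimulus gaps merge into single bouts", {
  ev <- data.frame(stimulus = "stim1", onset = c(0, 2.4),
                   offset = c(2, 5))
  expect_equal(mergeInvestigationGaps(ev),
               data.frame(stimulus = "stim1", onset = 0, offset = 5))
  ## a gap exactly at the threshold is NOT merged
  ev$onset[2] <- 2.5
  expect_equal(nrow(mergeInvestigationGaps(ev)), 2L)
  ## empty input passes through
  empty <- data.frame(stimulus = character(), onset = numeric(),
                      offset = numeric())
  expect_equal(nrow(mergeInvestigationGaps(empty)), 0L)
  ## an intervening other-stimulus bout blocks the merge
  ev3 <- data.frame(stimulus = c("stim1", "stim2", "stim1"),
                    onset = c(0, 2.1, 2.4), offset = c(2, 2.3, 5))
  merged <- mergeInvestigationGaps(ev3)
  expect_equal(nrow(merged), 3L)
})

test_that("gap merging matches the pairwise-fusion oracle and is idempotent", {
  for (seed in 1:10) {
    s <- randomSession(seed, nEvents = 50, maxGapS = 1.2, maxDurS = 3)
    got <- mergeInvestigationGaps(events(s))
    want <- oracleMerge(events(s))
    expect_equal(got, want, tolerance = 1e-12)
    ## idempotent
    expect_equal(mergeInvestigationGaps(got), got, tolerance = 1e-12)
    ## event count non-increasing, covered time non-decreasing
    expect_lte(nrow(got), nrow(events(s)))
    for (stim in c("stim1", "stim2")) {
      before <- events(s)[events(s)$stimulus == stim, ]
      after <- got[got$stimulus == stim, ]
      expect_gte(sum(after$offset - after$onset) + 1e-12,
                 sum(before$offset - before$onset))
    }
    ## merged sessions remain valid (no cross-stimulus overlap)
    expect_length(validateSession(mergeInvestigationGaps(s)), 0L)
  }
})

test_that("validateSession reports violations as data", {
  ok <- behaviorSession("m1", data.frame(stimulus = "stim1",
                                         onset = 0, offset = 2))
  expect_length(validateSession(ok), 0L)
  past <- new("BehaviorSession", subjectId = "m1", groupTag = "",
              testDuration = 300,
              events = data.frame(stimulus = "stim1", onset = 290,
                                  offset = 310),
              positions = NULL, rngSeed = NA_integer_)
  expect_match(validateSession(past), "after testDuration", all = FALSE)
  overl <- new("BehaviorSession", subjectId = "m1", groupTag = "",
               testDuration = 300,
               events = data.frame(stimulus = c("stim1", "stim1"),
                                   onset = c(0, 1), offset = c(2, 3)),
               positions = NULL, rngSeed = NA_integer_)
  expect_match(validateSession(overl), "overlapping stim1", all = FALSE)
  cross <- new("BehaviorSession", subjectId = "m1", groupTag = "",
               testDuration = 300,
               events = data.frame(stimulus = c("stim1", "stim2"),
                                   onset = c(0, 1), offset = c(2, 3)),
               positions = NULL, rngSeed = NA_integer_)
  expect_match(validateSession(cross), "across stimuli", all = FALSE)
})

test_that("contact logs round-trip and obey the gap rule", {
  con <- data.frame(onset = c(1, 5.2, 20), offset = c(5, 8, 26))
  f <- withr::local_tempfile()
  writeContactLog(con, f)
  merged <- readContactLog(f)           # 0.5-s rule fuses first two
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$onset, c(1, 20))
  expect_equal(merged$offset, c(8, 26))
  raw <- readContactLog(f, merge = FALSE)
  expect_equal(raw, con)
})

test_that("trajectories read back and arena specs validate", {
  f <- withr::local_tempfile()
  writeLines(c("time_s,x,y", "0,1,1", "0.5,2,2", "1,3,3"), f)
  pos <- readTrajectory(f)
  expect_equal(pos$time, c(0, 0.5, 1))
  writeLines(c("time_s,x,y", "0,1,1", "0,2,2"), f)
  expect_error(readTrajectory(f), "strictly increasing")
  expect_error(arenaSpec(-1, 10), "width")
  expect_error(arenaSpec(10, 10, centerFraction = 1.2))
  a <- arenaSpec(40, 30)
  expect_equal(a$centerFraction, 0.3)
})
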