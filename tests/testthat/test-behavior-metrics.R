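test_that("binned investigation time splits bouts across bins correctly", {
  s <- behaviorSession("m1", data.frame(stimulus = "stim1",
                                        onset = 10, offset = 50))
  b <- binnedInvestigationTime(s)
  v1 <- b$value[b$stimulus == "stim1"]
  expect_equal(v1[1:3], c(10, 20, 10))
  expect_equal(sum(v1), 40)
  expect_equal(b$value[b$stimulus == "stim2"], rep(0, 15))
  ## no events -> all zero
  e <- behaviorSession("m2", data.frame(stimulus = character(),
                                        onset = numeric(),
                                        offset = numeric()))
  expect_true(all(binnedInvestigationTime(e)$value == 0))
  expect_error(binnedInvestigationTime(s, binWidth = 0))
})

test_that("binned time matches a 1-ms discretization oracle and conserves totals", {
  for (seed in c(3, 14, 60)) {
    s <- mergeInvestigationGaps(randomSession(seed))
    b <- binnedInvestigationTime(s)
    orc <- oracleBinnedTime(s)
    for (stim in c("stim1", "stim2")) {
      expect_equal(b$value[b$stimulus == stim], orc[[stim]],
                   tolerance = 1e-6)
      ev <- events(s)
      tot <- sum(ev$offset[ev$stimulus == stim] -
                   ev$onset[ev$stimulus == stim])
      expect_equal(sum(b$value[b$stimulus == stim]), tot,
                   tolerance = 1e-6)
    }
  }
})

test_that("bout categorization respects duration boundaries and last-minute exclusion", {
  ev <- data.frame(stimulus = "stim1",
                   onset = c(0, 10, 20, 50, 280),
                   offset = c(0 + 5.9, 10 + 6.0, 20 + 19.0, 50 + 19.5,
                              280 + 5))
  s <- behaviorSession("m1", ev)
  cat <- boutCatalog(s)
  expect_equal(as.character(cat$category),
               c("short", "intermediate", "intermediate", "long"))
  ## bout starting at 280 s (inside the final minute) was dropped
  expect_equal(nrow(cat), 4L)
  all5 <- boutCatalog(s, excludeLastMinute = FALSE)
  expect_equal(nrow(all5), 5L)
  expect_error(boutCatalog(s, shortMax = 20, longMin = 19))
})

test_that("pooled category time credits full durations to onset bins", {
  s <- behaviorSession("m1", data.frame(stimulus = "stim1",
                                        onset = 70, offset = 95))
  pc <- pooledCategoryTime(boutCatalog(s))
  hit <- pc[pc$category == "long" & pc$stimulus == "stim1" &
              pc$binStart == 60, ]
  expect_equal(hit$value, 25)
  expect_equal(sum(pc$value), 25)
  ## conservation over random sessions: bin/category sums equal total
  ## retained bout time
  for (seed in c(8, 21)) {
    rs <- mergeInvestigationGaps(randomSession(seed))
    cat <- boutCatalog(rs)
    pc <- pooledCategoryTime(cat)
    expect_equal(sum(pc$value), sum(cat$duration), tolerance = 1e-9)
  }
  ## empty catalog -> zeros
  e <- behaviorSession("m1", data.frame(stimulus = character(),
                                        onset = numeric(),
                                        offset = numeric()))
  expect_true(all(pooledCategoryTime(boutCatalog(e))$value == 0))
})

test_that("RDI is the normalized absolute investigation difference", {
  expect_equal(rdi(10, 10), 0)
  expect_equal(rdi(10, 0), 1)
  expect_equal(rdi(30, 10), 0.5)
  expect_warning(expect_true(is.na(rdi(0, 0))), "undefined")
  ## symmetric under relabeling, bounded
  set.seed(4)
  for (i in 1:20) {
    t1 <- runif(1, 0, 100); t2 <- runif(1, 0, 100)
    expect_equal(rdi(t1, t2), rdi(t2, t1))
    expect_gte(rdi(t1, t2), 0); expect_lte(rdi(t1, t2), 1)
  }
})

test_that("transitions are onsets of bouts at a new stimulus", {
  ev <- data.frame(stimulus = c("stim1", "stim1", "stim2", "stim1"),
                   onset = c(0, 5, 10, 15),
                   offset = c(2, 7, 12, 17))
  s <- behaviorSession("m1", ev)
  expect_equal(transitionTimes(s), c(0, 10, 15))
  expect_equal(transitionTimes(s, countFirstBout = FALSE), c(10, 15))
  ## single-stimulus session with flag off
  s1 <- behaviorSession("m1", ev[ev$stimulus == "stim1", ])
  expect_length(transitionTimes(s1, countFirstBout = FALSE), 0L)
  ## run-length-encoding oracle on random sessions, both conventions
  for (seed in 30:39) {
    rs <- mergeInvestigationGaps(randomSession(seed, nEvents = 50))
    for (flag in c(TRUE, FALSE))
      expect_length(transitionTimes(rs, flag),
                    oracleTransitionCount(rs, flag))
  }
})

test_that("transition rate bins counts and conserves the total", {
  ev <- data.frame(stimulus = c("stim1", "stim2", "stim1"),
                   onset = c(5, 15, 25), offset = c(6, 16, 26))
  s <- behaviorSession("m1", ev)
  tr <- transitionRate(s)
  expect_equal(tr$count[1:3], c(2, 1, 0))
  expect_equal(sum(tr$count), length(transitionTimes(s)))
  e <- behaviorSession("m1", data.frame(stimulus = character(),
                                        onset = numeric(),
                                        offset = numeric()))
  expect_true(all(transitionRate(e)$count == 0))
})

test_that("mean bout duration per bin averages by onset bin with NA for empty bins", {
  ev <- data.frame(stimulus = c("stim1", "stim2"),
                   onset = c(10, 30), offset = c(14, 38))
  s <- behaviorSession("m1", ev)
  mb <- meanBoutDurationPerBin(s)
  expect_equal(mb$meanDuration[1], 6)
  expect_true(all(is.na(mb$meanDuration[-1])))
  ## group-by oracle
  for (seed in c(11, 55)) {
    rs <- mergeInvestigationGaps(randomSession(seed))
    mb <- meanBoutDurationPerBin(rs)
    ev <- events(rs)
    want <- tapply(ev$offset - ev$onset, floor(ev$onset / 60), mean)
    got <- mb$meanDuration[as.integer(names(want)) + 1L]
    expect_equal(unname(got), unname(as.numeric(want)))
  }
})

test_that("cohort summaries aggregate mean and SEM over subjects", {
  s <- mergeInvestigationGaps(randomSession(7))
  same <- lapply(1:4, function(i) {
    x <- s; x@subjectId <- sprintf("m%d", i); x
  })
  cs <- cohortSummary(same)
  expect_true(all(cs$investigation$sem == 0))
  expect_equal(cs$n, 4L)
  ## n = 1: mean equals the single series
  one <- cohortSummary(list(s))
  b <- binnedInvestigationTime(s)
  expect_equal(one$investigation$mean, b$value)
  ## two-pass textbook mean/SEM on a random cohort
  cohort <- lapply(1:6, function(i)
    mergeInvestigationGaps(randomSession(100 + i)))
  cs <- cohortSummary(cohort)
  mat <- sapply(cohort, function(x) {
    b <- binnedInvestigationTime(x); b$value[b$stimulus == "stim1"]
  })
  expect_equal(cs$investigation$mean[cs$investigation$stimulus ==
                                       "stim1"],
               rowMeans(mat))
  expect_equal(cs$investigation$sem[cs$investigation$stimulus ==
                                      "stim1"],
               apply(mat, 1, sd) / sqrt(6))
  ## heatmap rows are ordered by subject id
  expect_equal(rownames(cs$heatmap$stim1),
               sort(sapply(cohort, subjectId)))
  ## mixed durations are rejected
  short <- behaviorSession("x", data.frame(stimulus = "stim1",
                                           onset = 1, offset = 2),
                           testDuration = 200)
  expect_error(cohortSummary(list(s, short)), "mixed")
})

test_that("center/periphery ratio apportions time by zone", {
  arena <- arenaSpec(40, 40)
  cx <- 20; peri <- c(1, 1)
  ## entirely peripheral trajectory
  pos <- data.frame(time = 0:10, x = peri[1], y = peri[2])
  expect_equal(centerPeripheryRatio(pos, arena), 0)
  ## half the time in the center
  pos <- data.frame(time = 0:10,
                    x = rep(c(cx, peri[1]), length.out = 11),
                    y = rep(c(cx, peri[2]), length.out = 11))
  expect_equal(centerPeripheryRatio(pos, arena), 1)
  ## constructed 20% center occupancy -> ratio 0.25
  pos <- data.frame(time = seq(0, 100, by = 1),
                    x = c(rep(cx, 20), rep(peri[1], 81)),
                    y = c(rep(cx, 20), rep(peri[2], 81)))
  expect_equal(centerPeripheryRatio(pos, arena), 0.25)
  ## all-center trajectory is unbounded
  pos <- data.frame(time = 0:10, x = cx, y = cx)
  expect_warning(expect_equal(centerPeripheryRatio(pos, arena), Inf),
                 "unbounded")
})

test_that("contact metrics split total time at the class threshold", {
  con <- data.frame(onset = c(0, 10), offset = c(3, 20))
  m <- contactMetrics(con)
  expect_equal(m$short, 3)
  expect_equal(m$long, 10)
  expect_equal(m$total, 13)
  expect_equal(contactMetrics(data.frame(onset = numeric(),
                                         offset = numeric()))$total, 0)
  ## classes always partition the total
  for (seed in c(2, 9)) {
    g <- genContactLog(600, hazard = 0.05, meanContact = 5, seed = seed)
    m <- contactMetrics(g$contacts)
    expect_equal(m$short + m$long, m$total)
  }
})
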