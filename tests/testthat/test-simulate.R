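test_that("choice process hits its analytic extremes", {
  ## perfect alternation
  tr <- simulateChoices(agentParams(alternationFidelity = 1), nVisits = 60,
                        seed = 71)
  expect_equal(alternationRate(classifyChoices(tr$visits$arm)), 1)

  ## memoryless unbiased agent converges to 0.5
  tr <- simulateChoices(agentParams(alternationFidelity = 0, turningBias = 0),
                        nVisits = 3000, seed = 72)
  r <- alternationRate(classifyChoices(tr$visits$arm))
  expect_lt(abs(r - 0.5), 3 * sqrt(0.25 / 2998))

  ## memoryless biased agent converges to q^2 + (1-q)^2 = 0.82
  tr <- simulateChoices(agentParams(alternationFidelity = 0, turningBias = 0.4),
                        nVisits = 3000, seed = 73)
  r <- alternationRate(classifyChoices(tr$visits$arm))
  expect_lt(abs(r - 0.82), 3 * sqrt(0.82 * 0.18 / 2998))
})

test_that("the generator's own outcome bookkeeping agrees with the classifier", {
  tr <- simulateChoices(agentParams(), nVisits = 80, seed = 74)
  ch <- classifyChoices(tr$visits$arm)
  expect_equal(ch$outcome, tr$visits$outcome[-(1:2)])
})

test_that("schedules and cohorts are reproducible from their seeds", {
  p <- agentParams(sessionDuration = 60)
  a <- simulateChoices(p, seed = 75)
  b <- simulateChoices(p, seed = 75)
  expect_identical(a$visits, b$visits)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateCohort(p, n = 2, dir = d1, seed = 76)
  simulateCohort(p, n = 2, dir = d2, seed = 76)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("a dwell-only agent produces an empty visit sequence", {
  p <- agentParams(dwellCenter = 1e6, sessionDuration = 30)
  sim <- simulateSession(p, defaultGeometry(), seed = 77)
  expect_equal(nVisits(sim$truth$groundTruthVisits), 0L)
  det <- detectVisits(projectSession(sim$session, defaultGeometry()), 0.25)
  expect_equal(nVisits(det), 0L)
})

test_that("measured travel distance tracks the analytic path length", {
  geom <- defaultGeometry()
  for (sp in c(12, 24)) {
    p <- agentParams(speed = sp, sessionDuration = 120)
    sim <- simulateSession(p, geom, seed = 78)
    tr <- projectSession(sim$session, geom)
    lm <- locomotionMetrics(tr, detectVisits(tr, 0.25), geom)
    expect_lt(abs(lm$travelDistance - sim$pathLengthCm) / sim$pathLengthCm,
              0.01)
  }
})

test_that("partial visits lower the sufficiency ratio only above their depth", {
  tr <- simulateChoices(agentParams(pFull = 0.5), nVisits = 120, seed = 79)
  vs <- visitsFromTruth(tr, sessionID = "s")
  sw <- thresholdSweep(vs)
  expect_equal(sw$visitRatio[sw$threshold == 0.25], 1)
  expect_lt(sw$visitRatio[sw$threshold == 0.70], 1)
  expect_true(all(diff(sw$visitRatio) <= 0))
})

test_that("rendering with center wander still recovers the programmed visits", {
  geom <- defaultGeometry()
  p <- agentParams(centerDwellRadius = 0.2, sessionDuration = 120)
  sim <- simulateSession(p, geom, seed = 80)
  gt <- visits(sim$truth$groundTruthVisits)
  det <- visits(detectVisits(projectSession(sim$session, geom), 0.25))
  expect_identical(det$arm, gt$arm)
  expect_lt(max(abs(det$tEntry - gt$tEntry)), 1 / 30 + 1e-9)
})

test_that("cohort-mean alternation recovers the programmed expectation", {
  p <- agentParams(alternationFidelity = 0.7, pFull = 1)
  nC <- 0L
  nS <- 0L
  for (i in 1:8) {
    tr <- simulateChoices(p, seed = 81 + i)
    o <- tr$visits$outcome
    nC <- nC + sum(o == "correct", na.rm = TRUE)
    nS <- nS + sum(!is.na(o))
  }
  expected <- expectedAlternationRate(0.7, 0.1)
  expect_lt(abs(nC / nS - expected),
            1.96 * sqrt(expected * (1 - expected) / nS) + 1e-12)
})

test_that("memory decay lowers alternation and deepens with threshold", {
  rate <- function(hl, thr) {
    r <- vapply(1:10, function(i) {
      tr <- simulateChoices(agentParams(memoryHalflife = hl), seed = 82 * i)
      alternationRate(classifyChoices(
        sufficientVisits(visitsFromTruth(tr, sessionID = "s"), thr)
      ))
    }, 0)
    mean(r, na.rm = TRUE)
  }
  expect_lt(rate(5, 0.25), rate(Inf, 0.25) - 0.05)
  ## within the decaying cohort the high-threshold subsequence is worse
  expect_lt(rate(5, 0.70), rate(5, 0.25))
})

test_that("written cohorts carry readable tracks, geometry and ground truth", {
  d <- withr::local_tempdir()
  p <- agentParams(sessionDuration = 60)
  man <- simulateCohort(p, n = 3, dir = d, seed = 83)
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$file)))
  expect_true(file.exists(file.path(d, "geometry.yaml")))
  gt <- jsonlite::read_json(file.path(d, "groundtruth.json"),
                            simplifyVector = TRUE)
  expect_equal(length(gt$sessionID), 3L)
  s <- readDLC(man$file[1], fps = 30)
  expect_s4_class(s, "TrackingSession")
  cfg <- readYmazeConfig(file.path(d, "geometry.yaml"))
  expect_s4_class(cfg$geometry, "MazeGeometry")
})
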