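test_that("arm choices are classified by the last two visited arms", {
  out <- classifyChoices(c("A", "B", "C", "A", "C", "B", "A", "A", "B"))
  expect_equal(out$outcome, c("correct", "correct", "incorrect", "correct",
                              "correct", "incorrect", "neutral"))
  expect_equal(nrow(out), 7L)

  expect_equal(classifyChoices(c("A", "B", "A"))$outcome, "incorrect")
  expect_equal(classifyChoices(c("A", "A", "B"))$outcome, "neutral")
  expect_equal(nrow(classifyChoices(c("A", "B"))), 0L)

  ## outcome/arm consistency invariants on random sequences
  set.seed(41)
  for (i in 1:20) {
    arms <- sample(c("A", "B", "C"), sample(3:40, 1), TRUE)
    ch <- classifyChoices(arms)
    expect_equal(nrow(ch), length(arms) - 2L)
    neutral <- ch$lastArm == ch$secondLastArm
    expect_equal(ch$outcome == "neutral", neutral)
    corr <- ch$outcome == "correct"
    expect_true(all(ch$currentArm[corr] != ch$lastArm[corr] &
                      ch$currentArm[corr] != ch$secondLastArm[corr]))
  }
})

test_that("alternation rate matches a brute-force oracle exactly", {
  expect_equal(
    alternationRate(classifyChoices(c("A", "B", "C", "A", "C", "B", "A", "A", "B"))),
    4 / 6
  )
  rot <- rep(c("A", "B", "C"), 10)
  expect_equal(alternationRate(classifyChoices(rot)), 1)
  pp <- rep(c("A", "B"), 10)
  expect_equal(alternationRate(classifyChoices(pp)), 0)
  expect_true(is.na(alternationRate(classifyChoices(rep("A", 8)))))

  set.seed(42)
  for (i in 1:300) {
    arms <- sample(c("A", "B", "C"), sample(3:50, 1), TRUE)
    expect_identical(alternationRate(classifyChoices(arms)),
                     oracleAlternation(arms))
  }
})

test_that("arm-choice bias counts directions on the counterclockwise ring", {
  ## transitions A->B, B->C, C->A are CCW; A->C is CW: bias |1/4 - 1/2|
  expect_equal(armChoiceBias(c("A", "B", "C", "A", "C")), 0.25)
  ## balanced: two CW, two CCW
  expect_equal(armChoiceBias(c("A", "B", "A", "B", "A")), 0)
  ## pure rotation: all transitions one way
  expect_equal(armChoiceBias(c("A", "C", "B", "A", "C")), 0.5)
  ## same-arm reentries carry no direction
  expect_equal(armChoiceBias(c("A", "A", "B")), 0.5)
  expect_true(is.na(armChoiceBias(c("A", "A", "A"))))
  expect_true(is.na(armChoiceBias("A")))
})

test_that("threshold sweep recomputes metrics per threshold", {
  ## full-depth visits: filtering never removes anything, so every metric
  ## is constant along the grid
  set.seed(43)
  arms <- sample(c("A", "B", "C"), 30, TRUE)
  vs <- makeVisits(arms, maxHead = runif(30, 0.9, 1), maxTail = runif(30, 0.9, 1))
  sw <- thresholdSweep(vs, grid = seq(0.25, 0.7, 0.01))
  expect_equal(length(unique(sw$correctRate)), 1L)
  expect_equal(unique(sw$nSufficient), 30L)
  expect_equal(unique(sw$visitRatio), 1)

  ## a single threshold at the boundary equals the unfiltered metrics
  sw1 <- thresholdSweep(vs, grid = 0.25)
  expect_equal(sw1$correctRate, alternationRate(classifyChoices(vs)))
  expect_equal(sw1$armChoiceBias, armChoiceBias(vs))
  expect_equal(sw1$nSufficient, nVisits(vs))

  expect_error(thresholdSweep(vs, grid = c(0.1, 0.3)), "boundary")
  expect_error(thresholdSweep(vs, grid = c(0.5, 0.4)), "increasing")

  ## with chance band attached
  sw2 <- thresholdSweep(vs, grid = c(0.25, 0.5), chanceIterations = 200,
                        seed = 5)
  expect_true(all(c("chanceMean", "chanceLow", "chanceHigh") %in% names(sw2)))
  expect_true(all(sw2$chanceLow <= sw2$chanceMean &
                    sw2$chanceMean <= sw2$chanceHigh))
})

test_that("difference in recency follows its defining formula", {
  ch <- data.frame(
    ordinal = 3L, currentArm = "C", lastArm = "B", secondLastArm = "A",
    outcome = "correct", tCurrentEntry = 40, tBExit = 30, tAExit = 10
  )
  rs <- recencyStatistics(ch)
  expect_equal(rs$timeSinceBExit, 10)
  expect_equal(rs$diffRecency, 2)

  ## zero numerator
  ch$tAExit <- 30
  expect_equal(recencyStatistics(ch)$diffRecency, 0)

  ## global time shift leaves both statistics unchanged; dilation scales
  ## the time but not the (dimensionless) difference in recency
  ch$tAExit <- 10
  shifted <- ch
  shifted[c("tCurrentEntry", "tBExit", "tAExit")] <-
    ch[c("tCurrentEntry", "tBExit", "tAExit")] + 1000
  expect_equal(recencyStatistics(shifted)$diffRecency, 2)
  expect_equal(recencyStatistics(shifted)$timeSinceBExit, 10)
  dilated <- ch
  dilated[c("tCurrentEntry", "tBExit", "tAExit")] <-
    ch[c("tCurrentEntry", "tBExit", "tAExit")] * 3
  expect_equal(recencyStatistics(dilated)$diffRecency, 2)
  expect_equal(recencyStatistics(dilated)$timeSinceBExit, 30)
})

test_that("recency statistics exclude the documented cases", {
  base <- data.frame(
    ordinal = 3:6,
    currentArm = c("C", "B", "C", "A"),
    lastArm = c("B", "B", "C", "B"),
    secondLastArm = c("A", "B", "A", "C"),
    outcome = c("correct", "neutral", "incorrect", "correct"),
    tCurrentEntry = c(40, 60, 80, 100),
    tBExit = c(30, 50, 70, 90),
    tAExit = c(10, 20, NA, 85)
  )
  rs <- recencyStatistics(base)
  ## row 2 neutral, row 3 same-arm reentry + undefined tA: both dropped
  expect_equal(rs$ordinal, c(3L, 6L))
  expect_equal(rs$diffRecency, c(2, 0.5))

  bad <- base[1, ]
  bad$tBExit <- 45  # exit after the entry it precedes: impossible
  expect_error(recencyStatistics(bad), "intervening")
})

test_that("recency timestamps flow correctly out of classifyChoices", {
  ## visits: A(0-5), B(10-15), C(20-25), B(30-35)
  vs <- makeVisits(c("A", "B", "C", "B"),
                   tEntry = c(0, 10, 20, 30), tExit = c(5, 15, 25, 35))
  ch <- classifyChoices(vs)
  ## choice 3 (C after A,B): B exited at 5 (arm A... the second-last visit),
  ## candidate arm C never exited before -> excluded from recency
  expect_equal(ch$tBExit, c(5, 15))
  expect_equal(ch$tAExit, c(NA_real_, 5))
  rs <- recencyStatistics(ch)
  ## only the 4th visit survives: B after (B,C) is incorrect, A last exited
  ## at t = 5, B (second-last candidate) at 15, entry at 30
  expect_equal(rs$ordinal, 4L)
  expect_equal(rs$outcome, "incorrect")
  expect_equal(rs$timeSinceBExit, 30 - 15)
  expect_equal(rs$diffRecency, (15 - 5) / (30 - 15))
})

test_that("locomotion metrics: entries, travel distance, arm preference", {
  geom <- defaultGeometry()
  ## stationary mouse
  tr <- makeTraj("A", rep(0, 50), headXY = matrix(300, 50, 2))
  vs <- detectVisits(tr, 0.25)
  lm0 <- locomotionMetrics(tr, vs, geom)
  expect_equal(lm0$nEntries, 0L)
  expect_equal(lm0$travelDistance, 0)

  ## straight run: 100 frames at 1 px per frame, 10 px/cm -> 9.9 cm
  xy <- cbind(300 + 0:99, 300)
  tr2 <- makeTraj("A", seq(0, 0.3, length.out = 100), headXY = xy)
  lm2 <- locomotionMetrics(tr2, vs, geom)
  expect_equal(lm2$travelDistance, 9.9)

  ## equal time in all three arms -> zero arm preference
  vs3 <- makeVisits(c("A", "B", "C"), tEntry = c(0, 20, 40),
                    tExit = c(7, 27, 47))
  expect_equal(locomotionMetrics(tr2, vs3, geom)$armPreference, 0)

  ## population (n = 3) standard deviation of per-arm dwell
  vs4 <- makeVisits(c("A", "B", "C"), tEntry = c(0, 20, 40),
                    tExit = c(0 + 2, 20 + 5, 40 + 11))
  expect_equal(locomotionMetrics(tr2, vs4, geom)$armPreference,
               sqrt(mean((c(2, 5, 11) - 6)^2)))
})

test_that("choice count invariant holds on simulated sessions", {
  for (s in 1:5) {
    tr <- simulateChoices(agentParams(), seed = 800 + s)
    vs <- visitsFromTruth(tr, sessionID = "s")
    expect_equal(nrow(classifyChoices(vs)), nVisits(vs) - 2L)
    sv <- sufficientVisits(vs, 0.7)
    if (nVisits(sv) >= 3L) {
      expect_equal(nrow(classifyChoices(sv)), nVisits(sv) - 2L)
    }
  }
})
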