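test_that("noiseless rendered sessions reproduce the programmed visits", {
  geom <- defaultGeometry()
  for (s in 1:5) {
    p <- agentParams(sessionDuration = 150)
    sim <- simulateSession(p, geom, seed = 30 + s)
    gt <- visits(sim$truth$groundTruthVisits)
    det <- visits(detectVisits(projectSession(sim$session, geom), 0.25))
    expect_identical(det$arm, gt$arm)
    expect_lt(max(abs(det$tEntry - gt$tEntry)), 1 / 30 + 1e-9)
    ok <- !gt$censored
    expect_lt(max(abs(det$tExit[ok] - gt$tExit[ok])), 1 / 30 + 1e-9)
    expect_lt(max(abs(det$maxHeadPos - gt$maxHeadPos)), 1e-9)
    expect_lt(max(abs(det$maxTailPos - gt$maxTailPos)), 1e-9)
  }
})

test_that("a trajectory that never leaves the center yields no visits", {
  tr <- makeTraj("A", rep(0.1, 100))
  expect_equal(nVisits(detectVisits(tr, 0.25)), 0L)
})

test_that("entry requires head and tail base beyond the boundary in the same arm", {
  ## head deep in arm A while the tail base is deep in arm B: no entry
  tr <- makeTraj(headArm = rep("A", 50), headPos = rep(0.8, 50),
                 tailArm = rep("B", 50), tailPos = rep(0.8, 50))
  expect_equal(nVisits(detectVisits(tr, 0.25)), 0L)

  ## same frames but with the tail base in A as well: one (censored) visit
  tr2 <- makeTraj(headArm = rep("A", 50), headPos = rep(0.8, 50),
                  tailArm = rep("A", 50), tailPos = rep(0.8, 50))
  v <- visits(detectVisits(tr2, 0.25))
  expect_equal(nrow(v), 1L)
  expect_true(v$censored)

  expect_error(detectVisits(tr2, 1.2), "boundary")
})

test_that("running maxima only count frames assigned to the visited arm", {
  ## mid-visit the head flicks into arm B's sector at a large radius;
  ## that frame must not inflate the arm-A maximum
  headArm <- c("A", "A", "A", "B", "A", "A")
  headPos <- c(0.30, 0.50, 0.60, 0.95, 0.55, 0.10)
  tailArm <- rep("A", 6)
  tailPos <- c(0.30, 0.45, 0.55, 0.60, 0.50, 0.10)
  v <- visits(detectVisits(makeTraj(headArm, headPos, tailArm, tailPos), 0.25))
  expect_equal(nrow(v), 1L)
  expect_equal(v$maxHeadPos, 0.60)
  expect_equal(v$maxTailPos, 0.60)
})

test_that("sufficiency filtering applies the AND-of-maxima rule", {
  vs <- makeVisits(c("A", "B", "C"),
                   maxHead = c(0.90, 0.90, 0.40),
                   maxTail = c(0.88, 0.65, 0.40))
  expect_equal(nVisits(sufficientVisits(vs, 0.25)), 3L)  # vacuous at boundary
  kept <- sufficientVisits(vs, 0.7)
  expect_equal(visits(kept)$arm, "A")  # B fails on the tail, C on both
  expect_error(sufficientVisits(vs, 0.1), "boundary")

  ## brute-force filter oracle on random visits
  set.seed(31)
  maxH <- runif(100, 0.25, 1.1)
  maxT <- runif(100, 0.25, 1.1)
  vs <- makeVisits(sample(c("A", "B", "C"), 100, TRUE),
                   tEntry = seq(0, by = 10, length.out = 100),
                   maxHead = maxH, maxTail = maxT)
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    expect_equal(nVisits(sufficientVisits(vs, thr)),
                 sum(maxH >= thr & maxT >= thr))
  }
})

test_that("visit ratio is the sufficient fraction and shrinks with threshold", {
  vs <- makeVisits(rep(c("A", "B"), 20),
                   maxHead = c(rep(1, 34), rep(0.5, 6)),
                   maxTail = c(rep(1, 34), rep(0.5, 6)))
  expect_equal(visitRatio(vs, sufficientVisits(vs, 0.7)), 0.85)
  expect_equal(visitRatio(vs, sufficientVisits(vs, 0.25)), 1)
  empty <- makeVisits(character(0), tEntry = numeric(0), tExit = numeric(0),
                      maxHead = numeric(0), maxTail = numeric(0))
  expect_true(is.na(visitRatio(empty, empty)))

  ## monotone non-increasing along a fine grid, on a simulated session
  tr <- simulateChoices(agentParams(), seed = 99)
  sw <- thresholdSweep(visitsFromTruth(tr, sessionID = "s"),
                       grid = seq(0.25, 1, 0.01))
  expect_true(all(diff(sw$nSufficient) <= 0))
  expect_true(all(diff(sw$visitRatio) <= 0 | is.na(diff(sw$visitRatio))))
})

test_that("visit detection is idempotent and ignores appended center frames", {
  geom <- defaultGeometry()
  sim <- simulateSession(agentParams(sessionDuration = 100), geom, seed = 77)
  tr <- projectSession(sim$session, geom)
  v1 <- visits(detectVisits(tr, 0.25))
  v2 <- visits(detectVisits(tr, 0.25))
  expect_identical(v1, v2)

  n <- length(tr@frameTimes)
  pad <- 60
  tr2 <- new("ProjectedTrajectory",
    frameTimes = c(tr@frameTimes, max(tr@frameTimes) + (1:pad) / 30),
    headArm = c(tr@headArm, rep("A", pad)),
    headPos = c(tr@headPos, rep(0, pad)),
    tailArm = c(tr@tailArm, rep("A", pad)),
    tailPos = c(tr@tailPos, rep(0, pad)),
    headXY = rbind(tr@headXY, matrix(300, pad, 2)),
    sessionID = tr@sessionID, fps = tr@fps, flags = list()
  )
  v3 <- visits(detectVisits(tr2, 0.25))
  expect_equal(v3$arm, v1$arm)
  expect_equal(v3$tEntry, v1$tEntry)
})
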