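## Independent oracles and small object builders shared across tests.

## Brute-force alternation scorer: walks the sequence and applies the
## correct/incorrect/neutral rule by direct set logic, independent of the
## package's vectorized implementation.
oracleAlternation <- function(arms) {
  n <- length(arms)
  nCorrect <- 0L
  nIncorrect <- 0L
  if (n >= 3L) {
    for (k in 3:n) {
      a <- arms[k]
      l <- arms[k - 1L]
      s <- arms[k - 2L]
      if (l == s) next
      if (a %in% c(l, s)) nIncorrect <- nIncorrect + 1L else
        nCorrect <- nCorrect + 1L
    }
  }
  if (nCorrect + nIncorrect == 0L) NA_real_ else
    nCorrect / (nCorrect + nIncorrect)
}

## Welch t-test by the textbook formulas.
oracleWelch <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

## Pearson r and its two-sided p from the t transform, by hand.
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}

## Build a ProjectedTrajectory directly from per-frame vectors.
makeTraj <- function(headArm, headPos, tailArm = headArm, tailPos = headPos,
                     fps = 30, headXY = NULL, sessionID = "test") {
  n <- length(headPos)
  if (is.null(headXY)) headXY <- cbind(seq_len(n), seq_len(n))
  new("ProjectedTrajectory",
    frameTimes = (seq_len(n) - 1) / fps,
    headArm = rep_len(headArm, n), headPos = headPos,
    tailArm = rep_len(tailArm, n), tailPos = tailPos,
    headXY = headXY, sessionID = sessionID, fps = fps, flags = list()
  )
}

## Build a VisitSequence from arm labels and (optionally) times/maxima.
makeVisits <- function(arms, tEntry = NULL, tExit = NULL,
                       maxHead = NULL, maxTail = NULL, boundary = 0.25,
                       censored = FALSE, sessionID = "test") {
  k <- length(arms)
  if (is.null(tEntry)) tEntry <- seq(0, by = 10, length.out = k)
  if (is.null(tExit)) tExit <- tEntry + 5
  if (is.null(maxHead)) maxHead <- rep(1, k)
  if (is.null(maxTail)) maxTail <- rep(1, k)
  new("VisitSequence",
    visits = data.frame(
      arm = arms, tEntry = tEntry, tExit = tExit,
      maxHeadPos = maxHead, maxTailPos = maxTail,
      censored = rep_len(censored, k)
    ),
    boundary = boundary, sessionID = sessionID
  )
}

## Random TrackingSession with all likelihoods 1.
makeSession <- function(n = 10, fps = 30, sessionID = "raw") {
  parts <- c("nose", "left_ear", "right_ear", "neck", "tail_base")
  arr <- array(
    runif(n * 5 * 3, 0, 600),
    dim = c(n, 5, 3), dimnames = list(NULL, parts, c("x", "y", "likelihood"))
  )
  arr[, , "likelihood"] <- 1
  trackingSession(arr, fps = fps, sessionID = sessionID)
}

## Per-subject correct-rate curves over the default sweep grid, computed
## from the agent's ground-truth schedule (no rendering).
truthCurves <- function(params, n, seedOffset) {
  t(vapply(seq_len(n), function(i) {
    tr <- simulateChoices(params, seed = seedOffset + i)
    thresholdSweep(visitsFromTruth(tr, sessionID = "s"))$correctRate
  }, numeric(46)))
}
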