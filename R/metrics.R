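#' Classify arm choices as correct, incorrect or neutral
#'
#' From the third visit onward each arm choice is scored against the two
#' preceding visits: if the last and second-last visited arms differ and
#' the current arm differs from both, the choice is correct; if the current
#' arm is one of those two, it is incorrect; if the last and second-last
#' arms are the same, the choice is neutral.  When the input carries visit
#' times the record also keeps the timestamps needed for recency
#' statistics: the current entry time, the exit time of the second-last
#' visit (arm B, the incorrect candidate) and the most recent prior exit
#' from the remaining arm (arm A, the correct candidate; `NA` if that arm
#' was never exited before).
#'
#' @param x a [VisitSequence-class] (typically of sufficient visits) or a
#'   character vector of arm labels.
#' @return a data.frame with one row per choice (`nrow = visits - 2`):
#'   `ordinal`, `currentArm`, `lastArm`, `secondLastArm`, `outcome`,
#'   `tCurrentEntry`, `tBExit`, `tAExit`.
#' @examples
#' classifyChoices(c("A", "B", "C", "A", "C", "B", "A", "A", "B"))$outcome
#' @export
classifyChoices <- function(x) {
  if (is(x, "VisitSequence")) {
    v <- x@visits
    .classify(v$arm, v$tEntry, ifelse(v$censored, NA_real_, v$tExit))
  } else {
    arms <- as.character(x)
    if (!all(arms %in% .ARMS)) stop("arm labels must be A, B or C")
    .classify(arms, rep(NA_real_, length(arms)), rep(NA_real_, length(arms)))
  }
}

.classify <- function(arms, tEntry, tExit) {
  n <- length(arms)
  empty <- data.frame(
    ordinal = integer(0), currentArm = character(0),
    lastArm = character(0), secondLastArm = character(0),
    outcome = character(0), tCurrentEntry = numeric(0),
    tBExit = numeric(0), tAExit = numeric(0)
  )
  if (n < 3L) return(empty)

  ia <- match(arms, .ARMS)
  cur <- ia[3:n]
  last <- ia[2:(n - 1L)]
  second <- ia[1:(n - 2L)]
  neutral <- last == second
  correct <- !neutral & cur != last & cur != second
  outcome <- ifelse(neutral, "neutral", ifelse(correct, "correct", "incorrect"))

  ## latest prior exit of the correct-candidate arm (A = the arm that is
  ## neither the last nor the second-last; indices sum to 6), tracked per arm
  aIdx <- ifelse(neutral, NA_integer_, 6L - last - second)
  tA <- rep(NA_real_, n - 2L)
  lastExit <- rep(NA_real_, 3L)
  for (k in seq_len(n - 2L)) {
    lastExit[ia[k]] <- tExit[k]
    if (!is.na(aIdx[k])) tA[k] <- lastExit[aIdx[k]]
  }
  list2DF(list(
    ordinal = 3:n, currentArm = .ARMS[cur], lastArm = .ARMS[last],
    secondLastArm = .ARMS[second],
    outcome = outcome, tCurrentEntry = tEntry[3:n],
    tBExit = tExit[1:(n - 2L)], tAExit = tA
  ))
}

#' Spontaneous alternation rate
#'
#' The number of correct choices divided by the number of correct plus
#' incorrect choices; neutral choices are excluded from both numerator and
#' denominator.
#'
#' @param choices a choice table from [classifyChoices()], or a
#'   [VisitSequence-class] / arm-label vector which is classified first.
#' @return the alternation rate in \code{[0, 1]}, or `NA` when no
#'   non-neutral choice exists.
#' @export
alternationRate <- function(choices) {
  if (!is.data.frame(choices)) choices <- classifyChoices(choices)
  nCorrect <- sum(choices$outcome == "correct")
  nScored <- nCorrect + sum(choices$outcome == "incorrect")
  if (nScored == 0L) return(NA_real_)
  nCorrect / nScored
}

#' Arm-choice (turning) bias
#'
#' Each consecutive pair of distinct visited arms is classified as a
#' clockwise or counterclockwise step on the arm ring A -> B -> C -> A
#' (counterclockwise).  The bias is the absolute difference between the
#' clockwise fraction and 0.5, so it lies in \code{[0, 0.5]}; same-arm
#' reentries carry no direction and are ignored.
#'
#' @param x a [VisitSequence-class] or a character vector of arm labels.
#' @return the bias, or `NA` when there is no directional transition.
#' @export
armChoiceBias <- function(x) {
  arms <- if (is(x, "VisitSequence")) x@visits$arm else as.character(x)
  if (length(arms) < 2L) return(NA_real_)
  dir <- .armDirection(arms[-length(arms)], arms[-1L])
  dir <- dir[!is.na(dir)]
  if (!length(dir)) return(NA_real_)
  abs(mean(dir == -1L) - 0.5)
}

#' Sweep the arm-visit threshold
#'
#' For each threshold on the grid the visit sequence is filtered to
#' sufficient visits and the per-threshold metrics are recomputed: number
#' of sufficient visits, sufficiency ratio, alternation (correct) rate and
#' arm-choice bias.  Optionally a bias-matched chance band is attached per
#' threshold (see [simulateChance()]).
#'
#' @param seq a [VisitSequence-class] of all arm entries.
#' @param grid strictly increasing thresholds within
#'   \code{[boundary(seq), 1]}; default `seq(boundary, 0.70, 0.01)`
#'   starting no lower than 0.25.
#' @param chanceIterations Monte-Carlo iterations per threshold for the
#'   chance band; 0 (default) skips the chance computation.
#' @param seed RNG seed for the chance simulations.
#' @return a data.frame (class `ymSweep`) with one row per threshold:
#'   `threshold`, `nSufficient`, `visitRatio`, `correctRate`,
#'   `armChoiceBias` and, when requested, `chanceMean`, `chanceLow`,
#'   `chanceHigh`.
#' @export
thresholdSweep <- function(seq, grid = NULL, chanceIterations = 0,
                           seed = NULL) {
  stopifnot(is(seq, "VisitSequence"))
  b <- seq@boundary
  if (is.null(grid)) grid <- seq(max(b, 0.25), 0.70, by = 0.01)
  if (any(grid < b) || any(grid > 1)) {
    stop("sweep grid must lie within [boundary, 1]")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("sweep grid must be strictly increasing")
  }
  v <- seq@visits
  nAll <- nrow(v)
  tEx <- ifelse(v$censored, NA_real_, v$tExit)
  K <- length(grid)
  nSuf <- integer(K)
  rate <- numeric(K)
  bias <- numeric(K)
  for (i in seq_len(K)) {
    keep <- v$maxHeadPos >= grid[i] & v$maxTailPos >= grid[i]
    nSuf[i] <- sum(keep)
    rate[i] <- alternationRate(.classify(v$arm[keep], v$tEntry[keep],
                                         tEx[keep]))
    bias[i] <- armChoiceBias(v$arm[keep])
  }
  out <- data.frame(
    threshold = grid, nSufficient = nSuf,
    visitRatio = if (nAll) nSuf / nAll else NA_real_,
    correctRate = rate, armChoiceBias = bias
  )
  if (chanceIterations > 0) {
    cb <- chanceBand(out$nSufficient, out$armChoiceBias,
                     nIterations = chanceIterations, seed = seed)
    out <- cbind(out, cb)
  }
  attr(out, "sessionID") <- seq@sessionID
  attr(out, "boundary") <- b
  class(out) <- c("ymSweep", "data.frame")
  out
}

#' Recency statistics of scored choices
#'
#' For every retained choice this computes the time elapsed since the exit
#' from the second-last visited arm, `tCurrentEntry - tBExit`, and the
#' difference in recency `(tBExit - tAExit) / (tCurrentEntry - tBExit)` --
#' how much longer ago the correct-candidate arm (A) was exited than the
#' incorrect candidate (B), normalized by the time since B.  Excluded:
#' neutral choices, same-arm reentries (current = last arm), choices whose
#' correct-candidate arm was never previously exited, and choices with
#' censored timestamps.
#'
#' @param choices a choice table from [classifyChoices()] carrying
#'   timestamps.
#' @return a data.frame with columns `ordinal`, `outcome`,
#'   `timeSinceBExit` (s) and `diffRecency` (unitless).
#' @examples
#' ch <- data.frame(
#'   ordinal = 3L, currentArm = "C", lastArm = "B", secondLastArm = "A",
#'   outcome = "correct", tCurrentEntry = 40, tBExit = 30, tAExit = 10
#' )
#' recencyStatistics(ch)  # timeSinceBExit 10 s, diffRecency 2
#' @export
recencyStatistics <- function(choices) {
  need <- c("outcome", "currentArm", "lastArm", "tCurrentEntry", "tBExit",
            "tAExit")
  if (!all(need %in% names(choices))) {
    stop("choices must come from classifyChoices() with timestamps")
  }
  keep <- choices$outcome != "neutral" &
    choices$currentArm != choices$lastArm &
    !is.na(choices$tAExit) & !is.na(choices$tBExit) &
    !is.na(choices$tCurrentEntry)
  ch <- choices[keep, , drop = FALSE]
  denom <- ch$tCurrentEntry - ch$tBExit
  if (any(denom <= 0)) {
    stop(
      "non-positive time since the second-last arm exit: ",
      "an intervening visit must separate entry from that exit"
    )
  }
  data.frame(
    ordinal = ch$ordinal,
    outcome = ch$outcome,
    timeSinceBExit = denom,
    diffRecency = (ch$tBExit - ch$tAExit) / denom
  )
}

#' Locomotion metrics of a session
#'
#' Threshold-independent behavioral covariates: the number of arm entries
#' (center-boundary crossings), the total travel distance of the head
#' point, and the arm preference, defined as the population standard
#' deviation (n = 3) of the total time spent in each arm.
#'
#' @param traj a [ProjectedTrajectory-class] (supplies the head track).
#' @param seq the [VisitSequence-class] of all arm entries.
#' @param geometry the [MazeGeometry-class], for the px-to-cm scale.
#' @return a list with `nEntries`, `travelDistance` (cm) and
#'   `armPreference` (s).
#' @export
locomotionMetrics <- function(traj, seq, geometry) {
  stopifnot(
    is(traj, "ProjectedTrajectory"), is(seq, "VisitSequence"),
    is(geometry, "MazeGeometry")
  )
  xy <- traj@headXY
  travel <- if (nrow(xy) > 1L) {
    sum(sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)) / pxPerCm(geometry)
  } else {
    0
  }
  v <- seq@visits
  perArm <- vapply(.ARMS, function(a) {
    sum(v$tExit[v$arm == a] - v$tEntry[v$arm == a])
  }, 0)
  armPref <- sqrt(mean((perArm - mean(perArm))^2))
  list(
    nEntries = nrow(v),
    travelDistance = travel,
    armPreference = armPref
  )
}
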