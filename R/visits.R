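#' Detect arm visits with the dual-point crossing rule
#'
#' Runs a two-state machine over a projected trajectory.  From the center
#' state, a visit to arm `a` starts at the first frame where the head and
#' the tail base are both strictly beyond the boundary *and* assigned to
#' the same arm `a`.  The visit ends at the first frame where both points
#' are back at or below the boundary (in any arm).  While in an arm the
#' running maxima of the head and tail-base positions are tracked over the
#' frames assigned to that arm; these maxima decide sufficiency at any
#' later threshold.  A session that ends mid-visit closes the visit at the
#' last frame and marks it censored.
#'
#' @param traj a [ProjectedTrajectory-class].
#' @param boundary normalized center-zone boundary, in (0, 1) (default
#'   0.25).
#' @return a [VisitSequence-class].
#' @seealso [sufficientVisits()], [classifyChoices()]
#' @export
detectVisits <- function(traj, boundary = 0.25) {
  stopifnot(is(traj, "ProjectedTrajectory"))
  if (length(boundary) != 1L || boundary <= 0 || boundary >= 1) {
    stop("boundary must lie strictly within (0, 1)")
  }
  hPos <- traj@headPos
  tPos <- traj@tailPos
  hArm <- match(traj@headArm, .ARMS)
  tArm <- match(traj@tailArm, .ARMS)
  tms <- traj@frameTimes
  n <- length(tms)

  arm <- integer(0)
  tEntry <- numeric(0)
  tExit <- numeric(0)
  maxH <- numeric(0)
  maxT <- numeric(0)
  censored <- logical(0)

  inArm <- 0L
  curMaxH <- 0
  curMaxT <- 0
  curEntry <- NA_real_
  for (i in seq_len(n)) {
    if (inArm == 0L) {
      if (hPos[i] > boundary && tPos[i] > boundary && hArm[i] == tArm[i]) {
        inArm <- hArm[i]
        curEntry <- tms[i]
        curMaxH <- hPos[i]
        curMaxT <- tPos[i]
      }
    } else {
      if (hPos[i] <= boundary && tPos[i] <= boundary) {
        arm <- c(arm, inArm)
        tEntry <- c(tEntry, curEntry)
        tExit <- c(tExit, tms[i])
        maxH <- c(maxH, curMaxH)
        maxT <- c(maxT, curMaxT)
        censored <- c(censored, FALSE)
        inArm <- 0L
      } else {
        if (hArm[i] == inArm && hPos[i] > curMaxH) curMaxH <- hPos[i]
        if (tArm[i] == inArm && tPos[i] > curMaxT) curMaxT <- tPos[i]
      }
    }
  }
  if (inArm != 0L) {
    arm <- c(arm, inArm)
    tEntry <- c(tEntry, curEntry)
    tExit <- c(tExit, tms[n] + 0.5 / traj@fps)
    maxH <- c(maxH, curMaxH)
    maxT <- c(maxT, curMaxT)
    censored <- c(censored, TRUE)
  }
  new("VisitSequence",
    visits = data.frame(
      arm = .ARMS[arm], tEntry = tEntry, tExit = tExit,
      maxHeadPos = maxH, maxTailPos = maxT, censored = censored
    ),
    boundary = boundary, sessionID = traj@sessionID
  )
}

#' Filter a visit sequence to sufficient visits
#'
#' A visit is sufficient at a threshold when its maximal head position AND
#' its maximal tail-base position both reach the threshold at some time
#' during the visit (simultaneity is not required).
#'
#' @param seq a [VisitSequence-class].
#' @param threshold arm-visit threshold, at or above the sequence's
#'   boundary.
#' @return the filtered [VisitSequence-class].
#' @export
sufficientVisits <- function(seq, threshold) {
  stopifnot(is(seq, "VisitSequence"))
  if (length(threshold) != 1L || threshold < seq@boundary) {
    stop(sprintf(
      "threshold must be a single value >= the boundary (%g)", seq@boundary
    ))
  }
  v <- seq@visits
  keep <- v$maxHeadPos >= threshold & v$maxTailPos >= threshold
  new("VisitSequence",
    visits = v[keep, , drop = FALSE],
    boundary = seq@boundary, sessionID = seq@sessionID
  )
}

#' Ratio of sufficient visits to arm entries
#'
#' @param seqAll the full visit sequence (all arm entries).
#' @param seqSufficient the sufficient subset, from [sufficientVisits()].
#' @return the fraction of entries that were sufficient, or `NA` when the
#'   session contains no entries.
#' @export
visitRatio <- function(seqAll, seqSufficient) {
  stopifnot(is(seqAll, "VisitSequence"), is(seqSufficient, "VisitSequence"))
  nAll <- nrow(seqAll@visits)
  nSuf <- nrow(seqSufficient@visits)
  if (nSuf > nAll) stop("sufficient visits must be a subset of all visits")
  if (nAll == 0L) return(NA_real_)
  nSuf / nAll
}
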