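#' @import methods
NULL

## Canonical body-part and arm vocabularies.  Arm order A -> B -> C is the
## counterclockwise ring used for direction (CW/CCW) classification.
.PARTS <- c("nose", "left_ear", "right_ear", "neck", "tail_base")
.HEAD_PARTS <- c("nose", "left_ear", "right_ear", "neck")
.ARMS <- c("A", "B", "C")

#' TrackingSession: raw pose-tracking coordinates for one session
#'
#' Holds per-frame pixel coordinates and tracking likelihoods for the five
#' tracked body parts (nose, left ear, right ear, neck, tail base) of a
#' single animal in a single session, together with frame times and the
#' frame rate.
#'
#' @slot coords three-dimensional numeric array
#'   \code{[frame, body part, c("x", "y", "likelihood")]}; likelihoods lie
#'   in \code{[0, 1]}.
#' @slot frameTimes numeric vector of frame times in seconds, strictly
#'   increasing, first frame at 0.
#' @slot sessionID character scalar identifying the session.
#' @slot fps frames per second (> 0).
#'
#' @seealso [readDLC()], [trackingSession()], [computeHead()],
#'   [truncateSession()]
#' @export
setClass("TrackingSession",
  representation(
    coords = "array",
    frameTimes = "numeric",
    sessionID = "character",
    fps = "numeric"
  )
)

setValidity("TrackingSession", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L) {
    return("coords must be a 3-d array [frame, part, (x, y, likelihood)]")
  }
  dn <- dimnames(object@coords)
  if (is.null(dn) || !all(.PARTS %in% dn[[2L]])) {
    msg <- c(msg, sprintf(
      "coords must carry all body parts: %s", paste(.PARTS, collapse = ", ")
    ))
  }
  if (is.null(dn) || !identical(dn[[3L]], c("x", "y", "likelihood"))) {
    msg <- c(msg, "third dimension must be c('x', 'y', 'likelihood')")
  }
  if (length(object@frameTimes) != d[1L]) {
    msg <- c(msg, "frameTimes length must equal the number of frames")
  }
  if (d[1L] > 1L && any(diff(object@frameTimes) <= 0)) {
    msg <- c(msg, "frameTimes must be strictly increasing")
  }
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0) {
    msg <- c(msg, "fps must be a single positive number")
  }
  if (length(msg) == 0L && all(.PARTS %in% dn[[2L]])) {
    lik <- object@coords[, .PARTS, "likelihood", drop = FALSE]
    bad <- !is.na(lik) & (lik < 0 | lik > 1)
    if (any(bad)) msg <- c(msg, "likelihoods must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' MazeGeometry: calibration of a three-arm (Y) maze
#'
#' Describes the maze in image coordinates: the center point and the three
#' arm-end points, labeled A, B, C in counterclockwise order, plus the
#' physical arm length used to convert pixels to centimeters.  Validity
#' requires the three arm direction vectors to be pairwise approximately
#' 120 degrees apart and the three pixel arm lengths to be mutually
#' consistent.
#'
#' @slot center numeric length-2, maze center (x, y) in px.
#' @slot armEnds 3 x 2 numeric matrix of arm-end coordinates (px) with
#'   rownames \code{c("A", "B", "C")} in counterclockwise order.
#' @slot armLengthCm physical arm length in cm (default 36).
#' @slot angleTolDeg tolerance on the pairwise 120-degree arm separation,
#'   in degrees (default 10).
#' @slot scaleTol maximum allowed relative deviation of any single pixel
#'   arm length from the mean (default 0.1).
#'
#' @seealso [mazeGeometry()], [defaultGeometry()], [projectPoint()]
#' @export
setClass("MazeGeometry",
  representation(
    center = "numeric",
    armEnds = "matrix",
    armLengthCm = "numeric",
    angleTolDeg = "numeric",
    scaleTol = "numeric"
  )
)

setValidity("MazeGeometry", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center))) {
    msg <- c(msg, "center must be a finite (x, y) pair")
  }
  ae <- object@armEnds
  if (!is.numeric(ae) || !identical(dim(ae), c(3L, 2L)) ||
      !identical(rownames(ae), .ARMS)) {
    return(c(msg, "armEnds must be a 3 x 2 matrix with rownames A, B, C"))
  }
  if (object@armLengthCm <= 0) msg <- c(msg, "armLengthCm must be > 0")
  v <- sweep(ae, 2L, object@center)
  len <- sqrt(rowSums(v^2))
  if (any(len <= 0)) {
    return(c(msg, "arm ends must not coincide with the center"))
  }
  ang <- atan2(v[, 2L], v[, 1L]) * 180 / pi
  sep <- outer(ang, ang, "-")
  sep <- abs(((sep[upper.tri(sep)] + 180) %% 360) - 180)
  if (any(abs(sep - 120) > object@angleTolDeg)) {
    msg <- c(msg, sprintf(
      "arm direction vectors must be pairwise 120 +/- %g degrees apart",
      object@angleTolDeg
    ))
  }
  if (any(abs(len / mean(len) - 1) > object@scaleTol)) {
    msg <- c(msg, "pixel arm lengths are inconsistent across arms")
  }
  if (length(msg)) msg else TRUE
})

#' ProjectedTrajectory: per-frame arm assignment and normalized position
#'
#' The result of projecting the head and tail-base points of a session onto
#' the maze arms.  Each frame carries, for both body points, the arm whose
#' axis is nearest (largest cosine similarity) and the distance from the
#' center divided by that arm's pixel length (0 = center, 1 = arm end).
#' Values above 1 are retained, not clipped: tracking jitter routinely
#' places points slightly beyond the nominal arm end.
#'
#' @slot frameTimes numeric, seconds.
#' @slot headArm,tailArm character vectors of arm labels ("A"/"B"/"C").
#' @slot headPos,tailPos numeric vectors of normalized arm positions
#'   (>= 0).
#' @slot headXY n x 2 matrix of head pixel coordinates (kept for travel
#'   distance).
#' @slot sessionID character scalar.
#' @slot fps frames per second.
#' @slot flags list of quality annotations (interpolated frame indices,
#'   long likelihood gaps, number of beyond-arm-end frames).
#'
#' @seealso [projectSession()], [detectVisits()], [occupancyProfile()]
#' @export
setClass("ProjectedTrajectory",
  representation(
    frameTimes = "numeric",
    headArm = "character",
    headPos = "numeric",
    tailArm = "character",
    tailPos = "numeric",
    headXY = "matrix",
    sessionID = "character",
    fps = "numeric",
    flags = "list"
  )
)

setValidity("ProjectedTrajectory", function(object) {
  n <- length(object@frameTimes)
  msg <- character()
  lens <- c(
    length(object@headArm), length(object@headPos),
    length(object@tailArm), length(object@tailPos), nrow(object@headXY)
  )
  if (any(lens != n)) msg <- c(msg, "all per-frame slots must share length")
  if (any(object@headPos < 0, na.rm = TRUE) ||
      any(object@tailPos < 0, na.rm = TRUE)) {
    msg <- c(msg, "normalized positions must be >= 0")
  }
  if (n > 1L && any(diff(object@frameTimes) <= 0)) {
    msg <- c(msg, "frameTimes must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' VisitSequence: ordered arm visits of one session
#'
#' An ordered table of arm visits produced by the dual-point state machine:
#' a visit starts when both the head and the tail base are beyond the
#' center-zone boundary in the same arm and ends when both are back at or
#' below the boundary.  Each visit records its maximal head and tail-base
#' penetration depths, used to decide sufficiency at any arm-visit
#' threshold.
#'
#' @slot visits data.frame with columns \code{arm}, \code{tEntry},
#'   \code{tExit}, \code{maxHeadPos}, \code{maxTailPos}, \code{censored}
#'   (TRUE when the session ended mid-visit).
#' @slot boundary normalized center-zone boundary used for detection.
#' @slot sessionID character scalar.
#'
#' @seealso [detectVisits()], [sufficientVisits()], [classifyChoices()]
#' @export
setClass("VisitSequence",
  representation(
    visits = "data.frame",
    boundary = "numeric",
    sessionID = "character"
  )
)

setValidity("VisitSequence", function(object) {
  v <- object@visits
  need <- c("arm", "tEntry", "tExit", "maxHeadPos", "maxTailPos", "censored")
  if (!all(need %in% names(v))) {
    return(sprintf("visits must have columns: %s", paste(need, collapse = ", ")))
  }
  msg <- character()
  if (length(object@boundary) != 1L || object@boundary <= 0 ||
      object@boundary >= 1) {
    msg <- c(msg, "boundary must lie in (0, 1)")
  }
  if (nrow(v)) {
    if (!all(v$arm %in% .ARMS)) msg <- c(msg, "arms must be A, B or C")
    if (any(v$tExit <= v$tEntry)) msg <- c(msg, "tExit must exceed tEntry")
    if (nrow(v) > 1L && any(v$tEntry[-1L] < v$tExit[-nrow(v)])) {
      msg <- c(msg, "visits must be non-overlapping and time-ordered")
    }
    if (any(v$maxHeadPos < object@boundary) ||
        any(v$maxTailPos < object@boundary)) {
      msg <- c(msg, "visit maxima cannot fall below the boundary")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AgentParams: generative parameters of the synthetic Y-maze agent
#'
#' Parameters of the minimal generative mouse used to validate the
#' pipeline.  The agent alternates (chooses the arm visited least recently
#' among the two candidates) with probability \code{alternationFidelity},
#' optionally decayed with the time elapsed since the second-last arm exit
#' (halving every \code{memoryHalflife} seconds); otherwise it takes a
#' clockwise/counterclockwise step with clockwise probability
#' \code{0.5 + turningBias}.  Visits penetrate to a full depth
#' (uniform on \code{fullDepthRange}) with probability \code{pFull}, else
#' to a shallow depth (uniform on \code{shallowDepthRange}).
#'
#' @slot alternationFidelity probability of an alternating (correct) choice
#'   before memory decay, in \code{[0, 1]}.
#' @slot turningBias turning bias in \code{[0, 0.5]}; clockwise step
#'   probability is \code{0.5 + turningBias}.
#' @slot memoryHalflife seconds; \code{Inf} disables decay.
#' @slot pFull probability that a visit reaches full depth.
#' @slot fullDepthRange,shallowDepthRange normalized depth ranges of full
#'   and shallow (partial) visits.
#' @slot speed locomotion speed, cm/s.
#' @slot dwellCenter,dwellEnd mean center-zone and arm-end dwell times
#'   (seconds, exponential).
#' @slot bodyLength head to tail-base distance, cm.
#' @slot centerDwellRadius normalized radius of exploratory wandering
#'   during center dwells; 0 parks the agent at the center point.
#' @slot noiseSigma sd of iid Gaussian positional jitter added to every
#'   body-part coordinate, in arm-length units.
#' @slot fps frames per second of the rendered track.
#' @slot sessionDuration rendered session length, seconds.
#' @slot seed RNG seed (NA for none).
#'
#' @seealso [agentParams()], [simulateChoices()], [renderTrajectory()],
#'   [simulateCohort()]
#' @export
setClass("AgentParams",
  representation(
    alternationFidelity = "numeric",
    turningBias = "numeric",
    memoryHalflife = "numeric",
    pFull = "numeric",
    fullDepthRange = "numeric",
    shallowDepthRange = "numeric",
    speed = "numeric",
    dwellCenter = "numeric",
    dwellEnd = "numeric",
    bodyLength = "numeric",
    centerDwellRadius = "numeric",
    noiseSigma = "numeric",
    fps = "numeric",
    sessionDuration = "numeric",
    seed = "numeric"
  )
)

setValidity("AgentParams", function(object) {
  msg <- character()
  inunit <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!inunit(object@alternationFidelity)) {
    msg <- c(msg, "alternationFidelity must lie in [0, 1]")
  }
  if (!(length(object@turningBias) == 1L && is.finite(object@turningBias) &&
        object@turningBias >= 0 && object@turningBias <= 0.5)) {
    msg <- c(msg, "turningBias must lie in [0, 0.5]")
  }
  if (!inunit(object@pFull)) msg <- c(msg, "pFull must lie in [0, 1]")
  if (object@memoryHalflife <= 0) msg <- c(msg, "memoryHalflife must be > 0")
  for (s in c("speed", "dwellCenter", "dwellEnd", "bodyLength", "fps",
              "sessionDuration")) {
    if (slot(object, s) <= 0) msg <- c(msg, sprintf("%s must be > 0", s))
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@centerDwellRadius < 0 || object@centerDwellRadius >= 1) {
    msg <- c(msg, "centerDwellRadius must lie in [0, 1)")
  }
  rng <- function(x) length(x) == 2L && x[1L] > 0 && x[1L] <= x[2L]
  if (!rng(object@fullDepthRange) || !rng(object@shallowDepthRange)) {
    msg <- c(msg, "depth ranges must be increasing positive pairs")
  }
  if (length(msg)) msg else TRUE
})
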