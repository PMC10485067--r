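#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes.  Use these rather
#' than reaching into slots.
#'
#' @param object an object of one of the package's S4 classes.
#' @return `sessionID()` a character scalar; `frameTimes()` a numeric
#'   vector of seconds; `fps()` frames per second; `visits()` the visit
#'   table as a data.frame; `boundary()` the normalized center-zone
#'   boundary; `nVisits()` the number of visits.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sessionID", function(object) standardGeneric("sessionID"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("visits", function(object) standardGeneric("visits"))

#' @rdname accessors
#' @export
setGeneric("boundary", function(object) standardGeneric("boundary"))

#' @rdname accessors
#' @export
setGeneric("nVisits", function(object) standardGeneric("nVisits"))

#' @rdname accessors
#' @export
setMethod("sessionID", "TrackingSession", function(object) object@sessionID)

#' @rdname accessors
#' @export
setMethod("sessionID", "ProjectedTrajectory", function(object) object@sessionID)

#' @rdname accessors
#' @export
setMethod("sessionID", "VisitSequence", function(object) object@sessionID)

#' @rdname accessors
#' @export
setMethod("frameTimes", "TrackingSession", function(object) object@frameTimes)

#' @rdname accessors
#' @export
setMethod("frameTimes", "ProjectedTrajectory", function(object) object@frameTimes)

#' @rdname accessors
#' @export
setMethod("fps", "TrackingSession", function(object) object@fps)

#' @rdname accessors
#' @export
setMethod("fps", "ProjectedTrajectory", function(object) object@fps)

#' @rdname accessors
#' @export
setMethod("visits", "VisitSequence", function(object) object@visits)

#' @rdname accessors
#' @export
setMethod("boundary", "VisitSequence", function(object) object@boundary)

#' @rdname accessors
#' @export
setMethod("nVisits", "VisitSequence", function(object) nrow(object@visits))

#' Body-part coordinates of a session
#'
#' @param object a [TrackingSession-class].
#' @param part one of `"nose"`, `"left_ear"`, `"right_ear"`, `"neck"`,
#'   `"tail_base"`.
#' @return an n x 3 matrix with columns x, y, likelihood.
#' @export
setGeneric("partCoords", function(object, part) standardGeneric("partCoords"))

#' @rdname partCoords
#' @export
setMethod("partCoords", "TrackingSession", function(object, part) {
  part <- match.arg(part, .PARTS)
  object@coords[, part, , drop = TRUE]
})

setMethod("show", "TrackingSession", function(object) {
  cat(sprintf(
    "TrackingSession '%s': %d frames @ %g fps (%.1f s), %d body parts\n",
    object@sessionID, length(object@frameTimes), object@fps,
    if (length(object@frameTimes)) max(object@frameTimes) else 0,
    dim(object@coords)[2L]
  ))
})

setMethod("show", "MazeGeometry", function(object) {
  v <- sweep(object@armEnds, 2L, object@center)
  len <- sqrt(rowSums(v^2))
  cat(sprintf(
    "MazeGeometry: center (%.1f, %.1f) px, arm length %.1f cm (%.1f px/cm)\n",
    object@center[1L], object@center[2L], object@armLengthCm,
    mean(len) / object@armLengthCm
  ))
  for (a in .ARMS) {
    cat(sprintf(
      "  arm %s: end (%.1f, %.1f), %.1f px\n",
      a, object@armEnds[a, 1L], object@armEnds[a, 2L], len[a]
    ))
  }
})

setMethod("show", "ProjectedTrajectory", function(object) {
  n <- length(object@frameTimes)
  cat(sprintf(
    "ProjectedTrajectory '%s': %d frames @ %g fps\n",
    object@sessionID, n, object@fps
  ))
  if (n) {
    cat(sprintf(
      "  head pos range [%.3f, %.3f]; %d frame(s) beyond arm end\n",
      min(object@headPos), max(object@headPos),
      sum(object@headPos > 1)
    ))
  }
})

setMethod("show", "VisitSequence", function(object) {
  cat(sprintf(
    "VisitSequence '%s': %d visit(s), boundary %.2f\n",
    object@sessionID, nrow(object@visits), object@boundary
  ))
  if (nrow(object@visits)) {
    cat("  arms:", paste(object@visits$arm, collapse = " "), "\n")
  }
})

setMethod("show", "AgentParams", function(object) {
  cat(sprintf(
    paste0(
      "AgentParams: fidelity %.2f, turning bias %.2f, halflife %s s\n",
      "  pFull %.2f, speed %g cm/s, dwell C/E %g/%g s, noise %g arm units\n",
      "  %g fps, %g s session\n"
    ),
    object@alternationFidelity, object@turningBias,
    format(object@memoryHalflife), object@pFull, object@speed,
    object@dwellCenter, object@dwellEnd, object@noiseSigma,
    object@fps, object@sessionDuration
  ))
})
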