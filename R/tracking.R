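#' Construct a TrackingSession
#'
#' @param coords 3-d numeric array `[frame, part, c("x","y","likelihood")]`
#'   with all five body parts (`nose`, `left_ear`, `right_ear`, `neck`,
#'   `tail_base`) in the second dimension.
#' @param fps frames per second; frame times are derived as
#'   `(0:(n-1))/fps` unless `frameTimes` is given.
#' @param sessionID session identifier.
#' @param frameTimes optional explicit frame times in seconds.
#' @return a [TrackingSession-class].
#' @export
trackingSession <- function(coords, fps, sessionID = "session",
                            frameTimes = NULL) {
  if (is.null(frameTimes)) {
    frameTimes <- (seq_len(dim(coords)[1L]) - 1L) / fps
  }
  new("TrackingSession",
    coords = coords, frameTimes = as.numeric(frameTimes),
    sessionID = as.character(sessionID), fps = as.numeric(fps)
  )
}

#' Construct a MazeGeometry
#'
#' @param center maze center `(x, y)` in px.
#' @param armEnds 3 x 2 matrix of arm-end px coordinates, rows in
#'   counterclockwise order (rownames are set to A, B, C).
#' @param armLengthCm physical arm length in cm (default 36).
#' @param angleTolDeg tolerance on the 120-degree arm separation (default
#'   10 degrees).
#' @param scaleTol relative tolerance on per-arm pixel lengths (default
#'   0.1).
#' @return a validated [MazeGeometry-class].
#' @examples
#' geom <- defaultGeometry()
#' pxPerCm(geom)
#' @export
mazeGeometry <- function(center, armEnds, armLengthCm = 36,
                         angleTolDeg = 10, scaleTol = 0.1) {
  armEnds <- as.matrix(armEnds)
  rownames(armEnds) <- .ARMS
  colnames(armEnds) <- c("x", "y")
  new("MazeGeometry",
    center = as.numeric(center), armEnds = armEnds,
    armLengthCm = armLengthCm, angleTolDeg = angleTolDeg,
    scaleTol = scaleTol
  )
}

#' Default synthetic maze geometry
#'
#' A Y maze centered at (300, 300) px with 36 cm arms at 10 px/cm and arm A
#' pointing "up" (90 degrees), B and C following counterclockwise.
#'
#' @param pxPerCm pixel scale (default 10).
#' @param armLengthCm arm length in cm (default 36).
#' @return a [MazeGeometry-class].
#' @export
defaultGeometry <- function(pxPerCm = 10, armLengthCm = 36) {
  ang <- c(90, 210, 330) * pi / 180
  L <- armLengthCm * pxPerCm
  ends <- cbind(300 + L * cos(ang), 300 + L * sin(ang))
  mazeGeometry(c(300, 300), ends, armLengthCm = armLengthCm)
}

#' Pixel scale of a maze geometry
#'
#' @param geometry a [MazeGeometry-class].
#' @return mean pixels per centimeter across the three arms.
#' @export
pxPerCm <- function(geometry) {
  stopifnot(is(geometry, "MazeGeometry"))
  mean(.armLengthsPx(geometry)) / geometry@armLengthCm
}

.armLengthsPx <- function(geometry) {
  v <- sweep(geometry@armEnds, 2L, geometry@center)
  sqrt(rowSums(v^2))
}

.armUnitVectors <- function(geometry) {
  v <- sweep(geometry@armEnds, 2L, geometry@center)
  v / sqrt(rowSums(v^2))
}

#' Read a DeepLabCut-dialect tracking CSV
#'
#' Parses the standard three-row DeepLabCut header (scorer / bodyparts /
#' coords) followed by one row per frame with a leading frame index and
#' x, y, likelihood columns per body part.  All five canonical parts
#' (nose, left_ear, right_ear, neck, tail_base) must be present, possibly
#' under different names supplied through `partMap`.
#'
#' @param path CSV file path.
#' @param fps frames per second used to convert frame indices to seconds
#'   (first frame at t = 0).
#' @param sessionID session identifier; defaults to the file name without
#'   extension.
#' @param partMap optional named character vector mapping canonical part
#'   names to the names used in the file, e.g.
#'   `c(tail_base = "tailbase")`.
#' @return a [TrackingSession-class].
#' @seealso [writeDLC()]
#' @export
readDLC <- function(path, fps = 30, sessionID = NULL, partMap = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sessionID)) {
    sessionID <- sub("\\.[^.]*$", "", basename(path))
  }
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) stop("not a DeepLabCut CSV: fewer than 3 header rows")
  split3 <- strsplit(hdr, ",", fixed = TRUE)
  labels <- vapply(split3, `[`, "", 1L)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords"))) {
    stop(
      "not a DeepLabCut CSV: header rows must be scorer / bodyparts / coords"
    )
  }
  parts <- split3[[2L]][-1L]
  coordsRow <- tolower(split3[[3L]][-1L])

  wanted <- stats::setNames(.PARTS, .PARTS)
  if (!is.null(partMap)) wanted[names(partMap)] <- partMap

  dat <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "character")
  if (ncol(dat) != length(parts) + 1L) {
    stop("column count does not match the bodyparts header row")
  }
  n <- nrow(dat)
  arr <- array(
    NA_real_, dim = c(n, length(.PARTS), 3L),
    dimnames = list(NULL, .PARTS, c("x", "y", "likelihood"))
  )
  toNum <- function(col, what) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(is.na(col) | col == "" | col == "NA"))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value in %s at data row %d: '%s'",
        what, bad[1L], col[bad[1L]]
      ))
    }
    v
  }
  for (p in .PARTS) {
    for (cc in c("x", "y", "likelihood")) {
      j <- which(parts == wanted[[p]] & coordsRow == cc)
      if (length(j) != 1L) {
        stop(sprintf("missing body part column: %s (%s)", p, cc))
      }
      arr[, p, cc] <- toNum(dat[[j + 1L]], sprintf("%s %s", p, cc))
    }
  }
  trackingSession(arr, fps = fps, sessionID = sessionID)
}

#' Write a TrackingSession as a DeepLabCut-dialect CSV
#'
#' @param session a [TrackingSession-class].
#' @param path output file path.
#' @param scorer scorer string placed in the first header row.
#' @return `path`, invisibly.
#' @seealso [readDLC()]
#' @export
writeDLC <- function(session, path, scorer = "ymazer") {
  stopifnot(is(session, "TrackingSession"))
  co <- session@coords
  n <- dim(co)[1L]
  cols <- vector("list", length(.PARTS) * 3L)
  nmParts <- character(0)
  nmCoords <- character(0)
  k <- 0L
  for (p in .PARTS) {
    for (cc in c("x", "y", "likelihood")) {
      k <- k + 1L
      cols[[k]] <- co[, p, cc]
      nmParts <- c(nmParts, p)
      nmCoords <- c(nmCoords, cc)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("scorer", rep(scorer, k)), collapse = ","),
    paste(c("bodyparts", nmParts), collapse = ","),
    paste(c("coords", nmCoords), collapse = ",")
  ), con)
  body <- do.call(cbind, c(list(seq_len(n) - 1L), cols))
  utils::write.table(
    body, con, sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

## Likelihood-filtered single-point track: frames where likelihood falls
## below the floor are linearly interpolated from good neighbours; gaps
## longer than maxGap seconds are still interpolated but reported.
.filteredTrack <- function(session, parts, likelihoodFloor, maxGap) {
  co <- session@coords
  t <- session@frameTimes
  lik <- co[, parts, "likelihood", drop = FALSE]
  bad <- apply(is.na(lik) | lik < likelihoodFloor, 1L, any)
  if (all(bad)) {
    stop(sprintf(
      "unusable session '%s': every frame has a body-part likelihood below %g",
      session@sessionID, likelihoodFloor
    ))
  }
  x <- rowMeans(co[, parts, "x", drop = FALSE])
  y <- rowMeans(co[, parts, "y", drop = FALSE])
  longGaps <- integer(0)
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gapIdx <- which(r$values)
    gapDur <- t[ends[gapIdx]] - t[starts[gapIdx]] + 1 / session@fps
    longGaps <- starts[gapIdx][gapDur > maxGap]
    x <- .interpolateBad(x, bad, t)
    y <- .interpolateBad(y, bad, t)
  }
  list(
    xy = cbind(x = x, y = y), interpolated = which(bad),
    longGapStarts = longGaps
  )
}

#' Head point of each frame
#'
#' The head position is the arithmetic mean of the nose, left-ear,
#' right-ear and neck coordinates.  Frames where any of these four parts
#' falls below the likelihood floor are linearly interpolated from the
#' neighbouring good frames; interpolation runs longer than `maxGap`
#' seconds are reported in the attributes.
#'
#' @param session a [TrackingSession-class].
#' @param likelihoodFloor minimum per-part likelihood (default 0.6); set to
#'   0 to disable filtering.
#' @param maxGap gap length (seconds) above which an interpolated run is
#'   flagged (default 0.5).
#' @return an n x 2 matrix of head (x, y) px with attributes
#'   `interpolated` (frame indices) and `longGapStarts`.
#' @export
computeHead <- function(session, likelihoodFloor = 0.6, maxGap = 0.5) {
  stopifnot(is(session, "TrackingSession"))
  tr <- .filteredTrack(session, .HEAD_PARTS, likelihoodFloor, maxGap)
  structure(tr$xy,
    interpolated = tr$interpolated, longGapStarts = tr$longGapStarts
  )
}

#' Truncate a session to a fixed analysis window
#'
#' Keeps frames with time strictly below `duration`.  Sessions already
#' shorter than the window are returned whole with a warning.
#'
#' @param session a [TrackingSession-class].
#' @param duration analysis window in seconds (default 465, i.e. 7 min
#'   45 s).
#' @return the truncated [TrackingSession-class].
#' @export
truncateSession <- function(session, duration = 465) {
  stopifnot(is(session, "TrackingSession"))
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0) {
    stop("duration must be a single positive number of seconds")
  }
  t <- session@frameTimes
  if (max(t) < duration) {
    if (max(t) + 1 / session@fps < duration) {
      warning(sprintf(
        "session '%s' (%.1f s) is shorter than the %g s analysis window",
        session@sessionID, max(t), duration
      ))
    }
    return(session)
  }
  keep <- t < duration
  trackingSession(
    session@coords[keep, , , drop = FALSE], fps = session@fps,
    sessionID = session@sessionID, frameTimes = t[keep]
  )
}

## Vectorized arm assignment + normalized position.  Arm = largest cosine
## similarity between (point - center) and the arm direction (angular
## sectors); ties and zero-radius points inherit the previous frame's arm
## (arm A at the start of the track).
.projectXY <- function(xy, geometry, prevArm = NULL) {
  U <- .armUnitVectors(geometry)
  lens <- .armLengthsPx(geometry)
  V <- sweep(xy, 2L, geometry@center)
  dots <- V %*% t(U)
  r <- sqrt(rowSums(V^2))
  idx <- max.col(dots, ties.method = "first")
  ## frames needing the previous-frame tie-break: center point or an exact
  ## tie between the two largest cosines (second largest of three = sum -
  ## max - min)
  mx <- pmax(dots[, 1L], dots[, 2L], dots[, 3L])
  mn <- pmin(dots[, 1L], dots[, 2L], dots[, 3L])
  second <- rowSums(dots) - mx - mn
  tie <- r < .Machine$double.eps | (mx - second) < 1e-9 * pmax(r, 1)
  if (any(tie)) {
    prev <- if (is.null(prevArm)) 1L else match(prevArm, .ARMS)
    for (i in which(tie)) {
      cand <- which(dots[i, ] >= max(dots[i, ]) - 1e-9 * max(r[i], 1))
      if (r[i] < .Machine$double.eps) cand <- seq_len(3L)
      idx[i] <- if (prev %in% cand) prev else cand[1L]
      prev <- idx[i]
    }
  }
  pos <- r / unname(lens)[idx]
  pos[r < .Machine$double.eps] <- 0
  list(arm = .ARMS[idx], pos = pos)
}

#' Project a point onto the maze arms
#'
#' Assigns the arm whose direction vector has the largest cosine similarity
#' with `point - center` (angular-sector assignment) and returns the
#' distance from the center normalized by that arm's pixel length.
#'
#' @param point numeric `(x, y)` in px.
#' @param geometry a [MazeGeometry-class].
#' @param prevArm arm label of the previous frame, used to break ties at
#'   the center and on sector borders (defaults to arm A).
#' @return a list with elements `arm` (label) and `pos` (normalized
#'   position; 0 = center, 1 = arm end, values above 1 possible).
#' @examples
#' geom <- defaultGeometry()
#' projectPoint(geom@armEnds["A", ], geom)   # arm A end -> pos 1
#' @export
projectPoint <- function(point, geometry, prevArm = NULL) {
  stopifnot(is(geometry, "MazeGeometry"), length(point) == 2L)
  p <- .projectXY(matrix(as.numeric(point), 1L), geometry, prevArm)
  list(arm = p$arm[1L], pos = p$pos[1L])
}

#' Project a session onto normalized arm coordinates
#'
#' Computes the head point (mean of nose, ears, neck) and the tail-base
#' point, filters low-likelihood frames, and projects both onto the arm
#' axes frame by frame.
#'
#' @inheritParams computeHead
#' @param geometry a [MazeGeometry-class].
#' @return a [ProjectedTrajectory-class].
#' @export
projectSession <- function(session, geometry, likelihoodFloor = 0.6,
                           maxGap = 0.5) {
  stopifnot(is(session, "TrackingSession"), is(geometry, "MazeGeometry"))
  head <- .filteredTrack(session, .HEAD_PARTS, likelihoodFloor, maxGap)
  tail <- .filteredTrack(session, "tail_base", likelihoodFloor, maxGap)
  ph <- .projectXY(head$xy, geometry)
  pt <- .projectXY(tail$xy, geometry)
  new("ProjectedTrajectory",
    frameTimes = session@frameTimes,
    headArm = ph$arm, headPos = ph$pos,
    tailArm = pt$arm, tailPos = pt$pos,
    headXY = head$xy,
    sessionID = session@sessionID, fps = session@fps,
    flags = list(
      headInterpolated = head$interpolated,
      tailInterpolated = tail$interpolated,
      longGapStarts = sort(unique(c(head$longGapStarts, tail$longGapStarts))),
      nBeyondEnd = sum(ph$pos > 1) + sum(pt$pos > 1)
    )
  )
}
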