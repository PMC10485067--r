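#' Occupancy profile of normalized arm positions
#'
#' Pools all frames of one or more projected trajectories (arm identity
#' ignored), histograms the normalized arm position and normalizes the
#' counts to a probability mass function.  This is the profile from which
#' the center-zone boundary is derived: occupancy is high near the center,
#' falls off along the proximal arm, and settles to a steady transit level.
#'
#' @param trajectories a [ProjectedTrajectory-class] or list of them.
#' @param bodyPoint which body point to histogram: `"head"` or
#'   `"tail_base"`.
#' @param binWidth histogram bin width in normalized arm units (default
#'   0.01).
#' @return a data.frame with columns `binLeft`, `binRight`, `density`
#'   (summing to 1) and attributes `bodyPoint`, `nSessions`, `binWidth`.
#' @seealso [detectCenterBoundary()]
#' @export
occupancyProfile <- function(trajectories, bodyPoint = c("head", "tail_base"),
                             binWidth = 0.01) {
  bodyPoint <- match.arg(bodyPoint)
  if (is(trajectories, "ProjectedTrajectory")) {
    trajectories <- list(trajectories)
  }
  if (!length(trajectories)) stop("need at least one trajectory")
  if (!all(vapply(trajectories, is, TRUE, "ProjectedTrajectory"))) {
    stop("trajectories must be ProjectedTrajectory objects")
  }
  if (length(binWidth) != 1L || binWidth <= 0) stop("binWidth must be > 0")
  pos <- unlist(lapply(trajectories, function(tr) {
    if (bodyPoint == "head") tr@headPos else tr@tailPos
  }), use.names = FALSE)
  if (!length(pos)) stop("trajectories contain no frames")
  nb <- max(1L, ceiling(max(pos) / binWidth + 1e-12))
  breaks <- (0:nb) * binWidth
  counts <- tabulate(pmin(findInterval(pos, breaks, left.open = FALSE), nb),
                     nbins = nb)
  out <- data.frame(
    binLeft = breaks[-length(breaks)],
    binRight = breaks[-1L],
    density = counts / sum(counts)
  )
  attr(out, "bodyPoint") <- bodyPoint
  attr(out, "nSessions") <- length(trajectories)
  attr(out, "binWidth") <- binWidth
  class(out) <- c("ymOccupancy", "data.frame")
  out
}

#' Detect the center-zone boundary from an occupancy profile
#'
#' Finds the normalized position at which the occupancy profile reaches a
#' steady level: the density is smoothed with a centered moving average and
#' the boundary is the left edge of the first run of `k` consecutive bins
#' at or beyond `pMin` whose forward differences all stay strictly below a
#' tolerance of `tolFrac` times the smoothed density range.  If no such
#' plateau exists the fixed default boundary is returned with a warning.
#'
#' @param profile an occupancy profile from [occupancyProfile()].
#' @param window moving-average window in bins (default 5; 1 disables
#'   smoothing).
#' @param k number of consecutive flat bins required (default 5).
#' @param pMin smallest admissible boundary position (default 0.05).
#' @param tolFrac flatness tolerance as a fraction of the smoothed density
#'   range per bin (default 0.10).
#' @param fallback boundary returned when no plateau is found (default
#'   0.25).
#' @return the boundary as a normalized arm position.
#' @export
detectCenterBoundary <- function(profile, window = 5, k = 5, pMin = 0.05,
                                 tolFrac = 0.10, fallback = 0.25) {
  if (!all(c("binLeft", "density") %in% names(profile))) {
    stop("profile must have binLeft and density columns")
  }
  if (sum(profile$binLeft < 0.6) < 20L) {
    stop(
      "too few occupancy bins below position 0.6 for boundary detection; ",
      "use a fixed boundary (e.g. 0.25) instead"
    )
  }
  dens <- profile$density / sum(profile$density)  # scale invariance
  s <- .movingAverage(dens, window)
  rng <- max(s) - min(s)
  left <- profile$binLeft
  if (rng <= 1e-12 * max(abs(s))) {
    ## perfectly flat profile: the plateau starts at the first admissible bin
    return(left[which(left >= pMin)[1L]])
  }
  tol <- tolFrac * rng
  flat <- abs(diff(s)) < tol
  runOK <- if (length(flat) >= k) {
    ## flat[i .. i+k-1] all TRUE, computed via a running sum
    cs <- cumsum(c(0L, flat))
    (cs[(k + 1L):(length(flat) + 1L)] - cs[seq_len(length(flat) - k + 1L)]) == k
  } else {
    logical(0)
  }
  cand <- which(runOK & left[seq_along(runOK)] >= pMin)
  if (length(cand)) {
    return(left[cand[1L]])
  }
  warning(sprintf(
    "no occupancy plateau found; falling back to the fixed boundary %g",
    fallback
  ))
  fallback
}
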