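#' Construct synthetic-agent parameters
#'
#' Defaults describe a group-housed-like adult mouse in a 36 cm Y maze:
#' it alternates with fidelity 0.5 on top of a mild clockwise turning bias
#' of 0.1 (expected alternation rate about 0.76), explores the arm to the
#' distal end on 85% of entries (shallow visits turn around between 0.30
#' and 0.70), moves at 12 cm/s, dwells about 3 s in the center and 2 s at
#' arm ends (exponential), and is rendered at 30 Hz for 465 s.  Memory
#' decay is off (`memoryHalflife = Inf`); a short half-life emulates an
#' animal whose memory of recent arms fades between visits.
#'
#' @param alternationFidelity,turningBias,memoryHalflife,pFull,fullDepthRange,shallowDepthRange,speed,dwellCenter,dwellEnd,bodyLength,centerDwellRadius,noiseSigma,fps,sessionDuration,seed
#'   see [AgentParams-class].
#' @return an [AgentParams-class] object.
#' @export
agentParams <- function(alternationFidelity = 0.5, turningBias = 0.1,
                        memoryHalflife = Inf, pFull = 0.85,
                        fullDepthRange = c(0.85, 1.0),
                        shallowDepthRange = c(0.30, 0.70),
                        speed = 12, dwellCenter = 3, dwellEnd = 2,
                        bodyLength = 5, centerDwellRadius = 0,
                        noiseSigma = 0, fps = 30, sessionDuration = 465,
                        seed = NA_real_) {
  new("AgentParams",
    alternationFidelity = alternationFidelity, turningBias = turningBias,
    memoryHalflife = memoryHalflife, pFull = pFull,
    fullDepthRange = as.numeric(fullDepthRange),
    shallowDepthRange = as.numeric(shallowDepthRange),
    speed = speed, dwellCenter = dwellCenter, dwellEnd = dwellEnd,
    bodyLength = bodyLength, centerDwellRadius = centerDwellRadius,
    noiseSigma = noiseSigma, fps = fps, sessionDuration = sessionDuration,
    seed = as.numeric(seed)
  )
}

#' Simulate the agent's choice process and visit schedule
#'
#' Draws the sequence of arm choices together with a full kinematic
#' schedule (entry and exit times for a given ground-truth boundary,
#' penetration depths, dwell draws).  At each choice from the third visit
#' the agent picks the arm not among the last two with probability
#' `alternationFidelity`, scaled down by `2^(-dt / memoryHalflife)` where
#' `dt` is the time elapsed since the exit from the second-last visited
#' arm; otherwise it steps clockwise with probability `0.5 + turningBias`.
#' Entry is the moment both head and tail base pass the boundary (the tail
#' base trails the head by `bodyLength / speed` seconds), exit the moment
#' both are back inside.
#'
#' @param params an [AgentParams-class].
#' @param nVisits number of visits to draw; `NULL` (default) fills
#'   `sessionDuration`.
#' @param boundary ground-truth center-zone boundary (default 0.25).
#' @param seed RNG seed; defaults to `params@seed`.
#' @return a list (class `ymAgentTruth`) with `visits` (data.frame: `arm`,
#'   `depth`, `tEntry`, `tExit`, `tRunout`, `tReturnEnd`, `dwellCenter`,
#'   `dwellEnd`, `outcome`, `mEff`), `params` and `boundary`.
#' @seealso [renderTrajectory()], [simulateSession()]
#' @export
simulateChoices <- function(params, nVisits = NULL, boundary = 0.25,
                            seed = params@seed) {
  stopifnot(is(params, "AgentParams"))
  if (!is.null(nVisits) && nVisits < 3L) stop("nVisits must be >= 3")
  L <- 36  # normalized units are defined relative to the physical arm
  vN <- params@speed / L
  tau <- params@bodyLength / params@speed
  q <- 0.5 + params@turningBias
  m <- params@alternationFidelity

  .withSeed(seed, {
    arm <- character(0)
    depth <- numeric(0)
    tEntry <- numeric(0)
    tExit <- numeric(0)
    tRunout <- numeric(0)
    tReturnEnd <- numeric(0)
    dwC <- numeric(0)
    dwE <- numeric(0)
    outcome <- character(0)
    mEff <- numeric(0)

    t <- 0
    k <- 0L
    lastExit <- c(A = NA_real_, B = NA_real_, C = NA_real_)
    repeat {
      k <- k + 1L
      if (!is.null(nVisits) && k > nVisits) break
      Dc <- stats::rexp(1L) * params@dwellCenter
      tRun <- t + Dc
      if (is.null(nVisits) && tRun > params@sessionDuration) break
      entry <- tRun + boundary / vN + tau

      ## choice
      if (k == 1L) {
        a <- sample(.ARMS, 1L)
        out <- NA_character_
        me <- NA_real_
      } else if (k == 2L) {
        dir <- if (stats::runif(1L) < q) -1L else 1L
        a <- .armStep(arm[k - 1L], dir)
        out <- NA_character_
        me <- NA_real_
      } else {
        correctArm <- setdiff(.ARMS, c(arm[k - 1L], arm[k - 2L]))
        if (!is.na(tExit[k - 2L])) lastExit[arm[k - 2L]] <- tExit[k - 2L]
        prevExit <- tExit[k - 2L]
        ## memory attempt (probability m): two-trace recency memory.  Each
        ## candidate arm's trace halves every memoryHalflife seconds since
        ## that arm's last exit, and is retrieved with probability equal to
        ## its strength (wB = 2^(-dt/halflife) for the second-last arm, wA
        ## for the correct candidate).  Retrieving only B ("B was recent")
        ## gives a correct avoidance; retrieving only A gives a deliberate
        ## wrong entry (A seems recent, B forgotten); retrieving both ranks
        ## them, misranked with probability 0.5 * r * (1 - wB) where
        ## r = 2^(-(tB_exit - tA_exit)/halflife) is the confusability of the
        ## two recencies; retrieving neither falls back to the turning-bias
        ## step.  Errors therefore concentrate where the recency difference
        ## is small.  With the correct arm long forgotten (wA ~ 0) the model
        ## reduces to the plain decay m * 2^(-dt/halflife);
        ## memoryHalflife = Inf is perfect memory.
        pCorrect <- m
        pWrong <- 0
        if (is.finite(params@memoryHalflife) && !is.na(prevExit)) {
          hl <- params@memoryHalflife
          wB <- 2^(-(entry - prevExit) / hl)
          aExit <- lastExit[[correctArm]]
          wA <- if (is.na(aExit)) 0 else 2^(-(entry - aExit) / hl)
          r <- if (is.na(aExit)) 0 else 2^(-(prevExit - aExit) / hl)
          misrank <- 0.5 * r * (1 - wB)
          pCorrect <- m * (wB * wA * (1 - misrank) + wB * (1 - wA))
          pWrong <- m * (wB * wA * misrank + (1 - wB) * wA)
        }
        u <- stats::runif(1L)
        if (u < pCorrect) {
          a <- correctArm
        } else if (u < pCorrect + pWrong) {
          a <- arm[k - 2L]
        } else {
          dir <- if (stats::runif(1L) < q) -1L else 1L
          a <- .armStep(arm[k - 1L], dir)
        }
        out <- if (a == correctArm) "correct" else "incorrect"
        me <- pCorrect
      }

      d <- if (stats::runif(1L) < params@pFull) {
        stats::runif(1L, params@fullDepthRange[1L], params@fullDepthRange[2L])
      } else {
        stats::runif(1L, params@shallowDepthRange[1L],
                     params@shallowDepthRange[2L])
      }
      ## turning around at the end of an excursion takes a minimum time, so
      ## the end dwell is a shifted exponential (mean preserved): this keeps
      ## the window during which head and tail base are both beyond any
      ## crossed line wider than the tail-base lag
      minDe <- min(0.5, params@dwellEnd / 2)
      De <- minDe + stats::rexp(1L) * (params@dwellEnd - minDe)
      tRet <- tRun + d / vN + De
      tEnd <- tRet + d / vN

      arm <- c(arm, a)
      depth <- c(depth, d)
      tRunout <- c(tRunout, tRun)
      tReturnEnd <- c(tReturnEnd, tEnd)
      dwC <- c(dwC, Dc)
      dwE <- c(dwE, De)
      ## a visit exists only if head and tail base are beyond the boundary
      ## simultaneously at some point: entry (the tail-base out-crossing)
      ## must precede the head's return crossing
      headRet <- tRet + (d - boundary) / vN
      if (d > boundary && entry < headRet) {
        tEntry <- c(tEntry, entry)
        tExit <- c(tExit, headRet + tau)
      } else {
        ## excursion that never puts both points beyond the boundary at
        ## once: not a visit
        tEntry <- c(tEntry, NA_real_)
        tExit <- c(tExit, NA_real_)
      }
      outcome <- c(outcome, out)
      mEff <- c(mEff, me)
      t <- tEnd
    }

    structure(
      list(
        visits = data.frame(
          arm = arm, depth = depth, tEntry = tEntry, tExit = tExit,
          tRunout = tRunout, tReturnEnd = tReturnEnd,
          dwellCenter = dwC, dwellEnd = dwE,
          outcome = outcome, mEff = mEff
        ),
        params = params, boundary = boundary
      ),
      class = "ymAgentTruth"
    )
  })
}

#' Ground-truth visit sequence of a simulated schedule
#'
#' Converts the schedule produced by [simulateChoices()] into a
#' [VisitSequence-class] without rendering or re-detecting anything: each
#' excursion deeper than the boundary becomes a visit whose head and
#' tail-base maxima equal the programmed depth.  Useful for fast,
#' trajectory-free pipelines and as the reference in recovery tests.
#'
#' @param truth a `ymAgentTruth` list from [simulateChoices()].
#' @param maxTime optional truncation: visits entering after `maxTime` are
#'   dropped and a visit still open at `maxTime` is censored there.
#' @param sessionID identifier for the resulting sequence.
#' @return a [VisitSequence-class].
#' @export
visitsFromTruth <- function(truth, maxTime = NULL, sessionID = "truth") {
  v <- truth$visits
  v <- v[!is.na(v$tEntry), , drop = FALSE]
  censored <- rep(FALSE, nrow(v))
  vN <- truth$params@speed / 36
  tau <- truth$params@bodyLength / truth$params@speed
  ## if the tail base crosses out only after the head has left the arm-end
  ## dwell, the head's in-visit maximum is its (descending) position at entry
  tPeakEnd <- v$tRunout + v$depth / vN + v$dwellEnd
  maxHead <- v$depth - vN * pmax(0, v$tEntry - tPeakEnd)
  maxTail <- v$depth
  if (!is.null(maxTime)) {
    keep <- v$tEntry <= maxTime
    v <- v[keep, , drop = FALSE]
    maxHead <- maxHead[keep]
    maxTail <- maxTail[keep]
    censored <- rep(FALSE, nrow(v))
    if (nrow(v)) {
      open <- v$tExit > maxTime
      v$tExit[open] <- maxTime
      censored[open] <- TRUE
      if (any(open)) {
        ## cap the open visit's maxima at the positions reachable before
        ## truncation (the tail base lags the head by tau seconds)
        i <- which(open)
        maxHead[i] <- pmin(maxHead[i], (maxTime - v$tRunout[i]) * vN)
        maxTail[i] <- pmin(maxTail[i], (maxTime - tau - v$tRunout[i]) * vN)
      }
    }
  }
  new("VisitSequence",
    visits = data.frame(
      arm = v$arm, tEntry = v$tEntry, tExit = v$tExit,
      maxHeadPos = maxHead, maxTailPos = maxTail, censored = censored
    ),
    boundary = truth$boundary, sessionID = sessionID
  )
}

## Piecewise-linear 2-d head path of a schedule: breakpoint times/coords in
## px, plus wander waypoints during center dwells when centerDwellRadius>0.
.buildHeadPath <- function(truth, geometry) {
  params <- truth$params
  v <- truth$visits
  ctr <- geometry@center
  U <- .armUnitVectors(geometry)
  lens <- .armLengthsPx(geometry)
  vPx <- params@speed * pxPerCm(geometry)
  Rpx <- params@centerDwellRadius * mean(lens)

  bt <- 0
  bx <- ctr[1L]
  by <- ctr[2L]
  addBp <- function(t, x, y) {
    bt <<- c(bt, t)
    bx <<- c(bx, x)
    by <<- c(by, y)
  }
  tPrev <- 0
  for (k in seq_len(nrow(v))) {
    ## center dwell [tPrev, tRunout]
    if (Rpx > 0) {
      budget <- v$tRunout[k] - tPrev
      tCur <- tPrev
      px <- ctr[1L]
      py <- ctr[2L]
      repeat {
        r <- Rpx * sqrt(stats::runif(1L))
        th <- stats::runif(1L, 0, 2 * pi)
        wx <- ctr[1L] + r * cos(th)
        wy <- ctr[2L] + r * sin(th)
        leg <- sqrt((wx - px)^2 + (wy - py)^2) / vPx
        back <- r / vPx
        if (tCur - tPrev + leg + back > budget) break
        tCur <- tCur + leg
        addBp(tCur, wx, wy)
        px <- wx
        py <- wy
      }
      ret <- sqrt((px - ctr[1L])^2 + (py - ctr[2L])^2) / vPx
      if (ret > 0) addBp(tCur + ret, ctr[1L], ctr[2L])
    }
    addBp(v$tRunout[k], ctr[1L], ctr[2L])
    endPt <- ctr + U[v$arm[k], ] * v$depth[k] * lens[v$arm[k]]
    dT <- v$depth[k] * lens[v$arm[k]] / vPx
    addBp(v$tRunout[k] + dT, endPt[1L], endPt[2L])
    addBp(v$tReturnEnd[k] - dT, endPt[1L], endPt[2L])
    addBp(v$tReturnEnd[k], ctr[1L], ctr[2L])
    tPrev <- v$tReturnEnd[k]
  }
  addBp(max(tPrev, params@sessionDuration) + 60, ctr[1L], ctr[2L])
  list(t = bt, x = bx, y = by)
}

## Path length (px) of a piecewise-linear path clipped to [0, maxTime].
.pathLength <- function(path, maxTime) {
  t <- path$t
  dx <- diff(path$x)
  dy <- diff(path$y)
  seg <- sqrt(dx^2 + dy^2)
  ## pro-rate the segment containing maxTime
  dur <- diff(t)
  frac <- pmax(0, pmin(1, (maxTime - t[-length(t)]) / ifelse(dur > 0, dur, 1)))
  frac[dur <= 0] <- as.numeric(t[-length(t)][dur <= 0] < maxTime)
  sum(seg * frac)
}

#' Render a simulated schedule as a 30 Hz tracking session
#'
#' Converts a choice schedule into a pose-tracking session: the head moves
#' along the arm axes at constant speed with exponential dwells; the tail
#' base follows the head's path delayed by `bodyLength / speed` seconds;
#' nose, ears and neck are placed symmetrically around the head (so their
#' mean is exactly the head point) with likelihood 1; iid Gaussian jitter
#' of `noiseSigma` arm lengths is added to every coordinate of every part.
#'
#' @param truth a `ymAgentTruth` schedule from [simulateChoices()].
#' @param geometry a [MazeGeometry-class].
#' @param sessionID identifier for the rendered session.
#' @param seed RNG seed for wander and noise draws.
#' @return a list with `session` (a [TrackingSession-class]), `truth`
#'   (the input schedule plus `groundTruthVisits`, a [VisitSequence-class]
#'   truncated to the rendered frames) and `pathLengthCm` (analytic head
#'   path length over the rendered window).
#' @export
renderTrajectory <- function(truth, geometry = defaultGeometry(),
                             sessionID = "sim", seed = NULL) {
  stopifnot(inherits(truth, "ymAgentTruth"), is(geometry, "MazeGeometry"))
  params <- truth$params
  .withSeed(seed, {
    path <- .buildHeadPath(truth, geometry)
    nF <- floor(params@sessionDuration * params@fps)
    ft <- (seq_len(nF) - 1L) / params@fps
    tau <- params@bodyLength / params@speed
    hx <- stats::approx(path$t, path$x, xout = ft, rule = 2)$y
    hy <- stats::approx(path$t, path$y, xout = ft, rule = 2)$y
    tx <- stats::approx(path$t, path$x, xout = ft - tau, rule = 2)$y
    ty <- stats::approx(path$t, path$y, xout = ft - tau, rule = 2)$y

    ## heading from head motion; stationary frames carry the last heading
    dx <- c(NA, diff(hx))
    dy <- c(NA, diff(hy))
    nrm <- sqrt(dx^2 + dy^2)
    still <- is.na(nrm) | nrm < 1e-9
    ux <- ifelse(still, NA, dx / nrm)
    uy <- ifelse(still, NA, dy / nrm)
    fill <- function(z) {
      if (all(is.na(z))) return(rep(1, length(z)))
      idx <- cummax(ifelse(is.na(z), 0L, seq_along(z)))
      first <- which(idx > 0L)[1L]
      idx[seq_len(first - 1L)] <- which(!is.na(z))[1L]
      z[idx]
    }
    ux <- fill(ux)
    uy <- fill(uy)
    n2 <- sqrt(ux^2 + uy^2)
    ux <- ux / n2
    uy <- uy / n2

    ppc <- pxPerCm(geometry)
    fwd <- 1.5 * ppc  # nose/neck fore-aft offset, cm
    lat <- 1.0 * ppc  # ear lateral offset, cm
    wx <- -uy
    wy <- ux
    arr <- array(
      NA_real_, dim = c(nF, length(.PARTS), 3L),
      dimnames = list(NULL, .PARTS, c("x", "y", "likelihood"))
    )
    arr[, "nose", "x"] <- hx + fwd * ux
    arr[, "nose", "y"] <- hy + fwd * uy
    arr[, "neck", "x"] <- hx - fwd * ux
    arr[, "neck", "y"] <- hy - fwd * uy
    arr[, "left_ear", "x"] <- hx + lat * wx
    arr[, "left_ear", "y"] <- hy + lat * wy
    arr[, "right_ear", "x"] <- hx - lat * wx
    arr[, "right_ear", "y"] <- hy - lat * wy
    arr[, "tail_base", "x"] <- tx
    arr[, "tail_base", "y"] <- ty
    arr[, , "likelihood"] <- 1
    if (params@noiseSigma > 0) {
      sPx <- params@noiseSigma * mean(.armLengthsPx(geometry))
      arr[, , c("x", "y")] <- arr[, , c("x", "y")] +
        stats::rnorm(length(arr[, , c("x", "y")]), sd = sPx)
    }
    session <- trackingSession(arr, fps = params@fps, sessionID = sessionID)
    lastT <- ft[nF]
    truth$groundTruthVisits <- visitsFromTruth(
      truth, maxTime = lastT, sessionID = sessionID
    )
    list(
      session = session, truth = truth,
      pathLengthCm = .pathLength(path, lastT) / ppc
    )
  })
}

#' Simulate one full synthetic session
#'
#' Convenience wrapper: draws a schedule filling the session duration with
#' [simulateChoices()] and renders it with [renderTrajectory()].
#'
#' @inheritParams renderTrajectory
#' @param params an [AgentParams-class].
#' @param boundary ground-truth boundary (default 0.25).
#' @param seed RNG seed (default `params@seed`) controlling both the
#'   schedule and the rendering noise.
#' @return as [renderTrajectory()].
#' @export
simulateSession <- function(params, geometry = defaultGeometry(),
                            sessionID = "sim", boundary = 0.25,
                            seed = params@seed) {
  doIt <- function() {
    truth <- simulateChoices(params, nVisits = NULL, boundary = boundary,
                             seed = NULL)
    renderTrajectory(truth, geometry, sessionID = sessionID, seed = NULL)
  }
  .withSeed(seed, doIt())
}

#' Simulate and write a cohort of sessions
#'
#' Writes one DeepLabCut-dialect CSV per subject plus a geometry YAML and a
#' ground-truth JSON manifest.  Per-subject seeds are drawn
#' deterministically from the master seed, so the same master seed
#' reproduces the cohort exactly.
#'
#' @param params an [AgentParams-class] shared by all subjects, or a list
#'   of one per subject.
#' @param n number of subjects (ignored when `params` is a list).
#' @param dir output directory (created if needed).
#' @param geometry a [MazeGeometry-class].
#' @param seed master seed.
#' @param prefix file-name prefix (default `"mouse"`).
#' @return invisibly, a manifest data.frame (sessionID, file, seed).
#' @export
simulateCohort <- function(params, n = NULL, dir, geometry = defaultGeometry(),
                           seed = 1, prefix = "mouse") {
  if (is(params, "AgentParams")) {
    if (is.null(n)) stop("give n when params is a single AgentParams")
    params <- rep(list(params), n)
  }
  if (!length(params)) stop("need at least one set of agent parameters")
  n <- length(params)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seeds <- .withSeed(seed, sample.int(2^31 - 2, n))
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  files <- file.path(dir, paste0(ids, ".csv"))
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulateSession(params[[i]], geometry, sessionID = ids[i],
                           seed = seeds[i])
    writeDLC(sim$session, files[i])
    gt[[i]] <- list(
      sessionID = ids[i], seed = seeds[i],
      visits = visits(sim$truth$groundTruthVisits),
      outcomes = sim$truth$visits$outcome,
      pathLengthCm = sim$pathLengthCm,
      alternationFidelity = params[[i]]@alternationFidelity,
      turningBias = params[[i]]@turningBias,
      memoryHalflife = params[[i]]@memoryHalflife
    )
  }
  writeGeometryYAML(geometry, file.path(dir, "geometry.yaml"),
                    fps = params[[1L]]@fps)
  jsonlite::write_json(
    gt, file.path(dir, "groundtruth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(data.frame(sessionID = ids, file = files, seed = seeds))
}
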