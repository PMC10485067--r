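#' Write and read maze configuration YAML
#'
#' The configuration carries everything the pipeline needs besides the
#' tracking CSVs: frame rate, analysis window, maze calibration, likelihood
#' floor and the sweep definition.  Unspecified fields fall back to the
#' package defaults (30 fps, 465 s window, boundary 0.25, sweep 0.25-0.70
#' in steps of 0.01, likelihood floor 0.6, 1000 chance iterations).
#'
#' @param geometry a [MazeGeometry-class].
#' @param path output YAML path.
#' @param fps frame rate recorded alongside the calibration.
#' @return `path` invisibly (`writeGeometryYAML`); a config list
#'   (`readYmazeConfig`).
#' @export
writeGeometryYAML <- function(geometry, path, fps = 30) {
  stopifnot(is(geometry, "MazeGeometry"))
  cfg <- list(
    fps = fps,
    maze = list(
      center = as.numeric(geometry@center),
      arm_ends = list(
        A = as.numeric(geometry@armEnds["A", ]),
        B = as.numeric(geometry@armEnds["B", ]),
        C = as.numeric(geometry@armEnds["C", ])
      ),
      arm_length_cm = geometry@armLengthCm
    )
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeGeometryYAML
#' @export
readYmazeConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    fps = 30, analysis_duration_s = 465, likelihood_floor = 0.6,
    boundary = 0.25, sweep_from = 0.25, sweep_to = 0.70, sweep_step = 0.01,
    chance_iterations = 1000
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (!is.null(cfg$maze)) {
    cfg$geometry <- mazeGeometry(
      center = unlist(cfg$maze$center),
      armEnds = rbind(
        unlist(cfg$maze$arm_ends$A),
        unlist(cfg$maze$arm_ends$B),
        unlist(cfg$maze$arm_ends$C)
      ),
      armLengthCm = if (is.null(cfg$maze$arm_length_cm)) 36 else
        cfg$maze$arm_length_cm
    )
  }
  cfg
}

#' Analyze one tracking session
#'
#' Runs the full per-session pipeline: read (or accept) the tracking data,
#' truncate to the analysis window, project onto normalized arm
#' coordinates, detect arm visits at the center-zone boundary, and compute
#' the threshold sweep, recency statistics and locomotion metrics.
#'
#' @param x a CSV path or a [TrackingSession-class].
#' @param geometry a [MazeGeometry-class].
#' @param boundary center-zone boundary (default 0.25); pass the value
#'   returned by [detectCenterBoundary()] for an occupancy-derived
#'   boundary.
#' @param grid sweep thresholds (default 0.25-0.70 step 0.01, clipped to
#'   start at the boundary).
#' @param duration analysis window in seconds (default 465).
#' @param fps frames per second (used when `x` is a path).
#' @param likelihoodFloor per-part likelihood floor (default 0.6).
#' @param chanceIterations Monte-Carlo iterations for the per-threshold
#'   chance band (0 = skip).
#' @param seed RNG seed for the chance band.
#' @return a list (class `ymSession`): `sessionID`, `trajectory`,
#'   `visits`, `sweep`, `choices`, `recency`, `locomotion`, `boundary`.
#' @export
analyzeSession <- function(x, geometry, boundary = 0.25, grid = NULL,
                           duration = 465, fps = 30, likelihoodFloor = 0.6,
                           chanceIterations = 0, seed = NULL) {
  session <- if (is.character(x)) readDLC(x, fps = fps) else x
  stopifnot(is(session, "TrackingSession"))
  session <- truncateSession(session, duration)
  traj <- projectSession(session, geometry, likelihoodFloor = likelihoodFloor)
  seq <- detectVisits(traj, boundary = boundary)
  sweep <- thresholdSweep(seq, grid = grid,
                          chanceIterations = chanceIterations, seed = seed)
  choices <- classifyChoices(seq)
  structure(
    list(
      sessionID = sessionID(session),
      trajectory = traj,
      visits = seq,
      sweep = sweep,
      choices = choices,
      recency = recencyStatistics(choices),
      locomotion = locomotionMetrics(traj, seq, geometry),
      boundary = boundary
    ),
    class = "ymSession"
  )
}

#' @export
print.ymSession <- function(x, ...) {
  cat(sprintf(
    "ymSession '%s': %d arm entries (boundary %.2f), travel %.1f cm\n",
    x$sessionID, nVisits(x$visits), x$boundary, x$locomotion$travelDistance
  ))
  r <- x$sweep$correctRate[1L]
  cat(sprintf(
    "  correct rate %.3f at threshold %.2f\n",
    r, x$sweep$threshold[1L]
  ))
  invisible(x)
}

#' Analyze a cohort of sessions
#'
#' Applies [analyzeSession()] to each input and assembles per-subject
#' metric curves over the shared threshold grid, ready for
#' [clusterPermutationTest()] / [compareCohorts()].  Per-file failures are
#' collected, reported, and do not abort the remaining sessions.
#'
#' @param paths character vector of CSV paths, a directory containing
#'   them, or a list of [TrackingSession-class] objects.
#' @inheritParams analyzeSession
#' @return a list (class `ymCohort`): `sessions` (list of `ymSession`),
#'   `curves` (list of subject x threshold matrices: `correctRate`,
#'   `armChoiceBias`, `nSufficient`, `visitRatio`), `scalars` (data.frame
#'   of locomotion metrics), `thresholds`, `failures`.
#' @export
analyzeCohort <- function(paths, geometry, boundary = 0.25, grid = NULL,
                          duration = 465, fps = 30, likelihoodFloor = 0.6,
                          chanceIterations = 0, seed = NULL) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.csv$", full.names = TRUE))
  }
  if (!length(paths)) stop("no sessions to analyze")
  sessions <- list()
  failures <- character(0)
  for (i in seq_along(paths)) {
    x <- if (is.list(paths)) paths[[i]] else paths[i]
    res <- tryCatch(
      analyzeSession(x, geometry, boundary = boundary, grid = grid,
                     duration = duration, fps = fps,
                     likelihoodFloor = likelihoodFloor,
                     chanceIterations = chanceIterations,
                     seed = if (is.null(seed)) NULL else seed + i),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf(
        "%s: %s", if (is.character(x)) x else i, conditionMessage(res)
      ))
    } else {
      sessions[[length(sessions) + 1L]] <- res
    }
  }
  if (length(failures)) {
    warning("failed sessions:\n  ", paste(failures, collapse = "\n  "))
  }
  if (!length(sessions)) stop("every session failed to analyze")
  thresholds <- sessions[[1L]]$sweep$threshold
  pull <- function(col) {
    m <- do.call(rbind, lapply(sessions, function(s) s$sweep[[col]]))
    rownames(m) <- vapply(sessions, `[[`, "", "sessionID")
    colnames(m) <- format(thresholds)
    m
  }
  scalars <- data.frame(
    sessionID = vapply(sessions, `[[`, "", "sessionID"),
    nEntries = vapply(sessions, function(s) s$locomotion$nEntries, 0),
    travelDistance = vapply(sessions,
                            function(s) s$locomotion$travelDistance, 0),
    armPreference = vapply(sessions,
                           function(s) s$locomotion$armPreference, 0)
  )
  structure(
    list(
      sessions = sessions,
      curves = list(
        correctRate = pull("correctRate"),
        armChoiceBias = pull("armChoiceBias"),
        nSufficient = pull("nSufficient"),
        visitRatio = pull("visitRatio")
      ),
      scalars = scalars,
      thresholds = thresholds,
      failures = failures
    ),
    class = "ymCohort"
  )
}

#' Compare two analyzed cohorts
#'
#' Sweep curves (correct rate, arm-choice bias, number and ratio of
#' sufficient visits) are compared with the cluster-based permutation test;
#' scalar locomotion metrics with Welch t tests; and within-cohort
#' correlations of the correct rate against the sufficiency ratio, travel
#' distance and number of sufficient visits are reported at a reference
#' threshold.
#'
#' @param cohortA,cohortB `ymCohort` objects from [analyzeCohort()].
#' @param nPermutations permutations for the cluster tests (default
#'   10000).
#' @param seed RNG seed for the permutation tests.
#' @param corThreshold reference threshold for the correlations (default
#'   0.70).
#' @return a list (class `ymComparison`) with `clusterTests`, `tTests`,
#'   `correlations`.
#' @export
compareCohorts <- function(cohortA, cohortB, nPermutations = 10000,
                           seed = NULL, corThreshold = 0.70) {
  stopifnot(inherits(cohortA, "ymCohort"), inherits(cohortB, "ymCohort"))
  if (!isTRUE(all.equal(cohortA$thresholds, cohortB$thresholds))) {
    stop("cohorts were analyzed on different threshold grids")
  }
  metrics <- names(cohortA$curves)
  clusterTests <- lapply(seq_along(metrics), function(i) {
    clusterPermutationTest(
      cohortA$curves[[metrics[i]]], cohortB$curves[[metrics[i]]],
      nPermutations = nPermutations,
      seed = if (is.null(seed)) NULL else seed + i,
      thresholds = cohortA$thresholds
    )
  })
  names(clusterTests) <- metrics
  tTests <- lapply(c("nEntries", "travelDistance", "armPreference"),
                   function(col) {
    unpairedT(cohortA$scalars[[col]], cohortB$scalars[[col]])
  })
  names(tTests) <- c("nEntries", "travelDistance", "armPreference")
  correlations <- lapply(list(A = cohortA, B = cohortB), function(co) {
    j <- which.min(abs(co$thresholds - corThreshold))
    cr <- co$curves$correctRate[, j]
    list(
      visitRatioVsCorrect = pearsonCor(co$curves$visitRatio[, j], cr),
      travelVsCorrect = pearsonCor(co$scalars$travelDistance, cr),
      nSufficientVsCorrect = pearsonCor(co$curves$nSufficient[, j], cr)
    )
  })
  structure(
    list(
      clusterTests = clusterTests, tTests = tTests,
      correlations = correlations, thresholds = cohortA$thresholds
    ),
    class = "ymComparison"
  )
}

#' @export
print.ymComparison <- function(x, ...) {
  cat("Cohort comparison\n")
  for (nm in names(x$clusterTests)) {
    cl <- x$clusterTests[[nm]]$clusters
    sig <- cl[cl$significant, , drop = FALSE]
    if (nrow(sig)) {
      cat(sprintf(
        "  %s: significant cluster(s) %s\n", nm,
        paste(sprintf("[%.2f, %.2f] p=%.4f", sig$thresholdStart,
                      sig$thresholdEnd, sig$pValue), collapse = ", ")
      ))
    } else {
      cat(sprintf("  %s: no significant clusters\n", nm))
    }
  }
  for (nm in names(x$tTests)) {
    tt <- x$tTests[[nm]]
    cat(sprintf(
      "  %s: mean %.2f vs %.2f, t = %.2f, p = %.4f\n",
      nm, tt$meanA, tt$meanB, tt$statistic, tt$pValue
    ))
  }
  invisible(x)
}

#' Run manifest
#'
#' Collects the configuration snapshot, seeds, package version and input
#' file hashes needed to reproduce a run, and optionally writes it as JSON.
#'
#' @param config configuration list (as from [readYmazeConfig()]).
#' @param seeds named list or vector of seeds used.
#' @param inputs character vector of input file paths to hash.
#' @param path optional JSON output path.
#' @return the manifest list, invisibly when written.
#' @export
runManifest <- function(config = list(), seeds = list(), inputs = character(0),
                        path = NULL) {
  hashes <- vapply(inputs, function(f) {
    if (!file.exists(f)) return(NA_character_)
    unname(tools::md5sum(f))
  }, "")
  man <- list(
    package = "ymazer",
    version = as.character(utils::packageVersion("ymazer")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config[setdiff(names(config), "geometry")],
    seeds = seeds,
    inputs = as.list(hashes)
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
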