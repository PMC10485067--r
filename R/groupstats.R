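#' Cluster-based permutation test over a threshold sweep
#'
#' Compares two cohorts of per-subject metric curves (e.g. correct rate vs
#' arm threshold) while controlling the family-wise error across the grid.
#' Pointwise two-sided Welch t statistics are computed at every threshold;
#' candidate clusters are maximal contiguous runs whose pointwise p falls
#' below `clusterAlpha`; each cluster's mass is the sum of |t| over its
#' run.  The null distribution is the maximum cluster mass over random
#' relabelings of subjects, and each observed cluster gets
#' `p = (1 + #(null >= mass)) / (1 + nPermutations)`.
#'
#' @param curvesA,curvesB numeric matrices, one row per subject, one column
#'   per threshold; both must share the same grid.  `NA` drops that subject
#'   at that threshold only.
#' @param nPermutations number of random relabelings (default 10000).
#' @param clusterForming pointwise two-sided alpha forming candidate
#'   clusters (default 0.05).
#' @param seed RNG seed; the test is deterministic given the seed.
#' @param thresholds optional numeric grid labels; defaults to numeric
#'   column names or the column index.
#' @return a list (class `ymClusterTest`) with a `clusters` data.frame
#'   (`thresholdStart`, `thresholdEnd`, `idxStart`, `idxEnd`, `mass`,
#'   `pValue`, `significant`), the pointwise `t` and `p`, the `thresholds`,
#'   and the test parameters.
#' @examples
#' a <- matrix(rnorm(5 * 10), 5)
#' b <- matrix(rnorm(6 * 10), 6)
#' clusterPermutationTest(a, b, nPermutations = 99, seed = 1)
#' @export
clusterPermutationTest <- function(curvesA, curvesB, nPermutations = 10000,
                                   clusterForming = 0.05, seed = NULL,
                                   thresholds = NULL) {
  curvesA <- as.matrix(curvesA)
  curvesB <- as.matrix(curvesB)
  if (ncol(curvesA) != ncol(curvesB)) {
    stop("cohort curves must share the same threshold grid")
  }
  if (nrow(curvesA) < 2L || nrow(curvesB) < 2L) {
    stop("each cohort needs at least 2 subjects")
  }
  K <- ncol(curvesA)
  if (is.null(thresholds)) {
    thresholds <- suppressWarnings(as.numeric(colnames(curvesA)))
    if (length(thresholds) != K || anyNA(thresholds)) thresholds <- seq_len(K)
  }
  if (length(thresholds) != K) {
    stop("thresholds must have one value per curve column")
  }

  findClusters <- function(t, p) {
    member <- !is.na(p) & p < clusterForming
    r <- rle(member)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iCl <- which(r$values)
    list(
      start = starts[iCl], end = ends[iCl],
      mass = vapply(iCl, function(j) {
        sum(abs(t[starts[j]:ends[j]]))
      }, 0)
    )
  }

  obs <- .colWelch(curvesA, curvesB)
  obsCl <- findClusters(obs$t, obs$p)

  X <- rbind(curvesA, curvesB)
  nA <- nrow(curvesA)
  nTot <- nrow(X)
  nullMax <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      ia <- sample.int(nTot, nA)
      w <- .colWelch(X[ia, , drop = FALSE], X[-ia, , drop = FALSE])
      cl <- findClusters(w$t, w$p)
      if (length(cl$mass)) max(cl$mass) else 0
    }, 0)
  })

  pvals <- vapply(obsCl$mass, function(m) {
    (1 + sum(nullMax >= m)) / (1 + nPermutations)
  }, 0)
  clusters <- data.frame(
    thresholdStart = thresholds[obsCl$start],
    thresholdEnd = thresholds[obsCl$end],
    idxStart = obsCl$start, idxEnd = obsCl$end,
    mass = obsCl$mass, pValue = pvals,
    significant = pvals < 0.05
  )
  structure(
    list(
      clusters = clusters, t = obs$t, p = obs$p, thresholds = thresholds,
      nPermutations = nPermutations, clusterForming = clusterForming,
      seed = seed, nullMax = nullMax
    ),
    class = "ymClusterTest"
  )
}

#' @export
print.ymClusterTest <- function(x, ...) {
  cat(sprintf(
    "Cluster-based permutation test (%d permutations, cluster-forming alpha %g)\n",
    x$nPermutations, x$clusterForming
  ))
  if (!nrow(x$clusters)) {
    cat("  no candidate clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf(
        "  cluster %g-%g: mass %.2f, p = %.4f%s\n",
        cl$thresholdStart, cl$thresholdEnd, cl$mass, cl$pValue,
        if (cl$significant) " *" else ""
      ))
    }
  }
  invisible(x)
}

#' Two-sample t test on scalar metrics
#'
#' Thin wrapper around [stats::t.test()] comparing one scalar behavioral
#' metric between cohorts; Welch by default, Student optionally.
#'
#' @param valuesA,valuesB numeric vectors (>= 2 values each).
#' @param varEqual use the Student (pooled-variance) form (default FALSE =
#'   Welch).
#' @return a list with `statistic`, `df`, `pValue`, `meanA`, `meanB`.
#' @export
unpairedT <- function(valuesA, valuesB, varEqual = FALSE) {
  if (length(valuesA) < 2L || length(valuesB) < 2L) {
    stop("each group needs at least 2 values")
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = varEqual)
  list(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    pValue = tt$p.value, meanA = mean(valuesA), meanB = mean(valuesB)
  )
}

#' Pearson correlation with two-sided p value
#'
#' Wrapper around [stats::cor.test()] guarding against degenerate input:
#' zero variance in either variable yields `NA` with a warning rather than
#' an error.
#'
#' @param x,y paired numeric vectors (>= 3 pairs).
#' @return a list with `r`, `pValue`, `n`.
#' @export
pearsonCor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, pValue = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(x))
}
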