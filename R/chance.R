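#' Closed-form chance-level alternation rate
#'
#' For an agent choosing arms purely by a turning bias -- clockwise steps
#' with probability `q = 0.5 + bias`, independent across choices -- a
#' choice is correct exactly when its direction matches the previous one,
#' so the expected alternation rate is `q^2 + (1 - q)^2`.  This is the
#' analytic counterpart of [simulateChance()].
#'
#' @param bias turning bias in \code{[0, 0.5]}.
#' @return the asymptotic chance-level alternation rate.
#' @examples
#' analyticChance(0)    # 0.5
#' analyticChance(0.1)  # 0.52
#' analyticChance(0.5)  # 1
#' @export
analyticChance <- function(bias) {
  if (any(bias < 0 | bias > 0.5)) stop("bias must lie in [0, 0.5]")
  q <- 0.5 + bias
  q^2 + (1 - q)^2
}

#' Expected alternation rate of the synthetic agent
#'
#' The agent alternates with probability `fidelity`; otherwise it takes an
#' independent biased direction step, which is itself correct with the
#' chance-level probability [analyticChance()].  Hence the expected
#' alternation rate is `fidelity + (1 - fidelity) * analyticChance(bias)`.
#'
#' @param fidelity alternation fidelity in \code{[0, 1]}.
#' @param bias turning bias in \code{[0, 0.5]}.
#' @return the expected alternation rate.
#' @export
expectedAlternationRate <- function(fidelity, bias) {
  stopifnot(all(fidelity >= 0 & fidelity <= 1))
  fidelity + (1 - fidelity) * analyticChance(bias)
}

#' Monte-Carlo chance-level alternation rate
#'
#' Simulates sequences of arm choices driven purely by the observed turning
#' bias: each step is clockwise with probability `0.5 + bias` (the sign of
#' the bias is irrelevant by symmetry), mapped onto the arm ring
#' A -> B -> C, and each simulated sequence is scored with
#' [classifyChoices()] and [alternationRate()].  Returns the mean and the
#' 2.5/97.5 percentile band across iterations.
#'
#' @param nVisits number of visits per simulated sequence (>= 3).
#' @param bias arm-choice bias in \code{[0, 0.5]}.
#' @param nIterations Monte-Carlo iterations (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return a list (class `ymChance`) with `meanRate`, `ciLow`, `ciHigh`,
#'   the per-iteration `rates`, and the simulation parameters.
#' @seealso [analyticChance()]
#' @export
simulateChance <- function(nVisits, bias, nIterations = 1000, seed = NULL) {
  if (length(bias) != 1L || is.na(bias) || bias < 0 || bias > 0.5) {
    stop("bias must be a single value in [0, 0.5]")
  }
  if (nVisits < 3L) stop("nVisits must be at least 3")
  q <- 0.5 + bias
  rates <- .withSeed(seed, {
    vapply(seq_len(nIterations), function(i) {
      ## clockwise = -1 on the counterclockwise ring A -> B -> C
      dirs <- ifelse(stats::runif(nVisits - 1L) < q, -1L, 1L)
      arms <- .ARMS[(cumsum(c(0L, dirs)) %% 3L) + 1L]
      alternationRate(classifyChoices(arms))
    }, 0)
  })
  structure(
    list(
      meanRate = mean(rates),
      ciLow = unname(stats::quantile(rates, 0.025)),
      ciHigh = unname(stats::quantile(rates, 0.975)),
      rates = rates,
      nIterations = nIterations, nVisits = nVisits, bias = bias,
      seed = seed
    ),
    class = "ymChance"
  )
}

#' @export
print.ymChance <- function(x, ...) {
  cat(sprintf(
    "Chance-level alternation: mean %.3f [%.3f, %.3f] (bias %.3f, %d visits, %d iterations)\n",
    x$meanRate, x$ciLow, x$ciHigh, x$bias, x$nVisits, x$nIterations
  ))
  invisible(x)
}

#' Chance band along a threshold grid
#'
#' Runs [simulateChance()] for each (visit count, bias) pair -- typically
#' the per-threshold values of a sweep, or cohort means recycled across the
#' grid -- and returns the aligned band.
#'
#' @param nVisits vector of visit counts (recycled against `bias`).
#' @param bias vector of arm-choice biases.
#' @param nIterations iterations per entry (default 1000).
#' @param seed RNG seed; per-entry streams are derived from it.
#' @return a data.frame with `chanceMean`, `chanceLow`, `chanceHigh` (NA
#'   where fewer than 3 visits or the bias is undefined).
#' @export
chanceBand <- function(nVisits, bias, nIterations = 1000, seed = NULL) {
  k <- max(length(nVisits), length(bias))
  nVisits <- rep_len(nVisits, k)
  bias <- rep_len(bias, k)
  out <- data.frame(
    chanceMean = rep(NA_real_, k), chanceLow = NA_real_, chanceHigh = NA_real_
  )
  for (i in seq_len(k)) {
    if (is.na(bias[i]) || is.na(nVisits[i]) || nVisits[i] < 3L) next
    ch <- simulateChance(
      nVisits[i], bias[i], nIterations = nIterations,
      seed = if (is.null(seed)) NULL else seed + i
    )
    out$chanceMean[i] <- ch$meanRate
    out$chanceLow[i] <- ch$ciLow
    out$chanceHigh[i] <- ch$ciHigh
  }
  out
}
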