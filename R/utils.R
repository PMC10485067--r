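## Internal helpers shared across modules.

## Evaluate expr under a local RNG stream: the global .Random.seed is left
## untouched, and results are reproducible given `seed`.  seed = NULL uses
## (and advances) the global stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Centered moving average with shrinking windows at the edges (partial
## windows rather than NA padding), window = odd number of bins.
.movingAverage <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Linear interpolation of flagged frames in a coordinate vector; frames in
## `bad` are replaced by interpolation between good neighbours, with
## constant extrapolation at the ends.
.interpolateBad <- function(x, bad, t) {
  if (!any(bad)) return(x)
  if (all(bad)) stop("no frames left to interpolate from")
  stats::approx(t[!bad], x[!bad], xout = t, rule = 2)$y
}

## Column-wise Welch t statistics for matrices A (nA x K) and B (nB x K),
## NA-tolerant.  Returns t, Welch-Satterthwaite df and two-sided p per
## column; columns with fewer than 2 non-missing values per group give NA.
.colWelch <- function(A, B) {
  stat <- function(M) {
    ok <- !is.na(M)
    n <- colSums(ok)
    M0 <- M
    M0[!ok] <- 0
    m <- colSums(M0) / n
    v <- (colSums(M0^2) - n * m^2) / (n - 1)
    list(n = n, m = m, v = v)
  }
  a <- stat(A)
  b <- stat(B)
  se2 <- a$v / a$n + b$v / b$n
  t <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
  bad <- a$n < 2L | b$n < 2L | !is.finite(t)
  t[bad] <- NA_real_
  df[bad] <- NA_real_
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

## Ring arithmetic on arms A, B, C.  step +1 = counterclockwise (A -> B),
## step -1 = clockwise (A -> C).
.armStep <- function(arm, step) {
  idx <- match(arm, .ARMS)
  .ARMS[((idx - 1L + step) %% 3L) + 1L]
}

## Direction of a transition between two distinct arms: +1 (CCW), -1 (CW).
.armDirection <- function(from, to) {
  d <- (match(to, .ARMS) - match(from, .ARMS)) %% 3L
  ifelse(d == 1L, 1L, ifelse(d == 2L, -1L, NA_integer_))
}
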