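# Internal helpers shared across modules.

# trapezoidal integration on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# excess kurtosis (0 for a Gaussian)
excessKurtosis <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  mean((x - mean(x))^4) / s^4 - 3
}

# match two sorted event-time vectors within a tolerance; greedy nearest pairs.
# Returns a two-column matrix of indices (i in a, j in b).
matchEvents <- function(a, b, tol) {
  if (!length(a) || !length(b)) return(matrix(integer(), ncol = 2))
  pairs <- matrix(integer(), ncol = 2)
  usedB <- rep(FALSE, length(b))
  for (i in seq_along(a)) {
    d <- abs(b - a[i])
    d[usedB] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      pairs <- rbind(pairs, c(i, j))
      usedB[j] <- TRUE
    }
  }
  pairs
}

# least-squares slope of y against 1..n
lsSlope <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# structured condition helper so callers can test error classes
stopWith <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
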