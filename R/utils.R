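## shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stumblr <- function(message, class) {
  stop(errorCondition(message, class = c(class, "stumblr_error")))
}

## sample indices covering [start, end) on a uniform grid starting at t = 0
window_indices <- function(start, end, rate, n) {
  i1 <- floor(start * rate + 1e-9) + 1L
  i2 <- ceiling(end * rate - 1e-9)
  i1 <- max(1L, i1)
  i2 <- min(n, i2)
  if (i2 < i1) integer(0) else seq.int(i1, i2)
}

## local maxima of a series with a simple saddle-based prominence gate:
## a candidate peak is kept when it rises at least `min_prominence` above
## the higher of the two adjacent valleys.  Plateaus report their centre.
local_maxima <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  ## propagate sign through flat runs so plateaus register once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(diff(s) < 0) + 1L
  if (!length(idx)) return(integer(0))
  if (min_prominence <= 0) return(idx)
  valleys <- which(diff(s) > 0) + 1L
  bounds <- c(1L, valleys, n)
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    p <- idx[k]
    lo <- max(bounds[bounds < p])
    hi <- min(bounds[bounds > p])
    left_base <- min(x[lo:p])
    right_base <- min(x[p:hi])
    keep[k] <- (x[p] - max(left_base, right_base)) >= min_prominence
  }
  idx[keep]
}

## maximal runs of TRUE in a logical vector -> matrix with columns start, end
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
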