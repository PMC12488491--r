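#' Discrete Kneedle knee detection
#'
#' Finds the knee of a decreasing convex curve: both axes are normalized to
#' \[0, 1\], the curve is mapped to a concave increasing one, and the knee is
#' the first local maximum of the difference curve `d = y_t - x_n` whose value
#' is not regained before `d` drops below `d_max - sensitivity * mean(diff(x_n))`.
#'
#' @param x,y numeric vectors (same length, `x` strictly increasing).
#' @param sensitivity positive scalar; larger values demand a sharper knee.
#' @return the `x` value at the knee, or `NA` when no knee exists (flat or
#'   linear curves).
#' @export
kneedle <- function(x, y, sensitivity = 1.0) {
  stopifnot(length(x) == length(y), length(x) >= 2, all(diff(x) > 0))
  if (diff(range(y)) <= 0 || diff(range(x)) <= 0) return(NA_real_)
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  yt <- 1 - yn                               # decreasing convex -> increasing concave
  d <- yt - xn
  n <- length(d)
  if (n < 3) return(NA_real_)
  is_lmx <- vapply(2:(n - 1), function(i)
    d[i] >= d[i - 1] && d[i] >= d[i + 1] && d[i] > 0, logical(1))
  lmx <- (2:(n - 1))[is_lmx]
  if (!length(lmx)) return(NA_real_)
  step <- mean(diff(xn))
  for (i in lmx) {
    threshold <- d[i] - sensitivity * step
    j <- i + 1
    while (j <= n) {
      if (j %in% lmx && d[j] > d[i]) break   # a higher knee candidate supersedes
      if (d[j] < threshold) return(x[i])
      j <- j + 1
    }
  }
  NA_real_
}
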