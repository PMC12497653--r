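#' Weighted isotonic regression (pool adjacent violators)
#'
#' Exact least-squares non-decreasing fit: minimizes
#' \eqn{\sum_i w_i (y_i - f_i)^2} subject to \eqn{f_1 \le \dots \le f_n},
#' by the pool-adjacent-violators algorithm. Weighting by per-level
#' observation counts makes the pooled solution match the unpooled
#' least-squares objective when \code{y} holds per-level means.
#'
#' @param y numeric response values, ordered by the predictor.
#' @param w positive observation weights (default all 1).
#' @return Numeric vector of fitted non-decreasing values.
#' @examples
#' pava(c(0.6, 0.2))          # pooled to 0.4, 0.4
#' pava(c(0.1, 0.5, 0.9))     # already isotonic: unchanged
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  stop_if(length(w) != n, "y and w must have equal length")
  stop_if(any(w <= 0), "weights must be positive")
  if (n <= 1) return(y)
  # stack of blocks: value, weight, size
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] >= val[top]) {
      wtot <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wtot
      wt[top - 1L] <- wtot
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = sz[seq_len(top)])
}
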