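# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Sampling constants
#'
#' The recording convention used throughout: 20-kHz sampling, 45-ms trial
#' windows of 900 samples, stimulus onset at sample 100 (5 ms of pre-stimulus
#' context).
#' @keywords internal
#' @name trial-window
NULL

.SAMPLE_RATE_HZ <- 20000
.DT_MS <- 1000 / .SAMPLE_RATE_HZ  # 0.05 ms per sample
.TRIAL_LEN <- 900
.STIM_ONSET <- 100                # sample index (1-based: sample 101 is t=5ms)

# Deterministic sub-seed derivation so that one user-facing seed drives all
# modules without coupling their streams. Keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483629L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Inverse-CDF draw from a univariate normal truncated to (0, Inf).
rtruncnorm_pos <- function(n, mean, sd) {
  sd <- pmax(sd, .Machine$double.eps)
  lo <- stats::pnorm(0, mean, sd)
  u <- lo + (1 - lo) * stats::runif(n)
  # guard against u == 1 rounding
  u <- pmin(u, 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

# Mean of the positive-truncated normal (used by quadrature oracles/tests).
etruncnorm_pos <- function(mean, sd) {
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

logit <- function(p) log(p) - log1p(-p)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
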