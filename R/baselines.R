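#' CoSaMP: compressive sampling matching pursuit
#'
#' The standard greedy compressed-sensing baseline, run on the binary
#' stimulated/not-stimulated design matrix (laser powers collapsed) with no
#' model of stochastic presynaptic spiking — which is exactly why its
#' synaptic-weight estimates are biased toward zero when spike probabilities
#' are below one. The number of desired connections \code{sparsity} must be
#' supplied in advance.
#'
#' @param y vector of K observed responses.
#' @param A N x K binary stimulation matrix (or a power matrix; any nonzero
#'   entry counts as stimulated).
#' @param sparsity number of nonzero weights to recover (0 returns the zero
#'   vector).
#' @param max_iter iteration cap.
#' @param tol relative residual-stagnation tolerance.
#' @return An object of class \code{baseline_result}: \code{weights},
#'   \code{method = "cosamp"}, \code{iterations}, \code{sparsity}.
#' @export
cosamp <- function(y, A, sparsity, max_iter = 50, tol = 1e-6) {
  N <- nrow(A); K <- ncol(A)
  stop_if(length(y) != K, "length(y) must match ncol(A)")
  stop_if(sparsity > N, "sparsity cannot exceed the candidate pool")
  A <- (A != 0) * 1
  w <- numeric(N)
  if (sparsity == 0) {
    return(structure(list(weights = w, method = "cosamp", iterations = 0,
                          sparsity = 0), class = "baseline_result"))
  }
  r <- y
  rn_old <- sqrt(sum(r^2))
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    proxy <- as.numeric(A %*% r)
    cand <- union(which(w != 0),
                  order(abs(proxy), decreasing = TRUE)[seq_len(min(2 * sparsity, N))])
    X <- t(A[cand, , drop = FALSE])
    b <- qr.coef(qr(X), y)
    b[is.na(b)] <- 0
    keep <- cand[order(abs(b), decreasing = TRUE)[seq_len(min(sparsity, length(cand)))]]
    X2 <- t(A[keep, , drop = FALSE])
    b2 <- qr.coef(qr(X2), y)
    b2[is.na(b2)] <- 0
    w <- numeric(N)
    w[keep] <- b2
    r <- y - as.numeric(crossprod(A, w))
    rn <- sqrt(sum(r^2))
    if (abs(rn_old - rn) <= tol * max(rn_old, 1e-12)) break
    rn_old <- rn
  }
  structure(list(weights = w, method = "cosamp", iterations = it,
                 sparsity = sparsity), class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s baseline: %d nonzero weights after %d iterations\n",
              x$method, sum(x$weights != 0), x$iterations))
  invisible(x)
}

#' CAVI-SnS-style spike-and-slab ablation
#'
#' Runs the same coordinate-ascent engine as \code{\link{caviar_fit}} but
#' with the isotonic plausibility rule, trial masking and spontaneous-
#' current estimation disabled (z is identically zero) — an ablation in the
#' style of earlier spike-and-slab variational mapping methods, which lack
#' those mechanisms. Connections are selected post hoc by a posterior
#' spike-probability threshold: a neuron is kept when its mean inferred
#' spike probability at maximal power exceeds \code{spike_threshold}.
#'
#' @param y vector of K observed responses.
#' @param design a \code{\link{stim_design}}.
#' @param traces ignored (kept for interface parity).
#' @param hyper a \code{\link{caviar_hyper}} (its switches are overridden).
#' @param spike_threshold posterior spike-rate threshold at maximal power.
#' @param seed optional integer seed.
#' @return A \code{caviar_fit} with \code{method = "cavi_sns"} and
#'   thresholded \code{weights}/\code{connected}.
#' @export
cavi_sns <- function(y, design, traces = NULL, hyper = caviar_hyper(),
                     spike_threshold = 0.5, seed = NULL) {
  hyper$use_plausibility <- FALSE
  hyper$use_masking <- FALSE
  hyper$use_spont <- FALSE
  fit <- caviar_fit(y, design, traces = NULL, hyper = hyper, seed = seed)
  fmax <- vapply(fit$power_curves, curve_at_max, numeric(1))
  keep <- !is.na(fmax) & fmax > spike_threshold
  fit$connected <- keep
  w <- fit$mu
  w[!keep] <- 0
  fit$weights <- w
  fit$method <- "cavi_sns"
  fit
}
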