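#' Postsynaptic current (PSC) template
#'
#' A double-exponential PSC kernel with rise time constant \code{tau_r},
#' decay time constant \code{tau_d} and onset time \code{delta} (all in ms):
#' \deqn{h(t) = [\exp(-(t-\delta)/\tau_d) - \exp(-(t-\delta)/\tau_r)]\,
#'       1[t \ge \delta].}
#' When \code{normalize = TRUE} the kernel is scaled so that its discrete-time
#' integral equals one, so that multiplying by a synaptic weight (charge
#' transfer, pA ms) preserves that charge.
#'
#' @param tau_r rise time constant (ms); must satisfy \code{0 < tau_r < tau_d}.
#' @param tau_d decay time constant (ms).
#' @param delta onset time (ms), non-negative.
#' @param normalize logical; unit-integral normalization flag.
#' @return An object of class \code{psc_template}.
#' @examples
#' tpl <- psc_template(tau_r = 1, tau_d = 10)
#' w <- eval_template(tpl, n_samples = 4000)
#' sum(w) * 0.05  # integral = 1
#' @export
psc_template <- function(tau_r, tau_d, delta = 0, normalize = TRUE) {
  stop_if(!is.finite(tau_r) || !is.finite(tau_d) || tau_r <= 0,
          "tau_r must be positive and finite")
  stop_if(tau_d <= tau_r, "invalid kinetics: tau_d must exceed tau_r")
  stop_if(delta < 0, "delta must be non-negative")
  structure(list(tau_r = tau_r, tau_d = tau_d, delta = delta,
                 normalize = normalize),
            class = "psc_template")
}

#' @export
print.psc_template <- function(x, ...) {
  cat(sprintf("PSC template: tau_r = %.3g ms, tau_d = %.3g ms, delta = %.3g ms%s\n",
              x$tau_r, x$tau_d, x$delta,
              if (x$normalize) " (unit integral)" else ""))
  invisible(x)
}

# Discrete integral (sum * dt) of the unnormalized kernel on a grid aligned
# with t = 0, extended far enough that the truncated tail is negligible.
template_norm_const <- function(tau_r, tau_d, delta, dt = .DT_MS) {
  horizon <- delta + 14 * tau_d
  t <- seq(0, horizon, by = dt)
  u <- t - delta
  v <- ifelse(u >= 0, exp(-u / tau_d) - exp(-u / tau_r), 0)
  sum(v) * dt
}

#' Evaluate a PSC template on a regular time grid
#'
#' @param template a \code{\link{psc_template}}.
#' @param n_samples number of samples to evaluate (grid starts at t = 0).
#' @param dt sample spacing in ms (default 0.05 ms, i.e. 20 kHz).
#' @return Numeric vector of length \code{n_samples}; zero before the onset,
#'   non-negative, and (if normalized and the window covers the kernel) with
#'   discrete integral 1.
#' @export
eval_template <- function(template, n_samples = .TRIAL_LEN, dt = .DT_MS) {
  stopifnot(inherits(template, "psc_template"))
  t <- (seq_len(n_samples) - 1) * dt
  u <- t - template$delta
  v <- numeric(n_samples)
  pos <- u >= 0
  v[pos] <- exp(-u[pos] / template$tau_d) - exp(-u[pos] / template$tau_r)
  if (template$normalize) {
    v <- v / template_norm_const(template$tau_r, template$tau_d,
                                 template$delta, dt)
  }
  v
}

# Fast path used by the simulators: unit-charge kernel starting at its onset
# (t = 0 is the onset sample), truncated at 12 decay constants.
unit_kernel <- function(tau_r, tau_d, dt = .DT_MS, n_tail = 12) {
  len <- ceiling(n_tail * tau_d / dt)
  t <- (seq_len(len) - 1) * dt
  v <- exp(-t / tau_d) - exp(-t / tau_r)
  v / (sum(v) * dt)
}
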