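#' Hyperparameters for the CAVIaR inference engine
#'
#' CAVIaR (coordinate-ascent variational inference with isotonic
#' regularization) fits a hierarchical model in which each observed response
#' \eqn{y_k} (the charge of the demixed PSC on trial k) is a noisy sum of
#' synaptic weights over the presynaptic neurons that spiked:
#' \eqn{y_k ~ Normal(w' s_k, \sigma^2)}, with power-dependent Bernoulli
#' spikes \eqn{s_{nk} ~ Bern(f(\phi_n^0 I_{nk} - \phi_n^1))}, a Gaussian
#' weight prior, truncated-normal power-curve coefficients and a gamma prior
#' on the noise precision.
#'
#' The power-curve prior is deliberately conservative: under the prior mean
#' the spike probability at the maximal power is below the plausibility
#' threshold, so a neuron is only retained when the data lift its inferred
#' spike rate above \code{theta_pava + lambda_spont}. This is what gives the
#' method its selectivity against spurious connections.
#'
#' @param u,b2 weight prior mean and variance (pA ms)^2; \code{b2 = NULL}
#'   sets it at fit time from a robust scale of the observations
#'   (\code{quantile(|y|, .95)^2}).
#' @param t_sh,t_ra gamma prior shape and rate on the noise precision
#'   (vague by default).
#' @param phi_mean,phi_cov prior mean (length 2) and covariance (2 x 2) of
#'   the power-curve coefficients (phi0 slope in 1/mW, phi1 intercept).
#' @param theta_pava minimum isotonic spike rate at maximum power for a
#'   neuron to be considered connected (0.4 for inhibitory presynaptic
#'   mapping, 0.3 for excitatory).
#' @param mc_samples Monte-Carlo sample count M for the spike-update
#'   expectation.
#' @param tau_min trial-masking threshold on the regularized lag-1
#'   autocorrelation of the demixed trace (see \code{\link{mask_trials}}).
#' @param tau_floor noise-floor amplitude (pA) of the masking statistic.
#' @param eps_spont residual-norm tolerance of the spontaneous-current
#'   soft-threshold shrink loop.
#' @param theta_orthog spike-orthogonality bound: trials with total inferred
#'   spike probability above this cannot carry spontaneous current. The
#'   default of 1 ("no confident spike on the trial") leaves slack for the
#'   diffuse spike posteriors of unresolved weak candidates; sharply binary
#'   posteriors would permit a bound near 0.
#' @param max_iter,tol outer-loop iteration cap and relative convergence
#'   tolerance on the weight posterior mean.
#' @param warmup initial outer iterations during which neither the
#'   plausibility disconnect rule nor the spontaneous-current update is
#'   applied: both read residuals of the fitted model, and during the first
#'   sweeps those residuals reflect the diffuse warm-start spike posteriors
#'   rather than unexplained events, so engaging them early eliminates true
#'   connections.
#' @param use_plausibility,use_masking,use_spont switches for the isotonic
#'   plausibility rule, trial masking and spontaneous-current estimation
#'   (all on for CAVIaR; the spike-and-slab ablation turns them off).
#' @return An object of class \code{caviar_hyper}.
#' @export
caviar_hyper <- function(u = 0, b2 = NULL, t_sh = 1e-2, t_ra = 1e-2,
                         phi_mean = c(0.05, 4),
                         phi_cov = diag(c(0.05^2, 1^2)),
                         theta_pava = 0.4, mc_samples = 100,
                         tau_min = 0.5, tau_floor = 4, eps_spont = 0.05,
                         theta_orthog = 1,
                         max_iter = 50, tol = 1e-5, warmup = 5,
                         use_plausibility = TRUE, use_masking = TRUE,
                         use_spont = TRUE) {
  stop_if(!is.null(b2) && b2 <= 0, "b2 must be positive")
  stop_if(t_sh <= 0 || t_ra <= 0, "t_sh, t_ra must be positive")
  stop_if(theta_pava < 0 || theta_pava > 1, "theta_pava must lie in [0, 1]")
  stop_if(mc_samples < 1, "mc_samples must be >= 1")
  stop_if(eps_spont <= 0 || eps_spont >= 1, "eps_spont must lie in (0, 1)")
  structure(list(u = u, b2 = b2, t_sh = t_sh, t_ra = t_ra,
                 phi_mean = phi_mean, phi_cov = phi_cov,
                 theta_pava = theta_pava, mc_samples = mc_samples,
                 tau_min = tau_min, tau_floor = tau_floor,
                 eps_spont = eps_spont,
                 theta_orthog = theta_orthog,
                 max_iter = max_iter, tol = tol, warmup = warmup,
                 use_plausibility = use_plausibility,
                 use_masking = use_masking, use_spont = use_spont),
            class = "caviar_hyper")
}

#' Initialize the variational state
#'
#' Spike posteriors start at the prior sigmoid evaluated at the prior-mean
#' power-curve coefficients (zero on untargeted entries), the weight
#' posterior at its prior, the noise posterior at its prior, spontaneous
#' currents at zero. Deterministic given the inputs.
#'
#' @param design a \code{\link{stim_design}}.
#' @param y numeric vector of K observed responses (pA ms).
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return An object of class \code{caviar_state}.
#' @export
init_state <- function(design, y, hyper = caviar_hyper()) {
  I <- design$powers
  N <- nrow(I); K <- ncol(I)
  stop_if(length(y) != K, "length(y) must equal the number of trials")
  b2 <- hyper$b2 %||% max(stats::quantile(abs(y), 0.95)^2, 1)
  lambda <- matrix(0, N, K)
  targ <- I > 0
  lambda[targ] <- stats::plogis(hyper$phi_mean[1] * I[targ] - hyper$phi_mean[2])
  nu <- matrix(rep(hyper$phi_mean, each = N), N, 2)
  Sigma <- array(rep(as.numeric(hyper$phi_cov), each = N), c(N, 2, 2))
  structure(list(mu = rep(hyper$u, N),
                 Omega = diag(rep(b2, N)),
                 lambda = lambda,
                 nu = nu, Sigma = Sigma,
                 theta_sh = hyper$t_sh, theta_ra = hyper$t_ra,
                 z = numeric(K), lambda_spont = 0,
                 connected = rep(TRUE, N),
                 mask = rep(TRUE, K),
                 pred = as.numeric(crossprod(lambda, rep(hyper$u, N))),
                 b2 = b2),
            class = "caviar_state")
}

#' Variational block update of the synaptic-weight posterior
#'
#' Conjugate Gaussian update: with spike posteriors \eqn{\Lambda} and noise
#' precision expectation \eqn{\theta_{sh}/\theta_{ra}},
#' \deqn{\Omega = (\frac{\theta_{sh}}{\theta_{ra}} \sum_k (D_k + M_k) +
#'   I/b^2)^{-1}, \quad
#'   \mu = \Omega (\frac{\theta_{sh}}{\theta_{ra}} \sum_k y_k \lambda_{:,k} +
#'   u/b^2)}
#' with \eqn{D_k = diag(\lambda_{nk}(1-\lambda_{nk}))} and
#' \eqn{M_k = \lambda_{:,k}\lambda_{:,k}'}. Reduces to conjugate Bayesian
#' linear regression when \eqn{\Lambda} is binary.
#'
#' @param state a \code{caviar_state}.
#' @param y observation vector.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return The state with updated \code{mu}, \code{Omega}, \code{pred}.
#' @export
update_weights <- function(state, y, hyper = caviar_hyper()) {
  stop_if(any(!is.finite(y)), "non-finite observations")
  L <- state$lambda
  N <- nrow(L)
  prec <- state$theta_sh / state$theta_ra
  S <- tcrossprod(L)                       # sum_k M_k
  d <- rowSums(L * (1 - L))                # sum_k D_k (diagonal)
  A <- prec * (S + diag(d, N)) + diag(1 / state$b2, N)
  R <- chol(A)
  Omega <- chol2inv(R)
  rhs <- prec * as.numeric(L %*% y) + hyper$u / state$b2
  mu <- as.numeric(Omega %*% rhs)
  mu[!state$connected] <- 0
  state$mu <- mu
  state$Omega <- (Omega + t(Omega)) / 2
  state$pred <- as.numeric(crossprod(L, mu))
  state
}

#' Variational update of one neuron's spike posteriors (all trials)
#'
#' The logit of \eqn{\lambda_{nk}} is the Monte-Carlo estimate of
#' \eqn{E_q[\ln(f_{nk}/(1-f_{nk}))]} (with \eqn{\phi} drawn independently
#' from its truncated-normal marginals) plus the likelihood term
#' \eqn{-\frac{\theta_{sh}}{2\theta_{ra}}\{-2 y_k \mu_n +
#' 2\mu_n \sum_{j \ne n}\mu_j\lambda_{jk} - (\mu_n^2 + \beta_n^2)\}},
#' where \eqn{\beta_n^2} is the posterior weight variance (nth diagonal of
#' \eqn{\Omega}). Logits are clamped to ±15; untargeted and masked trials
#' stay at zero.
#'
#' @param state a \code{caviar_state}.
#' @param n neuron index.
#' @param y observation vector.
#' @param design a \code{\link{stim_design}}.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return The state with row n of \code{lambda} updated.
#' @export
update_spikes <- function(state, n, y, design, hyper = caviar_hyper()) {
  I <- design$powers
  ks <- which(I[n, ] > 0 & state$mask)
  if (!length(ks)) return(state)
  M <- hyper$mc_samples
  ph0 <- rtruncnorm_pos(M, state$nu[n, 1], sqrt(state$Sigma[n, 1, 1]))
  ph1 <- rtruncnorm_pos(M, state$nu[n, 2], sqrt(state$Sigma[n, 2, 2]))
  # E[ln(f/(1-f))] = E[phi0 I - phi1]; the MC estimator keeps the sampling
  # noise the algorithm is specified with.
  mc <- mean(ph0) * I[n, ks] - mean(ph1)
  prec <- state$theta_sh / state$theta_ra
  mu_n <- state$mu[n]
  beta2 <- state$Omega[n, n]
  resid <- y[ks] - (state$pred[ks] - mu_n * state$lambda[n, ks])
  lg <- clamp(mc + prec * (mu_n * resid - (mu_n^2 + beta2) / 2), -15, 15)
  lam <- stats::plogis(lg)
  state$pred[ks] <- state$pred[ks] + mu_n * (lam - state$lambda[n, ks])
  state$lambda[n, ks] <- lam
  state
}

#' Isotonically constrained optogenetic power curve
#'
#' Averages a neuron's inferred spike probabilities per power level
#' (\code{lambda_bar}) and fits a non-decreasing curve through them by
#' count-weighted PAVA. Masked trials enter the averages with their enforced
#' zero spike probability: a masked window contains no detectable PSC, so it
#' is evidence of a non-spike, and counting it keeps the power curve an
#' honest estimate of the per-stimulus spike rate. Power levels never used
#' for this neuron are excluded from the fit (with a warning).
#'
#' @param lambda_n spike posterior for one neuron over trials (length K).
#' @param powers_n laser powers applied to that neuron per trial (length K;
#'   0 = untargeted).
#' @param power_set the discrete set of non-zero powers used in the
#'   experiment.
#' @param mask logical trial mask (unused in the averaging; retained so
#'   callers can pass the fit mask for provenance).
#' @param warn warn about power levels with no trials.
#' @return An object of class \code{power_curve}: \code{power},
#'   \code{lambda_bar}, \code{fitted} (the isotonic fit), \code{counts}.
#' @export
isotonic_power_curve <- function(lambda_n, powers_n, power_set,
                                 mask = rep(TRUE, length(lambda_n)),
                                 warn = TRUE) {
  power_set <- sort(power_set)
  lb <- counts <- numeric(length(power_set))
  for (i in seq_along(power_set)) {
    ks <- which(powers_n == power_set[i])
    counts[i] <- length(ks)
    lb[i] <- if (length(ks)) mean(lambda_n[ks]) else NA_real_
  }
  use <- counts > 0
  if (warn && any(!use)) {
    warning(sprintf("power level(s) %s never used for this neuron; excluded",
                    paste(power_set[!use], collapse = ", ")))
  }
  fitted <- rep(NA_real_, length(power_set))
  if (any(use)) fitted[use] <- pava(lb[use], counts[use])
  structure(list(power = power_set, lambda_bar = lb, fitted = fitted,
                 counts = counts),
            class = "power_curve")
}

# value of the isotonic curve at the maximal power with data
curve_at_max <- function(curve) {
  ok <- which(!is.na(curve$fitted))
  if (!length(ok)) return(NA_real_)
  curve$fitted[max(ok)]
}

#' Apply the isotonic plausibility rule to one neuron
#'
#' A neuron whose isotonic power curve at the maximal applied power falls
#' below \code{theta_pava + lambda_spont} (the user threshold adaptively
#' raised by the estimated spontaneous-detection rate) is considered
#' unconnected: its weight posterior mean and spike posteriors are set to
#' zero.
#'
#' @param state a \code{caviar_state}.
#' @param n neuron index.
#' @param curve the neuron's \code{power_curve}.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return The (possibly disconnected) state.
#' @export
apply_plausibility <- function(state, n, curve, hyper = caviar_hyper()) {
  fmax <- curve_at_max(curve)
  if (is.na(fmax)) return(state)
  if (fmax < hyper$theta_pava + state$lambda_spont) {
    state$pred <- state$pred - state$mu[n] * state$lambda[n, ]
    state$mu[n] <- 0
    state$lambda[n, ] <- 0
    state$connected[n] <- FALSE
  }
  state
}

#' Mask low-information trials
#'
#' Computes a noise-floor-regularized lag-1 sample autocorrelation of each
#' (demixed) trace,
#' \deqn{\tau(c) = \frac{\sum_t \tilde c_t \tilde c_{t+1}}
#'   {\sum_t \tilde c_t^2 + T\,\sigma_{floor}^2}}
#' (with \eqn{\tilde c} the centered trace): for a smooth PSC waveform well
#' above the floor this is the ordinary autocorrelation (near 1); for white
#' noise it is near 0; and for the small smooth residuals the demixing
#' network emits on PSC-free windows the floor term shrinks it toward 0.
#' Trials with \eqn{\tau < \tau_{min}} carry no usable PSC and have all
#' spike posteriors and spontaneous currents forced to zero during
#' inference.
#'
#' @param traces K x T matrix of demixed traces.
#' @param tau_min masking threshold.
#' @param noise_floor amplitude floor \eqn{\sigma_{floor}} (pA); the default
#'   is calibrated so that at least 95\% of pure-noise windows are masked
#'   under the default simulated noise configuration.
#' @return Logical vector of length K: \code{TRUE} = keep (unmasked).
#' @export
mask_trials <- function(traces, tau_min = 0.5, noise_floor = 4) {
  apply(traces, 1, trace_autocor, noise_floor = noise_floor) >= tau_min
}

trace_autocor <- function(x, noise_floor = 0) {
  x <- x - mean(x)
  v <- sum(x^2) + length(x) * noise_floor^2
  if (v < .Machine$double.eps) return(0)
  sum(x[-1] * x[-length(x)]) / v
}

#' Laplace update of one neuron's power-curve coefficient posterior
#'
#' Finds the positive-orthant mode of the expected Bernoulli log-likelihood
#' of the inferred spikes plus the Gaussian prior, with a log-barrier
#' enforcing positivity, by damped Newton iterations with backtracking line
#' search; the barrier is sharpened a few times. The posterior covariance is
#' the inverse Hessian at the mode.
#'
#' @param state a \code{caviar_state}.
#' @param n neuron index.
#' @param design a \code{\link{stim_design}}.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @param barrier_schedule increasing barrier sharpness values.
#' @return The state with \code{nu[n, ]} and \code{Sigma[n, , ]} updated.
#' @export
update_phi <- function(state, n, design, hyper = caviar_hyper(),
                       barrier_schedule = c(10, 100, 1000)) {
  I <- design$powers
  ks <- which(I[n, ] > 0 & state$mask)
  if (!length(ks)) return(state)
  Ik <- I[n, ks]
  lam <- state$lambda[n, ks]
  v <- hyper$phi_mean
  Linv <- solve(hyper$phi_cov)
  objective <- function(phi, t) {
    x <- phi[1] * Ik - phi[2]
    # -sum[lam log f + (1-lam) log(1-f)] with stable log1p forms
    nll <- sum(log1p(exp(-abs(x))) + pmax(x, 0) - lam * x)
    nll + 0.5 * crossprod(phi - v, Linv %*% (phi - v)) -
      sum(log(phi)) / t
  }
  phi <- pmax(state$nu[n, ], 1e-3)
  for (t in barrier_schedule) {
    for (it in 1:50) {
      x <- phi[1] * Ik - phi[2]
      f <- stats::plogis(x)
      g_lik <- c(-sum((lam - f) * Ik), sum(lam - f))
      grad <- g_lik + as.numeric(Linv %*% (phi - v)) - 1 / (t * phi)
      wgt <- f * (1 - f)
      H <- rbind(c(sum(wgt * Ik^2), -sum(wgt * Ik)),
                 c(-sum(wgt * Ik), sum(wgt))) + Linv +
        diag(1 / (t * phi^2))
      step <- tryCatch(solve(H, grad), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        warning("regularizing non-PD Hessian in power-curve update")
        H <- H + diag(2, 2) * max(abs(H))
        step <- solve(H, grad)
      }
      f0 <- objective(phi, t)
      kappa <- 1
      repeat {
        cand <- phi - kappa * step
        if (all(cand > 0) && objective(cand, t) <= f0 - 1e-4 * kappa *
              sum(grad * step)) break
        kappa <- kappa / 2
        if (kappa < 1e-8) { cand <- phi; break }
      }
      moved <- sqrt(sum((cand - phi)^2))
      phi <- cand
      if (moved < 1e-8) break
    }
  }
  x <- phi[1] * Ik - phi[2]
  wgt <- stats::plogis(x) * (1 - stats::plogis(x))
  t_last <- barrier_schedule[length(barrier_schedule)]
  H <- rbind(c(sum(wgt * Ik^2), -sum(wgt * Ik)),
             c(-sum(wgt * Ik), sum(wgt))) + Linv + diag(1 / (t_last * phi^2))
  Sig <- tryCatch(solve(H), error = function(e) diag(1e-4, 2))
  state$nu[n, ] <- phi
  state$Sigma[n, , ] <- (Sig + t(Sig)) / 2
  state
}

#' Conjugate update of the noise-precision posterior
#'
#' \eqn{\theta_{sh} = t_{sh} + K/2};
#' \eqn{\theta_{ra} = t_{ra} + \frac12 \sum_k E_q[(y_k - w's_{:,k})^2]},
#' with the expectation evaluated analytically from
#' \eqn{E[w w'] = \Omega + \mu\mu'} and the Bernoulli moments of s.
#'
#' @param state a \code{caviar_state}.
#' @param y observation vector.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return The state with updated \code{theta_sh}, \code{theta_ra}.
#' @export
update_noise <- function(state, y, hyper = caviar_hyper()) {
  L <- state$lambda
  K <- ncol(L)
  Q <- state$Omega + tcrossprod(state$mu)
  a <- diag(Q)
  quad <- colSums(L * (Q %*% L)) + as.numeric(a %*% (L * (1 - L)))
  e2 <- y^2 - 2 * y * state$pred + quad
  state$theta_sh <- hyper$t_sh + K / 2
  state$theta_ra <- hyper$t_ra + 0.5 * sum(e2)
  state
}

#' Soft-threshold function for spontaneous-current estimation
#'
#' \eqn{S(e, \gamma) = 0} if \eqn{e \le \gamma}, else \eqn{e - \gamma}.
#'
#' @param e non-negative rectified residuals.
#' @param gamma threshold penalty.
#' @return Thresholded values.
#' @export
soft_threshold <- function(e, gamma) pmax(e - gamma, 0)

#' Update the spontaneous-current estimates
#'
#' Soft-thresholds the positively rectified residuals
#' \eqn{e_k = [y_k - \mu'\lambda_{:,k}]_+}, shrinking the penalty until the
#' residual norm is at most \code{eps_spont} of the observation norm. Trials
#' whose total inferred spike probability exceeds \code{theta_orthog} (the
#' approximate-orthogonality constraint) or that are masked carry no
#' spontaneous current. The spontaneous-detection rate \code{lambda_spont}
#' is the per-trial rate of detected events, \code{mean(z > 0)}. Note that z
#' absorbs any unexplained positive residual — real spontaneous PSCs and
#' residual demixing error alike — which is exactly the set of confounders
#' the adaptive plausibility threshold must guard against.
#'
#' @param state a \code{caviar_state}.
#' @param y observation vector.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return The state with updated \code{z} and \code{lambda_spont}.
#' @export
update_spont <- function(state, y, hyper = caviar_hyper()) {
  K <- length(y)
  e <- pmax(y - state$pred, 0)
  allowed <- colSums(state$lambda) <= hyper$theta_orthog & state$mask
  e[!allowed] <- 0
  denom <- sum(y^2)
  gamma <- max(e)
  z <- numeric(K)
  if (gamma > 0 && denom > 0) {
    repeat {
      z <- soft_threshold(e, gamma)
      ratio <- sum((y - state$pred - z)^2) / denom
      if (ratio <= hyper$eps_spont || gamma < 1e-10) break
      gamma <- gamma * 0.9
    }
  }
  state$z <- z
  state$lambda_spont <- mean(z > 0)
  state
}

#' Fit the CAVIaR model
#'
#' Runs the full coordinate-ascent loop on a mapping experiment: trial
#' masking, then outer iterations of \{weight block update, noise update,
#' per-neuron spike updates in randomized order with the isotonic
#' plausibility rule applied immediately after each neuron (after
#' \code{warmup} iterations), power-curve Laplace updates, spontaneous
#' update (also after warmup)\}, until the weight posterior mean
#' stabilizes or \code{max_iter}
#' is reached. Neurons failing the plausibility rule are removed from
#' subsequent sweeps; the post hoc scan (\code{\link{false_negative_scan}})
#' can later revisit them.
#'
#' @param y numeric vector of K observed responses (demixed PSC charges,
#'   pA ms).
#' @param design a \code{\link{stim_design}}.
#' @param traces optional K x T matrix of demixed traces (used for trial
#'   masking; omit to disable masking).
#' @param hyper a \code{\link{caviar_hyper}}.
#' @param seed optional integer seed (spike-update sampling and neuron
#'   ordering).
#' @return An object of class \code{caviar_fit}: the final state plus
#'   \code{weights} (posterior means, zero for unconnected), \code{connected},
#'   \code{power_curves}, \code{converged}, \code{n_iter}.
#' @examples
#' cfg <- sim_config(n_neurons = 40, ensemble_size = 5)
#' tr <- sample_ground_truth(cfg, seed = 1)
#' d <- design_stimulus(40, n_sweeps = 40, ensemble_size = 5, seed = 2)
#' rec <- simulate_trialwise(tr, d, seed = 3)
#' y <- integrate_charge(rec$traces)
#' fit <- caviar_fit(y, d, hyper = caviar_hyper(use_masking = FALSE),
#'                   seed = 4)
#' compare_maps(tr$weights, fit$weights)
#' @export
caviar_fit <- function(y, design, traces = NULL, hyper = caviar_hyper(),
                       seed = NULL) {
  with_seed(seed, {
    I <- design$powers
    N <- nrow(I); K <- ncol(I)
    stop_if(length(y) != K, "length(y) must match the design")
    st <- init_state(design, y, hyper)
    if (!is.null(traces) && hyper$use_masking) {
      st$mask <- mask_trials(traces, hyper$tau_min, hyper$tau_floor)
      st$lambda[, !st$mask] <- 0
      st$pred <- as.numeric(crossprod(st$lambda, st$mu))
    }
    pset <- design$power_set
    converged <- FALSE
    it <- 0
    while (it < hyper$max_iter) {
      it <- it + 1
      mu_old <- st$mu
      st <- update_weights(st, y, hyper)
      st <- update_noise(st, y, hyper)
      order_n <- sample(which(st$connected))
      for (n in order_n) {
        st <- update_spikes(st, n, y, design, hyper)
        if (hyper$use_plausibility && it > hyper$warmup) {
          curve <- isotonic_power_curve(st$lambda[n, ], I[n, ], pset,
                                        st$mask, warn = FALSE)
          st <- apply_plausibility(st, n, curve, hyper)
        }
      }
      for (n in which(st$connected)) {
        st <- update_phi(st, n, design, hyper)
      }
      if (hyper$use_spont && it > hyper$warmup) {
        st <- update_spont(st, y, hyper)
      }
      dmu <- max(abs(st$mu - mu_old))
      if (it > hyper$warmup + 1 &&
            dmu <= hyper$tol * max(max(abs(st$mu)), 1e-12)) {
        converged <- TRUE
        break
      }
    }
    st <- update_weights(st, y, hyper)  # final weights on final spikes
    curves <- lapply(seq_len(N), function(n)
      isotonic_power_curve(st$lambda[n, ], I[n, ], pset, st$mask,
                           warn = FALSE))
    w <- st$mu
    w[!st$connected] <- 0
    structure(c(st, list(weights = w, power_curves = curves,
                         converged = converged, n_iter = it,
                         design = design, y = y, hyper = hyper)),
              class = "caviar_fit")
  })
}

#' @export
print.caviar_fit <- function(x, ...) {
  cat(sprintf(
    "CAVIaR fit: %d/%d neurons connected, %d trials (%d masked), %s after %d iterations\n",
    sum(x$connected), length(x$mu), length(x$y), sum(!x$mask),
    if (x$converged) "converged" else "not converged", x$n_iter))
  cat(sprintf("  posterior noise s.d. %.3g, spontaneous rate %.3g/trial\n",
              sqrt(x$theta_ra / x$theta_sh), x$lambda_spont))
  invisible(x)
}

#' Integrate demixed traces into charge measurements
#'
#' Collapses each trace into a single number by its discrete-time integral
#' (sum times the sample interval, 0.05 ms): the total synaptic charge
#' transfer of the trial in pA ms.
#'
#' @param traces a numeric vector (one trace) or a K x T matrix.
#' @param dt sample interval in ms.
#' @return Numeric scalar or vector of charges.
#' @export
integrate_charge <- function(traces, dt = .DT_MS) {
  if (is.matrix(traces)) rowSums(traces) * dt else sum(traces) * dt
}
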