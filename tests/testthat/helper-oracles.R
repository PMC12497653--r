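# Independent oracles used by the unit and acceptance tests.

# Exact weighted isotonic least squares by exhaustive search over consecutive
# block partitions: the isotonic LS solution is piecewise constant on
# consecutive blocks with non-decreasing weighted block means, so enumerating
# all 2^(n-1) partitions and keeping the best feasible one is exact.
brute_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 1) return(y)
  best <- NULL
  best_sse <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Conjugate Bayesian linear regression posterior for fixed binary design:
# the analytic form the weight block update must reduce to.
conjugate_regression <- function(y, X, sigma2, u, b2) {
  N <- nrow(X)
  Omega <- solve(tcrossprod(X) / sigma2 + diag(1 / b2, N))
  mu <- Omega %*% (X %*% y / sigma2 + u / b2)
  list(mu = as.numeric(mu), Omega = Omega)
}

r2_score <- function(truth, est) {
  1 - sum((truth - est)^2) / sum((truth - mean(truth))^2)
}

# small deterministic circuit used by several fit-level tests: strong
# connections only, near-deterministic spiking, clean trial-wise traces
make_clean_toy <- function(n_neurons = 20, n_conn = 4, n_sweeps = 30,
                           ensemble = 1, seed = 1) {
  cfg <- sim_config(n_neurons = n_neurons, connect_rate = n_conn / n_neurons,
                    frac_strong = 1,
                    w_strong_min = 400, w_strong_max = 1200,
                    phi0_min = 0.5, phi0_max = 0.6,  # spike prob ~ 1
                    phi1_min = 3, phi1_max = 3.5,
                    sigma_mult = 0,
                    kinetics = list(tau_r_min = 0.3, tau_r_max = 0.4,
                                    tau_diff_min = 2, tau_diff_max = 2.2),
                    latency_min = 1.5, latency_alpha = 900,
                    ensemble_size = ensemble,
                    noise = noise_config(gp_scale = 1e-6, noise_var = 1e-6,
                                         spont_rate = 0))
  truth <- sample_ground_truth(cfg, seed = seed)
  design <- design_stimulus(n_neurons, n_sweeps, ensemble, cfg$powers,
                            stim_rate = 10, seed = seed + 1)
  rec <- simulate_trialwise(truth, design, cfg$noise, seed = seed + 2)
  list(cfg = cfg, truth = truth, design = design, rec = rec,
       y = integrate_charge(rec$traces))
}
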