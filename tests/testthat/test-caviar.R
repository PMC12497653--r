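toy_design <- function(N = 2, K = 3, power = 45) {
  I <- matrix(power, N, K)
  structure(list(powers = I, power_set = power,
                 holograms = list(seq_len(N)),
                 trial_hologram = rep(1L, K), sweep = rep(1L, K),
                 stim_rate = 30), class = "stim_design")
}

test_that("state initialization follows the prior and respects targeting", {
  d <- toy_design(N = 2, K = 3)
  d$powers[1, 2] <- 0
  hy <- caviar_hyper(b2 = 100)
  st <- init_state(d, y = c(10, 20, 30), hyper = hy)
  expect_equal(dim(st$lambda), c(2, 3))
  expect_equal(st$lambda[1, 2], 0)            # untargeted -> 0
  expect_equal(st$mu, rep(hy$u, 2))
  expect_equal(st$Omega, diag(100, 2))
  expect_true(all(st$z == 0))
  # prior giving f = 1/2 at the used power initializes lambda at 1/2
  hy2 <- caviar_hyper(phi_mean = c(0.1, 4.5))  # 0.1*45 - 4.5 = 0
  st2 <- init_state(toy_design(power = 45), c(1, 1, 1), hy2)
  expect_true(all(st2$lambda == 0.5))
  expect_error(init_state(d, y = c(1, 2)), "number of trials")
})

test_that("weight update reduces to the prior with no inferred spikes", {
  d <- toy_design(N = 3, K = 5)
  hy <- caviar_hyper(u = 2, b2 = 50)
  st <- init_state(d, rnorm(5), hy)
  st$lambda[] <- 0
  st <- update_weights(st, rnorm(5), hy)
  expect_equal(st$mu, rep(2, 3))
  expect_equal(st$Omega, diag(50, 3))
})

test_that("weight update equals the conjugate-regression oracle for binary spikes", {
  set.seed(21)
  N <- 4; K <- 60
  X <- matrix(rbinom(N * K, 1, 0.4), N, K)
  w_true <- c(3, 0, -1, 2)
  sigma2 <- 0.25
  y <- as.numeric(crossprod(X, w_true)) + rnorm(K, sd = sqrt(sigma2))
  d <- toy_design(N = N, K = K)
  hy <- caviar_hyper(u = 0.5, b2 = 10)
  st <- init_state(d, y, hy)
  st$lambda <- X                       # fixed binary spike posteriors
  st$theta_sh <- 1; st$theta_ra <- sigma2   # precision expectation 1/sigma2
  st <- update_weights(st, y, hy)
  oracle <- conjugate_regression(y, X, sigma2, u = 0.5, b2 = 10)
  expect_equal(st$mu, oracle$mu, tolerance = 1e-10)
  expect_equal(st$Omega, oracle$Omega, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("spike update leaves untargeted trials and respects the prior", {
  d <- toy_design(N = 2, K = 4, power = 45)
  d$powers[1, 3] <- 0
  hy <- caviar_hyper(phi_mean = c(0.1, 4.5), mc_samples = 50)
  st <- init_state(d, rep(0, 4), hy)
  # make the phi posterior effectively deterministic at the prior mean
  st$Sigma[, 1, 1] <- 1e-18
  st$Sigma[, 2, 2] <- 1e-18
  st$mu[] <- 0
  st$Omega[] <- 0
  st <- update_spikes(st, 1, y = rep(0, 4), d, hy)
  expect_equal(st$lambda[1, 3], 0)
  # mu = 0 and f(0) = 1/2: likelihood term vanishes, lambda stays 1/2
  expect_equal(st$lambda[1, c(1, 2, 4)], rep(0.5, 3), tolerance = 1e-6)
})

test_that("spike-update logits match the quadrature oracle at large M", {
  set.seed(22)
  N <- 2; K <- 4
  d <- toy_design(N = N, K = K)
  d$powers[, ] <- c(30, 45, 60, 45, 30, 60, 45, 30)
  y <- c(150, -20, 300, 80)
  hy <- caviar_hyper(mc_samples = 200000)
  st <- init_state(d, y, hy)
  st$nu[1, ] <- c(0.08, 3); st$nu[2, ] <- c(0.12, 5)
  st$Sigma[, 1, 1] <- 0.03^2
  st$Sigma[, 2, 2] <- 0.8^2
  st$mu <- c(120, 40)
  st$Omega <- diag(c(30, 10))
  st$theta_sh <- 1; st$theta_ra <- 80^2
  st$pred <- as.numeric(crossprod(st$lambda, st$mu))
  n <- 1
  ks <- 1:K
  # oracle: E[ln(f/(1-f))] = E[phi0] I - E[phi1] with exact truncated-normal
  # means (logit of the logistic sigmoid is its argument)
  m0 <- holomap:::etruncnorm_pos(st$nu[n, 1], 0.03)
  m1 <- holomap:::etruncnorm_pos(st$nu[n, 2], 0.8)
  prec <- st$theta_sh / st$theta_ra
  resid <- y - (st$pred - st$mu[n] * st$lambda[n, ])
  logit_oracle <- m0 * d$powers[n, ] - m1 +
    prec * (st$mu[n] * resid - (st$mu[n]^2 + st$Omega[n, n]) / 2)
  st2 <- update_spikes(st, n, y, d, hy)
  logit_mc <- qlogis(st2$lambda[n, ])
  # MC standard error of the expectation term
  se <- sqrt(0.03^2 * max(d$powers[n, ])^2 + 0.8^2) / sqrt(hy$mc_samples)
  expect_lt(max(abs(logit_mc - logit_oracle)), 4 * se + 1e-6)
})

test_that("power curves pool by PAVA and flag unused powers", {
  pc <- isotonic_power_curve(c(0.1, 0.5, 0.9), c(30, 45, 60),
                             power_set = c(30, 45, 60))
  expect_equal(pc$fitted, c(0.1, 0.5, 0.9))
  pc2 <- isotonic_power_curve(c(0.6, 0.6, 0.2, 0.2), c(30, 30, 60, 60),
                              power_set = c(30, 60))
  expect_equal(pc2$fitted, c(0.4, 0.4))
  expect_warning(
    pc3 <- isotonic_power_curve(c(0.5, 0.5), c(30, 30),
                                power_set = c(30, 60)),
    "never used")
  expect_true(is.na(pc3$fitted[2]))
  expect_equal(holomap:::curve_at_max(pc3), 0.5)
})

test_that("the plausibility rule disconnects below the adjusted threshold", {
  d <- toy_design(N = 2, K = 6, power = 60)
  hy <- caviar_hyper(theta_pava = 0.4)
  st <- init_state(d, rnorm(6), hy)
  st$mu <- c(100, 50)
  st$pred <- as.numeric(crossprod(st$lambda, st$mu))
  mk_curve <- function(v) structure(
    list(power = 60, lambda_bar = v, fitted = v, counts = 6),
    class = "power_curve")
  # 0.9 >= 0.4: retained
  st1 <- apply_plausibility(st, 1, mk_curve(0.9), hy)
  expect_true(st1$connected[1])
  # 0.35 < 0.4: disconnected, weights and spikes zeroed
  st2 <- apply_plausibility(st, 1, mk_curve(0.35), hy)
  expect_false(st2$connected[1])
  expect_equal(st2$mu[1], 0)
  expect_true(all(st2$lambda[1, ] == 0))
  # adjusted threshold: 0.45 < 0.4 + lambda_spont(0.1)
  st$lambda_spont <- 0.1
  st3 <- apply_plausibility(st, 1, mk_curve(0.45), hy)
  expect_false(st3$connected[1])
})

test_that("trial masking separates white noise from PSC waveforms", {
  set.seed(23)
  noise <- matrix(rnorm(20 * 900, sd = 3), 20)
  psc <- t(replicate(20, {
    k <- holomap:::unit_kernel(1, 10)
    x <- numeric(900)
    x[200 + seq_along(k)[1:600]] <- 500 * k[1:600]
    x + rnorm(900, sd = 1)
  }))
  msk <- mask_trials(rbind(noise, psc), tau_min = 0.5, noise_floor = 2)
  expect_true(all(!msk[1:20]))   # white noise masked
  expect_true(all(msk[21:40]))   # smooth PSCs retained
  # near-zero smooth residuals are shrunk below threshold by the floor
  tiny <- matrix(sin(seq(0, 20, length.out = 900)) * 0.5, 1)
  expect_false(mask_trials(tiny, 0.5, noise_floor = 2))
})

test_that("power-curve coefficient updates find the penalized mode", {
  d <- toy_design(N = 1, K = 90)
  d$powers[1, ] <- rep(c(30, 45, 60), each = 30)
  hy <- caviar_hyper(phi_mean = c(0.1, 4), phi_cov = diag(c(0.01, 1)))
  st <- init_state(d, rnorm(90), hy)
  truef <- plogis(0.15 * d$powers[1, ] - 5)
  st$lambda[1, ] <- truef
  st <- update_phi(st, 1, d, hy)
  nu <- st$nu[1, ]
  expect_true(all(nu > 0))
  # grid-search oracle over the positive quadrant
  obj <- function(p0, p1, t = 1000) {
    x <- p0 * d$powers[1, ] - p1
    f <- plogis(x)
    -sum(st$lambda[1, ] * log(f) + (1 - st$lambda[1, ]) * log(1 - f)) +
      0.5 * ((p0 - 0.1)^2 / 0.01 + (p1 - 4)^2 / 1) -
      (log(p0) + log(p1)) / t
  }
  grid0 <- seq(0.02, 0.3, by = 0.004)
  grid1 <- seq(0.5, 8, by = 0.1)
  vals <- outer(grid0, grid1, Vectorize(obj))
  best <- arrayInd(which.min(vals), dim(vals))
  expect_lt(abs(nu[1] - grid0[best[1]]), 0.008)
  expect_lt(abs(nu[2] - grid1[best[2]]), 0.2)
  # stationarity certificate: numerical gradient near zero at the mode
  eps <- 1e-6
  g0 <- (obj(nu[1] + eps, nu[2]) - obj(nu[1] - eps, nu[2])) / (2 * eps)
  g1 <- (obj(nu[1], nu[2] + eps) - obj(nu[1], nu[2] - eps)) / (2 * eps)
  expect_lt(abs(g0) + abs(g1), 1e-2)
  # a dominant prior pins the mode at the prior mean
  hy2 <- caviar_hyper(phi_mean = c(0.1, 4),
                      phi_cov = diag(c(1e-8, 1e-8)))
  st2 <- init_state(d, rnorm(90), hy2)
  st2$lambda[1, ] <- 0.9
  st2 <- update_phi(st2, 1, d, hy2)
  expect_equal(st2$nu[1, ], c(0.1, 4), tolerance = 1e-3)
})

test_that("noise update matches analytic residual moments", {
  d <- toy_design(N = 2, K = 4)
  hy <- caviar_hyper(t_sh = 0.01, t_ra = 0.01)
  y <- c(3, -1, 2, 0.5)
  st <- init_state(d, y, hy)
  # no spikes, zero weights: residual is y itself
  st$lambda[] <- 0; st$mu[] <- 0; st$Omega[] <- 0
  st$pred[] <- 0
  st <- update_noise(st, y, hy)
  expect_equal(st$theta_sh, 0.01 + 2)
  expect_equal(st$theta_ra, 0.01 + 0.5 * sum(y^2))
  # perfect fit with binary spikes and no weight uncertainty
  st$lambda <- matrix(c(1, 0, 1, 0, 0, 1, 1, 0), 2, 4)
  st$mu <- c(2, 1)
  st$Omega <- matrix(0, 2, 2)
  st$pred <- as.numeric(crossprod(st$lambda, st$mu))
  yfit <- st$pred
  st <- update_noise(st, yfit, hy)
  expect_equal(st$theta_ra, 0.01, tolerance = 1e-12)
})

test_that("analytic residual expectation agrees with Monte Carlo", {
  set.seed(24)
  N <- 3; K <- 5
  d <- toy_design(N = N, K = K)
  hy <- caviar_hyper(t_sh = 1e-9, t_ra = 1e-9)
  y <- rnorm(K, 2)
  st <- init_state(d, y, hy)
  st$lambda <- matrix(runif(N * K), N, K)
  st$mu <- rnorm(N)
  A <- matrix(rnorm(9), 3); st$Omega <- crossprod(A) / 3
  st$pred <- as.numeric(crossprod(st$lambda, st$mu))
  st <- update_noise(st, y, hy)
  analytic <- 2 * (st$theta_ra - hy$t_ra)
  R <- 200000
  L <- chol(st$Omega)
  mc <- numeric(R)
  W <- matrix(rnorm(R * N), R) %*% L
  W <- sweep(W, 2, st$mu, "+")
  S <- matrix(rbinom(R * N * K, 1, rep(as.numeric(st$lambda), each = R)),
              R)  # R x (N*K), column-major over (n, k)
  tot <- 0
  for (k in seq_len(K)) {
    Sk <- S[, (k - 1) * N + seq_len(N)]
    tot <- tot + (y[k] - rowSums(W * Sk))^2
  }
  mc_mean <- mean(tot)
  mc_se <- sd(tot) / sqrt(R)
  expect_lt(abs(analytic - mc_mean), 4 * mc_se)
})

test_that("soft thresholding and the shrink loop follow the residual rule", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(2, 1), 1)
  d <- toy_design(N = 2, K = 5)
  hy <- caviar_hyper(eps_spont = 0.05, theta_orthog = 0.2)
  y <- c(0.1, 5, 0.2, 8, 0.1)
  st <- init_state(d, y, hy)
  st$lambda[] <- 0.01    # spikes explain nothing; orthogonality satisfied
  st$mu[] <- 0
  st$pred[] <- 0
  st <- update_spont(st, y, hy)
  # grid oracle: largest gamma in [0, max(e)] meeting the residual bound
  e <- pmax(y, 0)
  ratio <- function(g) sum((y - soft_threshold(e, g))^2) / sum(y^2)
  grid <- seq(0, max(e), length.out = 20000)
  g_star <- max(grid[vapply(grid, ratio, numeric(1)) <= 0.05])
  g_loop <- max(e) * 0.9^(ceiling(log(g_star / max(e)) / log(0.9)))
  expect_equal(st$z, soft_threshold(e, g_loop), tolerance = 1e-8)
  expect_lte(ratio(max(e[st$z > 0] - st$z[st$z > 0])), 0.05 + 1e-9)
  expect_equal(st$lambda_spont, mean(st$z > 0))
  # perfectly explained data leaves no spontaneous current
  st2 <- init_state(d, y, hy)
  st2$lambda[] <- 0.01
  st2$mu[] <- 0
  st2$pred <- y
  st2 <- update_spont(st2, y, hy)
  expect_true(all(st2$z == 0))
  expect_equal(st2$lambda_spont, 0)
  # trials with confident spikes cannot carry spontaneous current
  st3 <- init_state(d, y, hy)
  st3$lambda[, 2] <- 0.9
  st3$mu[] <- 0; st3$pred[] <- 0
  st3 <- update_spont(st3, y, hy)
  expect_equal(st3$z[2], 0)
})

test_that("the full fit recovers a clean single-target circuit", {
  toy <- make_clean_toy(n_neurons = 20, n_conn = 4, n_sweeps = 15,
                        ensemble = 1, seed = 40)
  fit <- caviar_fit(toy$y, toy$design,
                    hyper = caviar_hyper(use_masking = FALSE), seed = 41)
  expect_true(fit$converged)
  expect_equal(which(fit$weights > 0), which(toy$truth$weights > 0))
  conn <- toy$truth$weights > 0
  expect_lt(max(abs(fit$weights[conn] - toy$truth$weights[conn]) /
                  toy$truth$weights[conn]), 0.01)
})

test_that("all-zero observations leave no neuron connected", {
  d <- design_stimulus(15, n_sweeps = 12, ensemble_size = 3, seed = 42)
  y <- numeric(ncol(d$powers))
  fit <- caviar_fit(y, d, hyper = caviar_hyper(use_masking = FALSE),
                    seed = 43)
  expect_equal(sum(fit$connected), 0)
  expect_true(all(fit$weights == 0))
})

test_that("every update preserves the variational-state invariants", {
  toy <- make_clean_toy(n_neurons = 12, n_conn = 3, n_sweeps = 10,
                        ensemble = 3, seed = 44)
  fit <- caviar_fit(toy$y, toy$design,
                    hyper = caviar_hyper(use_masking = FALSE), seed = 45)
  expect_true(all(fit$lambda >= 0 & fit$lambda <= 1))
  expect_true(all(fit$lambda[toy$design$powers == 0] == 0))
  ev <- eigen(fit$Omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(all(fit$nu > 0))
  expect_true(all(fit$z >= 0))
  expect_true(all(fit$mu[!fit$connected] == 0))
  expect_gt(fit$theta_ra, 0)
})

test_that("weight updates commute with neuron relabeling", {
  toy <- make_clean_toy(n_neurons = 10, n_conn = 3, n_sweeps = 8,
                        ensemble = 2, seed = 46)
  hy <- caviar_hyper(b2 = 1e4)
  st <- init_state(toy$design, toy$y, hy)
  st$lambda <- matrix(runif(length(st$lambda)), nrow(st$lambda))
  st$lambda[toy$design$powers == 0] <- 0
  st1 <- update_weights(st, toy$y, hy)
  perm <- sample(10)
  stp <- st
  stp$lambda <- st$lambda[perm, ]
  stp$mu <- st$mu[perm]
  stp$connected <- st$connected[perm]
  stp$Omega <- st$Omega[perm, perm]
  st2 <- update_weights(stp, toy$y, hy)
  expect_equal(st2$mu, st1$mu[perm], tolerance = 1e-10)
  expect_equal(st2$Omega, st1$Omega[perm, perm], tolerance = 1e-10)
})
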