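test_that("ground-truth sampling gives the specified circuit composition", {
  cfg <- sim_config(n_neurons = 100, connect_rate = 0.1)
  tr <- sample_ground_truth(cfg, seed = 1)
  expect_equal(sum(tr$weights > 0), 10)
  expect_equal(sum(tr$strong), 2)
  expect_equal(sum(tr$connected & !tr$strong), 8)
  expect_true(all(tr$weights[tr$connected & !tr$strong] >= cfg$w_weak_min))
  expect_true(all(tr$weights[!tr$connected] == 0))
  expect_true(all(tr$phi > 0))
  expect_true(all(tr$tau_d > tr$tau_r))
})

test_that("degenerate strong-weight bounds give equal strong weights", {
  cfg <- sim_config(n_neurons = 50, connect_rate = 0.2,
                    w_strong_min = 700, w_strong_max = 700)
  tr <- sample_ground_truth(cfg, seed = 2)
  expect_true(all(tr$weights[tr$strong] == 700))
})

test_that("weak weights follow the shifted-exponential mean", {
  # E[w_weak] = shift + mean parameter; check Monte-Carlo mean within 3 s.e.
  cfg <- sim_config(n_neurons = 4000, connect_rate = 0.5, frac_strong = 0,
                    w_weak_min = 50, w_weak_mean = 150)
  tr <- sample_ground_truth(cfg, seed = 3)
  wk <- tr$weights[tr$connected & !tr$strong]
  se <- 150 / sqrt(length(wk))
  expect_lt(abs(mean(wk) - 200), 3 * se)
})

test_that("invalid circuit configurations are rejected", {
  expect_error(sim_config(n_neurons = 5, connect_rate = 0.1),
               "at least 1")
  expect_error(sim_config(w_strong_min = 100, w_strong_max = 50),
               "weight bounds")
  expect_error(sim_config(phi0_min = -1), "phi bounds")
})

test_that("ensemble designs stimulate every target once per sweep", {
  d <- design_stimulus(100, n_sweeps = 5, ensemble_size = 10, seed = 4)
  expect_equal(ncol(d$powers), 50)
  expect_true(all(colSums(d$powers > 0) == 10))
  for (s in 1:5) {
    ks <- which(d$sweep == s)
    hit <- rowSums(d$powers[, ks, drop = FALSE] > 0)
    expect_true(all(hit == 1))  # each target exactly once per sweep
  }
  expect_true(all(d$powers[d$powers > 0] %in% d$power_set))
})

test_that("single-target and remainder designs are well formed", {
  d1 <- design_stimulus(20, n_sweeps = 2, ensemble_size = 1, seed = 5)
  expect_true(all(colSums(d1$powers > 0) == 1))
  # R does not divide N: last hologram of each sweep takes the remainder
  d2 <- design_stimulus(25, n_sweeps = 3, ensemble_size = 10, seed = 6)
  sizes <- colSums(d2$powers > 0)
  expect_true(all(sort(unique(sizes)) == c(5, 10)))
  for (s in 1:3) {
    expect_equal(sum(sizes[d2$sweep == s]), 25)
  }
  expect_error(design_stimulus(5, 1, ensemble_size = 10), "exceed")
})

test_that("per-trial inclusion probability converges to R/N", {
  d <- design_stimulus(300, n_sweeps = 100, ensemble_size = 10, seed = 7)
  K <- ncol(d$powers)
  frac <- mean(d$powers[17, ] > 0)  # a fixed neuron
  p <- 10 / 300
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / K) + 1e-9)
})

test_that("expected revisit interval follows N/(R f)", {
  expect_equal(expected_revisit_interval(1000, 20, 50), 1.0)
  expect_equal(expected_revisit_interval(100, 10, 10), 1.0)
  expect_equal(expected_revisit_interval(60, 60, 8), 1 / 8)
  expect_error(expected_revisit_interval(10, 20, 5))
})

test_that("spikes occur only on targeted trials with sigmoidal probability", {
  cfg <- sim_config(n_neurons = 40)
  tr <- sample_ground_truth(cfg, seed = 8)
  d <- design_stimulus(40, n_sweeps = 30, ensemble_size = 8, seed = 9)
  sl <- sample_spikes_and_latencies(tr, d, seed = 10)
  expect_true(all(sl$spikes[d$powers == 0] == 0))
  expect_true(all(sl$spikes %in% c(0L, 1L)))
  expect_true(all(sl$latency[sl$spikes == 1] > tr$latency_min))
  # sigmoid argument 0 -> spike probability 1/2
  tr2 <- tr
  tr2$phi[, 1] <- 0.1
  tr2$phi[, 2] <- 0.1 * 45  # phi0 * I - phi1 = 0 at I = 45
  d45 <- d
  d45$powers[d45$powers > 0] <- 45
  sl2 <- sample_spikes_and_latencies(tr2, d45, seed = 11)
  n_t <- sum(d45$powers > 0)
  expect_lt(abs(mean(sl2$spikes[d45$powers > 0]) - 0.5),
            3 * 0.5 / sqrt(n_t))
})

test_that("mean spike latency follows the inverse-square power law", {
  cfg <- sim_config(n_neurons = 2000, connect_rate = 0.5,
                    phi0_min = 1, phi0_max = 1, phi1_min = 1, phi1_max = 1)
  tr <- sample_ground_truth(cfg, seed = 12)
  for (pw in c(30, 60)) {
    d <- design_stimulus(2000, n_sweeps = 5, ensemble_size = 2000,
                         powers = pw, seed = 13)
    sl <- sample_spikes_and_latencies(tr, d, seed = 14)
    lat <- sl$latency[sl$spikes == 1]
    mean_expected <- tr$latency_min +
      tr$latency_alpha / (tr$latency_beta * pw^2)
    sd_expected <- sqrt(tr$latency_alpha / pw^2) / tr$latency_beta
    expect_lt(abs(mean(lat) - mean_expected),
              3 * sd_expected / sqrt(length(lat)))
  }
})

test_that("trial-wise simulation conserves charge and degenerates cleanly", {
  toy <- make_clean_toy(n_neurons = 10, n_conn = 2, n_sweeps = 6,
                        ensemble = 1, seed = 20)
  # silent circuit, silent noise -> identically zero traces
  tr0 <- toy$truth
  tr0$weights[] <- 0
  nz <- noise_config(spont_rate = 0)
  nz$gp_scale <- 1e-30; nz$noise_var <- 1e-30
  rec0 <- simulate_trialwise(tr0, toy$design, nz, seed = 21)
  expect_lt(max(abs(rec0$traces)), 1e-10)
  # sigma_mult = 0: every evoked PSC carries charge exactly w_n
  rec <- simulate_trialwise(toy$truth, toy$design, nz, seed = 22)
  sp <- rec$spikes
  for (k in seq_len(ncol(sp))) {
    expected <- sum(toy$truth$weights * sp[, k])
    if (expected > 0) {
      expect_equal(sum(rec$traces[k, ]) * 0.05, expected,
                   tolerance = 1e-4)
    }
  }
})

test_that("continuous windows overlap as dictated by the stimulation rate", {
  cfg <- sim_config(n_neurons = 30, stim_rate = 50)
  tr <- sample_ground_truth(cfg, seed = 23)
  d <- design_stimulus(30, n_sweeps = 10, ensemble_size = 5,
                       stim_rate = 50, seed = 24)
  rec <- simulate_continuous(tr, d, noise_config(spont_rate = 0),
                             seed = 25)
  # 20 kHz / 50 Hz = 400 samples between stimuli; 900-sample windows
  # therefore share 500 samples
  expect_true(all(diff(rec$stim_sample) == 400))
  expect_equal(ncol(rec$traces), 900)
  expect_error(simulate_continuous(tr, d, duration = 0.001),
               "too short")
})

test_that("AR coefficient near zero gives white continuous noise", {
  cfg <- sim_config(n_neurons = 10)
  tr <- sample_ground_truth(cfg, seed = 26)
  tr$weights[] <- 0
  d <- design_stimulus(10, n_sweeps = 5, ensemble_size = 2,
                       stim_rate = 10, seed = 27)
  nz <- noise_config(ar_coef = 1e-9, spont_rate = 0)
  rec <- simulate_continuous(tr, d, nz, seed = 28)
  x <- rec$continuous_trace
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.05)
})

test_that("trial-wise and continuous modes agree at low stimulation rates", {
  # non-overlapping windows, fast kernels, no noise: the distribution of
  # window charges should match across modes
  toy <- make_clean_toy(n_neurons = 15, n_conn = 3, n_sweeps = 40,
                        ensemble = 3, seed = 29)
  nz <- noise_config(spont_rate = 0)
  nz$gp_scale <- 1e-30; nz$noise_var <- 1e-30; nz$ar_noise_sd <- 0
  rec_t <- simulate_trialwise(toy$truth, toy$design, nz, seed = 30)
  rec_c <- simulate_continuous(toy$truth, toy$design, nz, seed = 31)
  y_t <- integrate_charge(rec_t$traces)
  y_c <- integrate_charge(rec_c$traces)
  se <- sqrt(var(y_t) / length(y_t) + var(y_c) / length(y_c))
  expect_lt(abs(mean(y_t) - mean(y_c)), 3 * se)
})

test_that("spontaneous events are logged consistently with their traces", {
  cfg <- sim_config(n_neurons = 10)
  tr <- sample_ground_truth(cfg, seed = 32)
  tr$weights[] <- 0
  d <- design_stimulus(10, n_sweeps = 40, ensemble_size = 2, seed = 33)
  nz <- noise_config(spont_rate = 20)
  nz$gp_scale <- 1e-30; nz$noise_var <- 1e-30
  rec <- simulate_trialwise(tr, d, nz, seed = 34)
  expect_false(is.null(rec$spont))
  # trials with a logged event have positive charge, others are silent
  has_ev <- seq_len(nrow(rec$traces)) %in% rec$spont$trial
  y <- integrate_charge(rec$traces)
  expect_true(all(abs(y[!has_ev]) < 1e-6))
  # per-trial event probability ~ rate * 45 ms
  p <- 20 * 0.045
  expect_lt(abs(mean(has_ev) - p),
            3 * sqrt(p * (1 - p) / length(has_ev)))
})
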