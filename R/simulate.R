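#' Noise configuration for simulated mapping experiments
#'
#' Trial-wise simulations corrupt each 45-ms window with a Gaussian-process
#' (GP) draw (radial-basis-function kernel) plus i.i.d. Gaussian noise;
#' continuous 20-kHz simulations use a first-order autoregressive (AR(1))
#' process, which scales to tens of minutes of recording. Spontaneous PSCs
#' occur as a Poisson process at \code{spont_rate} Hz with charges drawn from
#' a shifted exponential.
#'
#' @param gp_scale GP kernel variance scale (pA^2), trial-wise mode.
#' @param gp_lengthscale GP characteristic lengthscale (ms).
#' @param noise_var i.i.d. noise variance (pA^2), trial-wise mode.
#' @param ar_coef AR(1) coefficient in (0, 1), continuous mode.
#' @param ar_noise_sd AR(1) innovation s.d. (pA), continuous mode.
#' @param spont_rate spontaneous PSC rate (Hz), >= 0.
#' @param spont_charge_min,spont_charge_mean shift and mean parameters of the
#'   shifted-exponential spontaneous charge distribution (pA ms).
#' @return An object of class \code{noise_config}.
#' @export
noise_config <- function(gp_scale = 25, gp_lengthscale = 1, noise_var = 4,
                         ar_coef = 0.95, ar_noise_sd = 1,
                         spont_rate = 1,
                         spont_charge_min = 50, spont_charge_mean = 150) {
  stop_if(gp_scale <= 0 || gp_lengthscale <= 0 || noise_var <= 0,
          "GP scale, lengthscale and noise variance must be positive")
  stop_if(ar_coef <= 0 || ar_coef >= 1, "ar_coef must lie in (0, 1)")
  stop_if(spont_rate < 0, "spont_rate must be non-negative")
  structure(list(gp_scale = gp_scale, gp_lengthscale = gp_lengthscale,
                 noise_var = noise_var, ar_coef = ar_coef,
                 ar_noise_sd = ar_noise_sd, spont_rate = spont_rate,
                 spont_charge_min = spont_charge_min,
                 spont_charge_mean = spont_charge_mean),
            class = "noise_config")
}

#' Simulation configuration for circuit mapping experiments
#'
#' Defines the ground-truth circuit statistics and the stimulation protocol of
#' a simulated holographic mapping experiment. Defaults emulate mapping of
#' inhibitory (e.g. parvalbumin-positive) presynaptic candidates with a
#' fast soma-targeted opsin: connection density 0.1, of which 20\% are strong
#' (uniform charges) and 80\% weak (shifted-exponential charges); per-neuron
#' sigmoidal power curves with spike probability approaching 1 at the maximal
#' power for well-expressing cells; power-dependent spike latencies following
#' an inverse-square law (two-photon absorption); log-normal trial-to-trial
#' PSC amplitude jitter with median 1.
#'
#' @param n_neurons number of presynaptic candidates N.
#' @param connect_rate connection density alpha in (0, 1).
#' @param frac_strong fraction of connected neurons that are strong.
#' @param w_strong_min,w_strong_max bounds of the uniform strong-weight
#'   distribution (pA ms).
#' @param w_weak_min,w_weak_mean shift and mean parameters of the
#'   shifted-exponential weak-weight distribution (pA ms); the weak-weight
#'   expectation is \code{w_weak_min + w_weak_mean}.
#' @param phi0_min,phi0_max bounds for the power-curve slope phi0 (1/mW).
#' @param phi1_min,phi1_max bounds for the power-curve intercept phi1
#'   (rheobase-like offset).
#' @param kinetics \code{"inhibitory"} or \code{"excitatory"} PSC kinetics
#'   preset, or a list with \code{tau_r_min, tau_r_max, tau_diff_min,
#'   tau_diff_max} (ms).
#' @param latency_alpha,latency_beta,latency_min shifted-gamma latency-law
#'   parameters: latency ~ latency_min + Gamma(shape = latency_alpha / I^2,
#'   rate = latency_beta), so the mean latency is
#'   \code{latency_min + latency_alpha / (latency_beta * I^2)}.
#' @param sigma_mult s.d. of log amplitude (log-normal multiplicative noise,
#'   median 1).
#' @param powers discrete laser power set (mW).
#' @param ensemble_size targets per hologram R (1 = single-target mapping).
#' @param stim_rate stimulation rate f (Hz).
#' @param noise a \code{\link{noise_config}}.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_neurons = 300, connect_rate = 0.1, frac_strong = 0.2,
                       w_strong_min = 500, w_strong_max = 1500,
                       w_weak_min = 50, w_weak_mean = 150,
                       phi0_min = 0.10, phi0_max = 0.20,
                       phi1_min = 3, phi1_max = 6,
                       kinetics = "inhibitory",
                       latency_alpha = 3600, latency_beta = 1,
                       latency_min = 3,
                       sigma_mult = 0.2,
                       powers = c(30, 45, 60),
                       ensemble_size = 10, stim_rate = 30,
                       noise = noise_config()) {
  if (is.character(kinetics)) {
    kinetics <- switch(match.arg(kinetics, c("inhibitory", "excitatory")),
      inhibitory = list(tau_r_min = 0.5, tau_r_max = 2,
                        tau_diff_min = 6, tau_diff_max = 12),
      excitatory = list(tau_r_min = 0.3, tau_r_max = 1,
                        tau_diff_min = 3, tau_diff_max = 7))
  }
  stop_if(connect_rate <= 0 || connect_rate >= 1,
          "connect_rate must lie in (0, 1)")
  stop_if(connect_rate * n_neurons < 1,
          "connect_rate * n_neurons must be at least 1")
  stop_if(w_strong_max < w_strong_min || w_weak_min < 0 || w_weak_mean <= 0,
          "invalid weight bounds")
  stop_if(phi0_min <= 0 || phi1_min <= 0 || phi0_max < phi0_min ||
            phi1_max < phi1_min, "phi bounds must be positive and ordered")
  stop_if(any(powers <= 0), "powers must be positive")
  stop_if(ensemble_size < 1 || ensemble_size > n_neurons,
          "ensemble_size must lie in [1, n_neurons]")
  structure(list(n_neurons = n_neurons, connect_rate = connect_rate,
                 frac_strong = frac_strong,
                 w_strong_min = w_strong_min, w_strong_max = w_strong_max,
                 w_weak_min = w_weak_min, w_weak_mean = w_weak_mean,
                 phi0_min = phi0_min, phi0_max = phi0_max,
                 phi1_min = phi1_min, phi1_max = phi1_max,
                 kinetics = kinetics,
                 latency_alpha = latency_alpha, latency_beta = latency_beta,
                 latency_min = latency_min,
                 sigma_mult = sigma_mult,
                 powers = sort(powers), ensemble_size = ensemble_size,
                 stim_rate = stim_rate, noise = noise),
            class = "sim_config")
}

#' Sample a ground-truth circuit
#'
#' Draws synaptic weights (a small strongly connected subpopulation with
#' uniform charges; the rest weakly connected with shifted-exponential
#' charges; unconnected weights exactly zero), per-neuron power-curve
#' coefficients (uniform), and per-neuron PSC kinetics.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed optional integer seed.
#' @return An object of class \code{ground_truth} with elements
#'   \code{weights}, \code{connected}, \code{strong}, \code{phi} (N x 2),
#'   \code{tau_r}, \code{tau_d}, latency-law parameters and
#'   \code{sigma_mult}.
#' @export
sample_ground_truth <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    N <- config$n_neurons
    n_conn <- ceiling(config$connect_rate * N)
    n_strong <- round(config$frac_strong * n_conn)
    conn_idx <- sample.int(N, n_conn)
    strong_idx <- conn_idx[seq_len(n_strong)]
    weak_idx <- setdiff(conn_idx, strong_idx)
    w <- numeric(N)
    w[strong_idx] <- stats::runif(n_strong, config$w_strong_min,
                                  config$w_strong_max)
    w[weak_idx] <- config$w_weak_min +
      stats::rexp(length(weak_idx), rate = 1 / config$w_weak_mean)
    phi <- cbind(stats::runif(N, config$phi0_min, config$phi0_max),
                 stats::runif(N, config$phi1_min, config$phi1_max))
    colnames(phi) <- c("phi0", "phi1")
    kin <- config$kinetics
    tau_r <- stats::runif(N, kin$tau_r_min, kin$tau_r_max)
    tau_d <- tau_r + stats::runif(N, kin$tau_diff_min, kin$tau_diff_max)
    structure(list(weights = w,
                   connected = w > 0,
                   strong = seq_len(N) %in% strong_idx,
                   phi = phi, tau_r = tau_r, tau_d = tau_d,
                   latency_alpha = config$latency_alpha,
                   latency_beta = config$latency_beta,
                   latency_min = config$latency_min,
                   sigma_mult = config$sigma_mult),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d neurons, %d connected (%d strong / %d weak)\n",
              length(x$weights), sum(x$connected),
              sum(x$strong), sum(x$connected) - sum(x$strong)))
  invisible(x)
}

#' Randomized holographic stimulus design
#'
#' Builds the N x K matrix of per-neuron laser powers. In ensemble mode each
#' sweep randomly partitions all N targets into ensembles of size R (the last
#' hologram of a sweep takes any remainder), so every target is stimulated
#' exactly once per sweep; hologram order and per-trial powers are randomized.
#' With \code{ensemble_size = 1} this reduces to single-target mapping. Set
#' \code{n_partitions} to reuse a fixed collection of hologram partitions
#' (each sweep then draws from the pre-computed hologram sets, as required for
#' leave-one-hologram-out designs); by default a fresh random partition is
#' drawn every sweep.
#'
#' @param n_neurons number of candidate targets N.
#' @param n_sweeps number of sweeps (each sweep stimulates every target once).
#' @param ensemble_size targets per hologram R.
#' @param powers discrete power set (mW).
#' @param stim_rate stimulation rate f (Hz).
#' @param n_partitions if not \code{NULL}, the number of distinct random
#'   partitions to pre-compute and cycle over (sweep i uses partition
#'   \code{1 + (i-1) \%\% n_partitions}).
#' @param seed optional integer seed.
#' @return An object of class \code{stim_design}: \code{powers} (N x K
#'   matrix, 0 = untargeted), \code{power_set}, \code{holograms} (list of
#'   target-index vectors), \code{trial_hologram}, \code{sweep},
#'   \code{stim_rate}.
#' @export
design_stimulus <- function(n_neurons, n_sweeps, ensemble_size = 10,
                            powers = c(30, 45, 60), stim_rate = 30,
                            n_partitions = NULL, seed = NULL) {
  stop_if(ensemble_size > n_neurons, "ensemble_size R cannot exceed n_neurons")
  stop_if(ensemble_size < 1, "ensemble_size must be >= 1")
  with_seed(seed, {
    make_partition <- function() {
      perm <- sample.int(n_neurons)
      split(perm, ceiling(seq_along(perm) / ensemble_size))
    }
    partitions <- NULL
    if (!is.null(n_partitions)) {
      partitions <- lapply(seq_len(n_partitions), function(i) make_partition())
    }
    holograms <- list()
    holo_key <- character(0)
    trial_holo <- integer(0)
    sweep_id <- integer(0)
    for (s in seq_len(n_sweeps)) {
      part <- if (is.null(partitions)) make_partition() else
        partitions[[1 + (s - 1) %% length(partitions)]]
      part <- part[sample.int(length(part))]  # randomize hologram order
      for (h in part) {
        key <- paste(sort(h), collapse = ",")
        id <- match(key, holo_key)
        if (is.na(id)) {
          holograms[[length(holograms) + 1]] <- sort(h)
          holo_key <- c(holo_key, key)
          id <- length(holograms)
        }
        trial_holo <- c(trial_holo, id)
        sweep_id <- c(sweep_id, s)
      }
    }
    K <- length(trial_holo)
    I <- matrix(0, n_neurons, K)
    pw <- powers[sample.int(length(powers), K, replace = TRUE)]
    for (k in seq_len(K)) I[holograms[[trial_holo[k]]], k] <- pw[k]
    structure(list(powers = I, power_set = sort(unique(powers)),
                   holograms = holograms, trial_hologram = trial_holo,
                   sweep = sweep_id, stim_rate = stim_rate),
              class = "stim_design")
  })
}

#' @export
print.stim_design <- function(x, ...) {
  cat(sprintf(
    "Stimulus design: %d neurons, %d trials, %d holograms, powers {%s} mW, %g Hz\n",
    nrow(x$powers), ncol(x$powers), length(x$holograms),
    paste(x$power_set, collapse = ", "), x$stim_rate))
  invisible(x)
}

#' Expected revisit interval for ensemble stimulation
#'
#' Under uniformly random ensembles, any fixed neuron is included in a trial
#' with probability R/N, so on average N/R stimulations (N/(R f) seconds at
#' f Hz) elapse between revisits of the same neuron.
#'
#' @param n_neurons population size N.
#' @param ensemble_size ensemble size R (1 <= R <= N).
#' @param stim_rate stimulation rate f in Hz.
#' @return Expected revisit interval in seconds, N / (R f).
#' @export
expected_revisit_interval <- function(n_neurons, ensemble_size, stim_rate) {
  stop_if(ensemble_size < 1 || ensemble_size > n_neurons,
          "need 1 <= ensemble_size <= n_neurons")
  stop_if(stim_rate <= 0, "stim_rate must be positive")
  n_neurons / (ensemble_size * stim_rate)
}

#' Sample presynaptic spikes and spike latencies
#'
#' Spikes follow a linear-nonlinear-Bernoulli model: neuron n spikes on trial
#' k with probability \code{plogis(phi0_n * I_nk - phi1_n)} when targeted
#' (never when untargeted). Latencies (combined spike initiation and synaptic
#' transmission, ms after stimulus onset) follow a right-shifted gamma
#' distribution whose mean obeys an inverse-square dependence on laser power.
#'
#' @param truth a \code{\link{ground_truth}}.
#' @param design a \code{\link{stim_design}}.
#' @param seed optional integer seed.
#' @return List with \code{spikes} (N x K 0/1 matrix) and \code{latency}
#'   (N x K, ms; NA where no spike occurred).
#' @export
sample_spikes_and_latencies <- function(truth, design, seed = NULL) {
  with_seed(seed, {
    I <- design$powers
    N <- nrow(I); K <- ncol(I)
    s <- matrix(0L, N, K)
    lat <- matrix(NA_real_, N, K)
    targ <- which(I > 0)
    if (length(targ)) {
      n_idx <- ((targ - 1) %% N) + 1
      p <- stats::plogis(truth$phi[n_idx, 1] * I[targ] - truth$phi[n_idx, 2])
      sp <- stats::rbinom(length(targ), 1L, p)
      s[targ] <- sp
      fired <- targ[sp == 1L]
      if (length(fired)) {
        shape <- truth$latency_alpha / I[fired]^2
        lat[fired] <- truth$latency_min +
          stats::rgamma(length(fired), shape = shape,
                        rate = truth$latency_beta)
      }
    }
    list(spikes = s, latency = lat)
  })
}

# Sample a GP noise matrix (n_trials x len) from the RBF kernel; cholesky is
# computed once per call.
sample_gp_noise <- function(n_trials, len, scale, lengthscale, dt = .DT_MS) {
  t <- (seq_len(len) - 1) * dt
  K <- scale * exp(-outer(t, t, "-")^2 / (2 * lengthscale^2))
  diag(K) <- diag(K) + 1e-8 * scale
  L <- chol(K)
  matrix(stats::rnorm(n_trials * len), n_trials, len) %*% L
}

spont_charge <- function(n, noise) {
  noise$spont_charge_min +
    stats::rexp(n, rate = 1 / (noise$spont_charge_mean - 0))
}

rand_kinetics <- function(n, kin) {
  tau_r <- stats::runif(n, kin$tau_r_min, kin$tau_r_max)
  tau_d <- tau_r + stats::runif(n, kin$tau_diff_min, kin$tau_diff_max)
  cbind(tau_r, tau_d)
}

#' Simulate a trial-wise mapping experiment
#'
#' Generates K independent 45-ms windows. Each window sums the evoked PSCs of
#' spiking targeted neurons (unit-charge kernels scaled by weight and
#' log-normal multiplicative amplitude noise with median 1), an optional
#' spontaneous PSC (per-trial probability \code{spont_rate * 0.045}, onset
#' uniform in the window), a Gaussian-process noise draw and i.i.d. noise.
#'
#' @param truth a \code{\link{ground_truth}}.
#' @param design a \code{\link{stim_design}}.
#' @param noise a \code{\link{noise_config}} (defaults from
#'   \code{noise_config()}).
#' @param seed optional integer seed.
#' @param keep_components if \code{TRUE}, the clean evoked ("target")
#'   component of each window is stored in \code{target_traces}.
#' @return An object of class \code{experiment_record}: \code{traces}
#'   (K x 900), \code{design}, \code{truth}, \code{spikes}, \code{latency},
#'   \code{spont} (event log), \code{mode = "trialwise"}.
#' @export
simulate_trialwise <- function(truth, design, noise = noise_config(),
                               seed = NULL, keep_components = FALSE) {
  with_seed(seed, {
    I <- design$powers
    N <- nrow(I); K <- ncol(I)
    sl <- sample_spikes_and_latencies(truth, design)
    s <- sl$spikes; lat <- sl$latency
    traces <- matrix(0, K, .TRIAL_LEN)
    target <- if (keep_components) matrix(0, K, .TRIAL_LEN) else NULL
    mult <- matrix(1, N, K)
    fired <- which(s == 1L)
    if (truth$sigma_mult > 0 && length(fired)) {
      mult[fired] <- stats::rlnorm(length(fired), 0, truth$sigma_mult)
    }
    kernels <- lapply(seq_len(N), function(n)
      unit_kernel(truth$tau_r[n], truth$tau_d[n]))
    for (k in seq_len(K)) {
      who <- which(s[, k] == 1L)
      for (n in who) {
        onset <- .STIM_ONSET + round(lat[n, k] / .DT_MS)
        if (onset >= .TRIAL_LEN) next
        kern <- kernels[[n]]
        len <- min(length(kern), .TRIAL_LEN - onset)
        idx <- onset + seq_len(len)
        amp <- truth$weights[n] * mult[n, k]
        traces[k, idx] <- traces[k, idx] + amp * kern[seq_len(len)]
        if (keep_components) target[k, idx] <- target[k, idx] + amp * kern[seq_len(len)]
      }
    }
    # spontaneous PSCs: per-trial Bernoulli with probability rate * 45 ms
    p_spont <- min(1, noise$spont_rate * .TRIAL_LEN * .DT_MS / 1000)
    has_spont <- which(stats::runif(K) < p_spont)
    spont <- NULL
    if (length(has_spont)) {
      kin <- rand_kinetics(length(has_spont),
                           list(tau_r_min = 0.5, tau_r_max = 2,
                                tau_diff_min = 6, tau_diff_max = 12))
      ch <- spont_charge(length(has_spont), noise)
      onset_ms <- stats::runif(length(has_spont), 0, .TRIAL_LEN * .DT_MS)
      for (i in seq_along(has_spont)) {
        k <- has_spont[i]
        onset <- round(onset_ms[i] / .DT_MS)
        if (onset >= .TRIAL_LEN) next
        kern <- unit_kernel(kin[i, 1], kin[i, 2])
        len <- min(length(kern), .TRIAL_LEN - onset)
        idx <- onset + seq_len(len)
        traces[k, idx] <- traces[k, idx] + ch[i] * kern[seq_len(len)]
      }
      spont <- data.frame(trial = has_spont, onset_ms = onset_ms,
                          charge = ch, tau_r = kin[, 1], tau_d = kin[, 2])
    }
    if (noise$gp_scale > 0) {
      traces <- traces + sample_gp_noise(K, .TRIAL_LEN, noise$gp_scale,
                                         noise$gp_lengthscale)
    }
    if (noise$noise_var > 0) {
      traces <- traces + matrix(stats::rnorm(K * .TRIAL_LEN,
                                             sd = sqrt(noise$noise_var)),
                                K, .TRIAL_LEN)
    }
    structure(list(traces = traces, target_traces = target,
                   design = design, truth = truth,
                   spikes = s, latency = lat, mult = mult, spont = spont,
                   mode = "trialwise", dt = .DT_MS,
                   stim_onset = .STIM_ONSET,
                   sample_rate = .SAMPLE_RATE_HZ),
              class = "experiment_record")
  })
}

#' Simulate a continuous 20-kHz mapping experiment
#'
#' Builds one long current trace by placing weighted spike events (per-trial
#' spikes, latencies and multiplicative amplitudes as in
#' \code{\link{simulate_trialwise}}) convolved with each neuron's PSC kernel,
#' adding a Poisson train of spontaneous PSCs and AR(1) noise, then
#' restructures the recording into K (possibly overlapping) 900-sample trial
#' windows starting 100 samples before each stimulus.
#'
#' @inheritParams simulate_trialwise
#' @param duration experiment duration in seconds; the number of trials is
#'   \code{floor(stim_rate * duration)}.
#' @return An \code{experiment_record} with \code{mode = "continuous"}; the
#'   full-length recording is kept in \code{continuous_trace}.
#' @export
simulate_continuous <- function(truth, design, noise = noise_config(),
                                duration = NULL, seed = NULL,
                                keep_components = FALSE) {
  with_seed(seed, {
    I <- design$powers
    N <- nrow(I); K <- ncol(I)
    f <- design$stim_rate
    if (is.null(duration)) duration <- K / f
    stop_if(floor(f * duration) < 1, "duration too short for a single trial")
    K_use <- min(K, floor(f * duration))
    isi_samples <- .SAMPLE_RATE_HZ / f
    stim_sample <- round((seq_len(K_use) - 1) * isi_samples) + .STIM_ONSET + 1
    L <- stim_sample[K_use] + .TRIAL_LEN
    sl <- sample_spikes_and_latencies(truth, design)
    s <- sl$spikes[, seq_len(K_use), drop = FALSE]
    lat <- sl$latency[, seq_len(K_use), drop = FALSE]
    mult <- matrix(1, N, K_use)
    fired <- which(s == 1L)
    if (truth$sigma_mult > 0 && length(fired)) {
      mult[fired] <- stats::rlnorm(length(fired), 0, truth$sigma_mult)
    }
    kernels <- lapply(seq_len(N), function(n)
      unit_kernel(truth$tau_r[n], truth$tau_d[n]))
    cc <- numeric(L + 4000)
    target <- if (keep_components) matrix(0, K_use, .TRIAL_LEN) else NULL
    for (k in seq_len(K_use)) {
      who <- which(s[, k] == 1L)
      for (n in who) {
        onset <- stim_sample[k] + ceiling(lat[n, k] / .DT_MS)
        kern <- kernels[[n]]
        amp <- truth$weights[n] * mult[n, k]
        len <- min(length(kern), length(cc) - onset)
        cc[onset + seq_len(len)] <- cc[onset + seq_len(len)] +
          amp * kern[seq_len(len)]
        if (keep_components) {
          w0 <- stim_sample[k] - .STIM_ONSET  # window start sample
          rel <- onset - w0                    # onset within window (0-based)
          if (rel < .TRIAL_LEN) {
            lw <- min(length(kern), .TRIAL_LEN - rel)
            target[k, rel + seq_len(lw)] <- target[k, rel + seq_len(lw)] +
              amp * kern[seq_len(lw)]
          }
        }
      }
    }
    # spontaneous Poisson train over the whole recording
    spont <- NULL
    if (noise$spont_rate > 0) {
      n_spont <- stats::rpois(1, noise$spont_rate * L * .DT_MS / 1000)
      if (n_spont > 0) {
        onset <- sort(sample.int(L, n_spont, replace = TRUE))
        kin <- rand_kinetics(n_spont, list(tau_r_min = 0.5, tau_r_max = 2,
                                           tau_diff_min = 6,
                                           tau_diff_max = 12))
        ch <- spont_charge(n_spont, noise)
        for (i in seq_len(n_spont)) {
          kern <- unit_kernel(kin[i, 1], kin[i, 2])
          len <- min(length(kern), length(cc) - onset[i])
          cc[onset[i] + seq_len(len)] <- cc[onset[i] + seq_len(len)] +
            ch[i] * kern[seq_len(len)]
        }
        spont <- data.frame(onset_sample = onset, charge = ch,
                            tau_r = kin[, 1], tau_d = kin[, 2])
      }
    }
    if (noise$ar_noise_sd > 0) {
      eps <- stats::rnorm(length(cc), sd = noise$ar_noise_sd)
      cc <- cc + as.numeric(stats::filter(eps, noise$ar_coef,
                                          method = "recursive"))
    }
    traces <- matrix(0, K_use, .TRIAL_LEN)
    for (k in seq_len(K_use)) {
      w0 <- stim_sample[k] - .STIM_ONSET
      traces[k, ] <- cc[w0 + seq_len(.TRIAL_LEN)]
    }
    des <- design
    des$powers <- I[, seq_len(K_use), drop = FALSE]
    des$trial_hologram <- design$trial_hologram[seq_len(K_use)]
    des$sweep <- design$sweep[seq_len(K_use)]
    structure(list(traces = traces, target_traces = target,
                   continuous_trace = cc[seq_len(L)],
                   stim_sample = stim_sample,
                   design = des, truth = truth,
                   spikes = s, latency = lat, mult = mult, spont = spont,
                   mode = "continuous", dt = .DT_MS,
                   stim_onset = .STIM_ONSET,
                   sample_rate = .SAMPLE_RATE_HZ),
              class = "experiment_record")
  })
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("Simulated %s experiment: %d trials x %d samples, %d neurons\n",
              x$mode, nrow(x$traces), ncol(x$traces), nrow(x$design$powers)))
  invisible(x)
}
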