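#' Configuration of the neural waveform demixing (NWD) network
#'
#' The NWD network is a sequential 1D U-Net (four contraction and four
#' expansion blocks) trained on simulated PSC traces to isolate the PSC
#' evoked by the current trial's stimulus: synaptic currents from previous
#' and subsequent trials, spontaneous PSCs outside the admissible initiation
#' window, and electrical noise are subtracted out and the baseline reset to
#' zero.
#'
#' @param kinetics \code{"inhibitory"} or \code{"excitatory"}: selects the
#'   tau ranges of the training templates (matched to the synaptic currents
#'   being demixed).
#' @param channels per-block channel counts (length 4).
#' @param kernel_size convolution kernel width (odd).
#' @param initiation_window admissible PSC initiation window, ms after
#'   stimulus onset (default 3-12 ms): training targets only contain PSCs
#'   whose onset falls in this window.
#' @param t_monotone sample index after which the output is forced
#'   non-increasing (default: end of the initiation window plus three rise
#'   time constants).
#' @param j_mean_target,j_mean_prev,j_mean_next Poisson means of the PSC
#'   counts of the target / previous-trial / next-trial components.
#' @param amp_log_mean,amp_log_sd log-normal PSC charge distribution of the
#'   training templates (pA ms).
#' @param gp_scale,gp_lengthscale Gaussian-process noise variance (pA^2) and
#'   lengthscale (ms) of the training noise.
#' @param noise_var_range range of the (per-example uniform-random) i.i.d.
#'   noise variance.
#' @param neg_frac fraction of negative (pure-noise, all-zero target)
#'   training examples.
#' @param n_examples,epochs,batch_size,lr,momentum,optimizer training-set
#'   size and optimizer settings (\code{"adam"} or \code{"sgd"}).
#' @return An object of class \code{nwd_config}.
#' @export
nwd_config <- function(kinetics = "inhibitory",
                       channels = c(8, 16, 16, 16),
                       kernel_size = 9,
                       initiation_window = c(3, 12),
                       t_monotone = NULL,
                       j_mean_target = 1, j_mean_prev = 2.2,
                       j_mean_next = 2,
                       amp_log_mean = log(250), amp_log_sd = 1,
                       gp_scale = 25, gp_lengthscale = 1,
                       noise_var_range = c(1, 25),
                       neg_frac = 0.1,
                       n_examples = 3000, epochs = 30, batch_size = 64,
                       lr = 0.002, momentum = 0.9, optimizer = "adam") {
  kin <- switch(match.arg(kinetics, c("inhibitory", "excitatory")),
    inhibitory = list(tau_r_min = 0.5, tau_r_max = 2,
                      tau_diff_min = 6, tau_diff_max = 12),
    excitatory = list(tau_r_min = 0.3, tau_r_max = 1,
                      tau_diff_min = 3, tau_diff_max = 7))
  stop_if(length(channels) != 4, "depth is fixed at 4+4 blocks")
  stop_if(kernel_size %% 2 != 1, "kernel_size must be odd")
  stop_if(diff(initiation_window) <= 0 || any(initiation_window < 0),
          "invalid initiation window")
  if (is.null(t_monotone)) {
    mean_tau_r <- (kin$tau_r_min + kin$tau_r_max) / 2
    t_monotone <- round((5 + initiation_window[2] + 3 * mean_tau_r) / .DT_MS)
  }
  stop_if(t_monotone < 0 || t_monotone >= .TRIAL_LEN,
          "t_monotone must lie in [0, 900)")
  structure(list(kinetics = match.arg(kinetics,
                                      c("inhibitory", "excitatory")),
                 kin = kin, channels = channels, kernel_size = kernel_size,
                 initiation_window = initiation_window,
                 t_monotone = t_monotone,
                 j_mean_target = j_mean_target, j_mean_prev = j_mean_prev,
                 j_mean_next = j_mean_next,
                 amp_log_mean = amp_log_mean, amp_log_sd = amp_log_sd,
                 gp_scale = gp_scale, gp_lengthscale = gp_lengthscale,
                 noise_var_range = noise_var_range,
                 neg_frac = neg_frac,
                 n_examples = n_examples, epochs = epochs,
                 batch_size = batch_size, lr = lr, momentum = momentum,
                 optimizer = optimizer),
            class = "nwd_config")
}

# add J PSCs with onsets drawn uniformly in [onset_min, onset_max] (ms,
# absolute window time; negative = still-decaying current from before the
# window) to a 900-sample trace.
add_random_pscs <- function(trace, J, onset_min, onset_max, kin,
                            amp_log_mean, amp_log_sd) {
  if (J == 0) return(trace)
  onset <- stats::runif(J, onset_min, onset_max)
  tau_r <- stats::runif(J, kin$tau_r_min, kin$tau_r_max)
  tau_d <- tau_r + stats::runif(J, kin$tau_diff_min, kin$tau_diff_max)
  amp <- stats::rlnorm(J, amp_log_mean, amp_log_sd)
  for (j in seq_len(J)) {
    kern <- unit_kernel(tau_r[j], tau_d[j])
    o <- round(onset[j] / .DT_MS)
    if (o >= 0) {
      len <- min(length(kern), .TRIAL_LEN - o)
      if (len > 0) {
        trace[o + seq_len(len)] <- trace[o + seq_len(len)] +
          amp[j] * kern[seq_len(len)]
      }
    } else {
      skip <- -o
      len <- min(length(kern) - skip, .TRIAL_LEN)
      if (len > 0) {
        trace[seq_len(len)] <- trace[seq_len(len)] +
          amp[j] * kern[skip + seq_len(len)]
      }
    }
  }
  trace
}

#' Generate a synthetic NWD training set
#'
#' Each example is the sum of independent previous-trial, target-trial and
#' next-trial PSC components (random counts, kinetics, onsets and
#' amplitudes), temporally correlated Gaussian-process noise and i.i.d.
#' noise whose variance is itself uniform-random; the regression target is
#' exactly the target-trial component. Target-component onsets fall in the
#' admissible initiation window after the stimulus; previous/next onsets
#' fall outside it, emulating overlapping trials at high stimulation rates.
#' A configured fraction of examples are negative: pure noise with an
#' all-zero target.
#'
#' @param cfg an \code{\link{nwd_config}}.
#' @param n_examples number of examples (default from \code{cfg}).
#' @param seed optional integer seed.
#' @return An object of class \code{nwd_training_set}: \code{input} and
#'   \code{target} (n x 900 matrices), \code{is_negative}.
#' @export
make_training_set <- function(cfg, n_examples = cfg$n_examples, seed = NULL) {
  stopifnot(inherits(cfg, "nwd_config"))
  with_seed(seed, {
    n <- n_examples
    input <- matrix(0, n, .TRIAL_LEN)
    target <- matrix(0, n, .TRIAL_LEN)
    is_neg <- stats::runif(n) < cfg$neg_frac
    j_target <- integer(n)
    stim_ms <- .STIM_ONSET * .DT_MS
    win <- stim_ms + cfg$initiation_window     # absolute target-onset window
    for (i in seq_len(n)) {
      if (!is_neg[i]) {
        j_target[i] <- stats::rpois(1, cfg$j_mean_target)
        tar <- add_random_pscs(numeric(.TRIAL_LEN),
                               j_target[i],
                               win[1], win[2], cfg$kin,
                               cfg$amp_log_mean, cfg$amp_log_sd)
        prev <- add_random_pscs(numeric(.TRIAL_LEN),
                                stats::rpois(1, cfg$j_mean_prev),
                                -37, win[1] - 4, cfg$kin,
                                cfg$amp_log_mean, cfg$amp_log_sd)
        nxt <- add_random_pscs(numeric(.TRIAL_LEN),
                               stats::rpois(1, cfg$j_mean_next),
                               win[2] + 2, 50, cfg$kin,
                               cfg$amp_log_mean, cfg$amp_log_sd)
        target[i, ] <- tar
        input[i, ] <- tar + prev + nxt
      }
    }
    if (cfg$gp_scale > 0) {
      input <- input + sample_gp_noise(n, .TRIAL_LEN, cfg$gp_scale,
                                       cfg$gp_lengthscale)
    }
    sig2 <- stats::runif(n, cfg$noise_var_range[1], cfg$noise_var_range[2])
    input <- input + matrix(stats::rnorm(n * .TRIAL_LEN), n, .TRIAL_LEN) *
      sqrt(sig2)
    structure(list(input = input, target = target, is_negative = is_neg,
                   j_target = j_target, cfg = cfg),
              class = "nwd_training_set")
  })
}
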