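#' End-to-end accuracy-versus-stimulation-time benchmark
#'
#' For each replicate: simulates a continuous-mode mapping experiment,
#' demixes the trial windows (or integrates the raw windows when
#' \code{use_nwd = FALSE}), fits each method on growing trial prefixes
#' (presentation order), and records weight-recovery accuracy against the
#' ground truth. The stimulation-time axis is trials / stimulation rate
#' (simulated time).
#'
#' @param nwd_model a trained \code{\link{nwd_build}} model (required when
#'   \code{use_nwd = TRUE}).
#' @param n_neurons,connect_rate,ensemble_size,stim_rate,powers simulated
#'   circuit and protocol settings (see \code{\link{sim_config}}).
#' @param duration simulated stimulation time per replicate (s).
#' @param spont_rate spontaneous PSC rate (Hz).
#' @param methods subset of \code{c("caviar", "cosamp", "cavi_sns")}.
#' @param use_nwd demix with the network (\code{TRUE}), integrate raw
#'   windows (\code{FALSE}), or both (\code{c(TRUE, FALSE)}).
#' @param prefix_times vector of stimulation times (s) at which to evaluate;
#'   defaults to the full duration only.
#' @param replicates number of independent simulated experiments.
#' @param hyper a \code{\link{caviar_hyper}} passed to the model-based
#'   methods.
#' @param seed integer seed; replicate r uses a seed derived from it.
#' @return A data.frame with one row per (replicate, method, nwd, prefix
#'   time): \code{r2}, \code{precision}, \code{recall}, \code{trials},
#'   \code{time_s}.
#' @export
run_benchmark <- function(nwd_model = NULL, n_neurons = 300,
                          connect_rate = 0.1, ensemble_size = 20,
                          stim_rate = 50, powers = c(30, 45, 60),
                          duration = 30, spont_rate = 1,
                          methods = c("caviar", "cosamp", "cavi_sns"),
                          use_nwd = TRUE, prefix_times = NULL,
                          replicates = 1, hyper = caviar_hyper(),
                          seed = 1) {
  stop_if(any(use_nwd) && is.null(nwd_model),
          "a trained NWD model is required when use_nwd = TRUE")
  prefix_times <- prefix_times %||% duration
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    s0 <- derive_seed(seed, 100 * rep_i)
    cfg <- sim_config(n_neurons = n_neurons, connect_rate = connect_rate,
                      powers = powers, ensemble_size = ensemble_size,
                      stim_rate = stim_rate,
                      noise = noise_config(spont_rate = spont_rate))
    truth <- sample_ground_truth(cfg, seed = s0)
    K_total <- ceiling(stim_rate * duration)
    n_sweeps <- ceiling(K_total * ensemble_size / n_neurons)
    design <- design_stimulus(n_neurons, n_sweeps, ensemble_size, powers,
                              stim_rate, seed = derive_seed(s0, 1))
    rec <- simulate_continuous(truth, design, cfg$noise,
                               duration = duration,
                               seed = derive_seed(s0, 2))
    for (nwd_on in use_nwd) {
      traces <- if (nwd_on) demix(nwd_model, rec$traces) else rec$traces
      y <- integrate_charge(traces)
      for (tp in prefix_times) {
        Kp <- min(length(y), floor(tp * stim_rate))
        ks <- seq_len(Kp)
        d_p <- design_subset(rec$design, ks)
        for (method in methods) {
          w_est <- switch(method,
            caviar = caviar_fit(y[ks], d_p,
                                traces = if (nwd_on) traces[ks, , drop = FALSE]
                                         else NULL,
                                hyper = hyper,
                                seed = derive_seed(s0, 3))$weights,
            cosamp = cosamp(y[ks], d_p$powers,
                            sparsity = sum(truth$connected))$weights,
            cavi_sns = cavi_sns(y[ks], d_p, hyper = hyper,
                                seed = derive_seed(s0, 4))$weights)
          cmp <- compare_maps(truth$weights, w_est)
          rows[[length(rows) + 1]] <- data.frame(
            replicate = rep_i, method = method, nwd = nwd_on,
            time_s = tp, trials = Kp, r2 = cmp$r2,
            precision = cmp$precision, recall = cmp$recall)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("holomap_benchmark", class(out))
  out
}

#' Summarize a benchmark table
#'
#' Mean and standard deviation of accuracy over replicates for each
#' (method, nwd, time) cell.
#'
#' @param object a table from \code{\link{run_benchmark}}.
#' @param ... unused.
#' @return A data.frame of summary rows.
#' @export
summary.holomap_benchmark <- function(object, ...) {
  key <- interaction(object$method, object$nwd, object$time_s, drop = TRUE)
  out <- do.call(rbind, lapply(split(as.data.frame(object), key), function(g) {
    data.frame(method = g$method[1], nwd = g$nwd[1], time_s = g$time_s[1],
               r2_mean = mean(g$r2), r2_sd = stats::sd(g$r2),
               precision_mean = mean(g$precision),
               recall_mean = mean(g$recall), n = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$nwd, out$time_s), ]
}
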