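#' Compare two connectivity maps
#'
#' Computes the coefficient of determination between two weight vectors
#' (zeros meaning unconnected), and precision/recall of the binarized
#' connectivity, treating \code{w_ref} as the truth. A connection is any
#' strictly nonzero weight (matching the hard disconnect rule of the fit).
#'
#' @param w_ref reference ("true") weight vector.
#' @param w_est estimated weight vector of the same length.
#' @return An object of class \code{map_comparison}: \code{r2},
#'   \code{precision}, \code{recall} (NA when undefined), counts, and a
#'   per-neuron agreement table.
#' @export
compare_maps <- function(w_ref, w_est) {
  stop_if(length(w_ref) != length(w_est),
          "weight vectors must have equal length")
  sst <- sum((w_ref - mean(w_ref))^2)
  r2 <- if (sst > 0) 1 - sum((w_ref - w_est)^2) / sst else NA_real_
  ref_c <- w_ref != 0
  est_c <- w_est != 0
  tp <- sum(ref_c & est_c)
  fp <- sum(!ref_c & est_c)
  fn <- sum(ref_c & !est_c)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tab <- data.frame(neuron = seq_along(w_ref), w_ref = w_ref, w_est = w_est,
                    status = ifelse(ref_c & est_c, "TP",
                             ifelse(!ref_c & est_c, "FP",
                             ifelse(ref_c & !est_c, "FN", "TN"))))
  structure(list(r2 = r2, precision = precision, recall = recall,
                 tp = tp, fp = fp, fn = fn, table = tab),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("Map comparison: R2 = %.3f, precision = %.3f, recall = %.3f (TP %d / FP %d / FN %d)\n",
              x$r2, x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Recover canonical PSC waveforms by non-negative ridge regression
#'
#' Solves \eqn{\min_{R \ge 0} \|C - \Lambda^\top R\|_F^2 + \gamma
#' \|R\|_F^2} for the N x T matrix of per-neuron canonical waveforms, using
#' the inferred spike matrix \eqn{\Lambda} (much less biased than the raw
#' design matrix, which marks merely-stimulated neurons). Solved by
#' projected gradient from the projected unconstrained ridge solution, to a
#' fixed relative tolerance. Per-neuron synaptic weights are the waveform
#' integrals.
#'
#' @param traces K x T matrix of (demixed) traces.
#' @param Lambda N x K inferred spike matrix.
#' @param gamma_ridge ridge penalty (> 0 keeps the problem well posed even
#'   when \code{Lambda} is rank deficient).
#' @param tol relative convergence tolerance.
#' @param max_iter projected-gradient iteration cap.
#' @return N x T matrix of non-negative waveforms, with attribute
#'   \code{"objective"} (the achieved penalized objective value).
#' @export
estimate_waveforms <- function(traces, Lambda, gamma_ridge = 1,
                               tol = 1e-8, max_iter = 500) {
  stop_if(ncol(Lambda) != nrow(traces),
          "Lambda columns must match trace rows")
  G <- tcrossprod(Lambda)                 # N x N
  BT <- Lambda %*% traces                 # N x T
  N <- nrow(Lambda)
  A <- G + diag(gamma_ridge, N)
  R <- pmax(solve(A, BT), 0)
  # Lipschitz constant of the gradient: largest eigenvalue of A
  L <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  obj <- function(R) {
    sum((traces - crossprod(Lambda, R))^2) + gamma_ridge * sum(R^2)
  }
  f_old <- obj(R)
  for (it in seq_len(max_iter)) {
    grad <- A %*% R - BT
    R <- pmax(R - grad / L, 0)
    f_new <- obj(R)
    if (abs(f_old - f_new) <= tol * max(f_old, 1)) break
    f_old <- f_new
  }
  structure(R, objective = obj(R))
}

#' Post hoc scan for false-negative connections
#'
#' Revisits every neuron the fit declared unconnected, greedily in order of
#' the number of coincidental spontaneous PSCs (trials on which the neuron
#' was stimulated and a spontaneous current was detected). If assigning the
#' coincident events to the neuron as spikes satisfies the isotonic
#' plausibility criterion (per-power coincidence rate at maximal power at
#' least \code{theta_pava + lambda_spont}), the neuron is reconnected with
#' posterior summaries given by the sample statistics of those spontaneous
#' PSCs; either way the neuron is not revisited. Never disconnects a
#' connected neuron and terminates after at most one pass over the
#' disconnected set.
#'
#' @param fit a \code{\link{caviar_fit}}.
#' @param design the \code{\link{stim_design}} used for the fit.
#' @param hyper a \code{\link{caviar_hyper}}.
#' @return The updated \code{caviar_fit} (weights, connected set, lambda, z
#'   adjusted for any rescued neurons); \code{rescued} lists the reconnected
#'   neuron indices.
#' @export
false_negative_scan <- function(fit, design, hyper = caviar_hyper()) {
  I <- design$powers
  pset <- design$power_set
  s_disc <- which(!fit$connected)
  rescued <- integer(0)
  z <- fit$z
  while (length(s_disc)) {
    counts <- vapply(s_disc, function(n) sum(I[n, ] > 0 & z > 0), numeric(1))
    if (max(counts) == 0) break
    n_star <- s_disc[which.max(counts)]
    coin <- which(I[n_star, ] > 0 & z > 0)
    rate <- cnt <- numeric(length(pset))
    for (i in seq_along(pset)) {
      ks <- which(I[n_star, ] == pset[i])
      cnt[i] <- length(ks)
      rate[i] <- if (length(ks)) mean(z[ks] > 0) else NA_real_
    }
    use <- cnt > 0
    fitiso <- rep(NA_real_, length(pset))
    fitiso[use] <- pava(rate[use], cnt[use])
    fmax <- fitiso[max(which(use))]
    if (!is.na(fmax) && fmax >= hyper$theta_pava + fit$lambda_spont) {
      chg <- z[coin]
      fit$mu[n_star] <- mean(chg)
      fit$weights[n_star] <- mean(chg)
      fit$Omega[n_star, n_star] <- stats::var(chg) / length(chg)
      if (is.na(fit$Omega[n_star, n_star])) {
        fit$Omega[n_star, n_star] <- fit$b2
      }
      fit$lambda[n_star, coin] <- 1
      fit$connected[n_star] <- TRUE
      fit$power_curves[[n_star]] <- structure(
        list(power = pset, lambda_bar = rate, fitted = fitiso,
             counts = cnt), class = "power_curve")
      z[coin] <- 0  # events now explained by the rescued neuron
      rescued <- c(rescued, n_star)
    }
    s_disc <- setdiff(s_disc, n_star)
  }
  fit$z <- z
  fit$rescued <- rescued
  fit
}

# restrict a design to a subset of trials
design_subset <- function(design, ks) {
  design$powers <- design$powers[, ks, drop = FALSE]
  design$trial_hologram <- design$trial_hologram[ks]
  design$sweep <- design$sweep[ks]
  design
}

#' Leave-one-hologram-out cross-validation
#'
#' For each hologram h, fits the model on the trials of all other holograms
#' and predicts the mean response to h at each power level by averaging
#' samples from the posterior predictive distribution: weights are drawn
#' from the Gaussian weight posterior, power-curve coefficients from their
#' truncated marginals, spikes from the resulting Bernoulli probabilities,
#' and the predicted response is the spike-weighted sum. Predictions are
#' compared to the held-out observed means; the pooled coefficient of
#' determination summarizes predictive performance.
#'
#' @param y vector of K observed responses.
#' @param design a \code{\link{stim_design}} whose holograms are each
#'   presented at one or more powers.
#' @param traces optional demixed traces (passed to the inner fits for
#'   masking).
#' @param hyper a \code{\link{caviar_hyper}}.
#' @param n_samples posterior predictive samples per (hologram, power).
#' @param seed optional integer seed.
#' @param fit_fun fitting function (signature of \code{\link{caviar_fit}});
#'   replaceable so baselines can be cross-validated the same way.
#' @return An object of class \code{loho_result}: a table with one row per
#'   (held-out hologram, power) — observed and predicted mean responses and
#'   sample counts — plus \code{r2_pooled} and \code{r2_by_power}.
#' @export
loho_cv <- function(y, design, traces = NULL, hyper = caviar_hyper(),
                    n_samples = 500, seed = NULL, fit_fun = caviar_fit) {
  with_seed(seed, {
    holos <- sort(unique(design$trial_hologram))
    rows <- list()
    for (h in holos) {
      held <- which(design$trial_hologram == h)
      train <- setdiff(seq_along(y), held)
      d_tr <- design_subset(design, train)
      ft <- fit_fun(y[train], d_tr,
                    traces = if (is.null(traces)) NULL else
                      traces[train, , drop = FALSE],
                    hyper = hyper)
      members <- design$holograms[[h]]
      conn <- which(ft$connected)
      act <- intersect(members, conn)
      # posterior weight samples for the active members
      mu_a <- ft$mu[act]
      pw_held <- design$powers[members[1], held]
      for (p in sort(unique(pw_held))) {
        ks <- held[pw_held == p]
        if (!length(ks)) next
        pred_s <- numeric(n_samples)
        if (length(act)) {
          Om <- ft$Omega[act, act, drop = FALSE]
          Lch <- tryCatch(chol(Om), error = function(e)
            chol(Om + diag(1e-8 * max(diag(Om)), length(act))))
          Ws <- matrix(stats::rnorm(n_samples * length(act)),
                       n_samples) %*% Lch
          Ws <- sweep(Ws, 2, mu_a, "+")
          for (i in seq_along(act)) {
            n <- act[i]
            ph0 <- rtruncnorm_pos(n_samples, ft$nu[n, 1],
                                  sqrt(ft$Sigma[n, 1, 1]))
            ph1 <- rtruncnorm_pos(n_samples, ft$nu[n, 2],
                                  sqrt(ft$Sigma[n, 2, 2]))
            sp <- stats::rbinom(n_samples, 1,
                                stats::plogis(ph0 * p - ph1))
            pred_s <- pred_s + Ws[, i] * sp
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          hologram = h, power = p,
          observed = mean(y[ks]), predicted = mean(pred_s),
          n_trials = length(ks), n_samples = n_samples)
      }
    }
    tab <- do.call(rbind, rows)
    sst <- sum((tab$observed - mean(tab$observed))^2)
    r2_pooled <- if (sst > 0) {
      1 - sum((tab$observed - tab$predicted)^2) / sst
    } else NA_real_
    r2_by_power <- vapply(split(tab, tab$power), function(g) {
      s <- sum((g$observed - mean(g$observed))^2)
      if (s > 0) 1 - sum((g$observed - g$predicted)^2) / s else NA_real_
    }, numeric(1))
    structure(list(table = tab, r2_pooled = r2_pooled,
                   r2_by_power = r2_by_power),
              class = "loho_result")
  })
}

#' @export
print.loho_result <- function(x, ...) {
  cat(sprintf("LOHO-CV: %d (hologram, power) cells, pooled R2 = %.3f\n",
              nrow(x$table), x$r2_pooled))
  invisible(x)
}
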