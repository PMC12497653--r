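# 1D U-Net primitives. Activations are (C, T, B) arrays (channels first), so
# per-channel batch-norm arithmetic uses R's free vector recycling over
# columns; convolutions run in C as accumulating BLAS products. All layers
# implement an exact backward pass; training is mini-batch Adam (or SGD with
# momentum) with warm restarts.

.PAD_LEN <- 912  # 900 right-padded so that four 2x decimations are exact

# Convolutions run in C (src/conv1d.c): one accumulating BLAS dgemm per
# (example, kernel offset) on contiguous padded blocks.
conv_fwd <- function(X, W, b) {
  list(Y = .Call(C_conv1d_fwd, X, W, b), X = X)
}

conv_bwd <- function(cache, W, dY) {
  r <- .Call(C_conv1d_bwd, cache$X, W, dY)
  list(dX = r[[1]], dW = r[[2]], db = r[[3]])
}

bn_fwd <- function(X, gamma, beta, run_mean, run_var, train, eps = 1e-5,
                   mom = 0.9) {
  d <- dim(X)
  Xm <- matrix(X, d[1])
  if (train) {
    m <- rowMeans(Xm)
    v <- rowMeans(Xm^2) - m^2
    run_mean <- mom * run_mean + (1 - mom) * m
    run_var <- mom * run_var + (1 - mom) * v
  } else {
    m <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Xm - m) * invstd
  list(Y = array(xhat * gamma + beta, d), xhat = xhat, invstd = invstd,
       dims = d, run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(cache, gamma, dY) {
  d <- cache$dims
  dYm <- matrix(dY, d[1])
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * gamma
  mg <- rowMeans(dxhat)
  mgx <- rowMeans(dxhat * cache$xhat)
  dXm <- (dxhat - mg - cache$xhat * mgx) * cache$invstd
  list(dX = array(dXm, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(Y = X, mask = mask)
}

relu_bwd <- function(cache, dY) {
  dY[!cache$mask] <- 0
  dY
}

pool2_fwd <- function(X) {
  Tn <- dim(X)[2]
  odd <- seq(1, Tn, by = 2)
  (X[, odd, , drop = FALSE] + X[, odd + 1, , drop = FALSE]) / 2
}

pool2_bwd <- function(dY, Tn) {
  d <- dim(dY)
  dX <- array(0, c(d[1], Tn, d[3]))
  odd <- seq(1, Tn, by = 2)
  dX[, odd, ] <- dY / 2
  dX[, odd + 1, ] <- dY / 2
  dX
}

# 2x linear-interpolation upsampling along time: y[2t-1] = x[t],
# y[2t] = (x[t] + x[t+1])/2 (last even sample repeats x[T]).
up2_fwd <- function(X) {
  d <- dim(X); Tn <- d[2]
  Y <- array(0, c(d[1], 2 * Tn, d[3]))
  odd <- seq(1, 2 * Tn, by = 2)
  Y[, odd, ] <- X
  Xnext <- X[, c(2:Tn, Tn), , drop = FALSE]
  Y[, odd + 1, ] <- (X + Xnext) / 2
  Y
}

up2_bwd <- function(dY) {
  d <- dim(dY); Tn <- d[2] / 2
  odd <- seq(1, 2 * Tn, by = 2)
  dOdd <- dY[, odd, , drop = FALSE]
  dEven <- dY[, odd + 1, , drop = FALSE]
  dX <- dOdd + dEven / 2
  dX[, 2:Tn, ] <- dX[, 2:Tn, , drop = FALSE] +
    dEven[, 1:(Tn - 1), , drop = FALSE] / 2
  dX[, Tn, ] <- dX[, Tn, , drop = FALSE] + dEven[, Tn, , drop = FALSE] / 2
  dX
}

cat3 <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- A
  out[da[1] + seq_len(db[1]), , ] <- B
  out
}

new_conv <- function(k, cin, cout) {
  list(W = array(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                 c(k, cin, cout)),
       b = numeric(cout))
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

#' Build an untrained NWD network
#'
#' Constructs the sequential U-Net: four contraction blocks (2x temporal
#' decimation, 1D convolution, batch normalization, ReLU) and four expansion
#' blocks (1D convolution — a stride-1 transposed convolution — batch
#' normalization, ReLU, 2x linear interpolation), with skip connections
#' joining contraction outputs to the expansion path at matching temporal
#' resolutions, and a final linear 1D convolution. Inputs of 900 samples are
#' right-padded to 912 internally (so four 2x decimations are exact, giving
#' internal lengths 456/228/114/57) and cropped on output.
#'
#' @param cfg an \code{\link{nwd_config}}.
#' @param seed optional integer seed for weight initialization.
#' @return An object of class \code{nwd_model}; \code{n_params} reports the
#'   trainable parameter count.
#' @export
nwd_build <- function(cfg = nwd_config(), seed = NULL) {
  with_seed(seed, {
    ch <- cfg$channels; k <- cfg$kernel_size
    p <- list(
      enc1 = new_conv(k, 1, ch[1]),       bn_e1 = new_bn(ch[1]),
      enc2 = new_conv(k, ch[1], ch[2]),   bn_e2 = new_bn(ch[2]),
      enc3 = new_conv(k, ch[2], ch[3]),   bn_e3 = new_bn(ch[3]),
      enc4 = new_conv(k, ch[3], ch[4]),   bn_e4 = new_bn(ch[4]),
      dec1 = new_conv(k, ch[4], ch[3]),   bn_d1 = new_bn(ch[3]),
      dec2 = new_conv(k, 2 * ch[3], ch[2]), bn_d2 = new_bn(ch[2]),
      dec3 = new_conv(k, 2 * ch[2], ch[1]), bn_d3 = new_bn(ch[1]),
      dec4 = new_conv(k, 2 * ch[1], ch[1]), bn_d4 = new_bn(ch[1]),
      fin = new_conv(k, ch[1], 1))
    n_par <- sum(vapply(p, function(l)
      sum(lengths(l[intersect(names(l), c("W", "b", "gamma", "beta"))])),
      numeric(1)))
    structure(list(params = p, cfg = cfg, n_params = n_par, trained = FALSE),
              class = "nwd_model")
  })
}

#' @export
print.nwd_model <- function(x, ...) {
  cat(sprintf(
    "NWD 1D U-Net (%s kinetics): 4+4 blocks, channels %s, %d parameters%s\n",
    x$cfg$kinetics, paste(x$cfg$channels, collapse = "/"), x$n_params,
    if (x$trained) sprintf(", trained (%d epochs, final loss %.4g)",
                           length(x$loss_history),
                           x$loss_history[length(x$loss_history)])
    else " (untrained)"))
  invisible(x)
}

# Forward pass over a (1, Tpad, B) input array. Returns output and (when
# training) the caches needed for the backward pass.
nwd_forward <- function(model, X, train = FALSE) {
  p <- model$params
  cc <- list()
  enc_block <- function(X, conv, bn, nm) {
    Xp <- pool2_fwd(X)
    cv <- conv_fwd(Xp, p[[conv]]$W, p[[conv]]$b)
    b <- bn_fwd(cv$Y, p[[bn]]$gamma, p[[bn]]$beta, p[[bn]]$run_mean,
                p[[bn]]$run_var, train)
    r <- relu_fwd(b$Y)
    cc[[nm]] <<- list(conv = cv, bn = b, relu = r, t_in = dim(X)[2])
    r$Y
  }
  dec_block <- function(X, conv, bn, nm) {
    cv <- conv_fwd(X, p[[conv]]$W, p[[conv]]$b)
    b <- bn_fwd(cv$Y, p[[bn]]$gamma, p[[bn]]$beta, p[[bn]]$run_mean,
                p[[bn]]$run_var, train)
    r <- relu_fwd(b$Y)
    cc[[nm]] <<- list(conv = cv, bn = b, relu = r)
    up2_fwd(r$Y)
  }
  e1 <- enc_block(X, "enc1", "bn_e1", "e1")    # C1 x 456
  e2 <- enc_block(e1, "enc2", "bn_e2", "e2")   # C2 x 228
  e3 <- enc_block(e2, "enc3", "bn_e3", "e3")   # C3 x 114
  e4 <- enc_block(e3, "enc4", "bn_e4", "e4")   # C4 x 57
  d1 <- dec_block(e4, "dec1", "bn_d1", "d1")   # up to C3 x 114
  d2 <- dec_block(cat3(d1, e3), "dec2", "bn_d2", "d2")  # C2 x 228
  d3 <- dec_block(cat3(d2, e2), "dec3", "bn_d3", "d3")  # C1 x 456
  d4 <- dec_block(cat3(d3, e1), "dec4", "bn_d4", "d4")  # C1 x 912
  fin <- conv_fwd(d4, p$fin$W, p$fin$b)
  cc$fin <- fin
  list(Y = fin$Y, cache = cc)
}

nwd_backward <- function(model, cache, dY) {
  p <- model$params
  g <- list()
  dec_bwd <- function(nm, conv, bn, dUp) {
    cch <- cache[[nm]]
    dR <- up2_bwd(dUp)
    dB <- relu_bwd(cch$relu, dR)
    bb <- bn_bwd(cch$bn, p[[bn]]$gamma, dB)
    cb <- conv_bwd(cch$conv, p[[conv]]$W, bb$dX)
    g[[conv]] <<- list(W = cb$dW, b = cb$db)
    g[[bn]] <<- list(gamma = bb$dgamma, beta = bb$dbeta)
    cb$dX
  }
  enc_bwd <- function(nm, conv, bn, dOut) {
    cch <- cache[[nm]]
    dB <- relu_bwd(cch$relu, dOut)
    bb <- bn_bwd(cch$bn, p[[bn]]$gamma, dB)
    cb <- conv_bwd(cch$conv, p[[conv]]$W, bb$dX)
    g[[conv]] <<- list(W = cb$dW, b = cb$db)
    g[[bn]] <<- list(gamma = bb$dgamma, beta = bb$dbeta)
    pool2_bwd(cb$dX, cch$t_in)
  }
  split3 <- function(dX, c1) {
    list(dX[seq_len(c1), , , drop = FALSE],
         dX[-seq_len(c1), , , drop = FALSE])
  }
  ch <- model$cfg$channels
  fb <- conv_bwd(cache$fin, p$fin$W, dY)
  g$fin <- list(W = fb$dW, b = fb$db)
  d4 <- dec_bwd("d4", "dec4", "bn_d4", fb$dX)      # d(concat d3,e1) @456
  s4 <- split3(d4, ch[1])
  d3 <- dec_bwd("d3", "dec3", "bn_d3", s4[[1]])    # d(concat d2,e2) @228
  s3 <- split3(d3, ch[2])
  d2 <- dec_bwd("d2", "dec2", "bn_d2", s3[[1]])    # d(concat d1,e3) @114
  s2 <- split3(d2, ch[3])
  d1 <- dec_bwd("d1", "dec1", "bn_d1", s2[[1]])    # d(e4) @57
  de3 <- enc_bwd("e4", "enc4", "bn_e4", d1) + s2[[2]]
  de2 <- enc_bwd("e3", "enc3", "bn_e3", de3) + s3[[2]]
  de1 <- enc_bwd("e2", "enc2", "bn_e2", de2) + s4[[2]]
  dX <- enc_bwd("e1", "enc1", "bn_e1", de1)
  list(grads = g, dX = dX)
}

# Fold freshly computed batch-norm running statistics back into the model.
absorb_bn_stats <- function(model, cache) {
  map <- c(e1 = "bn_e1", e2 = "bn_e2", e3 = "bn_e3", e4 = "bn_e4",
           d1 = "bn_d1", d2 = "bn_d2", d3 = "bn_d3", d4 = "bn_d4")
  for (nm in names(map)) {
    model$params[[map[[nm]]]]$run_mean <- cache[[nm]]$bn$run_mean
    model$params[[map[[nm]]]]$run_var <- cache[[nm]]$bn$run_var
  }
  model
}

# robust per-trace normalization factor (stored and inverted on output)
trace_scale <- function(x) max(max(abs(x)), 1e-6)

prep_input <- function(traces) {
  # traces: B x 900 -> normalized (1, 912, B) array + scales
  B <- nrow(traces)
  sc <- apply(traces, 1, trace_scale)
  X <- array(0, c(1, .PAD_LEN, B))
  X[1, seq_len(.TRIAL_LEN), ] <- t(traces / sc)
  list(X = X, scale = sc)
}

#' Train the NWD network
#'
#' Minimizes the mean-squared error between the network output and the clean
#' target-trial component by mini-batch stochastic gradient descent (with
#' momentum). Inputs and targets are scaled per trace by a robust amplitude
#' statistic (the factor is inverted at inference time). Training is
#' deterministic given \code{seed}. Divergence (non-finite loss) aborts with
#' a diagnostic.
#'
#' @param model an untrained (or previously trained) \code{nwd_model}.
#' @param ts an \code{\link{nwd_training_set}}.
#' @param epochs,batch_size,lr,momentum optimizer settings (defaults from
#'   the model config).
#' @param optimizer \code{"adam"} (default; reaches low loss in the reduced
#'   training budgets this package targets) or \code{"sgd"} (plain
#'   momentum SGD).
#' @param restarts number of warm-restart segments: the optimizer moment
#'   estimates are reset between equal segments of the epoch budget, which
#'   reliably pulls runs out of the poor early optima that single-schedule
#'   Adam occasionally settles in at these step counts.
#' @param seed optional integer seed (batch order).
#' @param verbose print the loss every few epochs.
#' @return The trained model with a \code{loss_history} vector (mean
#'   training MSE per epoch, normalized scale).
#' @export
nwd_train <- function(model, ts, epochs = NULL, batch_size = NULL,
                      lr = NULL, momentum = NULL, optimizer = NULL,
                      restarts = 3, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "nwd_model"), inherits(ts, "nwd_training_set"))
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- lr %||% cfg$lr
  momentum <- momentum %||% cfg$momentum
  optimizer <- match.arg(optimizer %||% cfg$optimizer, c("adam", "sgd"))
  stop_if(nrow(ts$input) == 0, "empty training set")
  with_seed(seed, {
    n <- nrow(ts$input)
    sc <- apply(ts$input, 1, trace_scale)
    Xall <- ts$input / sc
    Tall <- ts$target / sc
    vel <- rapply(model$params, function(x) x * 0, how = "replace")
    m1 <- rapply(model$params, function(x) x * 0, how = "replace")
    m2 <- rapply(model$params, function(x) x * 0, how = "replace")
    step <- 0
    seg_len <- ceiling(epochs / max(restarts, 1))
    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      if (ep > 1 && (ep - 1) %% seg_len == 0) {
        # warm restart: reset the optimizer state, keep the weights
        m1 <- rapply(model$params, function(x) x * 0, how = "replace")
        m2 <- rapply(model$params, function(x) x * 0, how = "replace")
        vel <- rapply(model$params, function(x) x * 0, how = "replace")
        step <- 0
      }
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        B <- length(idx)
        X <- array(0, c(1, .PAD_LEN, B))
        X[1, seq_len(.TRIAL_LEN), ] <- t(Xall[idx, , drop = FALSE])
        Yt <- array(0, c(1, .PAD_LEN, B))
        Yt[1, seq_len(.TRIAL_LEN), ] <- t(Tall[idx, , drop = FALSE])
        fw <- nwd_forward(model, X, train = TRUE)
        diffY <- fw$Y - Yt
        loss <- mean(diffY^2)
        if (!is.finite(loss)) {
          stop(sprintf(
            "NWD training diverged (non-finite loss at epoch %d); lower the learning rate",
            ep), call. = FALSE)
        }
        dY <- 2 * diffY / length(diffY)
        bw <- nwd_backward(model, fw$cache, dY)
        model <- absorb_bn_stats(model, fw$cache)
        step <- step + 1
        for (lname in names(bw$grads)) {
          for (pn in names(bw$grads[[lname]])) {
            gr <- bw$grads[[lname]][[pn]]
            if (optimizer == "sgd") {
              vel[[lname]][[pn]] <- momentum * vel[[lname]][[pn]] - lr * gr
              model$params[[lname]][[pn]] <- model$params[[lname]][[pn]] +
                vel[[lname]][[pn]]
            } else {
              m1[[lname]][[pn]] <- 0.9 * m1[[lname]][[pn]] + 0.1 * gr
              m2[[lname]][[pn]] <- 0.999 * m2[[lname]][[pn]] + 0.001 * gr^2
              mh <- m1[[lname]][[pn]] / (1 - 0.9^step)
              vh <- m2[[lname]][[pn]] / (1 - 0.999^step)
              model$params[[lname]][[pn]] <- model$params[[lname]][[pn]] -
                lr * mh / (sqrt(vh) + 1e-8)
            }
          }
        }
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      loss_hist[ep] <- ep_loss / nb
      if (verbose && (ep %% 5 == 0 || ep == 1)) {
        message(sprintf("epoch %d/%d  loss %.5f", ep, epochs, loss_hist[ep]))
      }
    }
    model$loss_history <- c(model$loss_history, loss_hist)
    model$trained <- TRUE
    model
  })
}

#' Monotone-decay correction
#'
#' After a user-specified time index \code{t_monotone} (0-based sample
#' index), recursively sets \eqn{N_t = \min(N_t, N_{t-1})} so the output
#' decays monotonically. Idempotent; never increases any sample.
#'
#' @param x numeric vector (one trace) or K x T matrix.
#' @param t_monotone 0-based sample index after which the correction
#'   applies.
#' @return Corrected trace(s).
#' @examples
#' monotone_correct(c(1, 2, 1.5, 1.8), t_monotone = 1)  # 1 2 1.5 1.5
#' @export
monotone_correct <- function(x, t_monotone) {
  fix1 <- function(v) {
    i0 <- t_monotone + 1L  # 1-based index of sample t_monotone
    if (i0 >= length(v)) return(v)
    tail <- cummin(v[i0:length(v)])
    v[(i0 + 1L):length(v)] <- tail[-1]
    v
  }
  if (is.matrix(x)) t(apply(x, 1, fix1)) else fix1(x)
}

#' Demix PSC traces with a trained NWD network
#'
#' Normalizes each trace, runs the forward pass (batch-norm in inference
#' mode), inverts the normalization, and applies the monotone-decay
#' correction after \code{t_monotone}.
#'
#' @param model a trained \code{nwd_model}.
#' @param traces one trace (length 900) or a K x 900 matrix.
#' @param t_monotone 0-based sample index (default from the model config).
#' @param batch chunk size for the forward pass.
#' @return Demixed trace(s), same shape as the input.
#' @export
demix <- function(model, traces, t_monotone = NULL, batch = 256) {
  stopifnot(inherits(model, "nwd_model"))
  vec_in <- !is.matrix(traces)
  if (vec_in) traces <- matrix(traces, 1)
  stop_if(ncol(traces) != .TRIAL_LEN,
          sprintf("traces must have %d samples", .TRIAL_LEN))
  t_monotone <- t_monotone %||% model$cfg$t_monotone
  K <- nrow(traces)
  out <- matrix(0, K, .TRIAL_LEN)
  for (start in seq(1, K, by = batch)) {
    idx <- start:min(start + batch - 1, K)
    pp <- prep_input(traces[idx, , drop = FALSE])
    fw <- nwd_forward(model, pp$X, train = FALSE)
    out[idx, ] <- t(matrix(fw$Y[1, seq_len(.TRIAL_LEN), ],
                           .TRIAL_LEN)) * pp$scale
  }
  out <- monotone_correct(out, t_monotone)
  out <- out * (model$charge_scale %||% 1)
  if (vec_in) out[1, ] else out
}

#' Calibrate the charge scale of a trained NWD network
#'
#' A demixing network trained at reduced scale is a shrinkage estimator: its
#' output systematically under-estimates the amplitude of the target PSC
#' (the conditional-mean prediction under residual uncertainty), and the
#' monotone-decay correction removes a further small amount of charge. This
#' step measures the multiplicative charge bias on fresh held-out synthetic
#' examples — the through-origin regression slope of demixed on true target
#' charge among examples with appreciable charge, so large PSCs (which carry
#' the connectivity map) dominate the estimate — and stores its inverse in
#' the model, which \code{\link{demix}} then applies to every output
#' trace.
#'
#' @param model a trained \code{nwd_model}.
#' @param n_examples number of held-out calibration examples.
#' @param min_charge only examples with true target charge above this
#'   (pA ms) enter the ratio (tiny targets make the ratio unstable).
#' @param seed optional integer seed.
#' @return The model with \code{charge_scale} set (and the measured bias in
#'   \code{calibration}).
#' @export
nwd_calibrate <- function(model, n_examples = 300, min_charge = 100,
                          seed = NULL) {
  stopifnot(inherits(model, "nwd_model"))
  model$charge_scale <- NULL
  ts <- make_training_set(model$cfg, n_examples, seed = seed)
  dmx <- demix(model, ts$input)
  y_true <- integrate_charge(ts$target)
  y_dmx <- integrate_charge(dmx)
  use <- y_true > min_charge
  stop_if(sum(use) < 10, "too few calibration examples above min_charge")
  ratio <- sum(y_dmx[use] * y_true[use]) / sum(y_true[use]^2)
  stop_if(!is.finite(ratio) || ratio <= 0,
          "calibration failed: non-positive charge ratio")
  model$charge_scale <- 1 / ratio
  model$calibration <- list(n = sum(use), charge_ratio = ratio)
  model
}
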