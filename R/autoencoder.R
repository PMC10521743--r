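#' Configuration of the cyclic-trajectory autoencoder
#'
#' The encoder is a fully connected network over a fixed-length resampling
#' of the input slice (plus the slice duration as an extra feature for the
#' variants that learn a pace); its heads emit the trajectory parameters,
#' with the frequency passed through `softplus(x) + 0.1` so `f > 0` is
#' enforced structurally. The decoder is a separate network
#' `d -> 64 -> 64 -> 1` with tanh nonlinearities that maps latent points to
#' voltage values. Training minimizes the mean over slices of the per-slice
#' mean squared reconstruction error by Adam.
#'
#' @param variant One of `"DHB"`, `"P_DHB"`, `"S_DHB"`.
#' @param d Latent dimension (`>= 3`).
#' @param n_in Number of resampled input points fed to the encoder.
#' @param m_eval Number of time points per slice at which the
#'   reconstruction loss is evaluated.
#' @param hidden_widths Widths of the two encoder hidden layers.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param max_len_s Pad/crop horizon in seconds; defaults at training time
#'   to 2 s for heartbeat slices and 4 s otherwise.
#' @param cycle_reps For heartbeat slices under the pace-carrying variants,
#'   the number of cycle repetitions the loss is evaluated over. Beats tile
#'   a periodic signal, and supervising the trajectory over a second
#'   repetition of the cycle forces the latent loop to close exactly at the
#'   beat boundary, which pins `f` to one cycle per beat; with a single
#'   repetition `f` is only bounded, not identified, on one-cycle inputs.
#' @param seed Seed controlling initialization and batch shuffling.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(variant = c("DHB", "P_DHB", "S_DHB"), d = 16,
                           n_in = 96, m_eval = 48, hidden_widths = c(64, 64),
                           learning_rate = 1e-3, batch_size = 64,
                           epochs = 30, max_len_s = NULL, cycle_reps = 2,
                           seed = 1L) {
  variant <- match.arg(variant)
  if (d < 3) stop("latent dimension d must be >= 3", call. = FALSE)
  stopifnot(length(hidden_widths) == 2, cycle_reps >= 1)
  structure(list(variant = variant, d = as.integer(d), n_in = as.integer(n_in),
                 m_eval = as.integer(m_eval),
                 hidden_widths = as.integer(hidden_widths),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_len_s = max_len_s,
                 cycle_reps = as.integer(cycle_reps), seed = as.integer(seed)),
            class = "encoder_config")
}

ae_init_params <- function(config) {
  p_in <- config$n_in + as.integer(config$variant != "S_DHB")
  h <- config$hidden_widths
  d <- config$d
  params <- list(
    W1 = glorot(p_in, h[1]), b1 = zeros_row(h[1]),
    W2 = glorot(h[1], h[2]), b2 = zeros_row(h[2]),
    Wb = glorot(h[2], d - 2), bb = zeros_row(d - 2),
    V1 = glorot(d, 64), c1 = zeros_row(64),
    V2 = glorot(64, 64), c2 = zeros_row(64),
    v3 = glorot(64, 1), c3 = zeros_row(1)
  )
  if (config$variant != "S_DHB") {
    params$Wf <- glorot(h[2], 1)
    # bias chosen so the initial pace softplus(b)+0.1 is ~1 Hz, a typical
    # resting heart rate
    params$bf <- matrix(0.378, 1, 1)
  }
  if (config$variant == "DHB") {
    params$Wt <- glorot(h[2], 1)
    params$bt <- zeros_row(1)
  }
  params
}

# Resample one slice for the encoder input and the loss grid.
# Returns list(x = encoder input vector, t_eval, y_eval, dur).
ae_prepare_slice <- function(slice, config, max_len_s) {
  dur <- slice_duration(slice)
  if (dur > max_len_s + 1e-9) {
    stop("slice of ", round(dur, 3), " s exceeds the max_len_s horizon of ",
         max_len_s, " s", call. = FALSE)
  }
  n_in <- config$n_in
  m <- config$m_eval
  if (config$variant == "S_DHB") {
    # one-beat phase normalization: times rescaled to [0, 1)
    ph_in <- (seq_len(n_in) - 1) / n_in
    x <- stats::approx(slice$times / dur, slice$values, xout = ph_in,
                       rule = 2)$y
    ph_ev <- (seq_len(m) - 1) / m
    y <- stats::approx(slice$times / dur, slice$values, xout = ph_ev,
                       rule = 2)$y
    list(x = x, t_eval = ph_ev, y_eval = y, dur = dur)
  } else {
    span <- min(dur, max_len_s)
    tg <- (seq_len(n_in) - 1) / n_in * span
    x <- c(stats::approx(slice$times, slice$values, xout = tg, rule = 2)$y,
           dur)
    te <- (seq_len(m) - 1) / m * dur
    y <- stats::approx(slice$times, slice$values, xout = te, rule = 2)$y
    if (config$cycle_reps > 1 && slice$kind == "HEARTBEAT") {
      reps <- config$cycle_reps
      te <- as.vector(vapply(seq_len(reps) - 1, function(r) te + r * dur,
                             numeric(m)))
      y <- rep(y, reps)
    }
    list(x = x, t_eval = te, y_eval = y, dur = dur)
  }
}

# Forward pass of the full autoencoder on a prepared batch.
# X: B x p_in; Te, Y: B x m matrices. Returns activations for backprop.
ae_forward <- function(params, config, X, Te) {
  B <- nrow(X)
  H1 <- tanh(X %*% params$W1 + brow(params$b1, B))
  H2 <- tanh(H1 %*% params$W2 + brow(params$b2, B))
  bmat <- H2 %*% params$Wb + brow(params$bb, B)
  if (config$variant == "S_DHB") {
    f <- NULL; fraw <- NULL; tau <- NULL
    Phi <- Te
  } else {
    fraw <- H2 %*% params$Wf + brow(params$bf, B)
    f <- softplus(fraw) + 0.1
    if (config$variant == "DHB") {
      tau <- H2 %*% params$Wt + brow(params$bt, B)
      Phi <- (Te - as.vector(tau)) * as.vector(f)
    } else {
      tau <- NULL
      Phi <- Te * as.vector(f)
    }
  }
  C1 <- cos(2 * pi * Phi)
  C2 <- sin(2 * pi * Phi)
  m <- ncol(Te)
  rep_idx <- rep(seq_len(B), m)
  Z <- cbind(c(C1), c(C2), bmat[rep_idx, , drop = FALSE])
  G1 <- tanh(Z %*% params$V1 + brow(params$c1, nrow(Z)))
  G2 <- tanh(G1 %*% params$V2 + brow(params$c2, nrow(Z)))
  yhat <- as.vector(G2 %*% params$v3) + params$c3[1]
  list(H1 = H1, H2 = H2, bmat = bmat, fraw = fraw, f = f, tau = tau,
       Phi = Phi, C1 = C1, C2 = C2, Z = Z, G1 = G1, G2 = G2, yhat = yhat,
       rep_idx = rep_idx, B = B, m = m)
}

# Backward pass; returns list(grads, loss, per_slice_mse).
ae_backward <- function(params, config, X, Te, Y, fw) {
  B <- fw$B; m <- fw$m
  resid <- fw$yhat - c(Y)
  loss <- mean(resid^2)
  per_slice_mse <- rowMeans(matrix(resid^2, B, m))

  dout <- matrix(2 * resid / (B * m), ncol = 1)
  g <- list()
  g$v3 <- t(fw$G2) %*% dout
  g$c3 <- matrix(sum(dout), 1, 1)
  dG2 <- dout %*% t(params$v3)
  dA2 <- dG2 * (1 - fw$G2^2)
  g$V2 <- t(fw$G1) %*% dA2
  g$c2 <- matrix(colSums(dA2), 1)
  dG1 <- dA2 %*% t(params$V2)
  dA1 <- dG1 * (1 - fw$G1^2)
  g$V1 <- t(fw$Z) %*% dA1
  g$c1 <- matrix(colSums(dA1), 1)
  dZ <- dA1 %*% t(params$V1)

  dC1 <- matrix(dZ[, 1], B, m)
  dC2 <- matrix(dZ[, 2], B, m)
  db <- rowsum(dZ[, -(1:2), drop = FALSE], fw$rep_idx)
  dPhi <- 2 * pi * (-sin(2 * pi * fw$Phi) * dC1 + cos(2 * pi * fw$Phi) * dC2)

  g$Wb <- t(fw$H2) %*% db
  g$bb <- matrix(colSums(db), 1)
  dH2 <- db %*% t(params$Wb)
  if (config$variant != "S_DHB") {
    if (config$variant == "DHB") {
      df <- rowSums(dPhi * (Te - as.vector(fw$tau)))
      dtau <- matrix(-rowSums(dPhi) * as.vector(fw$f), ncol = 1)
      g$Wt <- t(fw$H2) %*% dtau
      g$bt <- matrix(sum(dtau), 1, 1)
      dH2 <- dH2 + dtau %*% t(params$Wt)
    } else {
      df <- rowSums(dPhi * Te)
    }
    dfraw <- matrix(df * sigmoid(fw$fraw), ncol = 1)
    g$Wf <- t(fw$H2) %*% dfraw
    g$bf <- matrix(sum(dfraw), 1, 1)
    dH2 <- dH2 + dfraw %*% t(params$Wf)
  }
  dA2e <- dH2 * (1 - fw$H2^2)
  g$W2 <- t(fw$H1) %*% dA2e
  g$b2 <- matrix(colSums(dA2e), 1)
  dH1 <- dA2e %*% t(params$W2)
  dA1e <- dH1 * (1 - fw$H1^2)
  g$W1 <- t(X) %*% dA1e
  g$b1 <- matrix(colSums(dA1e), 1)
  list(grads = g, loss = loss, per_slice_mse = per_slice_mse)
}

#' Train a cyclic-trajectory autoencoder
#'
#' Fits encoder and decoder jointly by Adam on the mean per-slice squared
#' reconstruction error. Fully reproducible from `config$seed` in
#' single-threaded execution. The per-epoch mean reconstruction RMSE is
#' recorded in `training_log`.
#'
#' @param slices List of [ecg_slice()]s; the shape-only variant requires
#'   heartbeat slices (its time axis is the cycle phase).
#' @param config An [encoder_config()].
#' @return A `trained_autoencoder` with fields `params`, `config`,
#'   `max_len_s` and `training_log`.
#' @export
train_autoencoder <- function(slices, config) {
  stopifnot(inherits(config, "encoder_config"))
  if (length(slices) < config$batch_size) {
    stop("need at least batch_size slices to train", call. = FALSE)
  }
  kinds <- vapply(slices, function(s) s$kind, character(1))
  if (config$variant == "S_DHB" && !all(kinds == "HEARTBEAT")) {
    stop("S_DHB requires heartbeat slices (phase-normalized single cycles)",
         call. = FALSE)
  }
  max_len_s <- config$max_len_s
  if (is.null(max_len_s)) {
    max_len_s <- if (all(kinds == "HEARTBEAT")) 2.0 else 4.0
  }

  prep <- lapply(slices, ae_prepare_slice, config = config,
                 max_len_s = max_len_s)
  m_tot <- length(prep[[1]]$t_eval)
  if (any(vapply(prep, function(p) length(p$t_eval), integer(1)) != m_tot)) {
    # mixed heartbeat/other kinds: disable cycle tiling for uniform shapes
    stop("cannot mix heartbeat and non-heartbeat slices with cycle_reps > 1",
         call. = FALSE)
  }
  X <- do.call(rbind, lapply(prep, `[[`, "x"))
  Te <- do.call(rbind, lapply(prep, `[[`, "t_eval"))
  Y <- do.call(rbind, lapply(prep, `[[`, "y_eval"))
  N <- nrow(X)

  with_seed(config$seed, {
    params <- ae_init_params(config)
    opt <- adam_init(params)
    log_rmse <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      ep_mse <- numeric(0)
      for (start in seq(1, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, N)]
        fw <- ae_forward(params, config, X[idx, , drop = FALSE],
                         Te[idx, , drop = FALSE])
        bw <- ae_backward(params, config, X[idx, , drop = FALSE],
                          Te[idx, , drop = FALSE], Y[idx, , drop = FALSE], fw)
        step <- adam_step(params, bw$grads, opt, config$learning_rate)
        params <- step$params
        opt <- step$state
        ep_mse <- c(ep_mse, bw$per_slice_mse)
      }
      log_rmse[ep] <- mean(sqrt(ep_mse))
    }
    structure(list(params = params, config = config, max_len_s = max_len_s,
                   training_log = log_rmse),
              class = "trained_autoencoder")
  })
}

#' @export
print.trained_autoencoder <- function(x, ...) {
  cat(sprintf("<trained_autoencoder %s d=%d> %d epochs, final RMSE %.4f mV\n",
              x$config$variant, x$config$d, length(x$training_log),
              utils::tail(x$training_log, 1)))
  invisible(x)
}

#' Encode slices as trajectory parameters
#'
#' Deterministic at inference. `encode()` maps one slice to its embedding;
#' `encode_slices()` is the vectorized form used by the pipeline.
#'
#' @param model A `trained_autoencoder`.
#' @param slice An [ecg_slice()] no longer than the model's horizon.
#' @return For `encode()`, a [trajectory_params()]; for `encode_slices()`, a
#'   list of them.
#' @export
encode <- function(model, slice) {
  encode_slices(model, list(slice))[[1]]
}

#' @rdname encode
#' @param slices List of [ecg_slice()]s.
#' @export
encode_slices <- function(model, slices) {
  stopifnot(inherits(model, "trained_autoencoder"))
  config <- model$config
  prep <- lapply(slices, ae_prepare_slice, config = config,
                 max_len_s = model$max_len_s)
  X <- do.call(rbind, lapply(prep, `[[`, "x"))
  B <- nrow(X)
  H1 <- tanh(X %*% model$params$W1 + brow(model$params$b1, B))
  H2 <- tanh(H1 %*% model$params$W2 + brow(model$params$b2, B))
  bmat <- H2 %*% model$params$Wb + brow(model$params$bb, B)
  f <- tau <- NULL
  if (config$variant != "S_DHB") {
    f <- softplus(H2 %*% model$params$Wf + brow(model$params$bf, B)) + 0.1
  }
  if (config$variant == "DHB") {
    tau <- H2 %*% model$params$Wt + brow(model$params$bt, B)
  }
  lapply(seq_len(B), function(i) {
    switch(config$variant,
      DHB = trajectory_params("DHB", f = f[i], tau = tau[i],
                              b = bmat[i, ]),
      P_DHB = trajectory_params("P_DHB", f = f[i], b = bmat[i, ]),
      S_DHB = trajectory_params("S_DHB", b = bmat[i, ])
    )
  })
}

#' Reconstruct signal values from an embedding
#'
#' Evaluates the decoder along the latent trajectory at arbitrary times, so
#' variable-length reconstruction (including extrapolation over further
#' cycles) comes for free.
#'
#' @param model A `trained_autoencoder`.
#' @param params A [trajectory_params()] of the model's variant.
#' @param times Numeric vector of times in seconds (cycle phase for the
#'   shape-only variant).
#' @return Numeric vector of reconstructed voltages, `length(times)` long.
#' @export
reconstruct <- function(model, params, times) {
  stopifnot(inherits(model, "trained_autoencoder"),
            inherits(params, "trajectory_params"))
  if (params$variant != model$config$variant) {
    stop("params variant does not match the model", call. = FALSE)
  }
  Z <- latent_trajectory(params, times)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  G1 <- tanh(Z %*% model$params$V1 + brow(model$params$c1, nrow(Z)))
  G2 <- tanh(G1 %*% model$params$V2 + brow(model$params$c2, nrow(Z)))
  as.vector(G2 %*% model$params$v3) + model$params$c3[1]
}

#' Per-slice reconstruction RMSE
#'
#' Encodes a slice, reconstructs it at its own sample times (phase for the
#' shape-only variant) and returns the reconstruction [rmse()] in mV.
#'
#' @param model A `trained_autoencoder`.
#' @param slice An [ecg_slice()].
#' @return Non-negative scalar RMSE.
#' @export
reconstruction_rmse <- function(model, slice) {
  params <- encode(model, slice)
  tt <- if (model$config$variant == "S_DHB") {
    slice$times / slice_duration(slice)
  } else {
    slice$times
  }
  rmse(slice$values, reconstruct(model, params, tt))
}
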