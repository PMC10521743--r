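#' Ordered sequence of per-slice embeddings of one record
#'
#' @param record_id Source record identifier.
#' @param embeddings Non-empty list of [trajectory_params()] of one common
#'   variant and latent dimension, ordered by the start index of the slices
#'   they encode.
#' @return An object of class `embedding_sequence`.
#' @export
embedding_sequence <- function(record_id, embeddings) {
  if (length(embeddings) == 0) {
    stop("embedding_sequence: must be non-empty", call. = FALSE)
  }
  variants <- vapply(embeddings, function(e) e$variant, character(1))
  ds <- vapply(embeddings, function(e) e$d, integer(1))
  if (length(unique(variants)) != 1 || length(unique(ds)) != 1) {
    stop("embedding_sequence: all embeddings must share variant and d",
         call. = FALSE)
  }
  structure(list(record_id = as.character(record_id), embeddings = embeddings,
                 variant = variants[1], d = ds[1]),
            class = "embedding_sequence")
}

#' Embedding sequence as a matrix
#'
#' One row per slice, columns in the flattened `(f, tau, b)` layout of
#' [flatten_params()].
#'
#' @param seq An [embedding_sequence()].
#' @return Numeric matrix, `n_slices` x `param_count`.
#' @export
embedding_matrix <- function(seq) {
  stopifnot(inherits(seq, "embedding_sequence"))
  do.call(rbind, lapply(seq$embeddings, flatten_params))
}

#' Mean aggregation of an embedding sequence
#'
#' The record-level embedding is the coordinate-wise arithmetic mean of the
#' flattened per-slice parameter vectors. Order-invariant by construction:
#' it discards the sequence ordering and the beat-to-beat variability, which
#' is exactly what motivates the recurrent alternative.
#'
#' @param seq An [embedding_sequence()].
#' @return A `record_embedding` with fields `vector`, `method = "MEAN"`,
#'   `variant`.
#' @export
aggregate_mean <- function(seq) {
  stopifnot(inherits(seq, "embedding_sequence"))
  structure(list(vector = colMeans(embedding_matrix(seq)), method = "MEAN",
                 variant = seq$variant),
            class = "record_embedding")
}

# ---- LSTM aggregator -------------------------------------------------------

#' Configuration of the recurrent aggregator
#'
#' @param hidden Hidden units per direction.
#' @param bidirectional Read the sequence in both directions (default) and
#'   concatenate the final hidden states.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (sequences are end-padded and masked).
#' @param epochs Training epochs.
#' @param max_seq Sequences longer than this are subsampled uniformly.
#' @param seed Seed for initialization and shuffling.
#' @return An `rnn_config` list.
#' @export
rnn_config <- function(hidden = 32, bidirectional = TRUE,
                       learning_rate = 5e-3, batch_size = 16, epochs = 30,
                       max_seq = 512, seed = 1L) {
  structure(list(hidden = as.integer(hidden), bidirectional = bidirectional,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_seq = as.integer(max_seq),
                 seed = as.integer(seed)),
            class = "rnn_config")
}

lstm_init_dir <- function(p, h) {
  W <- list(Wx = glorot(p, 4 * h), Wh = glorot(h, 4 * h),
            b = zeros_row(4 * h))
  W$b[1, (h + 1):(2 * h)] <- 1  # forget-gate bias
  W
}

# forward pass of one direction over a padded batch
# X: list of T matrices (B x p); M: B x T mask. Returns cache for BPTT.
lstm_forward_dir <- function(W, X, M, h) {
  B <- nrow(X[[1]])
  Tn <- length(X)
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    A <- X[[t]] %*% W$Wx + H %*% W$Wh + brow(W$b, B)
    ig <- sigmoid(A[, 1:h, drop = FALSE])
    fg <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
    gg <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
    og <- sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
    Cn <- fg * C + ig * gg
    Hn <- og * tanh(Cn)
    m <- M[, t]
    cache[[t]] <- list(Hprev = H, Cprev = C, i = ig, f = fg, g = gg, o = og,
                       Cn = Cn, m = m)
    C <- m * Cn + (1 - m) * C
    H <- m * Hn + (1 - m) * H
  }
  list(H = H, cache = cache)
}

# BPTT for one direction; dH_final: B x h. Returns grads for W.
lstm_backward_dir <- function(W, X, M, h, cache, dH_final) {
  B <- nrow(X[[1]])
  Tn <- length(X)
  dWx <- W$Wx * 0; dWh <- W$Wh * 0; db <- W$b * 0
  dH <- dH_final
  dC <- matrix(0, B, h)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    m <- cc$m
    dHn <- m * dH
    dCn <- m * dC
    tc <- tanh(cc$Cn)
    do <- dHn * tc
    dCn <- dCn + dHn * cc$o * (1 - tc^2)
    di <- dCn * cc$g
    df <- dCn * cc$Cprev
    dg <- dCn * cc$i
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + t(X[[t]]) %*% dA
    dWh <- dWh + t(cc$Hprev) %*% dA
    db <- db + matrix(colSums(dA), 1)
    dH <- (1 - m) * dH + dA %*% t(W$Wh)
    dC <- (1 - m) * dC + dCn * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

seq_to_matrix <- function(seq, max_seq) {
  S <- embedding_matrix(seq)
  if (nrow(S) > max_seq) {
    keep <- unique(round(seq(1, nrow(S), length.out = max_seq)))
    S <- S[keep, , drop = FALSE]
  }
  S
}

# pad a list of n_i x p matrices into step-major batch form
pad_batch <- function(mats) {
  B <- length(mats)
  p <- ncol(mats[[1]])
  lens <- vapply(mats, nrow, integer(1))
  Tn <- max(lens)
  M <- outer(lens, seq_len(Tn), ">=") * 1
  X <- lapply(seq_len(Tn), function(t) {
    rows <- lapply(seq_len(B), function(b) {
      if (t <= lens[b]) mats[[b]][t, ] else rep(0, p)
    })
    do.call(rbind, rows)
  })
  list(X = X, M = M, lens = lens)
}

rev_rows <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

rnn_forward <- function(params, cfg, mats, h) {
  pb <- pad_batch(mats)
  fw <- lstm_forward_dir(params$fwd, pb$X, pb$M, h)
  if (cfg$bidirectional) {
    pb_r <- pad_batch(lapply(mats, rev_rows))
    bw <- lstm_forward_dir(params$bwd, pb_r$X, pb_r$M, h)
    Hcat <- cbind(fw$H, bw$H)
  } else {
    pb_r <- NULL; bw <- NULL
    Hcat <- fw$H
  }
  list(pb = pb, pb_r = pb_r, fw = fw, bw = bw, Hcat = Hcat)
}

#' Train the LSTM aggregator jointly with a classifier head
#'
#' Reads each record's ordered embedding sequence with a (by default
#' bidirectional) LSTM; the record embedding is the concatenation of the
#' final hidden states, and a linear softmax head on top is trained
#' end-to-end with cross-entropy — aggregation has no loss of its own, so
#' the classifier objective drives it. Unlike mean aggregation, the result
#' is order-sensitive.
#'
#' @param sequences List of [embedding_sequence()]s sharing variant and `d`.
#' @param labels Factor (or coercible) of record labels, same length.
#' @param config An [rnn_config()].
#' @return An `rnn_aggregator` with the LSTM weights, head weights, class
#'   levels and per-epoch training loss.
#' @export
train_rnn_aggregator <- function(sequences, labels, config = rnn_config()) {
  stopifnot(inherits(config, "rnn_config"))
  if (length(sequences) != length(labels)) {
    stop("sequences and labels must have equal length", call. = FALSE)
  }
  variants <- vapply(sequences, function(s) s$variant, character(1))
  ds <- vapply(sequences, function(s) s$d, integer(1))
  if (length(unique(variants)) != 1 || length(unique(ds)) != 1) {
    stop("all sequences must share variant and d", call. = FALSE)
  }
  labels <- factor(labels)
  K <- nlevels(labels)
  y <- as.integer(labels)
  mats <- lapply(sequences, seq_to_matrix, max_seq = config$max_seq)
  p <- ncol(mats[[1]])
  h <- config$hidden
  out_dim <- if (config$bidirectional) 2 * h else h

  with_seed(config$seed, {
    params <- list(fwd = lstm_init_dir(p, h),
                   Wo = glorot(out_dim, K), bo = zeros_row(K))
    if (config$bidirectional) params$bwd <- lstm_init_dir(p, h)
    flat <- flatten_rnn(params, config$bidirectional)
    opt <- adam_init(flat)
    N <- length(mats)
    log_loss <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, N)]
        fwp <- rnn_forward(params, config, mats[idx], h)
        B <- length(idx)
        logits <- fwp$Hcat %*% params$Wo + brow(params$bo, B)
        P <- softmax(logits)
        Yoh <- matrix(0, B, K)
        Yoh[cbind(seq_len(B), y[idx])] <- 1
        losses <- c(losses, -mean(log(pmax(P[cbind(seq_len(B), y[idx])],
                                           1e-12))))
        dlogits <- (P - Yoh) / B
        g <- list(Wo = t(fwp$Hcat) %*% dlogits,
                  bo = matrix(colSums(dlogits), 1))
        dHcat <- dlogits %*% t(params$Wo)
        gf <- lstm_backward_dir(params$fwd, fwp$pb$X, fwp$pb$M, h,
                                fwp$fw$cache, dHcat[, 1:h, drop = FALSE])
        g$fwd.Wx <- gf$Wx; g$fwd.Wh <- gf$Wh; g$fwd.b <- gf$b
        if (config$bidirectional) {
          gb <- lstm_backward_dir(params$bwd, fwp$pb_r$X, fwp$pb_r$M, h,
                                  fwp$bw$cache,
                                  dHcat[, (h + 1):(2 * h), drop = FALSE])
          g$bwd.Wx <- gb$Wx; g$bwd.Wh <- gb$Wh; g$bwd.b <- gb$b
        }
        flat <- flatten_rnn(params, config$bidirectional)
        step <- adam_step(flat, g, opt, config$learning_rate)
        opt <- step$state
        params <- unflatten_rnn(step$params, config$bidirectional)
      }
      log_loss[ep] <- mean(losses)
    }
    structure(list(params = params, config = config, levels = levels(labels),
                   variant = variants[1], training_log = log_loss),
              class = "rnn_aggregator")
  })
}

flatten_rnn <- function(params, bidir) {
  flat <- list(Wo = params$Wo, bo = params$bo,
               fwd.Wx = params$fwd$Wx, fwd.Wh = params$fwd$Wh,
               fwd.b = params$fwd$b)
  if (bidir) {
    flat$bwd.Wx <- params$bwd$Wx
    flat$bwd.Wh <- params$bwd$Wh
    flat$bwd.b <- params$bwd$b
  }
  flat
}

unflatten_rnn <- function(flat, bidir) {
  params <- list(fwd = list(Wx = flat$fwd.Wx, Wh = flat$fwd.Wh,
                            b = flat$fwd.b),
                 Wo = flat$Wo, bo = flat$bo)
  if (bidir) {
    params$bwd <- list(Wx = flat$bwd.Wx, Wh = flat$bwd.Wh, b = flat$bwd.b)
  }
  params
}

#' Aggregate one sequence with a trained LSTM aggregator
#'
#' @param agg An `rnn_aggregator` from [train_rnn_aggregator()].
#' @param seq An [embedding_sequence()] of the aggregator's variant.
#' @return A `record_embedding` with `method = "RNN"` (the concatenated
#'   final hidden states).
#' @export
aggregate_rnn <- function(agg, seq) {
  stopifnot(inherits(agg, "rnn_aggregator"),
            inherits(seq, "embedding_sequence"))
  if (seq$variant != agg$variant) {
    stop("sequence variant does not match the aggregator", call. = FALSE)
  }
  mats <- list(seq_to_matrix(seq, agg$config$max_seq))
  fwp <- rnn_forward(agg$params, agg$config, mats, agg$config$hidden)
  structure(list(vector = as.vector(fwp$Hcat), method = "RNN",
                 variant = seq$variant),
            class = "record_embedding")
}

#' Class probabilities from the aggregator's classifier head
#'
#' @param agg An `rnn_aggregator`.
#' @param sequences List of [embedding_sequence()]s.
#' @return Matrix of class probabilities, columns named by class level.
#' @export
predict_rnn <- function(agg, sequences) {
  mats <- lapply(sequences, seq_to_matrix, max_seq = agg$config$max_seq)
  fwp <- rnn_forward(agg$params, agg$config, mats, agg$config$hidden)
  logits <- fwp$Hcat %*% agg$params$Wo +
    brow(agg$params$bo, length(sequences))
  P <- softmax(logits)
  colnames(P) <- agg$levels
  P
}
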