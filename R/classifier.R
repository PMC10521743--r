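#' Configuration of the fully connected classifier head
#'
#' A softmax multilayer perceptron (default 64-32 hidden units) trained
#' with cross-entropy by Adam, used both for the 4-class record task and
#' the binary AF-window task.
#'
#' @param hidden_widths Widths of the two hidden layers.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Seed for initialization and shuffling.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden_widths = c(64, 32), learning_rate = 5e-3,
                              batch_size = 32, epochs = 120, seed = 1L) {
  structure(list(hidden_widths = as.integer(hidden_widths),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stack record embeddings into a feature matrix
#'
#' @param embeddings List of `record_embedding`s (from [aggregate_mean()] or
#'   [aggregate_rnn()]) of identical length.
#' @return Numeric matrix, one row per record.
#' @export
embeddings_to_matrix <- function(embeddings) {
  do.call(rbind, lapply(embeddings, function(e) {
    stopifnot(inherits(e, "record_embedding"))
    e$vector
  }))
}

#' Train the softmax classifier
#'
#' Features are standardized internally (columns centered and scaled by the
#' training statistics); the fitted scaling travels with the model.
#'
#' @param X Numeric feature matrix, one row per record or window.
#' @param labels Factor (or coercible) of the same length as `nrow(X)`.
#' @param config A [classifier_config()].
#' @return A `trained_classifier`.
#' @export
train_classifier <- function(X, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) {
    stop("label/embedding count mismatch: ", nrow(X), " rows vs ",
         length(labels), " labels", call. = FALSE)
  }
  labels <- factor(labels)
  K <- nlevels(labels)
  y <- as.integer(labels)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  h <- config$hidden_widths
  with_seed(config$seed, {
    params <- list(W1 = glorot(ncol(X), h[1]), b1 = zeros_row(h[1]),
                   W2 = glorot(h[1], h[2]), b2 = zeros_row(h[2]),
                   W3 = glorot(h[2], K), b3 = zeros_row(K))
    opt <- adam_init(params)
    N <- nrow(Xs)
    log_loss <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, N)]
        B <- length(idx)
        Xb <- Xs[idx, , drop = FALSE]
        H1 <- tanh(Xb %*% params$W1 + brow(params$b1, B))
        H2 <- tanh(H1 %*% params$W2 + brow(params$b2, B))
        P <- softmax(H2 %*% params$W3 + brow(params$b3, B))
        Yoh <- matrix(0, B, K)
        Yoh[cbind(seq_len(B), y[idx])] <- 1
        losses <- c(losses,
                    -mean(log(pmax(P[cbind(seq_len(B), y[idx])], 1e-12))))
        dlog <- (P - Yoh) / B
        g <- list(W3 = t(H2) %*% dlog, b3 = matrix(colSums(dlog), 1))
        dH2 <- dlog %*% t(params$W3) * (1 - H2^2)
        g$W2 <- t(H1) %*% dH2; g$b2 <- matrix(colSums(dH2), 1)
        dH1 <- dH2 %*% t(params$W2) * (1 - H1^2)
        g$W1 <- t(Xb) %*% dH1; g$b1 <- matrix(colSums(dH1), 1)
        step <- adam_step(params, g, opt, config$learning_rate)
        params <- step$params
        opt <- step$state
      }
      log_loss[ep] <- mean(losses)
    }
    structure(list(params = params, config = config, mu = mu, sg = sg,
                   levels = levels(labels), training_log = log_loss),
              class = "trained_classifier")
  })
}

#' Class probabilities from a trained classifier
#'
#' @param model A `trained_classifier`.
#' @param X Feature matrix with the training layout.
#' @return Matrix of softmax probabilities (rows sum to 1), columns named
#'   by class level.
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sg, "/")
  B <- nrow(Xs)
  H1 <- tanh(Xs %*% model$params$W1 + brow(model$params$b1, B))
  H2 <- tanh(H1 %*% model$params$W2 + brow(model$params$b2, B))
  P <- softmax(H2 %*% model$params$W3 + brow(model$params$b3, B))
  colnames(P) <- model$levels
  P
}
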