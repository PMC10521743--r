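make_seq <- function(fvals, id = "r", bvals = NULL) {
  embedding_sequence(id, lapply(seq_along(fvals), function(i) {
    b <- if (is.null(bvals)) c(0.1, -0.2) else bvals[[i]]
    trajectory_params("P_DHB", f = fvals[i], b = b)
  }))
}

test_that("mean aggregation is the coordinate-wise mean and is symmetric", {
  s <- embedding_sequence("r", list(
    trajectory_params("P_DHB", f = 1, b = 2),
    trajectory_params("P_DHB", f = 3, b = 4)))
  expect_equal(aggregate_mean(s)$vector, c(2, 3))
  # single embedding aggregates to itself
  one <- embedding_sequence("r", list(trajectory_params("P_DHB", f = 1.5,
                                                        b = c(7, 8))))
  expect_equal(aggregate_mean(one)$vector, c(1.5, 7, 8))
  # permutation invariance
  set.seed(5)
  fv <- runif(9, 0.8, 2)
  s1 <- make_seq(fv)
  s2 <- make_seq(fv[sample(9)])
  expect_equal(aggregate_mean(s1)$vector, aggregate_mean(s2)$vector)
  # mean of n copies equals the embedding, for several n
  for (n in c(1, 4, 13)) {
    rep_seq <- make_seq(rep(1.2, n))
    expect_equal(aggregate_mean(rep_seq)$vector, c(1.2, 0.1, -0.2))
  }
})

test_that("embedding sequences enforce uniform variant and non-emptiness", {
  expect_error(embedding_sequence("r", list()), "non-empty")
  mixed <- list(trajectory_params("P_DHB", f = 1, b = 0.5),
                trajectory_params("S_DHB", b = 0.5))
  expect_error(embedding_sequence("r", mixed), "share variant")
})

test_that("LSTM backpropagation through time matches numerical gradients", {
  set.seed(3)
  p <- 3; h <- 4; K <- 2
  cfg <- rnn_config(hidden = h, bidirectional = TRUE, seed = 1)
  params <- list(fwd = cyclebeat:::lstm_init_dir(p, h),
                 bwd = cyclebeat:::lstm_init_dir(p, h),
                 Wo = cyclebeat:::glorot(2 * h, K),
                 bo = cyclebeat:::zeros_row(K))
  mats <- list(matrix(rnorm(5 * p), 5, p), matrix(rnorm(3 * p), 3, p),
               matrix(rnorm(7 * p), 7, p))
  y <- c(1L, 2L, 1L)
  lossfn <- function(pp) {
    fwp <- cyclebeat:::rnn_forward(pp, cfg, mats, h)
    P <- cyclebeat:::softmax(fwp$Hcat %*% pp$Wo + cyclebeat:::brow(pp$bo, 3))
    -mean(log(P[cbind(1:3, y)]))
  }
  fwp <- cyclebeat:::rnn_forward(params, cfg, mats, h)
  P <- cyclebeat:::softmax(fwp$Hcat %*% params$Wo +
                             cyclebeat:::brow(params$bo, 3))
  Yoh <- matrix(0, 3, K); Yoh[cbind(1:3, y)] <- 1
  dlog <- (P - Yoh) / 3
  dHcat <- dlog %*% t(params$Wo)
  gf <- cyclebeat:::lstm_backward_dir(params$fwd, fwp$pb$X, fwp$pb$M, h,
                                      fwp$fw$cache,
                                      dHcat[, 1:h, drop = FALSE])
  gb <- cyclebeat:::lstm_backward_dir(params$bwd, fwp$pb_r$X, fwp$pb_r$M, h,
                                      fwp$bw$cache,
                                      dHcat[, (h + 1):(2 * h), drop = FALSE])
  eps <- 1e-6
  for (dir in c("fwd", "bwd")) {
    for (nm in c("Wx", "Wh", "b")) {
      ga <- if (dir == "fwd") gf[[nm]] else gb[[nm]]
      g_num <- ga * 0
      for (i in seq_along(ga)) {
        p1 <- params; p1[[dir]][[nm]][i] <- p1[[dir]][[nm]][i] + eps
        p2 <- params; p2[[dir]][[nm]][i] <- p2[[dir]][[nm]][i] - eps
        g_num[i] <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      }
      expect_lt(max(abs(g_num - ga)) / (max(abs(g_num)) + 1e-9), 1e-5)
    }
  }
})

test_that("a trained LSTM aggregator is order-sensitive, unlike the mean", {
  # AF-like sequences: erratic beat-to-beat pace; NSR-like: steady pace
  set.seed(8)
  seqs <- list(); labs <- character(0)
  for (i in 1:40) {
    af <- i %% 2 == 0
    n <- sample(20:30, 1)
    fv <- if (af) runif(n, 0.9, 2.2) else 1.2 + rnorm(n, sd = 0.03)
    seqs[[i]] <- make_seq(fv, id = paste0("r", i))
    labs <- c(labs, if (af) "AF" else "NSR")
  }
  agg <- train_rnn_aggregator(seqs, labs,
                              rnn_config(hidden = 8, epochs = 10, seed = 2))
  s <- seqs[[1]]
  rev_s <- embedding_sequence(s$record_id, rev(s$embeddings))
  fwd_emb <- aggregate_rnn(agg, s)$vector
  rev_emb <- aggregate_rnn(agg, rev_s)$vector
  expect_false(isTRUE(all.equal(fwd_emb, rev_emb)))
  # mean aggregation of the same pair is identical
  expect_equal(aggregate_mean(s)$vector, aggregate_mean(rev_s)$vector)
  # inference is deterministic and finite for constant sequences
  const_seq <- make_seq(rep(1.1, 5))
  e1 <- aggregate_rnn(agg, const_seq)$vector
  expect_true(all(is.finite(e1)))
  expect_identical(e1, aggregate_rnn(agg, const_seq)$vector)
})

test_that("the LSTM pipeline separates erratic from steady pace sequences", {
  set.seed(9)
  seqs <- list(); labs <- character(0)
  for (i in 1:60) {
    af <- i <= 30
    n <- sample(25:35, 1)
    fv <- if (af) runif(n, 0.9, 2.2) else 1.2 + rnorm(n, sd = 0.03)
    seqs[[i]] <- make_seq(fv, id = paste0("r", i))
    labs <- c(labs, if (af) "AF" else "NSR")
  }
  train_idx <- c(1:20, 31:50)
  agg <- train_rnn_aggregator(seqs[train_idx], labs[train_idx],
                              rnn_config(hidden = 16, epochs = 25, seed = 3))
  P <- predict_rnn(agg, seqs[-train_idx])
  expect_gte(auc_rank(P[, "AF"], labs[-train_idx] == "AF"), 0.9)
})

test_that("aggregator rejects mismatched variants", {
  seqs <- list(make_seq(c(1, 1.1)),
               embedding_sequence("s", list(trajectory_params("S_DHB",
                                                              b = c(1, 2)))))
  expect_error(train_rnn_aggregator(seqs, c("A", "B")), "share variant")
  agg <- train_rnn_aggregator(list(make_seq(c(1, 1.2)),
                                   make_seq(c(1.4, 2))),
                              c("A", "B"),
                              rnn_config(hidden = 4, epochs = 2,
                                         batch_size = 2, seed = 1))
  sd_seq <- embedding_sequence("s", list(trajectory_params("S_DHB",
                                                           b = c(1, 2))))
  expect_error(aggregate_rnn(agg, sd_seq), "variant")
})
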