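test_that("classifier probabilities are normalized and capacity suffices", {
  set.seed(21)
  # four linearly separable clusters
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2),
             matrix(rnorm(40, -4), 20, 2),
             cbind(rnorm(20, 4), rnorm(20, -4)))
  y <- rep(c("NSR", "AF", "OTHER", "NOISY"), each = 20)
  model <- train_classifier(X, y, classifier_config(epochs = 80, seed = 2))
  P <- predict_classifier(model, X)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  expect_identical(sort(colnames(P)), sort(unique(y)))
  acc <- mean(colnames(P)[max.col(P)] == y)
  expect_gte(acc, 0.99)
  expect_error(train_classifier(X, y[-1]), "mismatch")
})

test_that("confusion-count metrics match hand arithmetic", {
  # TP=8, FP=2, FN=2, TN=88 at threshold 0.5
  probs <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 88))
  labs <- c(rep(TRUE, 8), rep(TRUE, 2), rep(FALSE, 2), rep(FALSE, 88))
  m <- evaluate_binary_af(probs, labs)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$specificity, 88 / 90)
  # metric identities on random confusion patterns
  set.seed(22)
  for (i in 1:20) {
    n <- 50
    pr <- runif(n); lb <- runif(n) > 0.4
    mm <- evaluate_binary_af(pr, lb, threshold = 0.5)
    expect_equal(mm$accuracy, (mm$tp + mm$tn) / n)
    if (!is.na(mm$f1)) {
      expect_equal(mm$f1, 2 * mm$ppv * mm$sensitivity /
                     (mm$ppv + mm$sensitivity))
    }
  }
  expect_error(evaluate_binary_af(c(0.5, 1.2), c(TRUE, FALSE)), "\\[0, 1\\]")
})

test_that("rank AUC equals the brute-force pairwise statistic", {
  # oracle: average over all (positive, negative) pairs with ties at 1/2
  brute_auc <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T)), 0.75)
  expect_equal(brute_auc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T)), 0.75)
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(F, F, T, T)), 1.0)
  expect_true(is.na(auc_rank(runif(5), rep(TRUE, 5))))
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    l <- runif(n) > 0.5
    expect_equal(auc_rank(s, l), brute_auc(s, l))
  }
  # the fold evaluation reports the same AUC
  m <- evaluate_binary_af(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T))
  expect_equal(m$auc, 0.75)
})

test_that("window labeling agrees with exhaustive-enumeration semantics", {
  # oracle for all three strategies straight from the flag pattern
  oracle <- function(flags, strategy, p = 0.8) {
    switch(strategy,
           MAJORITY = sum(flags) >= 15,
           MIDDLE = flags[16],
           THRESHOLD = sum(flags) / 30 >= p)
  }
  set.seed(24)
  for (i in 1:2000) {
    flags <- runif(30) > runif(1)
    for (st in c("MAJORITY", "MIDDLE", "THRESHOLD")) {
      expect_identical(label_window(flags, st), oracle(flags, st))
    }
    # majority equals threshold at p = 0.5 for 30-beat windows
    expect_identical(label_window(flags, "MAJORITY"),
                     label_window(flags, "THRESHOLD", p = 0.5))
  }
  # boundary cases
  expect_true(label_window(rep(c(TRUE, FALSE), c(15, 15)), "MAJORITY"))
  expect_false(label_window(rep(c(TRUE, FALSE), c(14, 16)), "MAJORITY"))
  expect_true(label_window(rep(c(TRUE, FALSE), c(24, 6)), "THRESHOLD",
                           p = 0.8))
  expect_false(label_window(rep(c(TRUE, FALSE), c(24, 6)), "THRESHOLD",
                            p = 0.8, strict = TRUE))
  expect_error(label_window(rep(TRUE, 29), "MAJORITY"), "exactly 30")
})

test_that("sliding windows respect fencepost and stride arithmetic", {
  expect_length(make_windows(rep(FALSE, 31)), 2)
  expect_length(make_windows(rep(FALSE, 30)), 1)
  w <- make_windows(rep(c(TRUE, FALSE), 45), stride = 30)
  expect_length(w, 3)
  starts <- vapply(w, function(x) x$start, integer(1))
  expect_identical(starts, c(1L, 31L, 61L))
  expect_warning(out <- make_windows(rep(TRUE, 10)), "fewer than")
  expect_length(out, 0)
  # embeddings travel with their window
  emb <- matrix(seq_len(62), 31, 2)
  w2 <- make_windows(rep(TRUE, 31), embeddings = emb)
  expect_equal(w2[[2]]$embeddings, emb[2:31, ])
  expect_error(make_windows(rep(TRUE, 31), embeddings = emb[1:5, ]),
               "align")
})

test_that("stratified folds partition the data evenly and reproducibly", {
  labs <- rep(c("NSR", "AF"), each = 50)
  folds <- make_folds(labs, k = 10, seed = 3)
  expect_identical(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 10))
  # every fold sees both classes
  expect_true(all(table(folds, labs) > 0))
  expect_identical(make_folds(labs, k = 10, seed = 3), folds)
  expect_error(make_folds(labs[1:5], k = 10), "exceed")
})

test_that("cross-validation reports per-fold means and the f1 identity", {
  set.seed(25)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 3), 50, 2))
  labs <- rep(c("NSR", "AF"), each = 50)
  rep_ <- cross_validate(X, labs, k = 5, seed = 4,
                         config = classifier_config(epochs = 40, seed = 1))
  expect_s3_class(rep_, "metric_report")
  expect_length(rep_$folds, 5)
  expect_identical(rep_$metrics$metric,
                   c("f1", "sensitivity", "specificity", "ppv", "auc",
                     "accuracy"))
  for (fm in rep_$folds) {
    if (!is.na(fm$f1)) {
      expect_equal(fm$f1,
                   2 * fm$ppv * fm$sensitivity / (fm$ppv + fm$sensitivity))
    }
  }
  # well-separated clusters should classify nearly perfectly
  expect_gte(rep_$metrics$mean[rep_$metrics$metric == "auc"], 0.95)
})

test_that("records without extractable beats rank most anomalous", {
  model <- sdhb_toy_model()
  ds <- generate_dataset(2, c(NSR = 1), seed = 26, duration_s = 20)
  flat <- ecg_record("flat", rep(0, 6000), 300)  # no beats at all
  scores <- noise_scores(model, list(ds[[1]]$record, flat,
                                     ds[[2]]$record))
  expect_true(all(is.finite(scores)))
  # beat-free records receive the dataset maximum (most anomalous rank)
  expect_identical(scores[2], max(scores))
  expect_true(is.na(noise_score(model, flat)))
})

test_that("heart-rate timelines convert pace to bpm and reject shape-only input", {
  s <- embedding_sequence("r", list(
    trajectory_params("P_DHB", f = 1.25, b = 0),
    trajectory_params("P_DHB", f = 1.5, b = 0)))
  tl <- heart_rate_timeline(s, c(0.5, 1.3))
  expect_equal(tl$bpm, c(75, 90))
  expect_equal(tl$time_s, c(0.5, 1.3))
  sd_seq <- embedding_sequence("r", list(trajectory_params("S_DHB", b = 1)))
  expect_error(heart_rate_timeline(sd_seq, 0.5), "no frequency")
  expect_error(heart_rate_timeline(s, 0.5), "align")
})
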