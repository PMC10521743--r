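#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic:
#' the probability that a random positive scores above a random negative,
#' with ties counted half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 vector of true classes.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary AF-vs-non-AF evaluation of one fold
#'
#' Thresholds the AF probabilities at `threshold` (0.5 by default) and
#' derives the confusion-count metrics: sensitivity, specificity, positive
#' predictive value, accuracy and their harmonic-mean summary F1, plus the
#' threshold-free rank AUC.
#'
#' @param probabilities AF probabilities in `[0, 1]`.
#' @param labels Logical or 0/1 vector; `TRUE` = AF.
#' @param threshold Decision threshold.
#' @return Named list with `f1`, `sensitivity`, `specificity`, `ppv`,
#'   `auc`, `accuracy`, `threshold` and the confusion counts `tp`, `fp`,
#'   `fn`, `tn`. Metrics undefined on the input (e.g. AUC for single-class
#'   labels, PPV with no positive calls) are `NA`, not 0.
#' @export
evaluate_binary_af <- function(probabilities, labels, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have equal length", call. = FALSE)
  }
  pred <- probabilities >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / length(labels)
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  list(f1 = f1, sensitivity = sens, specificity = spec, ppv = ppv,
       auc = auc_rank(probabilities, labels), accuracy = acc,
       threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Stratified fold assignment
#'
#' Partitions `n = length(labels)` items into `k` folds of sizes differing
#' by at most one, stratified by class so every fold sees every class where
#' possible. Deterministic given `seed`.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k = 10, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of items", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold between classes so fold sizes balance
      folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx) %% k
    }
  })
  folds
}

#' Cross-validated binary AF classification
#'
#' Splits the records into `k` near-equal stratified folds, trains the
#' softmax classifier on `k - 1` folds and evaluates on the held-out fold,
#' with hyperparameters held fixed across folds. When the labels have more
#' than two classes, the AF probability is the softmax component of the
#' positive class, so the binary evaluation is AF against everything else.
#'
#' @param X Feature matrix (one row per record).
#' @param labels Class labels (factor or coercible); must contain
#'   `positive`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment (classifier seeds derive from it).
#' @param config A [classifier_config()] used identically in every fold.
#' @param positive The label treated as the AF class.
#' @param threshold Decision threshold for the count metrics.
#' @return A `metric_report`: data frame `metrics` with per-metric mean and
#'   standard deviation over folds, plus `folds` (the per-fold lists) and
#'   `threshold`.
#' @export
cross_validate <- function(X, labels, k = 10, seed = 1L,
                           config = classifier_config(), positive = "AF",
                           threshold = 0.5) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (!positive %in% levels(labels)) {
    stop("positive class '", positive, "' not present in labels",
         call. = FALSE)
  }
  folds <- make_folds(as.character(labels), k = k, seed = seed)
  fold_metrics <- lapply(seq_len(k), function(fold) {
    train <- folds != fold
    cfg <- config
    cfg$seed <- as.integer(derive_seed(seed, fold))
    model <- train_classifier(X[train, , drop = FALSE], labels[train], cfg)
    P <- predict_classifier(model, X[!train, , drop = FALSE])
    evaluate_binary_af(P[, positive], labels[!train] == positive,
                       threshold = threshold)
  })
  metric_report(fold_metrics, threshold)
}

#' Summarize per-fold metrics as mean and standard deviation
#'
#' @param fold_metrics List of per-fold metric lists from
#'   [evaluate_binary_af()].
#' @param threshold The decision threshold the folds were evaluated at.
#' @return A `metric_report` object.
#' @export
metric_report <- function(fold_metrics, threshold = 0.5) {
  nm <- c("f1", "sensitivity", "specificity", "ppv", "auc", "accuracy")
  tab <- do.call(rbind, lapply(nm, function(m) {
    v <- vapply(fold_metrics, function(fm) fm[[m]], numeric(1))
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE))
  }))
  structure(list(metrics = tab, folds = fold_metrics, threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d folds, threshold %.2f\n",
              length(x$folds), x$threshold))
  for (i in seq_len(nrow(x$metrics))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$metrics$metric[i],
                x$metrics$mean[i], x$metrics$sd[i]))
  }
  invisible(x)
}

#' Label a 30-beat window from its per-beat AF flags
#'
#' Three strategies from the windowed-AF literature: `"MIDDLE"` takes the
#' flag of the central beat (0-based index 15 of 30 by default; even-length
#' windows have no true center), `"MAJORITY"` calls AF when at least half
#' the beats (15 of 30) are AF, and `"THRESHOLD"` calls AF when the AF
#' fraction reaches `p`. The threshold comparison is non-strict by default
#' (`24/30 >= 0.8` is AF), since the boundary is attainable exactly;
#' `strict = TRUE` switches to `>`.
#'
#' @param af_flags Logical vector of exactly `window` flags.
#' @param strategy One of `"MIDDLE"`, `"MAJORITY"`, `"THRESHOLD"`.
#' @param p Fraction for the threshold strategy.
#' @param strict Use a strict inequality for the threshold strategy.
#' @param middle_index 0-based index used by the middle strategy.
#' @param window Expected window length.
#' @return Logical: is the window AF?
#' @export
label_window <- function(af_flags,
                         strategy = c("MAJORITY", "MIDDLE", "THRESHOLD"),
                         p = 0.8, strict = FALSE, middle_index = 15L,
                         window = 30L) {
  strategy <- match.arg(strategy)
  if (length(af_flags) != window) {
    stop("label_window: expected exactly ", window, " flags, got ",
         length(af_flags), call. = FALSE)
  }
  af_flags <- as.logical(af_flags)
  n_af <- sum(af_flags)
  switch(strategy,
    MAJORITY = n_af >= ceiling(window / 2),
    MIDDLE = af_flags[middle_index + 1L],
    THRESHOLD = if (strict) n_af / window > p else n_af / window >= p
  )
}

#' Sliding 30-beat windows over a record's annotated beats
#'
#' @param embeddings Optional list of per-beat [trajectory_params()] (or a
#'   matrix with one row per beat) aligned with `af_flags`.
#' @param af_flags Logical AF flag per beat.
#' @param window Window length in beats.
#' @param stride Step between window starts.
#' @param strategy,p Passed to [label_window()] for the window label.
#' @return List of `beat_window` objects (fields `start` — 1-based beat
#'   index —, `af_flags`, `label`, and `embeddings` when supplied); empty
#'   with a warning when fewer than `window` beats are available.
#' @export
make_windows <- function(af_flags, embeddings = NULL, window = 30L,
                         stride = 1L, strategy = "MAJORITY", p = 0.8) {
  n <- length(af_flags)
  if (!is.null(embeddings)) {
    n_emb <- if (is.matrix(embeddings)) nrow(embeddings) else length(embeddings)
    if (n_emb != n) {
      stop("make_windows: embeddings and af_flags must align", call. = FALSE)
    }
  }
  if (n < window) {
    warning("make_windows: fewer than ", window, " beats; no windows")
    return(list())
  }
  starts <- as.integer(seq(1L, n - window + 1L, by = stride))
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    flags <- as.logical(af_flags[idx])
    emb <- if (is.null(embeddings)) NULL
           else if (is.matrix(embeddings)) embeddings[idx, , drop = FALSE]
           else embeddings[idx]
    structure(list(start = s, af_flags = flags,
                   label = label_window(flags, strategy, p = p,
                                        window = window),
                   embeddings = emb),
              class = "beat_window")
  })
}

#' Reconstruction-error noise score of a record
#'
#' Runs R-peak detection and heartbeat extraction on the record and returns
#' the mean per-beat reconstruction RMSE under the given autoencoder. A
#' model trained on clean beats reconstructs noise poorly, so the score
#' ranks noise-only records as anomalous. Records from which no beat can be
#' extracted return `NA`; [noise_scores()] replaces those with the maximum
#' observed score of the dataset (most anomalous).
#'
#' @param model A `trained_autoencoder`.
#' @param record An [ecg_record()].
#' @return Non-negative mean beat RMSE, or `NA` if no beats were extracted.
#' @export
noise_score <- function(model, record) {
  rpeaks <- pan_tompkins(record)
  beats <- suppressWarnings(extract_heartbeats(record, rpeaks))
  if (length(beats) == 0) return(NA_real_)
  mean(vapply(beats, function(b) reconstruction_rmse(model, b), numeric(1)))
}

#' @rdname noise_score
#' @param records List of [ecg_record()]s.
#' @export
noise_scores <- function(model, records) {
  s <- vapply(records, function(r) noise_score(model, r), numeric(1))
  if (anyNA(s)) {
    if (all(is.na(s))) stop("no record yielded any beat", call. = FALSE)
    s[is.na(s)] <- max(s, na.rm = TRUE)
  }
  s
}

#' Heart-rate timeline from a sequence of pace-carrying embeddings
#'
#' Converts each embedding's frequency to beats per minute (`60 * f`) and
#' pairs it with the time of the slice it encodes, giving the heart-rate
#' dynamics over the course of the record.
#'
#' @param seq An [embedding_sequence()] of variant `"DHB"` or `"P_DHB"`;
#'   the shape-only variant carries no frequency and is rejected.
#' @param beat_times Numeric vector of slice midpoint times (s), one per
#'   embedding, in temporal order.
#' @return Data frame with columns `time_s` and `bpm`.
#' @export
heart_rate_timeline <- function(seq, beat_times) {
  stopifnot(inherits(seq, "embedding_sequence"))
  if (seq$variant == "S_DHB") {
    stop("heart_rate_timeline: the shape-only variant has no frequency ",
         "parameter", call. = FALSE)
  }
  if (length(beat_times) != length(seq$embeddings)) {
    stop("beat_times must align with the embeddings", call. = FALSE)
  }
  data.frame(
    time_s = as.numeric(beat_times),
    bpm = 60 * vapply(seq$embeddings, function(e) e$f, numeric(1))
  )
}
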