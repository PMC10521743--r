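#' ECG slice
#'
#' A timed subsequence of a record: values `s_j` in mV and times `t_j` in
#' seconds relative to the slice start (`times[1] == 0`). Heartbeat slices
#' span exactly one RR interval, from one R peak to (but not including) the
#' next.
#'
#' @param values Numeric vector of voltages (mV).
#' @param times Numeric vector of times (s), strictly increasing, starting
#'   at 0; same length as `values`.
#' @param record_id Identifier of the source record.
#' @param start_index 0-based sample index of the slice start in the source.
#' @param kind One of `"RANDOM"`, `"RPEAK_ALIGNED"`, `"HEARTBEAT"`.
#' @return An object of class `ecg_slice`.
#' @export
ecg_slice <- function(values, times, record_id, start_index,
                      kind = c("RANDOM", "RPEAK_ALIGNED", "HEARTBEAT")) {
  kind <- match.arg(kind)
  if (length(values) != length(times)) {
    stop("ecg_slice: values and times must have equal length", call. = FALSE)
  }
  if (length(times) == 0 || times[1] != 0) {
    stop("ecg_slice: times must be non-empty and start at 0", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("ecg_slice: times must be strictly increasing", call. = FALSE)
  }
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 record_id = as.character(record_id),
                 start_index = as.integer(start_index), kind = kind),
            class = "ecg_slice")
}

#' @export
print.ecg_slice <- function(x, ...) {
  cat(sprintf("<ecg_slice %s '%s'> %d samples, %.3f s from index %d\n",
              x$kind, x$record_id, length(x$values), slice_duration(x),
              x$start_index))
  invisible(x)
}

#' Duration of a slice in seconds
#'
#' For heartbeat slices this is the RR interval the beat spans (the slice is
#' half-open, so the duration extends one sample step past the last time).
#'
#' @param slice An [ecg_slice()].
#' @return Positive scalar duration.
#' @export
slice_duration <- function(slice) {
  n <- length(slice$times)
  if (n == 1) return(slice$times[1] + 1e-9)
  step <- slice$times[n] - slice$times[n - 1]
  slice$times[n] + step
}

slice_from_record <- function(record, start0, n_samp, kind) {
  idx <- (start0 + 1):(start0 + n_samp)
  ecg_slice(record$samples[idx], (seq_len(n_samp) - 1) / record$fs,
            record$record_id, start0, kind)
}

#' Random slicing
#'
#' Extracts `n_slices` subsequences starting at uniformly random samples,
#' each with duration drawn uniformly in `[1.5, 4.0]` s (truncated to fit
#' the record). The workhorse augmentation strategy for training the
#' full-parameter autoencoder variant, which learns its own phase shift.
#'
#' @param record An [ecg_record()] of at least 4 s.
#' @param n_slices Number of slices.
#' @param seed Integer seed; output is a pure function of
#'   `(record, n_slices, seed)`.
#' @return List of [ecg_slice()]s of kind `"RANDOM"`.
#' @export
slice_random <- function(record, n_slices, seed = 1L) {
  validate_ecg_record(record)
  if (record_duration(record) < 4.0) {
    stop("slice_random: record must be at least 4 s long", call. = FALSE)
  }
  if (n_slices == 0) return(list())
  n <- length(record$samples)
  with_seed(seed, {
    starts <- sample.int(n - ceiling(1.5 * record$fs), n_slices,
                         replace = TRUE) - 1L
    durs <- runif(n_slices, 1.5, 4.0)
    lapply(seq_len(n_slices), function(i) {
      n_samp <- min(round(durs[i] * record$fs), n - starts[i])
      slice_from_record(record, starts[i], n_samp, "RANDOM")
    })
  })
}

#' R-peak-aligned slicing
#'
#' Like [slice_random()], but every slice starts exactly at one of the
#' detected R peaks, so all slices are aligned to the same point of the
#' cardiac cycle and the shift parameter becomes unnecessary downstream.
#' Durations are drawn uniformly in `[1.5, 4.0]` s.
#'
#' @param record An [ecg_record()].
#' @param rpeaks An [rpeak_list()] for the record.
#' @param n_slices Number of slices.
#' @param seed Integer seed.
#' @return List of [ecg_slice()]s of kind `"RPEAK_ALIGNED"`.
#' @export
slice_rpeak_aligned <- function(record, rpeaks, n_slices, seed = 1L) {
  validate_ecg_record(record)
  stopifnot(inherits(rpeaks, "rpeak_list"))
  n <- length(record$samples)
  eligible <- rpeaks$indices[rpeaks$indices + 1.5 * record$fs <= n]
  if (length(eligible) == 0) {
    stop("slice_rpeak_aligned: no R peak with 1.5 s of signal after it",
         call. = FALSE)
  }
  if (n_slices == 0) return(list())
  with_seed(seed, {
    starts <- eligible[sample.int(length(eligible), n_slices, replace = TRUE)]
    durs <- runif(n_slices, 1.5, 4.0)
    lapply(seq_len(n_slices), function(i) {
      n_samp <- min(round(durs[i] * record$fs), n - starts[i])
      slice_from_record(record, starts[i], n_samp, "RPEAK_ALIGNED")
    })
  })
}

#' Heartbeat extraction
#'
#' One slice per pair of consecutive R peaks, covering the half-open sample
#' interval `[r_k, r_{k+1})`, so the beats tile the signal between the first
#' and last peak without overlap. Beats whose RR interval falls outside
#' `[0.3, 2.0]` s (detector glitches, pauses) are dropped; the number of
#' rejected beats is attached as attribute `"rejected"`.
#'
#' @param record An [ecg_record()].
#' @param rpeaks An [rpeak_list()]; fewer than two peaks gives an empty list
#'   with a warning.
#' @return List of [ecg_slice()]s of kind `"HEARTBEAT"`, ordered by start
#'   index, with attribute `"rejected"`.
#' @export
extract_heartbeats <- function(record, rpeaks) {
  validate_ecg_record(record)
  stopifnot(inherits(rpeaks, "rpeak_list"))
  idx <- rpeaks$indices
  if (length(idx) < 2) {
    warning("extract_heartbeats: fewer than two R peaks; no beats extracted")
    return(structure(list(), rejected = 0L))
  }
  rr <- diff(idx) / record$fs
  ok <- rr >= 0.3 & rr <= 2.0
  beats <- lapply(which(ok), function(k) {
    slice_from_record(record, idx[k], idx[k + 1] - idx[k], "HEARTBEAT")
  })
  structure(beats, rejected = sum(!ok))
}
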