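#' R-peak list
#'
#' Sample indices (0-based) of detected R peaks, together with the sampling
#' rate needed to convert them to seconds. Successive peaks are at least the
#' physiological refractory period (0.2 s) apart.
#'
#' @param indices Strictly increasing non-negative integer vector.
#' @param fs Sampling frequency in Hz.
#' @return An object of class `rpeak_list`.
#' @export
rpeak_list <- function(indices, fs) {
  indices <- as.integer(round(indices))
  if (length(indices) > 1 && any(diff(indices) <= 0)) {
    stop("rpeak_list: indices must be strictly increasing", call. = FALSE)
  }
  if (length(indices) > 0 && any(indices < 0)) {
    stop("rpeak_list: indices must be non-negative", call. = FALSE)
  }
  structure(list(indices = indices, fs = fs), class = "rpeak_list")
}

#' @export
print.rpeak_list <- function(x, ...) {
  cat(sprintf("<rpeak_list> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Pan-Tompkins QRS detection
#'
#' The classic real-time QRS detector, run offline: band-pass 5-15 Hz
#' (zero-phase, forward-backward second-order Butterworth sections),
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' adaptive dual-threshold peak picking with a 200 ms refractory period and
#' a search-back pass triggered when no QRS is found within 1.66 times the
#' running RR average. Each integrator detection is refined to the local
#' maximum of the raw signal within +/-50 ms, so the returned indices anchor
#' at the R apex itself.
#'
#' Thresholds are initialized from the first 2 s of the integrated signal,
#' which keeps the output fully deterministic.
#'
#' @param record An [ecg_record()]; at least 2 s long, `fs >= 100` Hz.
#' @return An [rpeak_list()]. Zero detections give an empty list, not an
#'   error.
#' @export
pan_tompkins <- function(record) {
  validate_ecg_record(record)
  fs <- record$fs
  x <- record$samples
  x <- x - mean(x)  # detection invariant to constant voltage offsets
  if (length(x) < 2 * fs) {
    stop("pan_tompkins: record must be at least 2 s long", call. = FALSE)
  }
  if (fs < 100) stop("pan_tompkins: fs must be >= 100 Hz", call. = FALSE)

  # band-pass 5-15 Hz as two zero-phase biquads
  bp_lo <- signal::butter(2, 15 / (fs / 2), type = "low")
  bp_hi <- signal::butter(2, 5 / (fs / 2), type = "high")
  xf <- signal::filtfilt(bp_hi, signal::filtfilt(bp_lo, x))

  # five-point derivative (Pan & Tompkins 1985 kernel), squared
  der <- stats::filter(xf, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2

  # 150 ms moving-window integration
  nw <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / nw, nw), sides = 2))
  integ[is.na(integ)] <- 0

  peaks <- local_maxima(integ, min_dist = round(0.2 * fs))
  if (length(peaks) == 0) return(rpeak_list(integer(0), fs))

  # adaptive dual thresholds, warm-started from the first 2 s
  warm <- integ[seq_len(round(2 * fs))]
  spki <- max(warm) * 0.4
  npki <- mean(warm) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf
  refractory <- round(0.2 * fs)
  i <- 1L
  while (i <= length(peaks)) {
    p <- peaks[i]
    v <- integ[p]
    if (p - last_qrs >= refractory && v > thr1) {
      qrs <- c(qrs, p)
      if (is.finite(last_qrs)) {
        rr_hist <- utils::tail(c(rr_hist, p - last_qrs), 8)
      }
      last_qrs <- p
      spki <- 0.125 * v + 0.875 * spki
    } else {
      # search-back: no QRS within 1.66 * running RR -> accept the largest
      # candidate above the lower threshold in the missed stretch
      rr_avg <- if (length(rr_hist) > 0) mean(rr_hist) else fs
      if (is.finite(last_qrs) && (p - last_qrs) > 1.66 * rr_avg) {
        back <- peaks[peaks > last_qrs + refractory & peaks <= p]
        back <- back[integ[back] > 0.5 * thr1]
        if (length(back) > 0) {
          pb <- back[which.max(integ[back])]
          qrs <- c(qrs, pb)
          rr_hist <- utils::tail(c(rr_hist, pb - last_qrs), 8)
          last_qrs <- pb
          spki <- 0.25 * integ[pb] + 0.75 * spki
          i <- which(peaks > pb)[1]
          if (is.na(i)) break
          next
        }
      }
      npki <- 0.125 * v + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1L
  }
  if (length(qrs) == 0) return(rpeak_list(integer(0), fs))

  # refine to the raw-signal apex within +/-50 ms
  half <- round(0.05 * fs)
  refined <- vapply(qrs, function(p) {
    lo <- max(1L, p - half); hi <- min(length(x), p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement (keep earlier peak)
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= refractory)
    while (!all(keep)) {
      refined <- refined[keep]
      keep <- c(TRUE, diff(refined) >= refractory)
    }
  }
  rpeak_list(refined - 1L, fs)  # 0-based
}

# indices of local maxima separated by at least min_dist samples
local_maxima <- function(v, min_dist) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (p in cand) {
    if (all(abs(taken - p) >= min_dist)) taken <- c(taken, p)
  }
  sort(taken)
}

#' RR intervals from an R-peak list
#'
#' First differences of the peak indices divided by the sampling rate; the
#' RR tachogram whose irregularity is the classic AF marker.
#'
#' @param rpeaks An [rpeak_list()] with at least two peaks.
#' @return Numeric vector of RR intervals in seconds.
#' @export
rr_intervals <- function(rpeaks) {
  stopifnot(inherits(rpeaks, "rpeak_list"))
  if (length(rpeaks$indices) < 2) {
    stop("rr_intervals: need at least two R peaks", call. = FALSE)
  }
  diff(rpeaks$indices) / rpeaks$fs
}
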