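#' Single-lead ECG record
#'
#' The central container of the package: one lead of an ECG as a numeric
#' vector in millivolts together with its sampling rate, an optional
#' record-level rhythm label and optional per-beat annotations. Sample
#' indices are 0-based everywhere in this package; sample `k` occurs at
#' `k / fs` seconds.
#'
#' @param record_id Character scalar identifying the record.
#' @param samples Numeric vector of voltages in mV (non-empty, finite).
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param rhythm_label Optional record-level rhythm class, one of
#'   `"NSR"`, `"AF"`, `"OTHER"`, `"NOISY"`.
#' @param beat_annotations Optional data frame with columns `sample`
#'   (0-based sample indices, strictly increasing, all `< length(samples)`)
#'   and `af` (logical AF flag per beat).
#' @param source_lead 0-based index of the lead this record was taken from
#'   in its source file (multi-lead sources are reduced to one lead).
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs, rhythm_label = NULL,
                       beat_annotations = NULL, source_lead = 0L) {
  rec <- structure(
    list(
      record_id = as.character(record_id)[1],
      samples = as.numeric(samples),
      fs = as.numeric(fs)[1],
      rhythm_label = rhythm_label,
      beat_annotations = beat_annotations,
      source_lead = as.integer(source_lead)[1]
    ),
    class = "ecg_record"
  )
  validate_ecg_record(rec)
}

rhythm_levels <- c("NSR", "AF", "OTHER", "NOISY")

#' Validate an `ecg_record`
#'
#' Checks the type's invariants and returns the record invisibly unchanged;
#' stops with an informative error on the first violated invariant.
#'
#' @param rec An `ecg_record`.
#' @return `rec`, invisibly on validation paths, visibly when called directly.
#' @export
validate_ecg_record <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  if (length(rec$samples) == 0) {
    stop("ecg_record: 'samples' must be non-empty", call. = FALSE)
  }
  if (!is.finite(rec$fs) || rec$fs <= 0) {
    stop("ecg_record: 'fs' must be a positive number", call. = FALSE)
  }
  if (anyNA(rec$samples) || any(!is.finite(rec$samples))) {
    stop("ecg_record: 'samples' must be finite", call. = FALSE)
  }
  if (!is.null(rec$rhythm_label) &&
      !rec$rhythm_label %in% rhythm_levels) {
    stop("ecg_record: 'rhythm_label' must be one of ",
         paste(rhythm_levels, collapse = ", "), call. = FALSE)
  }
  ann <- rec$beat_annotations
  if (!is.null(ann)) {
    if (!is.data.frame(ann) || !all(c("sample", "af") %in% names(ann))) {
      stop("ecg_record: 'beat_annotations' needs columns 'sample' and 'af'",
           call. = FALSE)
    }
    if (nrow(ann) > 0) {
      s <- ann$sample
      if (any(s < 0) || any(s >= length(rec$samples))) {
        stop("ecg_record: annotation sample indices out of range",
             call. = FALSE)
      }
      if (nrow(ann) > 1 && any(diff(s) <= 0)) {
        stop("ecg_record: annotation sample indices must be strictly increasing",
             call. = FALSE)
      }
      if (!is.logical(ann$af)) {
        stop("ecg_record: annotation 'af' column must be logical", call. = FALSE)
      }
    }
  }
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$samples), x$fs, dur))
  if (!is.null(x$rhythm_label)) cat("  rhythm:", x$rhythm_label, "\n")
  if (!is.null(x$beat_annotations)) {
    cat(sprintf("  beats: %d annotated (%d AF)\n",
                nrow(x$beat_annotations), sum(x$beat_annotations$af)))
  }
  invisible(x)
}

#' Duration of a record in seconds
#' @param rec An `ecg_record`.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
record_duration <- function(rec) length(rec$samples) / rec$fs

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed, below 2^31.
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
}
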