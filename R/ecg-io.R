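#' Read a WFDB record as a single-lead `ecg_record`
#'
#' Parses the WFDB header (`.hea`) and signal (`.dat`) files used by the
#' PhysioNet databases and returns the requested lead converted to mV using
#' the header's gain and baseline. Signal formats 16 (16-bit little-endian)
#' and 212 (packed 12-bit pairs) are supported, which covers the
#' PhysioNet/CinC 2017 and MIT-BIH family of records. If an annotation file
#' is present, beat annotations with AF flags (derived from rhythm-change
#' annotations) are attached. No filtering or normalization is applied.
#'
#' When the header carries no gain (or gain 0), raw integer values are
#' returned as mV unchanged.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param lead 0-based lead index; multi-lead records are reduced to this
#'   lead.
#' @param annotator Extension of the annotation file to look for (default
#'   `"atr"`); `NULL` skips annotations.
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path, lead = 0L, annotator = "atr") {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) {
    stop("WFDB header not found: ", hea_path, call. = FALSE)
  }
  hdr <- parse_wfdb_header(hea_path)
  if (lead < 0 || lead >= hdr$nsig) {
    stop("lead ", lead, " out of range for a ", hdr$nsig, "-lead record",
         call. = FALSE)
  }
  sig <- hdr$signals[lead + 1, ]
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path)) {
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  }
  raw_mat <- read_wfdb_dat(dat_path, hdr$fmt, hdr$nsig, hdr$nsamp)
  adc <- raw_mat[, lead + 1]
  mv <- if (is.na(sig$gain) || sig$gain == 0) as.numeric(adc)
        else (adc - sig$baseline) / sig$gain

  ann <- NULL
  label <- NULL
  if (!is.null(annotator)) {
    ann_path <- paste0(base, ".", annotator)
    if (file.exists(ann_path)) {
      raw_ann <- read_wfdb_annotations(ann_path)
      ann <- beat_af_flags(raw_ann)
      ann <- ann[ann$sample < length(mv), , drop = FALSE]
      if (nrow(ann) == 0) ann <- NULL
    }
  }
  ecg_record(hdr$name, mv, hdr$fs, rhythm_label = label,
             beat_annotations = ann, source_lead = lead)
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- top[1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sigs <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "0"
    gain_num <- sub("^([-0-9.]+).*$", "\\1", gain_field)
    gain <- suppressWarnings(as.numeric(gain_num))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(baseline)) baseline <- 0
    data.frame(file = f[1], fmt = as.integer(f[2]),
               gain = gain, baseline = baseline,
               stringsAsFactors = FALSE)
  })
  sigs <- do.call(rbind, sigs)
  if (length(unique(sigs$fmt)) != 1) {
    stop("mixed WFDB signal formats are not supported", call. = FALSE)
  }
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp,
       fmt = sigs$fmt[1], signals = sigs)
}

read_wfdb_dat <- function(dat_path, fmt, nsig, nsamp) {
  bytes <- readBin(dat_path, "raw", file.info(dat_path)$size)
  if (fmt == 16) {
    vals <- readBin(bytes, "integer", n = length(bytes) %/% 2, size = 2,
                    signed = TRUE, endian = "little")
    n <- length(vals) %/% nsig
    mat <- matrix(vals[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  } else if (fmt == 212) {
    nb <- (length(bytes) %/% 3) * 3
    b <- as.integer(bytes[seq_len(nb)])
    b1 <- b[seq(1, nb, 3)]; b2 <- b[seq(2, nb, 3)]; b3 <- b[seq(3, nb, 3)]
    s1 <- bitwAnd(b2, 0x0F) * 256L + b1
    s2 <- bitwAnd(b2, 0xF0L) %/% 16L * 256L + b3
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    vals <- as.vector(rbind(s1, s2))
    n <- length(vals) %/% nsig
    mat <- matrix(vals[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  } else {
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE)
  }
  if (!is.na(nsamp) && nsamp > 0 && nsamp <= nrow(mat)) {
    mat <- mat[seq_len(nsamp), , drop = FALSE]
  }
  mat
}

#' Write an `ecg_record` as a WFDB record (format 16)
#'
#' Writes a `.hea`/`.dat` pair with gain 200 adu/mV and baseline 0, the
#' conventional resolution of the PhysioNet/CinC 2017 records. If the
#' record carries beat annotations, a MIT-format annotation file is written
#' alongside (beat code N, with rhythm-change annotations marking AF
#' stretches).
#'
#' @param record An [ecg_record()].
#' @param path Output path without extension.
#' @param annotator Extension for the annotation file (default `"atr"`).
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(record, path, annotator = "atr") {
  validate_ecg_record(record)
  gain <- 200
  adc <- as.integer(round(record$samples * gain))
  if (any(abs(adc) > 32767)) {
    stop("signal exceeds the 16-bit range at gain 200", call. = FALSE)
  }
  name <- basename(path)
  hea <- c(
    sprintf("%s 1 %g %d", name, record$fs, length(adc)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", name, gain, adc[1])
  )
  writeLines(hea, paste0(path, ".hea"))
  writeBin(adc, paste0(path, ".dat"), size = 2, endian = "little")
  ann <- record$beat_annotations
  if (!is.null(ann) && nrow(ann) > 0) {
    df <- data.frame(sample = ann$sample, code = 1L,
                     aux = NA_character_, stringsAsFactors = FALSE)
    # rhythm-change annotations at AF onsets/offsets
    state <- c(FALSE, ann$af[-length(ann$af)])
    change <- which(ann$af != state | seq_len(nrow(ann)) == 1L)
    rhy <- data.frame(sample = ann$sample[change] - 1L, code = 28L,
                      aux = ifelse(ann$af[change], "(AFIB", "(N"),
                      stringsAsFactors = FALSE)
    rhy$sample <- pmax(rhy$sample, 0L)
    df <- rbind(df, rhy)
    df <- df[order(df$sample, df$code), ]
    write_wfdb_annotations(df, paste0(path, ".", annotator))
  }
  invisible(path)
}

#' Read a MIT-format annotation file
#'
#' Decodes the packed binary annotation stream used by PhysioNet (`.atr`
#' and friends): per-annotation 6-bit type codes with 10-bit time
#' increments, plus the SKIP/NUM/SUB/CHN/AUX pseudo-annotations. Rhythm
#' changes arrive as code 28 with an aux string such as `"(AFIB"`.
#'
#' @param path Path to the annotation file.
#' @return Data frame with columns `sample` (0-based), `code` (integer
#'   annotation type) and `aux` (character or `NA`).
#' @export
read_wfdb_annotations <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  i <- 1L
  time <- 0
  out_sample <- numeric(0); out_code <- integer(0); out_aux <- character(0)
  pending_aux <- NA_character_
  while (i + 1L <= length(bytes)) {
    word <- bytes[i] + 256L * bytes[i + 1L]
    i <- i + 2L
    code <- word %/% 1024L
    data <- word %% 1024L
    if (code == 0L && data == 0L) break
    if (code == 59L) {  # SKIP: 4-byte interval, high word first
      if (i + 3L > length(bytes)) stop("truncated SKIP annotation", call. = FALSE)
      hi <- bytes[i] + 256L * bytes[i + 1L]
      lo <- bytes[i + 2L] + 256L * bytes[i + 3L]
      i <- i + 4L
      time <- time + hi * 65536 + lo
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN: modify the previous annotation; ignored here
    } else if (code == 63L) {  # AUX: data = byte count, padded to even
      nbytes <- data
      aux_raw <- bytes[i:(i + nbytes - 1L)]
      i <- i + nbytes + (nbytes %% 2L)
      aux <- rawToChar(as.raw(aux_raw[aux_raw != 0L]))
      if (length(out_code) > 0) out_aux[length(out_aux)] <- aux
      else pending_aux <- aux
    } else {
      time <- time + data
      out_sample <- c(out_sample, time)
      out_code <- c(out_code, code)
      out_aux <- c(out_aux, NA_character_)
    }
  }
  data.frame(sample = out_sample, code = out_code, aux = out_aux,
             stringsAsFactors = FALSE)
}

#' Write a MIT-format annotation file
#'
#' Inverse of [read_wfdb_annotations()] for annotation streams whose
#' inter-annotation gaps fit in 10 bits (larger gaps are encoded with SKIP
#' pseudo-annotations).
#'
#' @param ann Data frame with columns `sample`, `code`, `aux`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(ann, path) {
  stopifnot(all(c("sample", "code") %in% names(ann)))
  if (is.unsorted(ann$sample)) ann <- ann[order(ann$sample), ]
  con <- file(path, "wb")
  on.exit(close(con))
  put_word <- function(w) {
    writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
  }
  time <- 0
  for (k in seq_len(nrow(ann))) {
    gap <- ann$sample[k] - time
    if (gap > 1023) {
      put_word(59L * 1024L)
      hi <- floor(gap / 65536); lo <- gap - hi * 65536
      put_word(as.integer(hi)); put_word(as.integer(lo))
      gap <- 0
    }
    put_word(as.integer(ann$code[k]) * 1024L + as.integer(gap))
    time <- ann$sample[k]
    aux <- if ("aux" %in% names(ann)) ann$aux[k] else NA_character_
    if (!is.na(aux) && nzchar(aux)) {
      ab <- charToRaw(aux)
      put_word(63L * 1024L + length(ab))
      writeBin(ab, con)
      if (length(ab) %% 2L == 1L) writeBin(as.raw(0L), con)
    }
  }
  put_word(0L)
  invisible(path)
}

# standard MIT beat annotation codes (N, L, R, A, a, J, S, V, F, e, j, E, ...)
wfdb_beat_codes <- c(1:13, 25L, 34L, 35L, 38L)

#' Per-beat AF flags from raw annotations
#'
#' Maps a raw annotation stream to one row per beat with an AF flag: beats
#' are the annotations with beat-type codes, and the flag tracks the most
#' recent rhythm-change annotation (aux starting `"(AFIB"` switches AF on,
#' any other rhythm string switches it off). Records with no rhythm
#' annotations get all-`FALSE` flags.
#'
#' @param ann Data frame from [read_wfdb_annotations()].
#' @return Data frame with columns `sample` and `af`, one row per beat.
#' @export
beat_af_flags <- function(ann) {
  af_state <- FALSE
  samples <- numeric(0); flags <- logical(0)
  for (k in seq_len(nrow(ann))) {
    if (ann$code[k] == 28L && !is.na(ann$aux[k])) {
      af_state <- startsWith(ann$aux[k], "(AFIB")
    } else if (ann$code[k] %in% wfdb_beat_codes) {
      samples <- c(samples, ann$sample[k])
      flags <- c(flags, af_state)
    }
  }
  keep <- !duplicated(samples)
  data.frame(sample = samples[keep], af = flags[keep])
}

# ---- internal plain-text container ----------------------------------------

#' Write an `ecg_record` in the package's plain-text interchange format
#'
#' A line-oriented text container that round-trips every field losslessly:
#' doubles are printed with 17 significant digits, which reconstructs the
#' exact 64-bit value.
#'
#' @param record An [ecg_record()].
#' @param path Output path (conventionally `.ecg`).
#' @return `path`, invisibly.
#' @export
write_internal <- function(record, path) {
  validate_ecg_record(record)
  ann <- record$beat_annotations
  n_beats <- if (is.null(ann)) 0L else nrow(ann)
  lines <- c(
    "#cyclebeat-ecg 1",
    paste0("record_id\t", record$record_id),
    sprintf("fs\t%.17g", record$fs),
    paste0("source_lead\t", record$source_lead),
    paste0("rhythm_label\t",
           if (is.null(record$rhythm_label)) "." else record$rhythm_label),
    paste0("n_beats\t", n_beats)
  )
  if (n_beats > 0) {
    lines <- c(lines, sprintf("beat\t%d\t%d", as.integer(ann$sample),
                              as.integer(ann$af)))
  }
  lines <- c(lines, paste0("n_samples\t", length(record$samples)),
             sprintf("%.17g", record$samples))
  writeLines(lines, path)
  invisible(path)
}

#' Read a record written by [write_internal()]
#'
#' @param path Path to the file.
#' @return The reconstructed [ecg_record()]; malformed files raise a parse
#'   error naming the offending field.
#' @export
read_internal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7 || lines[1] != "#cyclebeat-ecg 1") {
    stop("parse error: missing '#cyclebeat-ecg 1' magic line", call. = FALSE)
  }
  take <- function(i, field) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || parts[1] != field) {
      stop("parse error in field '", field, "' (line ", i, ")", call. = FALSE)
    }
    parts[2]
  }
  record_id <- take(2, "record_id")
  fs <- as.numeric(take(3, "fs"))
  if (is.na(fs)) stop("parse error in field 'fs': not a number", call. = FALSE)
  source_lead <- as.integer(take(4, "source_lead"))
  label <- take(5, "rhythm_label")
  if (label == ".") label <- NULL
  n_beats <- as.integer(take(6, "n_beats"))
  if (is.na(n_beats) || n_beats < 0) {
    stop("parse error in field 'n_beats'", call. = FALSE)
  }
  ann <- NULL
  off <- 6L
  if (n_beats > 0) {
    rows <- lines[off + seq_len(n_beats)]
    parts <- strsplit(rows, "\t", fixed = TRUE)
    if (any(vapply(parts, function(p) length(p) != 3 || p[1] != "beat",
                   logical(1)))) {
      stop("parse error in field 'beat'", call. = FALSE)
    }
    ann <- data.frame(
      sample = as.numeric(vapply(parts, `[`, character(1), 2)),
      af = as.integer(vapply(parts, `[`, character(1), 3)) == 1L
    )
    if (nrow(ann) > 1 && any(diff(ann$sample) <= 0)) {
      stop("parse error in field 'beat': sample indices must be strictly ",
           "increasing", call. = FALSE)
    }
    off <- off + n_beats
  }
  n_samples <- as.integer(take(off + 1L, "n_samples"))
  if (is.na(n_samples) || n_samples <= 0) {
    stop("parse error in field 'n_samples'", call. = FALSE)
  }
  samp_lines <- lines[off + 1L + seq_len(n_samples)]
  samples <- as.numeric(samp_lines)
  if (length(samples) != n_samples || anyNA(samples)) {
    stop("parse error in field 'samples': expected ", n_samples,
         " numeric lines", call. = FALSE)
  }
  ecg_record(record_id, samples, fs, rhythm_label = label,
             beat_annotations = ann, source_lead = source_lead)
}

#' Export a record as CSV for inspection
#'
#' Two columns: `t_seconds` (0-based sample time) and `mv`.
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  validate_ecg_record(record)
  df <- data.frame(
    t_seconds = (seq_along(record$samples) - 1) / record$fs,
    mv = record$samples
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
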