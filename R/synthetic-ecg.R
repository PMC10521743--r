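#' Configuration for the synthetic single-lead ECG generator
#'
#' The generator emulates the kind of data the pipeline is built for:
#' 300 Hz single-lead recordings in a +/-5 mV range with P-QRS-T morphology,
#' controllable mean heart rate and RR-interval irregularity, optional
#' P-wave suppression (the hallmark of atrial fibrillation), additive white
#' noise and noise-only records.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration_s Record duration in seconds.
#' @param mean_hr_bpm Mean heart rate in beats per minute, in `[30, 220]`.
#' @param rr_cv Coefficient of variation of the RR intervals, in `[0, 0.5]`.
#'   `0` gives a metronomic rhythm; AF-like irregularity starts around 0.15.
#' @param p_wave_amplitude P-wave amplitude in mV; `0` suppresses P waves.
#' @param noise_sd Standard deviation of additive white Gaussian noise (mV).
#' @param noise_only If `TRUE` the record contains only noise and baseline
#'   wander: no beats, rhythm label `"NOISY"`.
#' @param rr_alternation Bigeminy-like alternation: consecutive RR intervals
#'   are scaled by `1 + a, 1 - a, 1 + a, ...`. `0` disables it.
#' @param seed Integer seed; the record is fully reproducible from it.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 300, duration_s = 30, mean_hr_bpm = 75,
                         rr_cv = 0.05, p_wave_amplitude = 0.15,
                         noise_sd = 0.02, noise_only = FALSE,
                         rr_alternation = 0, seed = 1L) {
  if (rr_cv < 0 || rr_cv > 0.5) stop("rr_cv must be in [0, 0.5]", call. = FALSE)
  if (mean_hr_bpm < 30 || mean_hr_bpm > 220) {
    stop("mean_hr_bpm must be in [30, 220]", call. = FALSE)
  }
  if (fs <= 0 || duration_s <= 0 || noise_sd < 0 || p_wave_amplitude < 0) {
    stop("fs and duration_s must be positive; amplitudes non-negative",
         call. = FALSE)
  }
  if (rr_alternation < 0 || rr_alternation > 0.6) {
    stop("rr_alternation must be in [0, 0.6]", call. = FALSE)
  }
  structure(list(fs = fs, duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
                 rr_cv = rr_cv, p_wave_amplitude = p_wave_amplitude,
                 noise_sd = noise_sd, noise_only = noise_only,
                 rr_alternation = rr_alternation, seed = as.integer(seed)),
            class = "synth_config")
}

# Beat morphology: five Gaussian bumps at fixed fractions of the RR cycle.
# The cycle starts at the R peak; the P and Q bumps near the end of a cycle
# are the atrial activity preceding the *next* R peak, so beats tile into a
# continuous periodic signal. Widths scale with RR so one-beat time
# normalization leaves the morphology invariant.
wave_table <- function(p_amp) {
  data.frame(
    wave = c("R", "S", "T", "P", "Q"),
    amp = c(1.0, -0.2, 0.3, p_amp, -0.1),
    frac = c(0.0, 0.045, 0.28, 0.80, 0.96),
    width = c(0.014, 0.016, 0.05, 0.035, 0.012)
  )
}

#' Generate one synthetic ECG record with ground truth
#'
#' RR intervals are drawn i.i.d. from a log-normal law with the configured
#' mean and coefficient of variation, clipped to `[0.3, 2.0]` s. Each beat is
#' a sum of five Gaussian bumps (P, Q, R, S, T) placed at fixed phase
#' fractions of its RR interval, so the R-peak times are known exactly. A
#' 0.05 mV, 0.3 Hz sinusoidal baseline wander and white Gaussian noise are
#' added. Noise-only records contain noise plus baseline wander and carry no
#' beats.
#'
#' @param config A [synth_config()].
#' @return A list with elements `record` (an [ecg_record()]) and `truth`
#'   (class `synth_truth`: `r_peak_times_s`, `rr_intervals_s`,
#'   `rhythm_label`).
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_record_impl(config))
}

generate_record_impl <- function(config) {
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  wander <- 0.05 * sin(2 * pi * 0.3 * t)

  if (config$noise_only) {
    x <- wander + rnorm(n, 0, max(config$noise_sd, 1e-12))
    rec <- ecg_record("synth", x, fs, rhythm_label = "NOISY")
    truth <- structure(list(r_peak_times_s = numeric(0),
                            rr_intervals_s = numeric(0),
                            rhythm_label = "NOISY"),
                       class = "synth_truth")
    return(list(record = rec, truth = truth))
  }

  mean_rr <- 60 / config$mean_hr_bpm
  t0 <- 0.05
  # draw RR intervals until the record is covered
  max_beats <- ceiling(config$duration_s / 0.3) + 2
  if (config$rr_cv > 0) {
    s2 <- log(1 + config$rr_cv^2)
    rr <- rlnorm(max_beats, meanlog = log(mean_rr) - s2 / 2, sdlog = sqrt(s2))
  } else {
    rr <- rep(mean_rr, max_beats)
  }
  if (config$rr_alternation > 0) {
    a <- config$rr_alternation
    rr <- rr * rep_len(c(1 + a, 1 - a), length(rr))
  }
  rr <- pmin(pmax(rr, 0.3), 2.0)
  ends <- t0 + cumsum(rr)
  keep <- which(ends <= config$duration_s - 1 / fs)
  if (length(keep) == 0) {
    stop("duration_s too short for a single beat at this heart rate",
         call. = FALSE)
  }
  rr <- rr[keep]
  r_times <- t0 + c(0, cumsum(rr[-length(rr)]))

  x <- wander
  waves <- wave_table(config$p_wave_amplitude)
  for (k in seq_along(rr)) {
    for (w in seq_len(nrow(waves))) {
      center <- r_times[k] + waves$frac[w] * rr[k]
      sigma <- waves$width[w] * rr[k]
      lo <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
      hi <- min(n, ceiling((center + 5 * sigma) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] +
        waves$amp[w] * exp(-((t[idx] - center)^2) / (2 * sigma^2))
    }
  }
  if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)

  label <- if (config$p_wave_amplitude == 0 && config$rr_cv >= 0.15) "AF"
           else if (config$rr_alternation > 0) "OTHER"
           else "NSR"
  rec <- ecg_record("synth", x, fs, rhythm_label = label)
  truth <- structure(list(r_peak_times_s = r_times,
                          rr_intervals_s = rr[-length(rr)],
                          rhythm_label = label),
                     class = "synth_truth")
  # truth invariant: diffs of peak times equal the RR intervals
  list(record = rec, truth = truth)
}

# Study conditions per rhythm class, used by generate_dataset(). Heart rates
# are drawn per record from plausible resting ranges; AF combines suppressed
# P waves with strongly irregular RR, OTHER is a bigeminy-like alternation,
# NOISY is noise-only at a noise level that buries the QRS.
class_condition <- function(class) {
  switch(class,
    NSR = list(rr_cv = 0.03, p = 0.15, noise = 0.02, alt = 0, only = FALSE),
    AF = list(rr_cv = 0.25, p = 0, noise = 0.02, alt = 0, only = FALSE),
    OTHER = list(rr_cv = 0.03, p = 0.15, noise = 0.02, alt = 0.3, only = FALSE),
    NOISY = list(rr_cv = 0.03, p = 0.15, noise = 0.3, alt = 0, only = TRUE)
  )
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_records` records with rhythm classes in the given proportions.
#' `NSR` records have mildly variable RR (`rr_cv = 0.03`) with P waves, `AF`
#' records combine suppressed P waves with `rr_cv = 0.25`, `OTHER` records
#' are bigeminy-like alternations of short and long cycles, and `NOISY`
#' records are noise-only. Mean heart rate is drawn uniformly per record
#' (55-90 bpm; 70-110 bpm for AF). Per-record seeds are derived
#' deterministically from `seed`.
#'
#' @param n_records Number of records (non-negative).
#' @param class_mix Named numeric vector of proportions over
#'   `c("NSR", "AF", "OTHER", "NOISY")`, summing to 1.
#' @param seed Master seed.
#' @param duration_s Duration of each record in seconds.
#' @param fs Sampling frequency in Hz.
#' @return A list of `list(record, truth)` pairs.
#' @export
generate_dataset <- function(n_records,
                             class_mix = c(NSR = 0.5, AF = 0.5, OTHER = 0,
                                           NOISY = 0),
                             seed = 1L, duration_s = 30, fs = 300) {
  if (n_records < 0) stop("n_records must be non-negative", call. = FALSE)
  if (n_records == 0) return(list())
  mix <- rep(0, 4)
  names(mix) <- rhythm_levels
  mix[names(class_mix)] <- class_mix
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("class_mix proportions must sum to 1", call. = FALSE)
  }
  # largest-remainder apportionment: exact counts at divisible n
  raw <- mix * n_records
  counts <- floor(raw)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(rhythm_levels, counts)

  with_seed(seed, {
    classes <- sample(classes)
    hr <- ifelse(classes == "AF", runif(n_records, 70, 110),
                 runif(n_records, 55, 90))
  })

  lapply(seq_len(n_records), function(i) {
    cond <- class_condition(classes[i])
    cfg <- synth_config(fs = fs, duration_s = duration_s,
                        mean_hr_bpm = hr[i], rr_cv = cond$rr_cv,
                        p_wave_amplitude = cond$p, noise_sd = cond$noise,
                        noise_only = cond$only, rr_alternation = cond$alt,
                        seed = derive_seed(seed, i))
    out <- generate_record(cfg)
    out$record$record_id <- sprintf("synth-%04d", i)
    out
  })
}
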