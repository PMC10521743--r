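# Shared fixtures. Trained models are cached so several test files (and the
# acceptance suite) can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# heartbeats pooled from clean constant-rate synthetic records
fixed_hr_beats <- function(n_beats, hr = 75, rr_cv = 0, noise_sd = 0.02,
                           seed0 = 100) {
  beats <- list()
  i <- 0
  while (length(beats) < n_beats) {
    i <- i + 1
    out <- generate_record(synth_config(duration_s = 150, mean_hr_bpm = hr,
                                        rr_cv = rr_cv, noise_sd = noise_sd,
                                        seed = seed0 + i))
    rp <- pan_tompkins(out$record)
    beats <- c(beats, extract_heartbeats(out$record, rp))
  }
  beats[seq_len(n_beats)]
}

# P-DHB autoencoder trained on 2,000 beats at a fixed 75 bpm
pdhb75_model <- function() {
  cached("pdhb75", function() {
    beats <- cached("beats75", function() fixed_hr_beats(2000))
    train_autoencoder(beats,
                      encoder_config("P_DHB", d = 16, epochs = 30, seed = 1))
  })
}

# small shape-only model for invariance contracts
sdhb_toy_model <- function() {
  cached("sdhb_toy", function() {
    ds <- generate_dataset(6, c(NSR = 1), seed = 31, duration_s = 60)
    beats <- unlist(lapply(ds, function(o) {
      extract_heartbeats(o$record, pan_tompkins(o$record))
    }), recursive = FALSE)
    train_autoencoder(beats,
                      encoder_config("S_DHB", d = 16, epochs = 10, seed = 3))
  })
}

# a tiny trained model of any variant, for shape/bookkeeping contracts
tiny_model <- function(variant, d, kind = "HEARTBEAT", seed = 9) {
  slices <- replicate(8, {
    n <- 150
    ecg_slice(stats::rnorm(n, sd = 0.1), (seq_len(n) - 1) / 300, "toy", 0L,
              kind)
  }, simplify = FALSE)
  cfg <- encoder_config(variant, d = d, n_in = 16, m_eval = 8,
                        hidden_widths = c(8, 8), batch_size = 4, epochs = 1,
                        seed = seed)
  train_autoencoder(slices, cfg)
}

# match detected peak times against truth at +/-50 ms
match_peaks <- function(det_s, truth_s, tol = 0.05) {
  sens <- mean(vapply(truth_s, function(tt) any(abs(det_s - tt) <= tol),
                      logical(1)))
  ppv <- mean(vapply(det_s, function(dd) any(abs(truth_s - dd) <= tol),
                     logical(1)))
  list(sens = sens, ppv = ppv)
}
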