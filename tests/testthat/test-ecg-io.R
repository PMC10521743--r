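make_annotated_record <- function() {
  ann <- data.frame(sample = c(100, 400, 700, 1000),
                    af = c(FALSE, TRUE, TRUE, FALSE))
  ecg_record("r01", sin(seq(0, 20, length.out = 1500)) * 2, 300,
             rhythm_label = "AF", beat_annotations = ann)
}

test_that("the internal text format round-trips records losslessly", {
  rec <- make_annotated_record()
  path <- withr::local_tempfile(fileext = ".ecg")
  write_internal(rec, path)
  back <- read_internal(path)
  expect_identical(back$samples, rec$samples)  # bit-exact doubles
  expect_identical(back$fs, rec$fs)
  expect_identical(back$record_id, rec$record_id)
  expect_identical(back$rhythm_label, rec$rhythm_label)
  expect_identical(back$beat_annotations$sample,
                   as.numeric(rec$beat_annotations$sample))
  expect_identical(back$beat_annotations$af, rec$beat_annotations$af)
  # no label, no annotations
  bare <- ecg_record("bare", c(0.5, -0.25, 1 / 3), 250)
  write_internal(bare, path)
  back2 <- read_internal(path)
  expect_identical(back2$samples, bare$samples)
  expect_null(back2$rhythm_label)
  expect_null(back2$beat_annotations)
})

test_that("malformed internal files raise parse errors naming the field", {
  path <- withr::local_tempfile(fileext = ".ecg")
  rec <- make_annotated_record()
  write_internal(rec, path)
  lines <- readLines(path)
  # non-increasing beat indices
  bad <- lines
  bad[7:8] <- c("beat\t400\t0", "beat\t100\t1")
  writeLines(bad, path)
  expect_error(read_internal(path), "strictly")
  # wrong magic
  writeLines(c("#other-format", lines[-1]), path)
  expect_error(read_internal(path), "magic")
  # corrupt sample count
  bad2 <- lines
  bad2[grep("^n_samples", bad2)] <- "n_samples\t999999"
  writeLines(bad2, path)
  expect_error(read_internal(path), "samples")
})

test_that("empty or invalid records are refused at construction", {
  expect_error(ecg_record("x", numeric(0), 300), "non-empty")
  expect_error(ecg_record("x", 1:10, -1), "positive")
  expect_error(ecg_record("x", 1:10, 300,
                          beat_annotations = data.frame(sample = c(5, 2),
                                                        af = c(TRUE, FALSE))),
               "strictly increasing")
  expect_error(ecg_record("x", 1:10, 300,
                          beat_annotations = data.frame(sample = c(2, 50),
                                                        af = c(TRUE, FALSE))),
               "out of range")
})

test_that("WFDB format-16 records round-trip through write/read", {
  rec <- make_annotated_record()
  dir <- withr::local_tempdir()
  base <- file.path(dir, "r01")
  write_wfdb_record(rec, base)
  back <- read_wfdb_record(base, lead = 0)
  # quantized at gain 200 adu/mV: worst-case error half an adu
  expect_lte(max(abs(back$samples - rec$samples)), 1 / 400)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$record_id, "r01")
  expect_identical(back$beat_annotations$sample,
                   as.numeric(rec$beat_annotations$sample))
  expect_identical(back$beat_annotations$af, rec$beat_annotations$af)
  # deterministic I/O
  expect_identical(back$samples, read_wfdb_record(base, lead = 0)$samples)
})

test_that("WFDB errors: missing files and out-of-range leads", {
  dir <- withr::local_tempdir()
  expect_error(read_wfdb_record(file.path(dir, "absent")), "not found")
  rec <- make_annotated_record()
  base <- file.path(dir, "r02")
  write_wfdb_record(rec, base)
  expect_error(read_wfdb_record(base, lead = 5), "out of range")
})

test_that("format 212 decoding matches hand-packed 12-bit pairs", {
  # oracle: pack two-signal samples into 212 triplets by hand
  pack212 <- function(a, b) {
    a <- ifelse(a < 0, a + 4096L, a)
    b <- ifelse(b < 0, b + 4096L, b)
    as.raw(c(a %% 256, (b %/% 256) * 16 + a %/% 256, b %% 256))
  }
  v1 <- c(100L, -200L, 2047L, -2048L)
  v2 <- c(50L, 1000L, -1L, 0L)
  dir <- withr::local_tempdir()
  con <- file.path(dir, "t212.dat")
  writeBin(do.call(c, lapply(seq_along(v1), function(i) {
    pack212(v1[i], v2[i])
  })), con)
  writeLines(c("t212 2 360 4",
               "t212.dat 212 200(0)/mV 12 0 100 0 0 I",
               "t212.dat 212 200(0)/mV 12 0 50 0 0 II"),
             file.path(dir, "t212.hea"))
  r0 <- read_wfdb_record(file.path(dir, "t212"), 0, annotator = NULL)
  r1 <- read_wfdb_record(file.path(dir, "t212"), 1, annotator = NULL)
  expect_equal(r0$samples * 200, as.numeric(v1))
  expect_equal(r1$samples * 200, as.numeric(v2))
})

test_that("headers without gain fall back to raw units", {
  dir <- withr::local_tempdir()
  writeBin(c(10L, -3L, 7L), file.path(dir, "g0.dat"), size = 2,
           endian = "little")
  writeLines(c("g0 1 300 3", "g0.dat 16 0 16 0 10 0 0 ECG"),
             file.path(dir, "g0.hea"))
  rec <- read_wfdb_record(file.path(dir, "g0"), 0, annotator = NULL)
  expect_equal(rec$samples, c(10, -3, 7))
})

test_that("MIT annotation streams round-trip, including SKIP and aux", {
  ann <- data.frame(sample = c(50, 120, 5000, 5400),
                    code = c(28L, 1L, 1L, 1L),
                    aux = c("(AFIB", NA, NA, NA),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".atr")
  write_wfdb_annotations(ann, path)
  back <- read_wfdb_annotations(path)
  expect_equal(back$sample, ann$sample)
  expect_identical(back$code, ann$code)
  expect_identical(back$aux[1], "(AFIB")
})

test_that("rhythm-change annotations map to per-beat AF flags", {
  ann <- data.frame(
    sample = c(10, 100, 200, 250, 300, 400, 500),
    code = c(28L, 1L, 1L, 28L, 1L, 1L, 5L),
    aux = c("(N", NA, NA, "(AFIB", NA, NA, NA),
    stringsAsFactors = FALSE)
  flags <- beat_af_flags(ann)
  expect_equal(flags$sample, c(100, 200, 300, 400, 500))
  expect_identical(flags$af, c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("CSV export writes the documented two-column layout", {
  rec <- ecg_record("c", c(0.1, 0.2, -0.3), 300)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(rec, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("t_seconds", "mv"))
  expect_equal(df$t_seconds, c(0, 1, 2) / 300)
  expect_equal(df$mv, rec$samples)
})
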