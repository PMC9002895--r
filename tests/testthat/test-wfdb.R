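test_that("write/read round-trips annotations exactly and signal to quantization", {
  r <- generate_record(synth_params(
    duration = 10, noise_sd = 0.005,
    anomaly_plan = list(list(beat_index = 3, kind = "premature")),
    rhythm_plan = list(list(start_beat = 6, end_beat = 8, symbol = "VT"))))
  d <- withr::local_tempdir()
  p <- file.path(d, "rec01")
  write_record(r, p, gain = 1000)
  r2 <- read_record(p)
  expect_identical(r2$beat_ann$sample, r$beat_ann$sample)
  expect_identical(r2$beat_ann$symbol, r$beat_ann$symbol)
  expect_identical(r2$rhythm_ann$sample, r$rhythm_ann$sample)
  expect_identical(r2$rhythm_ann$symbol, r$rhythm_ann$symbol)
  expect_lt(max(abs(r$signal$MLII - r2$signal[[1]])), 1 / 1000)
  expect_equal(r2$fs, r$fs)
  expect_equal(names(r2$signal), c("MLII", "V5"))
})

test_that("write-read-write is idempotent on annotation streams", {
  r <- generate_record(synth_params(duration = 6,
    anomaly_plan = list(list(beat_index = 2, kind = "tall_t"))))
  d <- withr::local_tempdir()
  write_record(r, file.path(d, "a"))
  ra <- read_record(file.path(d, "a"))
  write_record(ra, file.path(d, "b"))
  rb <- read_record(file.path(d, "b"))
  expect_identical(ra$beat_ann, rb$beat_ann)
  expect_identical(ra$rhythm_ann, rb$rhythm_ann)
  expect_identical(readBin(file.path(d, "a.atr"), "raw", 1e4),
                   readBin(file.path(d, "b.atr"), "raw", 1e4))
})

test_that("a record with no rhythm annotations falls back to NSR at 0", {
  r <- generate_record(synth_params(duration = 5))
  d <- withr::local_tempdir()
  p <- file.path(d, "norhy")
  write_record(r, p)
  # rewrite the annotation file with beats only
  ecgfusion:::.write_atr(r$beat_ann,
                         data.frame(sample = integer(), symbol = character()),
                         paste0(p, ".atr"))
  r2 <- read_record(p)
  expect_equal(r2$rhythm_ann, data.frame(sample = 0, symbol = "NSR"))
})

test_that("missing and truncated files give distinct, named errors", {
  d <- withr::local_tempdir()
  expect_error(read_record(file.path(d, "ghost")), "header file not found")
  r <- generate_record(synth_params(duration = 5))
  p <- file.path(d, "trunc")
  write_record(r, p)
  writeBin(raw(8), paste0(p, ".dat"))
  expect_error(read_record(p), "truncated signal file.*trunc\\.dat")
})

test_that("label maps are total over both vocabularies", {
  expect_equal(label_rhythm("NSR"), 0L)
  expect_equal(label_rhythm("VT"), 1L)
  expect_equal(label_beat("PVC"), 1L)
  expect_equal(label_beat("N"), 0L)
  expect_true(all(label_rhythm(setdiff(rhythm_vocabulary(), "NSR")) == 1L))
  expect_true(all(label_beat(setdiff(beat_vocabulary(), "N")) == 1L))
  expect_error(label_rhythm("XYZ", strict = TRUE), "unknown rhythm symbol")
  expect_error(label_beat("XYZ", strict = TRUE), "unknown beat symbol")
})

test_that("long inter-annotation gaps survive the SKIP encoding", {
  ann <- data.frame(sample = c(100, 50000, 50100),
                    symbol = c("N", "PVC", "N"))
  sig <- list(MLII = numeric(60000))
  sig$MLII[c(100, 50000, 50100) + 1] <- 1
  r <- ecg_record("gap", 250, sig, ann,
                  data.frame(sample = 0, symbol = "NSR"))
  d <- withr::local_tempdir()
  write_record(r, file.path(d, "gap"))
  r2 <- read_record(file.path(d, "gap"))
  expect_identical(r2$beat_ann$sample, ann$sample)
  expect_identical(r2$beat_ann$symbol, ann$symbol)
})
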