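test_that("beat annotations fall on an arithmetic R grid", {
  r <- clean_record()
  # duration 10 s, 60 bpm, first R at 0.5 s: 10 beats at samples 125..2375
  expect_equal(r$beat_ann$sample, seq(125, 2375, by = 250))
  expect_true(all(r$beat_ann$symbol == "N"))
  expect_equal(r$rhythm_ann, data.frame(sample = 0, symbol = "NSR"))
})

test_that("beat count follows floor((duration - first_r) * hr/60) + 1", {
  # durations chosen so no beat lands exactly on the record boundary
  # (a boundary apex would fall outside [0, length) and is dropped)
  for (p in list(c(10, 60), c(30, 75), c(12.3, 100), c(59.8, 120))) {
    r <- generate_record(synth_params(duration = p[1], heart_rate = p[2]))
    expect_equal(nrow(r$beat_ann),
                 floor((p[1] - 0.5) * p[2] / 60) + 1)
  }
})

test_that("the noise-free QRS apex sits exactly on the annotated sample", {
  r <- clean_record()
  x <- r$signal$MLII
  for (s in r$beat_ann$sample) {
    win <- (s - 10):(s + 10) + 1
    expect_equal(which.max(x[win]), 11)
  }
})

test_that("generation is deterministic and noise leaves annotations alone", {
  p <- synth_params(duration = 8, noise_sd = 0.05, seed = 99)
  a <- generate_record(p); b <- generate_record(p)
  expect_identical(a$signal, b$signal)
  clean <- generate_record(synth_params(duration = 8, noise_sd = 0, seed = 99))
  expect_identical(a$beat_ann, clean$beat_ann)
  expect_identical(a$rhythm_ann, clean$rhythm_ann)
  expect_false(identical(a$signal$MLII, clean$signal$MLII))
})

test_that("a premature beat shortens exactly the preceding RR gap", {
  r <- generate_record(synth_params(
    duration = 10, anomaly_plan = list(list(beat_index = 5,
                                            kind = "premature"))))
  gaps <- diff(r$beat_ann$sample)
  expect_equal(gaps[5], 150, tolerance = 1)   # 0.6 x 250 samples
  expect_true(all(abs(gaps[-5] - 250) <= 1))
  expect_equal(r$beat_ann$symbol[6], "PAC")
})

test_that("anomaly and rhythm plans are validated", {
  expect_error(generate_record(synth_params(
    duration = 5, anomaly_plan = list(list(beat_index = 50,
                                           kind = "premature")))),
    "out of range")
  expect_error(generate_record(synth_params(
    duration = 5, anomaly_plan = list(list(beat_index = 1,
                                           kind = "nonsense")))),
    "unknown anomaly kind")
  expect_error(synth_params(fs = 300), "250 or 360")
  expect_error(generate_dataset(0), "n_records")
})

test_that("lead 2 is a scaled copy with its own noise", {
  r <- clean_record()
  expect_equal(r$signal$V5, 0.7 * r$signal$MLII)
  rn <- generate_record(synth_params(duration = 5, noise_sd = 0.02))
  expect_false(identical(rn$signal$V5, 0.7 * rn$signal$MLII))
})

test_that("datasets reproduce and follow the normal/abnormal grid", {
  grid <- list(
    synth_params(duration = 6),
    synth_params(duration = 6,
                 anomaly_plan = list(list(beat_index = 2, kind = "wide_qrs")))
  )
  d1 <- generate_dataset(4, grid, seed = 5)
  d2 <- generate_dataset(4, grid, seed = 5)
  expect_identical(d1, d2)
  expect_equal(vapply(d1, function(r) r$record_id, character(1)),
               sprintf("syn-%03d", 0:3))
  abnormal <- vapply(d1, function(r) any(r$beat_ann$symbol != "N"),
                     logical(1))
  expect_equal(abnormal, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("rhythm plans produce half-open annotated spans", {
  r <- generate_record(synth_params(
    duration = 12, rhythm_plan = list(list(start_beat = 4, end_beat = 7,
                                           symbol = "VT"))))
  expect_equal(r$rhythm_ann$symbol, c("NSR", "VT", "NSR"))
  expect_equal(r$rhythm_ann$sample[2], r$beat_ann$sample[5])
  expect_equal(r$rhythm_ann$sample[3], r$beat_ann$sample[9])
})
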