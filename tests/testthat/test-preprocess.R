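test_that("resampling is identity at 250 Hz and 25/36 at 360 Hz", {
  x <- rnorm(1000)
  expect_identical(resample_to_250(x, 250), x)
  y <- resample_to_250(rnorm(3600), 360)
  expect_length(y, 2500)
  expect_error(resample_to_250(x, 500), "unsupported sampling frequency")
})

test_that("a 10 Hz tone survives 360 -> 250 Hz resampling", {
  t <- (0:3599) / 360
  y <- resample_to_250(sin(2 * pi * 10 * t), 360)
  sp <- Mod(fft(y - mean(y)))[seq_len(length(y) %/% 2)]
  peak_hz <- (which.max(sp[-1])) * 250 / length(y)
  expect_lt(abs(peak_hz - 10), 250 / length(y) + 1e-9)   # within one bin
})

test_that("min-max normalization maps range to [0, 1] linearly", {
  expect_equal(minmax_normalize(c(-1, 0, 1)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x), x)
  expect_error(minmax_normalize(c(5, 5, 5)), "constant")
})

test_that("rhythm windows tile the record with 3-s span and 1-s step", {
  rec <- normalize_record(clean_record())    # 10 s at 250 Hz
  w <- slide_rhythm_windows(rec, 1)
  expect_length(w, 8)
  expect_equal(vapply(w, `[[`, numeric(1), "start_sample"),
               seq(0, 1750, by = 250))
  expect_true(all(vapply(w, function(s) length(s$samples), numeric(1)) == 750))
  # 3-s record: exactly one window; shorter: none
  r3 <- normalize_record(generate_record(synth_params(duration = 3)))
  expect_length(slide_rhythm_windows(r3, 1), 1)
  r2 <- normalize_record(generate_record(synth_params(duration = 2.5)))
  expect_length(slide_rhythm_windows(r2, 1), 0)
})

test_that("window labels come from overlap with abnormal rhythm intervals", {
  rec <- normalize_record(clean_record())
  rec$rhythm_ann <- data.frame(sample = c(0, 1000), symbol = c("NSR", "VT"))
  w <- slide_rhythm_windows(rec, 1)
  labels <- vapply(w, `[[`, integer(1), "label")
  starts <- vapply(w, `[[`, numeric(1), "start_sample")
  # brute-force overlap oracle: abnormal span is [1000, 2500)
  expect_equal(labels, as.integer(starts + 750 > 1000))
})

test_that("heartbeats span [R(i-1), R(i+1)) with the n-2 count", {
  rec <- normalize_record(clean_record())    # 10 annotated beats
  hb <- extract_heartbeats(rec, 1)
  expect_length(hb, 8)
  expect_true(all(vapply(hb, function(b) length(b$samples), numeric(1)) == 500))
  expect_true(all(vapply(hb, `[[`, numeric(1), "r_index") == 250))
  # spans tile [R(0), R(n-1)) with double coverage of every gap
  spans <- t(vapply(hb, function(b) c(b$start_sample,
                                      b$start_sample + b$right_r),
                    numeric(2)))
  covered <- rep(0, 2500)
  for (i in seq_len(nrow(spans))) {
    covered[(spans[i, 1] + 1):spans[i, 2]] <-
      covered[(spans[i, 1] + 1):spans[i, 2]] + 1
  }
  inner <- (rec$beat_ann$sample[2] + 1):rec$beat_ann$sample[9]
  expect_true(all(covered[inner] == 2))
  expect_length(extract_heartbeats(normalize_record(
    generate_record(synth_params(duration = 2.4))), 1), 0)
})

test_that("heartbeat labels follow the beat symbol", {
  rec <- normalize_record(generate_record(synth_params(
    duration = 10, anomaly_plan = list(list(beat_index = 4,
                                            kind = "wide_qrs")))))
  hb <- extract_heartbeats(rec, 1)
  labels <- vapply(hb, `[[`, integer(1), "label")
  expect_equal(which(labels == 1), 4L)       # beat 4 is the PVC
  expect_equal(hb[[4]]$symbol, "PVC")
})

test_that("balancing undersamples to parity and splits 90/10 stratified", {
  set.seed(1)
  labels <- c(rep(1, 300), rep(0, 2000))
  sp <- balance_and_split(seq_along(labels), labels, seed = 7)
  n_tot <- length(sp$train$labels) + length(sp$test$labels)
  expect_equal(n_tot, 600)
  expect_equal(length(sp$test$labels), 60)
  expect_lte(abs(sum(sp$train$labels == 1) - sum(sp$train$labels == 0)), 1)
  expect_lte(abs(sum(sp$test$labels == 1) - sum(sp$test$labels == 0)), 1)
  expect_identical(balance_and_split(seq_along(labels), labels, seed = 7),
                   sp)
  expect_false(identical(
    balance_and_split(seq_along(labels), labels, seed = 8)$test$idx,
    sp$test$idx))
  expect_error(balance_and_split(1:5, rep(1, 5)), "both classes")
})
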