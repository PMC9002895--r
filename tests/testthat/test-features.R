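# brute-force central moment, the independent oracle for the moment trio
brute_moment <- function(x, k) {
  mu <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - mu)^k
  s / length(x)
}

test_that("skewness matches its defining population-moment formula", {
  expect_equal(ecg_skewness(c(-1, 0, 1)), 0)
  # Bernoulli(1/4) closed form (1 - 2p) / sqrt(p (1 - p))
  p <- 1 / 4
  expect_equal(ecg_skewness(c(0, 0, 0, 1)), (1 - 2 * p) / sqrt(p * (1 - p)),
               tolerance = 1e-12)
  expect_equal(ecg_skewness(c(0, 0, 0, 1)), 1.1547, tolerance = 1e-4)
  x <- rnorm(100)
  expect_equal(ecg_skewness(-x), -ecg_skewness(x))
  expect_error(ecg_skewness(rep(2, 5)), "constant")
})

test_that("kurtosis is the non-excess fourth standardized moment", {
  expect_equal(ecg_kurtosis(c(-1, 1, -1, 1)), 1)
  set.seed(20240205)
  z <- rnorm(1e5)
  expect_equal(ecg_kurtosis(z), 3, tolerance = 0.1)
  x <- rexp(200)
  expect_equal(ecg_kurtosis(3.7 * x - 2), ecg_kurtosis(x), tolerance = 1e-9)
  expect_equal(ecg_kurtosis(z, excess = TRUE), ecg_kurtosis(z) - 3)
})

test_that("variance uses the N-1 denominator exactly", {
  expect_equal(ecg_variance(c(0, 2)), 2)
  expect_equal(ecg_variance(rep(1, 10)), 0)
  expect_error(ecg_variance(3), "at least 2")
})

test_that("moment trio agrees with brute-force sums to 1e-12", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1), sd = runif(1, 0.1, 10))
    m2 <- brute_moment(x, 2)
    expect_equal(ecg_skewness(x), brute_moment(x, 3) / m2^1.5,
                 tolerance = 1e-12)
    expect_equal(ecg_kurtosis(x), brute_moment(x, 4) / m2^2,
                 tolerance = 1e-12)
    expect_equal(ecg_variance(x),
                 brute_moment(x, 2) * length(x) / (length(x) - 1),
                 tolerance = 1e-12)
  }
})

test_that("moments cross-check against the reference implementations", {
  skip_if_not_installed("e1071")
  set.seed(6)
  x <- rnorm(500)
  expect_equal(ecg_skewness(x), e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(ecg_kurtosis(x, excess = TRUE),
               e1071::kurtosis(x, type = 1), tolerance = 1e-12)
  expect_equal(ecg_variance(x), var(x), tolerance = 1e-12)
})

test_that("rhythm feature vectors have the fixed 9-entry schema", {
  seg <- ecg_segment(clean_lead()[1:750], 250, 0)
  f <- rhythm_features(seg)
  expect_named(f, rhythm_feature_names())
  expect_equal(unname(f["n_r_pt"]), 3)
  expect_equal(unname(f["n_r_seeht"]), 3)
  expect_equal(unname(f["avg_rr"]), 1, tolerance = 0.02)
  expect_true(all(f[c("avg_qrs", "avg_pr", "avg_qt")] > 0))
})

test_that("feature assembly is total on degenerate segments", {
  f <- rhythm_features(rep(0.5, 750), 250)
  expect_named(f, rhythm_feature_names())
  expect_true(all(f == 0))
})

test_that("heartbeat feature vectors have the fixed 11-entry schema", {
  rec <- normalize_record(clean_record())
  b <- extract_heartbeats(rec, 1)[[3]]
  f <- heartbeat_features(b)
  expect_named(f, heartbeat_feature_names())
  expect_true(all(f > 0))

  ra <- normalize_record(generate_record(synth_params(
    duration = 10, anomaly_plan = list(list(beat_index = 4,
                                            kind = "absent_p")))))
  fa <- heartbeat_features(extract_heartbeats(ra, 1)[[4]])
  expect_equal(unname(fa["p_amp"]), 0)
  expect_equal(unname(fa["pr_len"]), 0)
  expect_true(all(fa[setdiff(heartbeat_feature_names(),
                             c("p_amp", "pr_len"))] > 0))
})

test_that("feature vectors are deterministic and order-stable", {
  seg <- clean_lead()[251:1000]
  expect_identical(rhythm_features(seg), rhythm_features(seg))
})

test_that("the min-max scaler spans, clips and round-trips", {
  set.seed(9)
  train <- cbind(a = runif(20, -5, 5), b = rnorm(20), c = rep(2, 20))
  sc <- fit_scaler(train)
  scaled <- apply_scaler(sc, train)
  expect_equal(apply(scaled[, 1:2], 2, range), cbind(a = 0:1, b = 0:1))
  expect_true(all(scaled[, 3] == 0))          # constant feature maps to 0
  expect_equal(unname(apply_scaler(sc, c(100, 0, 2))[1]), 1)  # clipped
  expect_equal(unname(apply_scaler(sc, c(-100, 0, 2))[1]), 0)
  f <- withr::local_tempfile(fileext = ".json")
  save_scaler(sc, f)
  sc2 <- load_scaler(f)
  expect_equal(apply_scaler(sc2, train), unname(scaled) |>
                 `colnames<-`(colnames(scaled)), ignore_attr = TRUE)
  expect_error(fit_scaler(train[1, , drop = FALSE]), "at least 2")
})
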