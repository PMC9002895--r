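# Statistical moments and assembly of the fixed-schema handcrafted feature
# vectors. The schema order is part of the public contract: trained model
# weights depend on it.

#' Statistical moments of a signal
#'
#' `ecg_skewness` is the third central population moment over the cube of
#' the population standard deviation; `ecg_kurtosis` the fourth central
#' population moment over the fourth power (non-excess, so a Gaussian gives
#' 3; set `excess = TRUE` to subtract 3). `ecg_variance` is the sample
#' variance with the `N - 1` denominator. The mixed population/sample
#' conventions are deliberate: each matches its printed defining formula.
#'
#' @param x Numeric vector (length >= 2, non-constant for the standardized
#'   moments).
#' @param excess Subtract 3 from the kurtosis.
#' @return Scalar moment value.
#' @export
ecg_skewness <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("skewness undefined for a constant signal")
  mean((x - mu)^3) / sigma^3
}

#' @rdname ecg_skewness
#' @export
ecg_kurtosis <- function(x, excess = FALSE) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  mu <- mean(x)
  sigma2 <- mean((x - mu)^2)
  if (sigma2 == 0) stop("kurtosis undefined for a constant signal")
  k <- mean((x - mu)^4) / sigma2^2
  if (excess) k - 3 else k
}

#' @rdname ecg_skewness
#' @export
ecg_variance <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  mu <- mean(x)
  sum(abs(x - mu)^2) / (n - 1)
}

# moments with the flat-signal convention used inside feature assembly:
# a zero-variance segment yields 0 for the standardized moments
.safe_moments <- function(x) {
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 == 0) {
    c(skewness = 0, kurtosis = 0, variance = 0)
  } else {
    c(skewness = ecg_skewness(x), kurtosis = ecg_kurtosis(x),
      variance = ecg_variance(x))
  }
}

#' Feature schema names
#'
#' Fixed, ordered names of the 9 rhythm features and 11 heartbeat features.
#'
#' @return Character vector of feature names in schema order.
#' @export
rhythm_feature_names <- function() {
  c("n_r_pt", "n_r_seeht", "skewness", "kurtosis", "variance",
    "avg_rr", "avg_qrs", "avg_pr", "avg_qt")
}

#' @rdname rhythm_feature_names
#' @export
heartbeat_feature_names <- function() {
  c("r_amp", "rr_left", "rr_right", "skewness", "kurtosis", "variance",
    "qrs_len", "pr_len", "qt_len", "p_amp", "t_amp")
}

# delineate every detected beat in a segment, bounding each by its
# neighbors (or up to 1 s of context at the segment edges)
.segment_intervals <- function(x, fs, r_idx, config) {
  n <- length(x)
  lapply(seq_along(r_idx), function(i) {
    r <- r_idx[i]
    left <- if (i > 1) r_idx[i - 1] else max(0, r - fs)
    right <- if (i < length(r_idx)) r_idx[i + 1] else min(n - 1, r + fs)
    fid <- delineate_beat(x, fs, r, left, right, config)
    measure_intervals(fid, left, right, fs, x)
  })
}

#' Rhythm handcrafted feature vector (9 features)
#'
#' Runs both R-peak detectors on the segment (their counts are two separate
#' features, never merged), computes the statistical moments over the raw
#' segment samples, and averages the interval measurements over all beats
#' detected by the Pan-Tompkins chain. Averages include beats whose
#' fiducials were undetected, which contribute 0 (the zero-is-sentinel
#' rule); a segment with no detected beats gets counts 0 and zero averages.
#'
#' @param segment An [ecg_segment()] or a numeric vector.
#' @param fs Sampling frequency in Hz (ignored when `segment` carries one).
#' @param config A [delineate_config()].
#' @return Named numeric vector of length 9 in [rhythm_feature_names()]
#'   order.
#' @export
rhythm_features <- function(segment, fs = 250, config = delineate_config()) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else segment
  if (inherits(segment, "ecg_segment")) fs <- segment$fs
  pt <- pan_tompkins(x, fs)
  se <- seeht(x, fs)
  mom <- .safe_moments(x)
  r_idx <- pt$r_indices
  if (length(r_idx) >= 2) {
    avg_rr <- mean(diff(r_idx)) / fs
  } else {
    avg_rr <- 0
  }
  if (length(r_idx) >= 1) {
    ivs <- .segment_intervals(x, fs, r_idx, config)
    avg_qrs <- mean(vapply(ivs, `[[`, numeric(1), "qrs_len"))
    avg_pr <- mean(vapply(ivs, `[[`, numeric(1), "pr_len"))
    avg_qt <- mean(vapply(ivs, `[[`, numeric(1), "qt_len"))
  } else {
    avg_qrs <- avg_pr <- avg_qt <- 0
  }
  out <- c(length(pt$r_indices), length(se$r_indices), mom["skewness"],
           mom["kurtosis"], mom["variance"], avg_rr, avg_qrs, avg_pr, avg_qt)
  names(out) <- rhythm_feature_names()
  out
}

#' Heartbeat handcrafted feature vector (11 features)
#'
#' Delineates the single beat between its bounding R peaks and assembles
#' the fixed 11-feature schema; amplitudes are read from the normalized
#' excerpt and undetected fiducials contribute 0.
#'
#' @param beat An [ecg_heartbeat()].
#' @param config A [delineate_config()].
#' @return Named numeric vector of length 11 in
#'   [heartbeat_feature_names()] order.
#' @export
heartbeat_features <- function(beat, config = delineate_config()) {
  stopifnot(inherits(beat, "ecg_heartbeat"))
  fid <- delineate_beat(beat$samples, beat$fs, beat$r_index, beat$left_r,
                        beat$right_r, config)
  iv <- measure_intervals(fid, beat$left_r, beat$right_r, beat$fs,
                          beat$samples)
  mom <- .safe_moments(beat$samples)
  out <- c(iv$r_amp, iv$rr_left, iv$rr_right, mom["skewness"],
           mom["kurtosis"], mom["variance"], iv$qrs_len, iv$pr_len,
           iv$qt_len, iv$p_amp, iv$t_amp)
  names(out) <- heartbeat_feature_names()
  out
}

#' Min-max feature scaler learned on training data
#'
#' Stores per-feature (min, max) over the training matrix. Applying the
#' scaler maps each feature linearly to `[0, 1]` and clips out-of-range
#' test values; a feature constant across training maps to 0.
#'
#' @param train Numeric matrix, rows = training vectors, columns = features.
#' @return Object of class `feature_scaler`.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training vectors")
  structure(list(min = apply(train, 2, min), max = apply(train, 2, max),
                 names = colnames(train)),
            class = "feature_scaler")
}

#' @param scaler A `feature_scaler`.
#' @param v Numeric vector or matrix of feature vectors (rows).
#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, v) {
  stopifnot(inherits(scaler, "feature_scaler"))
  m <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  rng <- scaler$max - scaler$min
  out <- sweep(m, 2, scaler$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, 0), 1)    # argument order keeps the dim attribute
  if (is.matrix(v)) out else drop(out)
}

#' @rdname fit_scaler
#' @param path File path for JSON (de)serialization.
#' @export
save_scaler <- function(scaler, path) {
  jsonlite::write_json(
    list(min = unname(scaler$min), max = unname(scaler$max),
         names = scaler$names),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname fit_scaler
#' @export
load_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = as.numeric(obj$min), max = as.numeric(obj$max),
                 names = obj$names),
            class = "feature_scaler")
}
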