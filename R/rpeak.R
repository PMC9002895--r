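# Two independent R-peak detectors. The pipeline deliberately carries both
# detectors' counts as separate features and never merges them: the two
# chains fail differently on distorted beats, and the disagreement itself
# is informative.

#' R-peak detection result
#'
#' @param r_indices Strictly increasing 0-based sample indices of R apexes.
#' @param detector `"pan_tompkins"` or `"seeht"`.
#' @return Object of class `rpeak_result`.
#' @export
rpeak_result <- function(r_indices, detector) {
  r_indices <- as.integer(r_indices)
  if (length(r_indices) > 1) stopifnot(all(diff(r_indices) > 0))
  structure(list(r_indices = r_indices, detector = detector),
            class = "rpeak_result")
}

#' @export
print.rpeak_result <- function(x, ...) {
  cat(sprintf("%s: %d R peaks\n", x$detector, length(x$r_indices)))
  invisible(x)
}

.bandpass <- function(x, fs, low, high, order = 3) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# refine detections to the raw-signal local maximum, then enforce the
# refractory period keeping the taller peak of any conflicting pair
.refine_peaks <- function(x, cand, fs, back, fwd, refractory) {
  n <- length(x)
  refined <- vapply(as.integer(cand), function(p) {
    i0 <- max(1L, p - as.integer(back)); i1 <- min(n, p + as.integer(fwd))
    i0 + which.max(x[i0:i1]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  min_gap <- round(refractory * fs)
  repeat {
    gaps <- diff(refined)
    j <- which(gaps < min_gap)
    if (length(refined) < 2 || length(j) == 0) break
    j <- j[1]
    drop <- if (x[refined[j]] >= x[refined[j + 1]]) j + 1 else j
    refined <- refined[-drop]
  }
  refined
}

#' Pan-Tompkins R-peak detector
#'
#' Classic chain: band-pass (5-15 Hz, zero-phase Butterworth), derivative,
#' squaring, 150 ms moving-window integration, adaptive dual thresholds
#' with search-back and a 200 ms refractory period. Detections are refined
#' to the local signal maximum within +/-50 ms so that positions are
#' comparable across detectors. Output is invariant to positive rescaling
#' of the input (the chain normalizes amplitude first).
#'
#' @param x Numeric signal vector (>= 2 s of samples).
#' @param fs Sampling frequency in Hz.
#' @param refractory Minimum R-to-R spacing in seconds.
#' @param refine Half-width of the apex-refinement window in seconds.
#' @return An [rpeak_result()].
#' @export
pan_tompkins <- function(x, fs, refractory = 0.2, refine = 0.05) {
  n <- length(x)
  if (n < 2 * fs) stop("signal too short: need at least 2 s of samples")
  amp <- max(abs(x - mean(x)))
  if (amp == 0) return(rpeak_result(integer(0), "pan_tompkins"))
  xn <- (x - mean(x)) / amp

  bp <- .bandpass(xn, fs, 5, 15)
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  w <- max(2L, round(0.15 * fs))
  m <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  m[is.na(m)] <- 0

  cand <- which(diff(sign(diff(m))) < 0) + 1L   # local maxima of m
  if (length(cand) == 0) return(rpeak_result(integer(0), "pan_tompkins"))

  init <- m[seq_len(min(n, 2 * fs))]
  spki <- 0.6 * max(init)
  npki <- 0.5 * mean(init)
  min_gap <- round(refractory * fs)
  qrs <- integer(0)
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (m[p] >= thr &&
        (length(qrs) == 0 || p - qrs[length(qrs)] >= min_gap)) {
      qrs <- c(qrs, p)
      spki <- 0.125 * m[p] + 0.875 * spki
    } else {
      npki <- 0.125 * m[p] + 0.875 * npki
    }
  }
  # search-back over long gaps with the lowered threshold
  if (length(qrs) >= 2) {
    thr2 <- 0.5 * (npki + 0.25 * (spki - npki))
    avg_rr <- mean(diff(qrs))
    filled <- qrs
    for (g in which(diff(qrs) > 1.66 * avg_rr)) {
      lo <- qrs[g] + min_gap; hi <- qrs[g + 1] - min_gap
      inside <- cand[cand > lo & cand < hi]
      inside <- inside[m[inside] >= thr2]
      if (length(inside)) filled <- c(filled, inside[which.max(m[inside])])
    }
    qrs <- sort(filled)
  }
  if (length(qrs) == 0) return(rpeak_result(integer(0), "pan_tompkins"))

  r50 <- round(refine * fs)
  peaks <- .refine_peaks(xn, qrs, fs, back = w + r50, fwd = r50, refractory)
  rpeak_result(peaks - 1L, "pan_tompkins")     # 0-based
}

# analytic-signal Hilbert transform (odd / imaginary part)
.hilbert_odd <- function(x) {
  n <- length(x)
  H <- numeric(n)
  if (n %% 2 == 0) {
    H[c(1, n / 2 + 1)] <- 1
    H[2:(n / 2)] <- 2
  } else {
    H[1] <- 1
    H[2:((n + 1) / 2)] <- 2
  }
  Im(fft(fft(x) * H, inverse = TRUE) / n)
}

#' Shannon-energy-envelope Hilbert-transform (SEEHT) R-peak detector
#'
#' Chain: band-pass (4-20 Hz), first difference, amplitude normalization,
#' Shannon energy `s = -d^2 log(d^2)`, zero-phase envelope smoothing
#' (~150 ms), Hilbert transform of the mean-removed envelope, and R peaks
#' at the zero crossings of the odd (imaginary-part) signal where the
#' envelope is active. Detections are refined to the local signal maximum
#' within +/-50 ms with a 200 ms refractory period.
#'
#' @inheritParams pan_tompkins
#' @return An [rpeak_result()].
#' @export
seeht <- function(x, fs, refractory = 0.2, refine = 0.05) {
  n <- length(x)
  if (n < 2 * fs) stop("signal too short: need at least 2 s of samples")
  amp <- max(abs(x - mean(x)))
  if (amp == 0) return(rpeak_result(integer(0), "seeht"))
  xn <- (x - mean(x)) / amp

  bp <- .bandpass(xn, fs, 4, 20)
  d <- c(0, diff(bp))
  dmax <- max(abs(d))
  if (dmax == 0) return(rpeak_result(integer(0), "seeht"))
  dn <- d / dmax
  d2 <- dn^2
  se <- ifelse(d2 > 0, -d2 * log(d2), 0)
  w <- max(2L, round(0.15 * fs))
  ee <- as.numeric(stats::filter(se, rep(1 / w, w), sides = 2))
  ee[is.na(ee)] <- 0

  # the Hilbert transform of a positive envelope bump crosses zero upward
  # at the bump apex, so R candidates sit at negative-to-positive crossings
  h <- .hilbert_odd(ee - mean(ee))
  s <- sign(h)
  cross <- which(s[-n] < 0 & s[-1] >= 0) + 1L
  thr <- 0.1 * max(ee)
  cross <- cross[ee[cross] >= thr]
  if (length(cross) == 0) return(rpeak_result(integer(0), "seeht"))

  r50 <- round(refine * fs)
  peaks <- .refine_peaks(xn, cross, fs, back = r50, fwd = r50, refractory)
  rpeak_result(peaks - 1L, "seeht")
}
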