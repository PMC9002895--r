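# P-QRS-T fiducial detection on a single beat excerpt, in the style of the
# classic ecgpuwave delineator: QRS boundaries from the derivative around
# the known R peak, then P and T located in search windows before/after
# the complex, each wave apex at the zero crossing of the smoothed first
# derivative between the window's derivative extrema. All indices are
# 0-based offsets into the excerpt; undetected fiducials are NA.

#' Delineation configuration
#'
#' Search-window geometry and thresholds for [delineate_beat()]. Units are
#' seconds unless noted.
#'
#' @param qrs_search Maximum distance from R searched for each QRS boundary.
#' @param qrs_deriv_frac Fraction of the peak QRS derivative below which the
#'   complex is considered ended.
#' @param p_gap Gap between the end of the P search window and QRS onset.
#' @param p_span Length of the P search window.
#' @param t_gap Gap between QRS offset and the start of the T search window.
#' @param t_span Maximum length of the T search window (also capped at
#'   `0.6 * RR` after the R peak).
#' @param noise_floor_frac Fraction of the excerpt's peak derivative below
#'   which a search window is declared empty (wave missing).
#' @param smooth Moving-average length in samples applied to the derivative
#'   before zero-crossing search.
#' @return List of class `delineate_config`.
#' @export
delineate_config <- function(qrs_search = 0.25, qrs_deriv_frac = 0.05,
                             p_gap = 0.04, p_span = 0.2,
                             t_gap = 0.08, t_span = 0.4,
                             noise_floor_frac = 0.02, smooth = 5L) {
  structure(list(qrs_search = qrs_search, qrs_deriv_frac = qrs_deriv_frac,
                 p_gap = p_gap, p_span = p_span, t_gap = t_gap,
                 t_span = t_span, noise_floor_frac = noise_floor_frac,
                 smooth = as.integer(smooth)),
            class = "delineate_config")
}

# apex = zero crossing of the smoothed derivative between the window's
# derivative maximum and the minimum that follows it (an upright wave rises
# then falls; pairing the rise with a *preceding* fall would lock onto the
# tail of the previous wave). Falls back to the inverted-wave pairing.
# Returns NA when the window is inactive.
.wave_peak <- function(d, i0, i1, floor_abs) {
  if (is.na(i0) || is.na(i1) || i1 <= i0) return(NA_integer_)
  win <- d[i0:i1]
  if (max(abs(win)) < floor_abs) return(NA_integer_)
  imax <- i0 + which.max(win) - 1L
  if (imax < i1) {
    imin <- imax + which.min(d[imax:i1]) - 1L
    if (d[imin] < 0) {
      seg <- d[imax:imin]
      cr <- which(seg[-length(seg)] > 0 & seg[-1] <= 0)
      if (length(cr)) return(imax + cr[1] - 1L)
    }
  }
  imin <- i0 + which.min(win) - 1L
  if (imin < imax) {
    seg <- d[imin:imax]
    cr <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)
    if (length(cr)) return(imin + cr[1] - 1L)
  }
  NA_integer_
}

#' Locate P-QRS-T fiducial points on one heartbeat excerpt
#'
#' @param signal Normalized voltage excerpt (numeric vector).
#' @param fs Sampling frequency in Hz.
#' @param r_index 0-based R apex offset within the excerpt.
#' @param left_r,right_r 0-based offsets of the bounding R peaks.
#' @param config A [delineate_config()].
#' @return List of class `fiducial_set` with 0-based offsets `p_peak`, `q`,
#'   `r_peak`, `s`, `t_peak`, `qrs_on`, `qrs_off`; undetected points are
#'   `NA` (degenerate windows never raise an error).
#' @export
delineate_beat <- function(signal, fs, r_index, left_r = 0,
                           right_r = length(signal) - 1,
                           config = delineate_config()) {
  n <- length(signal)
  stopifnot(r_index >= 0, r_index < n)
  r1 <- r_index + 1L                           # 1-based internal
  d <- c(0, diff(signal)) * fs
  k <- config$smooth
  d <- as.numeric(stats::filter(d, rep(1 / k, k), sides = 2))
  d[is.na(d)] <- 0
  floor_abs <- config$noise_floor_frac * max(abs(d))
  if (max(abs(d)) == 0) {
    fid <- list(p_peak = NA, q = NA, r_peak = r_index, s = NA, t_peak = NA,
                qrs_on = NA, qrs_off = NA)
    class(fid) <- "fiducial_set"
    return(fid)
  }

  # QRS boundaries: walk out from R until the derivative stays quiet
  qs <- round(config$qrs_search * fs)
  lo <- max(1L, r1 - qs); hi <- min(n, r1 + qs)
  qrs_thr <- config$qrs_deriv_frac * max(abs(d[lo:hi]))
  qrs_on1 <- lo
  for (i in seq(r1, lo)) {
    if (abs(d[i]) < qrs_thr &&
        all(abs(d[max(lo, i - 2):i]) < qrs_thr)) { qrs_on1 <- i; break }
  }
  qrs_off1 <- hi
  for (i in seq(r1, hi)) {
    if (abs(d[i]) < qrs_thr &&
        all(abs(d[i:min(hi, i + 2)]) < qrs_thr)) { qrs_off1 <- i; break }
  }

  q1 <- if (qrs_on1 < r1) qrs_on1 + which.min(signal[qrs_on1:r1]) - 1L else NA
  s1 <- if (qrs_off1 > r1) r1 + which.min(signal[r1:qrs_off1]) - 1L else NA

  # P window: p_span seconds, ending p_gap before QRS onset
  p_hi <- qrs_on1 - round(config$p_gap * fs)
  p_lo <- max(1L, p_hi - round(config$p_span * fs))
  p_lo <- max(p_lo, left_r + 1L)
  p1 <- if (p_hi > p_lo) .wave_peak(d, p_lo, p_hi, floor_abs) else NA_integer_

  # T window: from t_gap after QRS offset, capped at 0.6 * right RR
  rr_right <- (right_r - r_index) / fs
  t_lo <- qrs_off1 + round(config$t_gap * fs)
  t_hi <- min(n, qrs_off1 + round((config$t_gap + config$t_span) * fs),
              r1 + round(0.6 * rr_right * fs))
  t1 <- if (t_hi > t_lo && t_lo >= 1) .wave_peak(d, t_lo, t_hi, floor_abs)
        else NA_integer_

  to0 <- function(i) if (is.na(i)) NA_integer_ else as.integer(i - 1L)
  fid <- list(p_peak = to0(p1), q = to0(q1), r_peak = as.integer(r_index),
              s = to0(s1), t_peak = to0(t1),
              qrs_on = to0(qrs_on1), qrs_off = to0(qrs_off1))
  class(fid) <- "fiducial_set"
  fid
}

#' Measure beat intervals and amplitudes from fiducial points
#'
#' Intervals follow the peak-based conventions of the delineator: PR is
#' P-peak to R-peak and QT is Q to T-peak. Any interval or amplitude whose
#' defining fiducial is missing is set to 0 (the zero-is-sentinel rule), so
#' the function is total and a zero value co-occurs exactly with a missing
#' fiducial.
#'
#' @param fiducials A `fiducial_set` from [delineate_beat()].
#' @param left_r,right_r 0-based bounding R offsets.
#' @param fs Sampling frequency in Hz.
#' @param signal The excerpt the fiducials refer to (for amplitudes).
#' @return List of class `interval_set` with `rr_left`, `rr_right`,
#'   `qrs_len`, `pr_len`, `qt_len` (seconds) and `p_amp`, `r_amp`, `t_amp`
#'   (normalized units).
#' @export
measure_intervals <- function(fiducials, left_r, right_r, fs, signal) {
  f <- fiducials
  val <- function(i) if (is.na(i)) 0 else signal[i + 1]
  len <- function(a, b) if (is.na(a) || is.na(b)) 0 else max(0, (b - a) / fs)
  out <- list(
    rr_left = (f$r_peak - left_r) / fs,
    rr_right = (right_r - f$r_peak) / fs,
    qrs_len = len(f$qrs_on, f$qrs_off),
    pr_len = len(f$p_peak, f$r_peak),
    qt_len = len(f$q, f$t_peak),
    p_amp = val(f$p_peak),
    r_amp = val(f$r_peak),
    t_amp = val(f$t_peak)
  )
  class(out) <- "interval_set"
  out
}
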