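#' Resample an ECG signal to 250 Hz
#'
#' Signals already at 250 Hz are returned unchanged; 360 Hz signals are
#' resampled by the rational factor 25/36 with a polyphase FIR
#' anti-aliasing low-pass designed with a Kaiser window
#' (via [signal::resample()]). Output length is `ceiling(N * 25/36)`.
#'
#' @param x Numeric signal vector.
#' @param fs Input sampling frequency, 250 or 360 Hz.
#' @return Numeric vector sampled at 250 Hz.
#' @export
resample_to_250 <- function(x, fs) {
  if (fs == 250) return(x)
  if (fs == 360) {
    y <- signal::resample(x, 25, 36)
    return(y[seq_len(ceiling(length(x) * 25 / 36))])
  }
  stop("unsupported sampling frequency: ", fs, " (expected 250 or 360)")
}

#' Min-max normalize a signal to [0, 1]
#'
#' `S(t) = (value(t) - min) / (max - min)`: the minimum maps to 0 and the
#' maximum to 1. Constant signals have zero range and are rejected.
#'
#' @param x Numeric signal vector.
#' @return Normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("cannot normalize a constant signal (zero range)")
  (x - lo) / (hi - lo)
}

#' Resample and normalize every lead of a record
#'
#' Convenience wrapper applying [resample_to_250()] and
#' [minmax_normalize()] per lead (normalization is per record per lead),
#' rescaling annotation sample indices when the rate changes.
#'
#' @param record An [ecg_record()].
#' @return An [ecg_record()] at 250 Hz with each lead in `[0, 1]`.
#' @export
preprocess_record <- function(record) {
  ratio <- 250 / record$fs
  signal <- lapply(record$signal,
                   function(s) minmax_normalize(resample_to_250(s, record$fs)))
  n <- length(signal[[1]])
  rescale <- function(ann) {
    ann$sample <- pmin(n - 1, round(ann$sample * ratio))
    ann[!duplicated(ann$sample), , drop = FALSE]
  }
  ecg_record(record$record_id, 250, signal,
             rescale(record$beat_ann), rescale(record$rhythm_ann))
}

#' Construct a labeled rhythm segment
#'
#' @param samples Normalized voltage vector (length `3 * fs` for rhythm
#'   windows).
#' @param fs Sampling frequency in Hz.
#' @param label 0 (normal) or 1 (abnormal).
#' @param record_id,lead,start_sample Provenance; `start_sample` is the
#'   0-based index of the first sample in the source record.
#' @return Object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, fs, label, record_id = NA, lead = NA,
                        start_sample = NA) {
  structure(list(samples = samples, fs = fs, label = as.integer(label),
                 record_id = record_id, lead = lead,
                 start_sample = start_sample),
            class = "ecg_segment")
}

# half-open abnormal rhythm intervals [onset, next onset) from annotations
.abnormal_intervals <- function(rhythm_ann, n, map) {
  if (nrow(rhythm_ann) == 0) return(matrix(numeric(0), ncol = 2))
  lab <- label_rhythm(rhythm_ann$symbol, map)
  starts <- rhythm_ann$sample
  ends <- c(rhythm_ann$sample[-1], n)
  cbind(starts, ends)[lab == 1, , drop = FALSE]
}

#' Slide 3-second rhythm windows over a record lead
#'
#' Window size is `3 * fs` samples and the step is `fs` samples; the
#' trailing partial window is discarded. A window is labeled abnormal (1)
#' when its span overlaps any abnormal rhythm interval; rhythm onsets are
#' valid until the next onset (half-open intervals).
#'
#' @param record A preprocessed [ecg_record()].
#' @param lead Lead name or index.
#' @param map A [label_map()].
#' @param window_seconds,step_seconds Window and step size in seconds.
#' @return List of [ecg_segment()] objects (empty if the record is shorter
#'   than one window).
#' @export
slide_rhythm_windows <- function(record, lead = 1, map = label_map(),
                                 window_seconds = 3, step_seconds = 1) {
  x <- record$signal[[lead]]
  fs <- record$fs
  win <- round(window_seconds * fs)
  step <- round(step_seconds * fs)
  n <- length(x)
  if (n < win) return(list())
  starts <- seq(0, n - win, by = step)        # 0-based
  abn <- .abnormal_intervals(record$rhythm_ann, n, map)
  lead_name <- if (is.numeric(lead)) record$leads[lead] else lead
  lapply(starts, function(s) {
    overlap <- nrow(abn) > 0 && any(abn[, 1] < s + win & abn[, 2] > s)
    ecg_segment(x[(s + 1):(s + win)], fs, as.integer(overlap),
                record$record_id, lead_name, s)
  })
}

#' Construct a labeled heartbeat excerpt
#'
#' @param samples Normalized voltage vector spanning the beat.
#' @param fs Sampling frequency in Hz.
#' @param r_index 0-based offset of the central R apex within the excerpt.
#' @param left_r,right_r 0-based offsets of the bounding R peaks
#'   (`0 <= left_r < r_index < right_r <= length`).
#' @param label 0 (normal) or 1 (abnormal).
#' @param symbol Beat annotation symbol.
#' @param record_id,lead,start_sample Provenance.
#' @return Object of class `ecg_heartbeat`.
#' @export
ecg_heartbeat <- function(samples, fs, r_index, left_r, right_r, label,
                          symbol = NA, record_id = NA, lead = NA,
                          start_sample = NA) {
  stopifnot(0 <= left_r, left_r < r_index, r_index < right_r,
            right_r <= length(samples))
  structure(list(samples = samples, fs = fs, r_index = r_index,
                 left_r = left_r, right_r = right_r,
                 label = as.integer(label), symbol = symbol,
                 record_id = record_id, lead = lead,
                 start_sample = start_sample),
            class = "ecg_heartbeat")
}

#' Extract R-to-R bounded heartbeats from an annotated record
#'
#' Beat `i` (0-based, `1 <= i <= n-2`) spans from the previous annotated R
#' peak to the following one, half-open `[R(i-1), R(i+1))`, so consecutive
#' excerpts tile the record with double coverage and no 1-sample overlap.
#' The label comes from the beat symbol at `R(i)`.
#'
#' @param record A preprocessed [ecg_record()].
#' @param lead Lead name or index.
#' @param map A [label_map()].
#' @return List of [ecg_heartbeat()] objects (empty when fewer than 3
#'   annotated beats).
#' @export
extract_heartbeats <- function(record, lead = 1, map = label_map()) {
  ann <- record$beat_ann
  if (nrow(ann) < 3) return(list())
  x <- record$signal[[lead]]
  lead_name <- if (is.numeric(lead)) record$leads[lead] else lead
  out <- vector("list", nrow(ann) - 2)
  for (i in 2:(nrow(ann) - 1)) {
    l <- ann$sample[i - 1]; r <- ann$sample[i]; rt <- ann$sample[i + 1]
    seg <- x[(l + 1):rt]                       # [R(i-1), R(i+1)) half-open
    out[[i - 1]] <- ecg_heartbeat(
      seg, record$fs, r_index = r - l, left_r = 0, right_r = rt - l,
      label = label_beat(ann$symbol[i], map), symbol = ann$symbol[i],
      record_id = record$record_id, lead = lead_name, start_sample = l
    )
  }
  out
}

#' Balance classes by undersampling and split into train/test
#'
#' The majority class is down-sampled uniformly at random (seeded) to the
#' minority count, items are shuffled, and the test set takes
#' `floor((1 - train_frac) * total)` items stratified per class so both
#' splits keep the 50-50 class balance within one item.
#'
#' @param items List or vector of items (any type).
#' @param labels Integer 0/1 labels, parallel to `items`.
#' @param train_frac Fraction of the balanced set used for training.
#' @param seed Integer seed.
#' @return List with `train` and `test`, each holding `items`, `labels`
#'   and `idx` (indices into the original `items`).
#' @export
balance_and_split <- function(items, labels, train_frac = 0.9, seed = 1L) {
  stopifnot(length(items) == length(labels))
  labels <- as.integer(labels)
  idx0 <- which(labels == 0); idx1 <- which(labels == 1)
  if (length(idx0) == 0 || length(idx1) == 0) {
    stop("both classes must be non-empty")
  }
  set.seed(seed)
  m <- min(length(idx0), length(idx1))
  if (length(idx0) > m) idx0 <- sort(sample(idx0, m))
  if (length(idx1) > m) idx1 <- sort(sample(idx1, m))
  total <- 2 * m
  n_test <- floor((1 - train_frac) * total + 1e-9)
  n_test0 <- n_test %/% 2
  n_test1 <- n_test - n_test0                 # odd test size: +1 to class 1
  test0 <- sample(idx0, n_test0)
  test1 <- sample(idx1, n_test1)
  test_idx <- sample(c(test0, test1))
  train_idx <- sample(c(setdiff(idx0, test0), setdiff(idx1, test1)))
  pick <- function(ix) list(items = items[ix], labels = labels[ix], idx = ix)
  list(train = pick(train_idx), test = pick(test_idx))
}
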