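# Confusion counts, the four headline metrics, and the end-to-end
# two-stage detector. Positive class is always "abnormal" (label 1).

#' Confusion counts for binary anomaly labels
#'
#' @param pred,truth Integer 0/1 vectors of equal length (1 = abnormal).
#' @return Object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("label vectors differ in length")
  stopifnot(all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(list(tp = sum(pred == 1 & truth == 1),
                 fp = sum(pred == 1 & truth == 0),
                 tn = sum(pred == 0 & truth == 0),
                 fn = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Sensitivity, false-alarm rate, positive predictive value, accuracy
#'
#' `SEN = TP/(TP+FN)`, `FAR = 1 - specificity = FP/(FP+TN)`,
#' `PPV = TP/(TP+FP)`, `ACC = (TP+TN)/(TP+FP+TN+FN)`, all as percentages.
#' Full precision is retained; the print method rounds to 2 decimals. A
#' metric whose denominator is zero is undefined and reported as `NA`,
#' never as 0.
#'
#' @param counts A [confusion_counts()] object (or list with tp/fp/tn/fn).
#' @return Object of class `ecg_metrics` with `sen`, `far`, `ppv`, `acc`
#'   in percent.
#' @export
classification_metrics <- function(counts) {
  c <- counts
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    sen = pct(c$tp, c$tp + c$fn),
    far = pct(c$fp, c$fp + c$tn),
    ppv = pct(c$tp, c$tp + c$fp),
    acc = pct(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn)
  ), class = "ecg_metrics")
}

#' @export
print.ecg_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("SEN %s  FAR %s  PPV %s  ACC %s\n",
              fmt(x$sen), fmt(x$far), fmt(x$ppv), fmt(x$acc)))
  invisible(x)
}

# score one lead's items with a model (an ecg_fusion fit, or a plain
# function(images, features) -> scores, used for oracle models in tests)
.score_lead <- function(model, images, features) {
  if (is.function(model)) model(images, features)
  else predict(model, images, features, type = "score")
}

.lead_model <- function(model, lead) {
  if (inherits(model, "ecg_fusion") || is.function(model)) model
  else model[[lead]]
}

# merge abnormal window spans [start, end) into disjoint intervals
.merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) return(data.frame(start = integer(),
                                             end = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  rs <- c(); re <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= out_e) {
      out_e <- max(out_e, ends[i])
    } else {
      rs <- c(rs, out_s); re <- c(re, out_e)
      out_s <- starts[i]; out_e <- ends[i]
    }
  }
  data.frame(start = c(rs, out_s), end = c(re, out_e))
}

#' Two-stage anomaly detection over a whole record
#'
#' Stage 1 scores every 3-second window on both leads, fuses the per-lead
#' scores, and reports fused-abnormal windows as merged `[start, end)`
#' sample intervals. Stage 2 scans only the heartbeats whose central R
#' peak lies outside every abnormal interval (beats inside abnormal rhythm
#' are already covered by stage 1, so no beat is double-counted) and
#' reports fused-abnormal beats.
#'
#' @param record An [ecg_record()] (raw; it is resampled/normalized here).
#' @param rhythm_model,beat_model Fitted [fusion_fit()] models: either one
#'   model applied to both leads, a `list(lead1, lead2)` pair, or a
#'   `function(images, features)` returning scores (oracle stubs).
#' @param map A [label_map()].
#' @param opts List of rendering options: `rhythm_window`, `beat_window`
#'   (STFT window lengths), `img_height`, `img_width`, `mode`.
#' @return Object of class `ecg_detection`: `rhythm_intervals` (data frame
#'   of abnormal spans with fused scores), `beat_flags` (per scanned beat:
#'   sample, fused score, label), `n_windows`, `n_beats_scanned`,
#'   `n_beats_skipped`.
#' @export
detect_anomalies <- function(record, rhythm_model, beat_model,
                             map = label_map(),
                             opts = list()) {
  o <- modifyList(list(rhythm_window = 167L, beat_window = 28L,
                       img_height = 32L, img_width = 32L, mode = "gray"),
                  opts)
  if (is.null(rhythm_model) || is.null(beat_model)) {
    stop("both a rhythm model and a beat model are required")
  }
  rec <- preprocess_record(record)
  fs <- rec$fs
  n <- length(rec$signal[[1]])
  if (n < 3 * fs) {
    warning("record shorter than one 3-s window; empty report")
    return(structure(list(rhythm_intervals = data.frame(),
                          beat_flags = data.frame(), n_windows = 0L,
                          n_beats_scanned = 0L, n_beats_skipped = 0L),
                     class = "ecg_detection"))
  }

  item_image <- function(x, L) {
    render_spectrogram(ecg_stft(x, L, max(1L, floor(L / 2)), fs = fs),
                       o$mode, o$img_height, o$img_width)
  }

  # stage 1: fused rhythm windows
  lead_scores <- vector("list", 2)
  win <- NULL
  for (ld in 1:2) {
    segs <- slide_rhythm_windows(rec, ld, map)
    if (ld == 1) win <- segs
    imgs <- lapply(segs, function(s) item_image(s$samples, o$rhythm_window))
    feats <- t(vapply(segs, function(s) rhythm_features(s, fs),
                      numeric(9)))
    lead_scores[[ld]] <- .score_lead(.lead_model(rhythm_model, ld),
                                     imgs, feats)
  }
  fused <- fuse_leads(lead_scores[[1]], lead_scores[[2]])
  starts <- vapply(win, `[[`, numeric(1), "start_sample")
  abn <- fused$label == 1
  intervals <- .merge_intervals(starts[abn], starts[abn] + 3 * fs)
  if (nrow(intervals)) {
    intervals$max_score <- vapply(seq_len(nrow(intervals)), function(i) {
      max(fused$y[abn & starts >= intervals$start[i] - 3 * fs &
                    starts < intervals$end[i]])
    }, numeric(1))
  }

  # stage 2: beats in normal rhythm only
  beats1 <- extract_heartbeats(rec, 1, map)
  beats2 <- extract_heartbeats(rec, 2, map)
  r_abs <- vapply(beats1, function(b) b$start_sample + b$r_index, numeric(1))
  in_abn <- if (nrow(intervals) == 0) rep(FALSE, length(r_abs)) else
    vapply(r_abs, function(r) any(r >= intervals$start & r < intervals$end),
           logical(1))
  scan <- which(!in_abn)
  beat_flags <- data.frame()
  if (length(scan)) {
    bs <- vector("list", 2)
    for (ld in 1:2) {
      bb <- (if (ld == 1) beats1 else beats2)[scan]
      imgs <- lapply(bb, function(b) item_image(b$samples, o$beat_window))
      feats <- t(vapply(bb, heartbeat_features, numeric(11)))
      bs[[ld]] <- .score_lead(.lead_model(beat_model, ld), imgs, feats)
    }
    bf <- fuse_leads(bs[[1]], bs[[2]])
    beat_flags <- data.frame(sample = r_abs[scan], score = bf$y,
                             label = bf$label)
  }

  structure(list(rhythm_intervals = intervals, beat_flags = beat_flags,
                 n_windows = length(win), n_beats_scanned = length(scan),
                 n_beats_skipped = sum(in_abn)),
            class = "ecg_detection")
}

#' @export
print.ecg_detection <- function(x, ...) {
  cat(sprintf("Two-stage detection: %d windows, %d abnormal rhythm interval(s)\n",
              x$n_windows, nrow(x$rhythm_intervals)))
  cat(sprintf("  beats scanned %d (skipped inside abnormal rhythm: %d), flagged %d\n",
              x$n_beats_scanned, x$n_beats_skipped,
              if (nrow(x$beat_flags)) sum(x$beat_flags$label) else 0L))
  invisible(x)
}
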