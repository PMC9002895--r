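#' Default P-QRS-T wave specification
#'
#' Each beat of the synthetic ECG is a sum of five Gaussian bumps, one per
#' wave component. `amplitude` is in normalized voltage units, `width` is the
#' full width at half maximum in seconds, and `offset` is the bump center
#' relative to the R apex in seconds. Defaults are physiologic: a 0.1-unit
#' P wave 160 ms before R, a dominant R with small flanking Q and S
#' deflections, and a 0.3-unit T wave 250 ms after R.
#'
#' @return Named list with components `P`, `Q`, `R`, `S`, `T`, each a list
#'   with `amplitude`, `width`, `offset`.
#' @export
default_wave_spec <- function() {
  list(
    P = list(amplitude = 0.10, width = 0.08, offset = -0.16),
    Q = list(amplitude = -0.10, width = 0.03, offset = -0.04),
    R = list(amplitude = 1.00, width = 0.03, offset = 0.00),
    S = list(amplitude = -0.20, width = 0.03, offset = 0.04),
    T = list(amplitude = 0.30, width = 0.12, offset = 0.25)
  )
}

#' Parameters for the synthetic two-lead ECG generator
#'
#' @param duration Record length in seconds (> 0).
#' @param fs Sampling frequency in Hz; 250 or 360, matching the two source
#'   databases the pipeline targets.
#' @param heart_rate Heart rate in beats per minute (> 0).
#' @param wave_spec Per-wave morphology, see [default_wave_spec()].
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   normalized voltage units.
#' @param anomaly_plan List of `list(beat_index, kind)` entries with 0-based
#'   `beat_index` and `kind` one of `"premature"`, `"wide_qrs"`,
#'   `"absent_p"`, `"tall_t"`. A premature beat shortens the preceding
#'   R-to-R gap by `premature_factor` and suppresses its P wave; a wide-QRS
#'   beat stretches the whole QRS complex to twice its duration and has no
#'   P wave (PVC-like morphology); `absent_p` drops the P bump; `tall_t`
#'   triples the T amplitude.
#' @param rhythm_plan List of `list(start_beat, end_beat, symbol)` entries
#'   (0-based, inclusive beat range) overriding the default single normal
#'   sinus rhythm annotation at sample 0. The plan changes annotations only;
#'   morphology is controlled through `heart_rate`, `wave_spec` and
#'   `anomaly_plan`.
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical record.
#' @param first_r Time of the first R apex in seconds.
#' @param lead2_scale Fixed scale factor applied to lead 1's noise-free
#'   waveform to obtain lead 2 (which then receives independent noise).
#' @param premature_factor R-to-R shortening factor for premature beats.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration = 30, fs = 250, heart_rate = 60,
                         wave_spec = default_wave_spec(), noise_sd = 0,
                         anomaly_plan = list(), rhythm_plan = list(),
                         seed = 1L, first_r = 0.5, lead2_scale = 0.7,
                         premature_factor = 0.6) {
  stopifnot(duration > 0, heart_rate > 0, noise_sd >= 0, first_r >= 0)
  if (!fs %in% c(250, 360)) {
    stop("fs must be 250 or 360 Hz")
  }
  widths <- vapply(wave_spec, function(w) w$width, numeric(1))
  stopifnot(all(widths > 0))
  p <- list(
    duration = duration, fs = fs, heart_rate = heart_rate,
    wave_spec = wave_spec, noise_sd = noise_sd,
    anomaly_plan = anomaly_plan, rhythm_plan = rhythm_plan,
    seed = as.integer(seed), first_r = first_r, lead2_scale = lead2_scale,
    premature_factor = premature_factor
  )
  class(p) <- "synth_params"
  p
}

# symbol assigned to each planted anomaly kind (Table-2 style vocabulary)
.anomaly_symbols <- c(
  premature = "PAC", wide_qrs = "PVC", absent_p = "J", tall_t = "Q"
)

#' Construct an ECG record object
#'
#' Container for multi-lead sampled voltages plus beat and rhythm
#' annotations. All annotation sample indices are 0-based (the native WFDB
#' convention); they index `signal[[lead]][sample + 1]` in R.
#'
#' @param record_id Record identifier string.
#' @param fs Sampling frequency in Hz.
#' @param signal Named list of equal-length numeric vectors, one per lead.
#' @param beat_ann Data frame with columns `sample` (0-based, strictly
#'   increasing) and `symbol` (beat type).
#' @param rhythm_ann Data frame with columns `sample` (0-based onset,
#'   strictly increasing) and `symbol` (rhythm type). Each onset is valid
#'   until the next onset (half-open intervals).
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, fs, signal, beat_ann, rhythm_ann) {
  stopifnot(is.list(signal), length(signal) >= 1, !is.null(names(signal)))
  n <- length(signal[[1]])
  if (!all(vapply(signal, length, integer(1)) == n)) {
    stop("all leads must have equal length")
  }
  beat_ann <- as.data.frame(beat_ann)
  rhythm_ann <- as.data.frame(rhythm_ann)
  for (ann in list(beat_ann, rhythm_ann)) {
    if (nrow(ann) > 0) {
      stopifnot(all(ann$sample >= 0), all(ann$sample < n))
      if (any(diff(ann$sample) <= 0)) {
        stop("annotation sample indices must be strictly increasing")
      }
    }
  }
  structure(
    list(record_id = record_id, fs = fs, leads = names(signal),
         signal = signal, beat_ann = beat_ann, rhythm_ann = rhythm_ann),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$signal[[1]])
  cat(sprintf("ECG record '%s': %d leads (%s), %.1f s at %d Hz\n",
              x$record_id, length(x$leads),
              paste(x$leads, collapse = ", "), n / x$fs, x$fs))
  cat(sprintf("  %d beat annotations (%s)\n", nrow(x$beat_ann),
              paste(utils::head(unique(x$beat_ann$symbol), 6), collapse = " ")))
  cat(sprintf("  %d rhythm annotations (%s)\n", nrow(x$rhythm_ann),
              paste(unique(x$rhythm_ann$symbol), collapse = " ")))
  invisible(x)
}

.gauss_bump <- function(t, center, amplitude, width) {
  sd <- width / (2 * sqrt(2 * log(2)))  # width is FWHM
  amplitude * exp(-0.5 * ((t - center) / sd)^2)
}

#' Generate an annotated synthetic two-lead ECG record
#'
#' Deterministic, seedable generator: each beat is a sum of Gaussian bumps
#' (P, Q, R, S, T) centered around equally spaced R times at `60/heart_rate`
#' seconds, with the R apex of each noise-free beat falling exactly on its
#' annotated sample. Lead 2 is lead 1 scaled by a fixed factor with
#' independent noise. Annotations default to all-`"N"` beats in a single
#' normal sinus rhythm unless `anomaly_plan` / `rhythm_plan` override.
#'
#' @param params A [synth_params()] object.
#' @param record_id Identifier stored in the record.
#' @return An [ecg_record()] with leads `"MLII"` and `"V5"`.
#' @export
generate_record <- function(params, record_id = "syn-000") {
  stopifnot(inherits(params, "synth_params"))
  fs <- params$fs
  n_samp <- round(params$duration * fs)
  rr <- 60 / params$heart_rate
  n_beats <- floor((params$duration - params$first_r) / rr + 1e-9) + 1

  kinds <- rep(NA_character_, n_beats)
  for (a in params$anomaly_plan) {
    bi <- a$beat_index
    if (is.null(bi) || bi < 0 || bi >= n_beats) {
      stop(sprintf("anomaly_plan beat_index %s out of range [0, %d)",
                   format(bi), n_beats))
    }
    if (!a$kind %in% names(.anomaly_symbols)) {
      stop("unknown anomaly kind: ", a$kind)
    }
    kinds[bi + 1] <- a$kind
  }

  gaps <- rep(rr, n_beats - 1)
  prem <- which(kinds == "premature")
  for (b in prem) {
    if (b == 1) stop("a premature beat needs a preceding beat")
    gaps[b - 1] <- rr * params$premature_factor
  }
  r_times <- params$first_r + cumsum(c(0, gaps))
  r_samples <- round(r_times * fs)
  keep <- r_samples < n_samp
  r_samples <- r_samples[keep]
  kinds <- kinds[keep]
  n_beats <- length(r_samples)

  t <- (0:(n_samp - 1)) / fs
  base <- numeric(n_samp)
  for (b in seq_len(n_beats)) {
    center_r <- r_samples[b] / fs   # exact sample time => apex on the sample
    kind <- kinds[b]
    for (wname in names(params$wave_spec)) {
      w <- params$wave_spec[[wname]]
      amp <- w$amplitude
      width <- w$width
      offset <- w$offset
      if (!is.na(kind)) {
        # wide_qrs mimics a PVC: the whole complex is stretched to twice
        # its duration (widths and Q/S offsets) and the P wave is absent
        if (wname == "P" && kind %in% c("premature", "absent_p", "wide_qrs")) next
        if (wname %in% c("Q", "R", "S") && kind == "wide_qrs") {
          width <- 2 * width
          offset <- 2 * offset
        }
        if (wname == "T" && kind == "tall_t") amp <- 3 * amp
      }
      sd <- width / (2 * sqrt(2 * log(2)))
      center <- center_r + offset
      i0 <- max(1L, floor((center - 5 * sd) * fs) + 1L)
      i1 <- min(n_samp, ceiling((center + 5 * sd) * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      base[idx] <- base[idx] + .gauss_bump(t[idx], center, amp, width)
    }
  }

  set.seed(params$seed)
  lead1 <- base
  lead2 <- base * params$lead2_scale
  if (params$noise_sd > 0) {
    lead1 <- lead1 + rnorm(n_samp, sd = params$noise_sd)
    lead2 <- lead2 + rnorm(n_samp, sd = params$noise_sd)
  }

  symbols <- ifelse(is.na(kinds), "N", .anomaly_symbols[kinds])
  beat_ann <- data.frame(sample = r_samples, symbol = unname(symbols),
                         stringsAsFactors = FALSE)

  rhythm_ann <- data.frame(sample = 0, symbol = "NSR", stringsAsFactors = FALSE)
  for (rp in params$rhythm_plan) {
    sb <- rp$start_beat; eb <- rp$end_beat
    if (sb < 0 || sb >= n_beats || eb < sb) {
      stop("rhythm_plan beat range out of range")
    }
    onset <- r_samples[sb + 1]
    rhythm_ann <- rhythm_ann[rhythm_ann$sample < onset, , drop = FALSE]
    rhythm_ann <- rbind(rhythm_ann,
                        data.frame(sample = onset, symbol = rp$symbol))
    if (eb + 1 < n_beats) {
      rhythm_ann <- rbind(rhythm_ann,
                          data.frame(sample = r_samples[eb + 2], symbol = "NSR"))
    }
  }
  rhythm_ann <- rhythm_ann[order(rhythm_ann$sample), , drop = FALSE]
  rhythm_ann <- rhythm_ann[!duplicated(rhythm_ann$sample, fromLast = TRUE), ,
                           drop = FALSE]
  rownames(rhythm_ann) <- NULL

  ecg_record(record_id, fs, list(MLII = lead1, V5 = lead2),
             beat_ann, rhythm_ann)
}

#' Generate the two-class synthetic study records
#'
#' Convenience generator for the scaled-down end-to-end experiment: half
#' the records are normal sinus rhythm at resting heart rates (60-81 bpm),
#' half are abnormal — ventricular-tachycardia-like, with tachycardic RR
#' (150-171 bpm) and a wide (PVC-like) QRS planted on every other beat.
#' With the default 27-s duration each record yields 25 rhythm windows,
#' so `n_per_class = 8` gives the 200-per-class window corpus used by the
#' package's own experiments. A small additive noise (`noise_sd = 0.01`)
#' keeps the records from being unrealistically clean.
#'
#' @param n_per_class Records per class.
#' @param duration Record duration in seconds.
#' @param seed Master seed (see [generate_dataset()]).
#' @return List of `2 * n_per_class` records, alternating normal/abnormal.
#' @export
synth_study_records <- function(n_per_class = 8, duration = 27, seed = 1L) {
  grid <- list()
  for (i in seq_len(n_per_class)) {
    hr_n <- 60 + 3 * (i - 1) %% 24
    hr_a <- 150 + 3 * (i - 1) %% 24
    n_beats_a <- floor((duration - 0.5) * hr_a / 60) + 1
    grid[[2 * i - 1]] <- synth_params(
      duration = duration, heart_rate = hr_n, noise_sd = 0.01
    )
    grid[[2 * i]] <- synth_params(
      duration = duration, heart_rate = hr_a, noise_sd = 0.01,
      anomaly_plan = lapply(seq(1, n_beats_a - 1, by = 2),
                            function(b) list(beat_index = b,
                                             kind = "wide_qrs")),
      rhythm_plan = list(list(start_beat = 0, end_beat = n_beats_a - 1,
                              symbol = "VT"))
    )
  }
  generate_dataset(2 * n_per_class, grid, seed)
}

#' Generate a reproducible dataset of synthetic records
#'
#' Per-record seeds are derived from the master seed by the fixed affine
#' hash `(seed * 7919 + i * 104729) mod (2^31 - 1)` so datasets reproduce
#' across platforms. The parameter grid is recycled over records.
#'
#' @param n_records Number of records (>= 1).
#' @param params_grid List of [synth_params()] templates, recycled.
#' @param seed Master integer seed.
#' @return List of [ecg_record()] objects with ids `"syn-000"`, `"syn-001"`, ...
#' @export
generate_dataset <- function(n_records, params_grid = list(synth_params()),
                             seed = 1L) {
  if (n_records < 1) stop("n_records must be >= 1")
  stopifnot(length(params_grid) >= 1)
  lapply(seq_len(n_records), function(i) {
    p <- params_grid[[(i - 1) %% length(params_grid) + 1]]
    p$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %%
                           (2^31 - 1))
    generate_record(p, record_id = sprintf("syn-%03d", i - 1))
  })
}
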