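# Minimal WFDB codec: header (.hea), signal (.dat, formats 16 and 212) and
# MIT annotation (.atr) files. Sample indices are 0-based throughout,
# preserving the native WFDB convention.

#' Rhythm and beat annotation vocabularies
#'
#' The rhythm vocabulary covers the rhythm types annotated in the two target
#' ambulatory databases (normal sinus rhythm, atrial fibrillation/flutter,
#' bigeminy, heart block, ventricular tachycardia/flutter, ...); the beat
#' vocabulary covers the beat types (normal, bundle branch blocks, premature
#' beats, escape beats, paced beats, ...).
#'
#' @return Character vector of annotation symbols.
#' @export
rhythm_vocabulary <- function() {
  c("NSR", "AB", "AFIB", "AFL", "B", "BII", "B3", "IVR", "NOD", "P",
    "PREX", "SAB", "SBR", "SVTA", "T", "VFL", "VT")
}

#' @rdname rhythm_vocabulary
#' @export
beat_vocabulary <- function() {
  c("N", "LBBB", "RBBB", "PAC", "a", "J", "S", "PVC", "F", "e", "j",
    "E", "P", "f", "Q")
}

# beat symbol -> MIT annotation type code
.beat_codes <- c(
  N = 1L, LBBB = 2L, RBBB = 3L, a = 4L, PVC = 5L, F = 6L, J = 7L,
  PAC = 8L, S = 9L, E = 10L, j = 11L, P = 12L, Q = 13L, e = 34L, f = 38L
)
.RHYTHM_CODE <- 40L  # '+' rhythm change, symbol carried in the aux string

#' Binary label maps for rhythm and beat symbols
#'
#' Symbols in the normal sets map to 0, every other vocabulary symbol to 1
#' (abnormal). `beat_exclude` lists beat types the heartbeat-stage dataset
#' builder drops because they do not occur inside normal rhythm; the set is
#' configurable because the source databases describe it inconsistently.
#'
#' @param rhythm_normal Rhythm symbols treated as normal.
#' @param beat_normal Beat symbols treated as normal.
#' @param beat_exclude Beat symbols excluded from the heartbeat dataset.
#' @return Object of class `label_map`.
#' @export
label_map <- function(rhythm_normal = "NSR", beat_normal = "N",
                      beat_exclude = c("P", "RBBB")) {
  stopifnot(length(rhythm_normal) >= 1, length(beat_normal) >= 1)
  structure(list(rhythm_normal = rhythm_normal, beat_normal = beat_normal,
                 beat_exclude = beat_exclude),
            class = "label_map")
}

.label_from <- function(symbol, normal, vocab, strict, what) {
  unknown <- !(symbol %in% vocab)
  if (any(unknown) && strict) {
    stop("unknown ", what, " symbol: ", paste(symbol[unknown], collapse = ", "))
  }
  as.integer(!(symbol %in% normal))
}

#' Map annotation symbols to binary labels (0 normal, 1 abnormal)
#'
#' @param symbol Character vector of annotation symbols.
#' @param map A [label_map()].
#' @param strict Error on symbols outside the vocabulary (default: treat as
#'   abnormal).
#' @return Integer vector of 0/1 labels, 1 = abnormal.
#' @export
label_rhythm <- function(symbol, map = label_map(), strict = FALSE) {
  .label_from(symbol, map$rhythm_normal, rhythm_vocabulary(), strict, "rhythm")
}

#' @rdname label_rhythm
#' @export
label_beat <- function(symbol, map = label_map(), strict = FALSE) {
  .label_from(symbol, map$beat_normal, beat_vocabulary(), strict, "beat")
}

.ann_path <- function(path, ext) paste0(path, ".", ext)

# ---- annotation stream codec ---------------------------------------------

.write_atr <- function(beat_ann, rhythm_ann, file) {
  events <- rbind(
    if (nrow(rhythm_ann)) data.frame(sample = rhythm_ann$sample,
                                     code = .RHYTHM_CODE,
                                     aux = paste0("(", rhythm_ann$symbol)),
    if (nrow(beat_ann)) data.frame(sample = beat_ann$sample,
                                   code = unname(.beat_codes[beat_ann$symbol]),
                                   aux = NA_character_)
  )
  if (is.null(events)) events <- data.frame(sample = integer(), code = integer(),
                                            aux = character())
  if (any(is.na(events$code))) {
    bad <- beat_ann$symbol[!beat_ann$symbol %in% names(.beat_codes)]
    stop("cannot encode beat symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  # rhythm onsets sort before beats at the same sample
  events <- events[order(events$sample, events$code != .RHYTHM_CODE), ,
                   drop = FALSE]
  con <- file(file, "wb")
  on.exit(close(con))
  word <- function(w) writeBin(as.integer(w), con, size = 2, endian = "little")
  prev <- 0
  for (i in seq_len(nrow(events))) {
    delta <- events$sample[i] - prev
    prev <- events$sample[i]
    if (delta > 1023) {
      word(bitwShiftL(59L, 10))               # SKIP, 4-byte operand follows
      word(bitwAnd(bitwShiftR(delta, 16), 0xFFFF))  # high 16 bits first
      word(bitwAnd(delta, 0xFFFF))
      delta <- 0
    }
    word(bitwOr(bitwShiftL(events$code[i], 10), delta))
    aux <- events$aux[i]
    if (!is.na(aux)) {
      raw_aux <- charToRaw(aux)
      word(bitwOr(bitwShiftL(63L, 10), length(raw_aux)))
      writeBin(raw_aux, con)
      if (length(raw_aux) %% 2 == 1) writeBin(as.raw(0), con)
    }
  }
  word(0L)  # end of annotation stream
  invisible(file)
}

.read_atr <- function(file) {
  raw <- readBin(file, "raw", file.size(file))
  nw <- length(raw) %/% 2
  words <- readBin(raw, "integer", n = nw, size = 2, endian = "little",
                   signed = FALSE)
  beat <- list(); rhythm <- list()
  time <- 0; i <- 1
  code_to_symbol <- stats::setNames(names(.beat_codes), .beat_codes)
  while (i <= nw) {
    w <- words[i]; i <- i + 1
    code <- bitwShiftR(w, 10)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == 59L) {                      # SKIP: 4-byte time operand
      time <- time + words[i] * 65536 + words[i + 1]
      i <- i + 2
      next
    }
    if (code %in% c(60L, 61L, 62L)) next    # NUM / SUB / CHN modifiers
    if (code == 63L) {                      # stray AUX, skip payload
      i <- i + ceiling(delta / 2)
      next
    }
    time <- time + delta
    aux <- NULL
    if (i <= nw && bitwShiftR(words[i], 10) == 63L) {
      len <- bitwAnd(words[i], 1023L)
      off <- 2 * i                           # aux bytes follow the AUX word
      aux <- rawToChar(raw[(off + 1):(off + len)])
      i <- i + 1 + ceiling(len / 2)
    }
    if (code == .RHYTHM_CODE) {
      sym <- sub("^\\(", "", if (is.null(aux)) "" else aux)
      rhythm[[length(rhythm) + 1]] <- list(sample = time, symbol = sym)
    } else {
      sym <- code_to_symbol[as.character(code)]
      if (is.na(sym)) {
        sym <- sprintf("code%d", code)
        warning("unknown annotation code ", code, "; symbol retained as ", sym)
      }
      beat[[length(beat) + 1]] <- list(sample = time, symbol = unname(sym))
    }
  }
  list(
    beat = do.call(rbind.data.frame, c(beat, stringsAsFactors = FALSE)),
    rhythm = do.call(rbind.data.frame, c(rhythm, stringsAsFactors = FALSE))
  )
}

# ---- record reader / writer ----------------------------------------------

#' Write an ECG record in WFDB format
#'
#' Emits `<path>.hea` (header), `<path>.dat` (format 16, interleaved 16-bit
#' little-endian integers at the given gain) and `<path>.atr` (MIT
#' annotation stream holding beats plus rhythm-change annotations).
#'
#' @param record An [ecg_record()].
#' @param path Record path without extension.
#' @param gain ADC units per physical unit; quantization step is `1/gain`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  nsig <- length(record$leads)
  n <- length(record$signal[[1]])
  digital <- vapply(record$signal,
                    function(s) pmin(32767, pmax(-32768, round(s * gain))),
                    numeric(n))
  dat_name <- paste0(basename(path), ".dat")
  chks <- apply(digital, 2, function(d) sum(d) %% 65536)
  hdr <- c(
    sprintf("%s %d %g %d", basename(path), nsig, record$fs, n),
    sprintf("%s 16 %g(0)/mV 16 0 %d %d 0 %s",
            dat_name, gain, digital[1, ], chks, record$leads)
  )
  writeLines(hdr, .ann_path(path, "hea"))
  con <- file(.ann_path(path, "dat"), "wb")
  interleaved <- as.integer(t(digital))
  writeBin(interleaved, con, size = 2, endian = "little")
  close(con)
  .write_atr(record$beat_ann, record$rhythm_ann, .ann_path(path, "atr"))
  invisible(path)
}

.parse_gain <- function(field) {
  # "1000(0)/mV" | "1000/mV" | "1000"
  gain <- as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", field))
  baseline <- 0
  m <- regmatches(field, regexec("\\(([-0-9]+)\\)", field))[[1]]
  if (length(m) == 2) baseline <- as.numeric(m[2])
  c(gain = if (is.na(gain) || gain == 0) 200 else gain, baseline = baseline)
}

.read_dat <- function(file, nsig, n, format) {
  if (!file.exists(file)) stop("signal file not found: ", file)
  sz <- file.size(file)
  if (format == 16) {
    need <- 2 * nsig * n
    if (sz < need) {
      stop(sprintf("truncated signal file %s: %d bytes, expected %d",
                   file, sz, need))
    }
    v <- readBin(file, "integer", n = nsig * n, size = 2, endian = "little",
                 signed = TRUE)
    matrix(v, nrow = nsig)                    # samples interleaved by lead
  } else if (format == 212) {
    total <- nsig * n
    need <- ceiling(total * 1.5)
    if (sz < need) {
      stop(sprintf("truncated signal file %s: %d bytes, expected %d",
                   file, sz, need))
    }
    b <- as.integer(readBin(file, "raw", need))
    trip <- matrix(b[1:(3 * (total %/% 2))], nrow = 3)
    s1 <- trip[1, ] + bitwShiftL(bitwAnd(trip[2, ], 0x0F), 8)
    s2 <- trip[3, ] + bitwShiftL(bitwAnd(bitwShiftR(trip[2, ], 4), 0x0F), 8)
    s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
    s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
    v <- as.vector(rbind(s1, s2))[1:total]
    matrix(v, nrow = nsig)
  } else {
    stop("unsupported WFDB signal format: ", format)
  }
}

#' Read a WFDB record
#'
#' Parses the header, converts the digital signal to physical units using
#' the per-signal gain and baseline, and separates beat annotations from
#' rhythm-change annotations (the aux-labeled stream). A record with no
#' rhythm annotations receives the fallback `(0, "NSR")` onset.
#'
#' @param path Record path without extension.
#' @return An [ecg_record()].
#' @export
read_record <- function(path) {
  hea <- .ann_path(path, "hea")
  if (!file.exists(hea)) stop("header file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n <- as.integer(top[4])
  sig_lines <- lines[2:(1 + nsig)]
  fields <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  dat_file <- file.path(dirname(path), fields[[1]][1])
  format <- as.integer(fields[[1]][2])
  digital <- .read_dat(dat_file, nsig, n, format)
  signal <- vector("list", nsig)
  lead_names <- character(nsig)
  for (k in seq_len(nsig)) {
    gb <- .parse_gain(fields[[k]][3])
    signal[[k]] <- (digital[k, ] - gb["baseline"]) / gb["gain"]
    f <- fields[[k]]
    lead_names[k] <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                     else paste0("sig", k - 1)
  }
  names(signal) <- make.unique(lead_names)

  atr <- .ann_path(path, "atr")
  beat_ann <- data.frame(sample = integer(), symbol = character())
  rhythm_ann <- data.frame(sample = integer(), symbol = character())
  if (file.exists(atr)) {
    anns <- .read_atr(atr)
    if (nrow(anns$beat)) beat_ann <- anns$beat
    if (nrow(anns$rhythm)) rhythm_ann <- anns$rhythm
  }
  if (nrow(rhythm_ann) == 0) {
    rhythm_ann <- data.frame(sample = 0, symbol = "NSR",
                             stringsAsFactors = FALSE)
  }
  ecg_record(basename(path), fs, signal, beat_ann, rhythm_ann)
}
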