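# Short-time Fourier transform of segments/heartbeats and rendering to
# fixed-size images. Window lengths follow the tuned defaults: 167 samples
# (0.668 s at 250 Hz) for rhythm windows and 28 samples (0.112 s) for
# heartbeats, both with a Hann taper.

#' Hann (Hanning) window
#'
#' Symmetric raised-cosine taper `0.5 * (1 - cos(2 pi k / (L - 1)))`,
#' `k = 0, ..., L-1`: endpoints are exactly 0, all values lie in `[0, 1]`,
#' and the center of an odd-length window is exactly 1 — matching the
#' normalized ECG amplitude range.
#'
#' @param L Window length in samples (>= 2).
#' @return Numeric vector of length `L`.
#' @export
hanning_window <- function(L) {
  if (L < 2) stop("window length must be >= 2")
  0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
}

#' Short-time Fourier transform power matrix
#'
#' Column `m` is the squared magnitude of the one-sided DFT of
#' `window * signal[m*hop + (1:L)]`. The number of columns is
#' `k = floor((N - L) / hop) + 1` and the number of frequency bins is
#' `floor(n_fft / 2) + 1`. The default hop of `floor(L / 2)` gives 50%
#' overlap; `n_fft` defaults to `L` (no zero padding).
#'
#' @param x Numeric signal (length >= `L`).
#' @param window_len Window length `L` in samples.
#' @param hop Hop size in samples (>= 1).
#' @param n_fft DFT length (>= `window_len`).
#' @param fs Sampling frequency in Hz (metadata only).
#' @return Object of class `ecg_stft`: list with `power` (frequency x time
#'   matrix, row 1 = DC), `window_len`, `hop`, `n_fft`, `fs`.
#' @export
ecg_stft <- function(x, window_len = 167, hop = floor(window_len / 2),
                     n_fft = window_len, fs = 250) {
  N <- length(x)
  L <- window_len
  if (N < L) stop("signal shorter than the analysis window")
  stopifnot(hop >= 1, n_fft >= L)
  w <- hanning_window(L)
  k <- floor((N - L) / hop) + 1
  nf <- floor(n_fft / 2) + 1
  frames <- vapply(seq_len(k), function(m) {
    fr <- w * x[((m - 1) * hop + 1):((m - 1) * hop + L)]
    c(fr, numeric(n_fft - L))
  }, numeric(n_fft))
  spec <- stats::mvfft(frames)
  power <- Mod(spec[seq_len(nf), , drop = FALSE])^2
  structure(list(power = power, window_len = L, hop = hop, n_fft = n_fft,
                 fs = fs),
            class = "ecg_stft")
}

#' @export
print.ecg_stft <- function(x, ...) {
  cat(sprintf("STFT: %d frequency bins x %d frames (L=%d, hop=%d, fs=%g)\n",
              nrow(x$power), ncol(x$power), x$window_len, x$hop, x$fs))
  invisible(x)
}

# 256-entry jet-like colormap lookup table (dark blue -> cyan -> yellow ->
# red), built in code; columns R, G, B in [0, 1]
.jet_lut <- function(n = 256) {
  u <- seq(0, 1, length.out = n)
  r <- pmin(pmax(1.5 - abs(4 * u - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * u - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * u - 1), 0), 1)
  cbind(r, g, b)
}

.bilinear_resize <- function(m, height, width) {
  src_h <- nrow(m); src_w <- ncol(m)
  if (src_h == 1) m <- rbind(m, m)
  if (src_w == 1) m <- cbind(m, m)
  xs <- seq(1, ncol(m), length.out = width)
  ys <- seq(1, nrow(m), length.out = height)
  pracma::interp2(x = seq_len(ncol(m)), y = seq_len(nrow(m)), Z = m,
                  xp = rep(xs, each = height),
                  yp = rep(ys, times = width)) |>
    matrix(nrow = height, ncol = width)
}

#' Render an STFT power matrix as a fixed-size image
#'
#' Power is converted to decibels with a floor at -100 dB, linearly
#' rescaled to 8-bit intensities, resized bilinearly, and encoded either as
#' grayscale (one integer per pixel) or RGB through a fixed jet-like
#' colormap. Frequency increases upward (row 1 of the image is the highest
#' frequency), time runs left to right. Rendering is deterministic and
#' monotone: larger power never maps to a smaller grayscale intensity.
#'
#' @param stft An [ecg_stft()] (or a bare power matrix).
#' @param mode `"gray"` or `"rgb"`.
#' @param height,width Output dimensions in pixels.
#' @return Object of class `spectro_image`: integer array
#'   `height x width x channels` with values in 0..255.
#' @export
render_spectrogram <- function(stft, mode = c("gray", "rgb"),
                               height = 656, width = 875) {
  mode <- match.arg(mode)
  power <- if (inherits(stft, "ecg_stft")) stft$power else stft
  if (length(power) == 0) stop("empty power matrix")
  db <- 10 * log10(pmax(power, 1e-10))        # floor at -100 dB
  rng <- range(db)
  scaled <- if (rng[2] > rng[1]) (db - rng[1]) / (rng[2] - rng[1])
            else matrix(0, nrow(db), ncol(db))
  img <- .bilinear_resize(scaled[rev(seq_len(nrow(scaled))), , drop = FALSE],
                          height, width)
  img <- pmin(1, pmax(0, img))
  intensity <- round(img * 255)
  if (mode == "gray") {
    px <- array(as.integer(intensity), dim = c(height, width, 1))
  } else {
    lut <- .jet_lut(256)
    px <- array(as.integer(round(lut[intensity + 1, ] * 255)),
                dim = c(height, width, 3))
  }
  structure(list(pixels = px, mode = mode), class = "spectro_image")
}

#' @export
print.spectro_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("%s spectrogram image: %d x %d x %d (8-bit)\n",
              x$mode, d[1], d[2], d[3]))
  invisible(x)
}

#' Write a rendered spectrogram image to a PNG file
#'
#' @param image A `spectro_image` from [render_spectrogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_png <- function(image, path) {
  stopifnot(inherits(image, "spectro_image"))
  arr <- image$pixels / 255
  if (dim(arr)[3] == 1) arr <- arr[, , 1]
  png::writePNG(arr, path)
  invisible(path)
}
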