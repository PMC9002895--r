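# O(N^2) DFT, the independent oracle for the STFT
naive_stft <- function(x, L, hop, n_fft = L) {
  w <- hanning_window(L)
  k <- floor((length(x) - L) / hop) + 1
  nf <- floor(n_fft / 2) + 1
  sapply(seq_len(k), function(m) {
    fr <- c(w * x[((m - 1) * hop + 1):((m - 1) * hop + L)],
            numeric(n_fft - L))
    vapply(0:(nf - 1), function(f) {
      Mod(sum(fr * exp(-2i * pi * f * (0:(n_fft - 1)) / n_fft)))^2
    }, numeric(1))
  })
}

test_that("the Hann window has unit range, zero endpoints and symmetry", {
  expect_equal(hanning_window(3), c(0, 1, 0))
  for (L in c(2, 5, 28, 167)) {
    w <- hanning_window(L)
    expect_equal(w, rev(w))
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(w[c(1, L)], c(0, 0))
  }
  expect_equal(max(hanning_window(167)), 1)
  expect_error(hanning_window(1), ">= 2")
})

test_that("column and bin counts follow the closed-form bookkeeping", {
  s <- ecg_stft(runif(750), 167, 83)
  expect_equal(ncol(s$power), 8)              # floor((750-167)/83)+1
  expect_equal(nrow(s$power), 84)             # floor(167/2)+1
  for (case in list(c(300, 28, 14), c(512, 64, 32), c(100, 16, 5))) {
    s <- ecg_stft(runif(case[1]), case[2], case[3])
    expect_equal(ncol(s$power),
                 floor((case[1] - case[2]) / case[3]) + 1)
    expect_equal(nrow(s$power), floor(case[2] / 2) + 1)
  }
  expect_error(ecg_stft(runif(100), 167), "shorter")
})

test_that("the FFT path equals the naive DFT oracle to 1e-9", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(64:512, 1)
    L <- sample(c(16, 28, 32), 1)
    hop <- max(1, L %/% 2)
    x <- rnorm(n)
    expect_equal(ecg_stft(x, L, hop)$power, naive_stft(x, L, hop),
                 tolerance = 1e-9)
  }
})

test_that("per-column energy satisfies Parseval with the one-sided fold", {
  set.seed(32)
  x <- rnorm(400)
  L <- 32; hop <- 16
  s <- ecg_stft(x, L, hop)
  w <- hanning_window(L)
  for (m in seq_len(ncol(s$power))) {
    fr <- w * x[((m - 1) * hop + 1):((m - 1) * hop + L)]
    col <- s$power[, m]
    folded <- col[1] + col[L / 2 + 1] + 2 * sum(col[2:(L / 2)])
    expect_equal(folded / L, sum(fr^2), tolerance = 1e-6 * sum(fr^2))
  }
})

test_that("a bin-aligned tone concentrates in a single bin per column", {
  fs <- 250; L <- 50; hop <- 25
  f0 <- 4 * fs / L                            # exactly bin 4
  x <- sin(2 * pi * f0 * (0:999) / fs)
  s <- ecg_stft(x, L, hop, fs = fs)
  for (m in seq_len(ncol(s$power))) {
    expect_equal(which.max(s$power[, m]) - 1, 4)
    expect_gt(s$power[5, m], 10 * max(s$power[-(4:6), m]))
  }
})

test_that("rendering produces the fixed image geometry per mode", {
  s <- ecg_stft(clean_lead()[1:750], 167, 83)
  rgb <- render_spectrogram(s, "rgb")
  expect_equal(dim(rgb$pixels), c(656, 875, 3))
  gray <- render_spectrogram(s, "gray")
  expect_equal(dim(gray$pixels), c(656, 875, 1))
  expect_true(is.integer(gray$pixels))
  expect_true(all(gray$pixels >= 0 & gray$pixels <= 255))
  expect_identical(render_spectrogram(s, "rgb")$pixels, rgb$pixels)
})

test_that("grayscale rendering is monotone in power and safe on zeros", {
  p <- matrix(10^seq(-8, 2, length.out = 24), 4, 6)
  img <- render_spectrogram(p, "gray", height = 4, width = 6)
  v <- as.vector(img$pixels[rev(seq_len(4)), , 1])  # undo frequency flip
  expect_true(all(diff(v[order(as.vector(p))]) >= 0))
  z <- render_spectrogram(matrix(0, 5, 5), "gray", 8, 8)
  expect_true(all(z$pixels == z$pixels[1]))
})

test_that("PNG output round-trips pixel intensities", {
  s <- ecg_stft(clean_lead()[1:750], 167, 83)
  img <- render_spectrogram(s, "gray", height = 64, width = 87)
  f <- withr::local_tempfile(fileext = ".png")
  write_spectrogram_png(img, f)
  back <- round(png::readPNG(f) * 255)
  expect_equal(back, img$pixels[, , 1], ignore_attr = TRUE)
})
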