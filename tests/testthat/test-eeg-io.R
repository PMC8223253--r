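# EDF round trips, montages, band filters, segment extraction

test_that("EDF round trip preserves channels, fs, annotations and samples to quantization", {
  set.seed(42)
  ann <- data.frame(label = c("SED", "hfo_gamma"), onset_s = c(0.25, 1.0),
                    duration_s = c(1.5, 0.1), channel = c("all", "C3"),
                    stringsAsFactors = FALSE)
  rec <- eeg_recording(matrix(rnorm(3 * 4000, sd = 40), ncol = 3),
                       c("C3", "C4", "Cz"), 1000, ann)
  path <- tempfile(fileext = ".edf")
  on.exit(unlink(c(path, paste0(path, ".ann.tsv"))), add = TRUE)
  write_edf(rec, path)
  rt <- read_edf(path)
  expect_identical(rt$channel_names, rec$channel_names)
  expect_equal(rt$fs, 1000)
  expect_equal(rt$annotations, rec$annotations)
  for (j in 1:3) {
    step <- 2 * max(abs(rec$data[, j])) * 1.0001 / 2^16
    expect_lt(max(abs(rt$data[, j] - rec$data[, j])), step + 1e-12)
  }
})

test_that("EDF handles non-integer-second records and rejects bad input", {
  x <- matrix(sin(2 * pi * 10 * (0:1499) / 1000), ncol = 1)
  rec <- eeg_recording(x, "Cz", 1000)
  path <- tempfile(fileext = ".edf")
  on.exit(unlink(path), add = TRUE)
  write_edf(rec, path)
  rt <- read_edf(path)
  expect_equal(nrow(rt$data), 1500)
  expect_equal(rt$fs, 1000)

  # duplicate channel labels: patch the second label field in the header
  rec2 <- eeg_recording(matrix(rnorm(2000), ncol = 2), c("C3", "C4"), 1000)
  path2 <- tempfile(fileext = ".edf")
  on.exit(unlink(path2), add = TRUE)
  write_edf(rec2, path2)
  raw <- readBin(path2, "raw", file.info(path2)$size)
  raw[256 + 16 + seq_len(16)] <- raw[256 + seq_len(16)]
  writeBin(raw, path2)
  expect_error(read_edf(path2), "duplicate channel labels")

  # empty recording refuses to write
  empty <- structure(list(data = matrix(numeric(0), nrow = 0, ncol = 0),
                          channel_names = character(), fs = 1000,
                          annotations = NULL), class = "eeg_recording")
  expect_error(write_edf(empty, tempfile()), "empty recording")
  expect_error(read_edf(tempfile("nope")), "no such file")
})

test_that("average reference removes common mode and sums to zero", {
  set.seed(1)
  x <- matrix(rnorm(4 * 500), ncol = 4)
  rec <- eeg_recording(x, c("C3", "C4", "P3", "P4"), 500)
  ar <- apply_montage(rec, "average_reference")
  expect_lt(max(abs(rowSums(ar$data))), 1e-10)
  # constant offset on all channels is rejected entirely
  rec2 <- rec; rec2$data <- rec2$data + 57.3
  ar2 <- apply_montage(rec2, "average_reference")
  expect_equal(ar2$data, ar$data, tolerance = 1e-12)
  # linearity
  rec3 <- rec; rec3$data <- rec3$data * 2.5
  ar3 <- apply_montage(rec3, "average_reference")
  expect_equal(ar3$data, ar$data * 2.5, tolerance = 1e-12)
})

test_that("longitudinal bipolar montage chains and errors on missing channels", {
  set.seed(2)
  x <- matrix(rnorm(19 * 200), ncol = 19)
  rec <- eeg_recording(x, channels_1020(), 200)
  # identical signals on Fp1 and F7 => Fp1-F7 derivation is zero
  rec$data[, "F7"] <- rec$data[, "Fp1"]
  bp <- apply_montage(rec, "longitudinal_bipolar")
  expect_equal(bp$channel_names[1], "Fp1-F7")
  expect_equal(max(abs(bp$data[, "Fp1-F7"])), 0)
  expect_equal(bp$data[, "F7-T3"], rec$data[, "F7"] - rec$data[, "T3"])
  expect_equal(ncol(bp$data), 18)

  rec_small <- eeg_recording(x[, 1:3], c("Fp1", "Fp2", "F3"), 200)
  expect_error(apply_montage(rec_small, "longitudinal_bipolar"), "missing channel")
})

test_that("bandpass meets pass-band and stop-band specs", {
  fs <- 1000
  t <- (0:9999) / fs
  x <- sin(2 * pi * 60 * t)
  mid <- 3000:7000
  expect_gt(max(abs(bandpass(x, "gamma", fs)[mid])), 0.89)
  expect_lte(max(abs(bandpass(x, "gamma", fs)[mid])), 1.0 + 1e-6)
  expect_lt(max(abs(bandpass(x, "fast_ripple", fs)[mid])), 0.01)
  # one octave above the ripple band: >= 40 dB down
  x400 <- sin(2 * pi * 400 * t)
  expect_lt(max(abs(bandpass(x400, "ripple", fs)[mid])), 0.01)
  expect_error(bandpass(x, "fast_ripple", 500), "Nyquist")
})

test_that("band powers of white noise sum to at most the 40-300 Hz total", {
  set.seed(3)
  fs <- 1000
  x <- rnorm(30000)
  bandpow <- sum(vapply(names(hfo_bands()),
                        function(b) var(bandpass(x, b, fs)), numeric(1)))
  psd <- welch_psd(x, fs, nperseg = 2048)
  sel <- psd$freq >= 40 & psd$freq <= 300
  total <- sum(psd$psd[sel]) * (psd$freq[2] - psd$freq[1])
  expect_lte(bandpow, total * 1.05)
  expect_gt(bandpow, total * 0.7)  # filters cover most of 40-300
})

test_that("filtering an already band-limited signal changes RMS by < 5%", {
  set.seed(4)
  n <- 20000; fs <- 1000
  freqs <- seq(0, fs - fs / n, length.out = n)
  freqs <- pmin(freqs, fs - freqs)
  for (b in hfo_bands()) {
    # flat-spectrum noise strictly inside the band (inner 80%)
    bw <- b$high - b$low
    shape <- as.numeric(freqs >= b$low + 0.1 * bw & freqs <= b$high - 0.1 * bw)
    y1 <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE)) / n
    y2 <- bandpass(y1, b, fs)
    expect_lt(abs(sd(y2) - sd(y1)) / sd(y1), 0.05)
  }
})

test_that("extract_segment honours the state protocol", {
  rec <- generate_background(301, 1000, c("C3", "C4"), 15, seed = 9)
  rec$annotations <- data.frame(label = c("SED", "S"), onset_s = c(0.5, 300.6),
                                duration_s = c(300, 0.4), channel = "all",
                                stringsAsFactors = FALSE)
  seg <- extract_segment(rec, "SED", 300, subject = "IS01", group = "IS")
  expect_equal(nrow(seg$data), 300000)
  expect_identical(seg$state, "SED")
  expect_identical(seg$subject, "IS01")

  rec2 <- generate_background(3, 1000, "Cz", 15, seed = 10)
  rec2$annotations <- data.frame(label = "S", onset_s = 0.5, duration_s = 2,
                                 channel = "all", stringsAsFactors = FALSE)
  seg2 <- extract_segment(rec2, "S", 2)
  expect_equal(nrow(seg2$data), 2000)
  expect_error(extract_segment(rec2, "Pre-S", 2), "available labels")
})
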