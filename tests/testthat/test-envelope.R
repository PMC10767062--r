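test_that("ERB-rate scale evaluates the closed form and inverts", {
  expect_equal(erb_rate(1000), 21.4 * log10(1 + 4.37), tolerance = 1e-12)
  expect_equal(erb_rate(1000), 15.62145, tolerance = 1e-4)
  expect_equal(erb_rate_inv(erb_rate(c(50, 440, 4000))), c(50, 440, 4000),
               tolerance = 1e-9)
})

test_that("filter-bank centres are strictly increasing and ERB-rate equispaced", {
  bank <- erb_filterbank(cochleagram_spec(n_filters = 30))
  expect_equal(nrow(bank), 30)
  expect_true(all(diff(bank$center_hz) > 0))
  gaps <- diff(bank$erb_rate)
  expect_lt(max(gaps) - min(gaps), 1e-9)
  # degenerate one-filter bank collapses to the requested frequency
  single <- erb_filterbank(cochleagram_spec(n_filters = 1, f_low = 1000,
                                            f_high = 1000))
  expect_equal(single$center_hz, 1000, tolerance = 1e-9)
  expect_error(cochleagram_spec(f_high = 30000, audio_fs = 44100), "Nyquist")
})

test_that("cochlear envelope recovers an amplitude modulation and is linear", {
  fs <- 8000
  t <- seq(0, 2, by = 1 / fs)
  am <- (1 + sin(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t)
  spec <- cochleagram_spec(n_filters = 10, f_low = 200, f_high = 3000,
                           audio_fs = fs)
  env <- cochlear_envelope(am, spec)$envelope
  expect_true(all(env >= 0))
  sp <- stats::spec.pgram(env - mean(env), plot = FALSE, taper = 0)
  peak_hz <- sp$freq[which.max(sp$spec)] * fs
  expect_equal(peak_hz, 4, tolerance = 0.5)
  # homogeneity: doubling the audio doubles the envelope
  env2 <- cochlear_envelope(2 * am, spec)$envelope
  expect_equal(env2, 2 * env, tolerance = 1e-8)
  # silence in, silence out
  expect_equal(cochlear_envelope(numeric(1000), spec)$envelope,
               numeric(1000))
})

test_that("band-limiting passes 4 Hz, rejects 20 Hz and DC, with zero phase", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  keep <- seq(fs, length(t) - fs)  # interior, away from filter edges
  s4 <- sin(2 * pi * 4 * t)
  y4 <- bandlimit_resample(s4, fs, fs)
  expect_equal(sqrt(mean(y4[keep]^2)) / sqrt(mean(s4[keep]^2)), 1,
               tolerance = 0.05)
  s20 <- sin(2 * pi * 20 * t)
  y20 <- bandlimit_resample(s20, fs, fs)
  expect_lt(sqrt(mean(y20[keep]^2)) / sqrt(mean(s20[keep]^2)), 0.1)
  dc <- bandlimit_resample(rep(1, 5000), fs, fs)
  expect_lt(max(abs(dc[keep])), 0.01)  # > 40 dB DC rejection
  # forward-backward filtering leaves an impulse response symmetric
  imp <- c(rep(0, 2499), 1, rep(0, 2500))
  h <- bandlimit_resample(imp, fs, fs)
  xc <- stats::ccf(h, imp, lag.max = 50, plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 0)
})

test_that("resampling to 64 Hz yields the expected length", {
  fs <- 1000
  x <- sin(2 * pi * 4 * seq(0, 30, by = 1 / fs))[1:30000]
  y <- bandlimit_resample(x, fs, 64)
  expect_equal(length(y), 1920)
})

test_that("epoching reproduces the trial arithmetic of the emulated design", {
  x <- rnorm(60 * 64)
  ep <- epoch_trace(x, fs = 64, epoch_seconds = 30)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$n_samples, c(1920, 1920))
  expect_equal(nrow(epoch_trace(rnorm(30 * 64), 64, 30)), 1)
  # 500 ms head discard: second epoch is the residual 29.5 s
  ep2 <- epoch_trace(x, fs = 64, epoch_seconds = 30, discard_head_ms = 500)
  expect_equal(nrow(ep2), 2)
  expect_equal(ep2$n_samples, c(1920, 1888))
  expect_equal(ep2$start_sample, c(33, 1953))
  expect_error(epoch_trace(rnorm(100), 64, 30), "shorter")
})

test_that("audio and EEG epoch grids are sample-aligned", {
  env <- rnorm(60 * 64)
  eeg <- matrix(rnorm(3 * 60 * 64), nrow = 3)
  a <- epoch_trace(env, 64, 30, discard_head_ms = 500)
  b <- epoch_trace(eeg, 64, 30, discard_head_ms = 500)
  expect_equal(a$start_sample, b$start_sample)
  expect_equal(a$n_samples, b$n_samples)
  expect_equal(ncol(b$data[[2]]), a$n_samples[2])
})

test_that("end-to-end envelope of an AM tone lands on the modulation rate", {
  fs <- 8000
  t <- seq(0, 10, by = 1 / fs)[1:(10 * fs)]
  spec <- cochleagram_spec(n_filters = 8, f_low = 300, f_high = 2500,
                           audio_fs = fs)
  for (m in c(2, 4, 8)) {
    am <- (1 + sin(2 * pi * m * t)) * sin(2 * pi * 800 * t)
    env <- cochlear_envelope(am, spec)$envelope
    env64 <- bandlimit_resample(env, fs, 64)
    sp <- stats::spec.pgram(env64 - mean(env64), plot = FALSE, taper = 0)
    peak_hz <- sp$freq[which.max(sp$spec)] * 64
    bin <- 64 / length(env64)
    expect_equal(peak_hz, m, tolerance = bin + 1e-9)
  }
})

test_that("WAV reader round-trips PCM16 and averages stereo to mono", {
  fs <- 8000
  x <- sin(2 * pi * 440 * seq(0, 0.1, by = 1 / fs))
  pcm <- as.integer(round(x * 32767))
  path <- withr::local_tempfile(fileext = ".wav")
  write_pcm16_wav <- function(path, samples, fs, channels = 1L) {
    con <- file(path, "wb"); on.exit(close(con))
    data_bytes <- length(samples) * 2L
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(16L, con, size = 4, endian = "little")
    writeBin(1L, con, size = 2, endian = "little")
    writeBin(channels, con, size = 2, endian = "little")
    writeBin(as.integer(fs), con, size = 4, endian = "little")
    writeBin(as.integer(fs * channels * 2), con, size = 4, endian = "little")
    writeBin(as.integer(channels * 2), con, size = 2, endian = "little")
    writeBin(16L, con, size = 2, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(data_bytes, con, size = 4, endian = "little")
    writeBin(samples, con, size = 2, endian = "little")
  }
  write_pcm16_wav(path, pcm, fs)
  wav <- read_wav(path)
  expect_equal(wav$fs, fs)
  expect_equal(wav$samples, pcm / 32768, tolerance = 1e-9)
  # stereo: interleaved L/R averages to mono
  inter <- as.integer(rbind(pcm, 0L))
  write_pcm16_wav(path, inter, fs, channels = 2L)
  expect_warning(wav2 <- read_wav(path), "mono")
  expect_equal(wav2$samples, pcm / 32768 / 2, tolerance = 1e-9)
})
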