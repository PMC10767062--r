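#' ERB-rate scale
#'
#' Convert frequency in Hz to the equivalent-rectangular-bandwidth (ERB) rate
#' scale, `21.4 * log10(1 + 0.00437 * f)`, the standard perceptual scale used
#' to space cochlear filter banks, and back.
#'
#' @param f Frequency in Hz.
#' @param e ERB-rate value.
#' @return Numeric vector of ERB-rate values (Hz for the inverse).
#' @examples
#' erb_rate(1000)
#' erb_rate_inv(erb_rate(1000))
#' @export
erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' @rdname erb_rate
#' @export
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Equivalent rectangular bandwidth at a centre frequency
#'
#' Glasberg-Moore ERB in Hz: `24.7 * (4.37 * f / 1000 + 1)`.
#' @param f Centre frequency, Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Cochleagram specification
#'
#' Parameters of the ERB filter bank used to compute a cochleagram. Defaults
#' follow common cochleagram practice: 38 band-pass filters with centres
#' equally spaced on the ERB-rate scale between 30 Hz and 7.5 kHz.
#'
#' @param n_filters Number of band-pass filters.
#' @param f_low,f_high Lowest and highest centre frequencies, Hz.
#' @param audio_fs Audio sampling rate, Hz.
#' @return A list of class `cochleagram_spec`.
#' @export
cochleagram_spec <- function(n_filters = 38L, f_low = 30, f_high = 7500,
                             audio_fs = 44100) {
  if (n_filters < 1) abort("`n_filters` must be >= 1.")
  if (!(f_low > 0 && f_low <= f_high)) abort("need 0 < f_low <= f_high.")
  if (f_high > audio_fs / 2) abort("`f_high` is above the Nyquist frequency.")
  structure(list(n_filters = as.integer(n_filters), f_low = f_low,
                 f_high = f_high, audio_fs = audio_fs),
            class = "cochleagram_spec")
}

#' ERB-spaced filter bank
#'
#' Centre frequencies are equally spaced on the ERB-rate scale between
#' `f_low` and `f_high`; each band spans +/- 0.5 ERB-rate units around its
#' centre (about one equivalent rectangular bandwidth), realised as a 4th-order
#' Butterworth band-pass applied forward-backward (zero phase).
#'
#' @param spec A [cochleagram_spec()].
#' @return A tibble with one row per band: `band`, `center_hz`, `erb_rate`,
#'   `edge_lo_hz`, `edge_hi_hz`.
#' @export
erb_filterbank <- function(spec) {
  stopifnot(inherits(spec, "cochleagram_spec"))
  e <- if (spec$n_filters == 1L) {
    mean(erb_rate(c(spec$f_low, spec$f_high)))
  } else {
    seq(erb_rate(spec$f_low), erb_rate(spec$f_high), length.out = spec$n_filters)
  }
  centers <- erb_rate_inv(e)
  nyq <- spec$audio_fs / 2
  tibble(
    band = seq_along(centers),
    center_hz = centers,
    erb_rate = e,
    edge_lo_hz = pmax(erb_rate_inv(e - 0.5), 1e-3),
    edge_hi_hz = pmin(erb_rate_inv(e + 0.5), 0.999 * nyq)
  )
}

# Analytic signal via FFT (Hilbert construction): negative frequencies zeroed,
# positive doubled. Returns a complex vector; Mod() of it is the envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Cochlear amplitude envelope of an audio signal
#'
#' Decomposes audio through an ERB-spaced Butterworth filter bank, takes each
#' subband's envelope as the magnitude of its analytic signal, and averages
#' the subband envelopes into a single nonnegative amplitude envelope at the
#' audio sampling rate.
#'
#' @param audio Numeric vector, mono audio at `spec$audio_fs`.
#' @param spec A [cochleagram_spec()].
#' @return A tibble with columns `t` (seconds) and `envelope`.
#' @export
cochlear_envelope <- function(audio, spec) {
  stopifnot(inherits(spec, "cochleagram_spec"))
  if (!is.numeric(audio) || anyNA(audio)) abort("`audio` must be numeric, no NA.")
  bank <- erb_filterbank(spec)
  nyq <- spec$audio_fs / 2
  env <- rep(0, length(audio))
  for (i in seq_len(nrow(bank))) {
    bf <- signal::butter(2, c(bank$edge_lo_hz[i], bank$edge_hi_hz[i]) / nyq,
                         type = "pass")
    sub <- signal::filtfilt(bf, audio)
    env <- env + Mod(analytic_signal(sub))
  }
  tibble(t = (seq_along(audio) - 1) / spec$audio_fs,
         envelope = env / nrow(bank))
}

#' Band-limit and resample a trace
#'
#' Applies a 4th-order Butterworth band-pass (default corners 1 and 9 Hz)
#' forward and backward (zero phase), then resamples to `fs_out`. The
#' band-pass itself provides anti-aliasing: `fs_out` must exceed twice the
#' upper corner. This is the common preprocessing applied to both the EEG and
#' the stimulus envelope before decoding.
#'
#' @param x Numeric vector sampled at `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates, Hz.
#' @param band Length-2 band corners in Hz, default `c(1, 9)`.
#' @return Numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @export
bandlimit_resample <- function(x, fs_in, fs_out = fs_in, band = c(1, 9)) {
  if (fs_in <= 2 * band[2]) abort("`fs_in` must exceed twice the upper corner.")
  if (fs_out > fs_in) abort("`fs_out` must be <= `fs_in`.")
  if (fs_out <= 2 * band[2]) abort("`fs_out` must exceed twice the upper corner.")
  # filtfilt needs enough samples to pad its edge transients
  if (length(x) < 24) abort("input too short to band-pass filter.")
  bf <- signal::butter(2, band / (fs_in / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  if (fs_out == fs_in) return(y)
  n_out <- round(length(x) * fs_out / fs_in)
  t_in <- (seq_along(y) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, y, xout = t_out, rule = 2)$y
}

#' Cut a trace into consecutive epochs
#'
#' Drops the first `discard_head_ms` milliseconds, then emits consecutive
#' non-overlapping epochs of `floor(epoch_seconds * fs)` samples. A trailing
#' fragment of at least half an epoch is kept as a (shorter) final epoch; this
#' rule turns a 60-s trial with 500 ms discarded into one 30-s epoch and one
#' 29.5-s epoch, so sixteen trials yield 32 epochs. EEG and envelope traces
#' epoched with the same parameters share identical boundaries and so stay
#' sample-aligned.
#'
#' @param x Numeric vector (envelope samples) or a channels-by-time matrix
#'   (EEG), sampled at `fs`.
#' @param fs Sampling rate, Hz.
#' @param epoch_seconds Epoch duration, seconds.
#' @param discard_head_ms Milliseconds discarded from the head (default 0).
#' @return A tibble with `epoch_index`, `start_sample` (1-based, in the
#'   original trace), `n_samples`, and a list-column `data` holding each
#'   epoch's vector (or matrix, channels x time).
#' @export
epoch_trace <- function(x, fs, epoch_seconds, discard_head_ms = 0) {
  is_mat <- is.matrix(x)
  n <- if (is_mat) ncol(x) else length(x)
  drop_n <- round(discard_head_ms / 1000 * fs)
  len <- floor(epoch_seconds * fs)
  avail <- n - drop_n
  if (avail < len) abort("trace shorter than one epoch after head discard.")
  starts <- seq(drop_n + 1, n, by = len)
  lens <- pmin(len, n - starts + 1)
  keep <- lens >= len / 2
  starts <- starts[keep]; lens <- lens[keep]
  slices <- purrr::map2(starts, lens, function(s, l) {
    if (is_mat) x[, s:(s + l - 1), drop = FALSE] else x[s:(s + l - 1)]
  })
  tibble(epoch_index = seq_along(starts), start_sample = starts,
         n_samples = lens, data = slices)
}

#' Read a mono waveform from a RIFF WAV file
#'
#' Minimal PCM reader (8/16/24/32-bit integer and 32/64-bit float). Stereo
#' files are averaged to mono with a warning. Provided so audio excerpts can
#' be fed straight into [cochlear_envelope()]; no resampling is performed.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric, in \[-1, 1\]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) abort("not a RIFF/WAV file.")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    abort("not a WAVE file.")
  }
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little")
      )
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("malformed WAV: missing chunk.")
  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  x <- if (fmt$code == 3L) {
    readBin(data_raw, "double", n, bytes, endian = "little")
  } else if (fmt$bits == 8L) {
    (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 24L) {
    b <- matrix(as.integer(data_raw), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else {
    readBin(data_raw, "integer", n, bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1)
  }
  if (fmt$channels > 1L) {
    warn(sprintf("averaging %d channels to mono", fmt$channels))
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  list(samples = as.numeric(x), fs = fmt$fs)
}
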