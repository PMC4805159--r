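#' Sampled waveform
#'
#' @param samples Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @return A `waveform` object.
#' @export
waveform <- function(samples, sample_rate) {
  sample_rate <- as.integer(sample_rate)
  if (sample_rate < 1L) abort("sample_rate must be positive")
  samples <- as.double(samples)
  if (anyNA(samples)) abort("waveform samples must be finite")
  structure(list(samples = samples, sample_rate = sample_rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %d Hz (%.2f s), peak %.3f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Render a note sequence to audio
#'
#' Additive synthesizer: each note renders as a sine at its equal-temperament
#' frequency (A4 = 440 Hz, `f = 440 * 2^((pitch - 69)/12)`) with a linear
#' 10 ms attack/release envelope (shortened to half the note for very short
#' notes); rests render as silence. Amplitude is `velocity / 127 * gain`.
#' Event boundaries are derived from cumulative tick times, so total duration
#' equals `total_ticks * tick_duration` to within one sample.
#'
#' A one-LSB (16-bit) uniform dither is added by default, reproducing the
#' noise floor any PCM render chain has; it keeps downstream spectral
#' summaries well-conditioned on pure tones and exact silence. The dither is
#' drawn under a fixed internal seed, so synthesis is fully deterministic.
#'
#' @param seq A [note_sequence()].
#' @param sample_rate Output rate in Hz (44100 for a CD-rate WAV).
#' @param gain Linear gain applied to all notes (default 0.8, headroom for
#'   16-bit output).
#' @param dither Peak amplitude of the uniform dither; 0 disables it.
#'
#' @return A [waveform()].
#' @export
synthesize <- function(seq, sample_rate = 44100, gain = 0.8, dither = 1 / 32767) {
  stopifnot(inherits(seq, "note_sequence"))
  tick_s <- tick_duration_us(seq$timing) * 1e-6
  n_total <- round(total_ticks(seq) * tick_s * sample_rate)
  out <- numeric(n_total)
  ev <- seq$events
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] != "note") next
    a <- floor(ev$start_tick[i] * tick_s * sample_rate)
    z <- floor((ev$start_tick[i] + ev$duration_ticks[i]) * tick_s * sample_rate)
    n <- z - a
    if (n <= 0) next
    f <- 440 * 2^((ev$pitch[i] - 69) / 12)
    t <- (seq_len(n) - 1) / sample_rate
    y <- sin(2 * pi * f * t)
    ramp <- min(round(0.010 * sample_rate), n %/% 2L)
    if (ramp > 0) {
      env <- rep(1, n)
      env[seq_len(ramp)] <- seq_len(ramp) / ramp
      env[(n - ramp + 1L):n] <- rev(seq_len(ramp)) / ramp
      y <- y * env
    }
    out[(a + 1L):z] <- y * (ev$velocity[i] / 127) * gain
  }
  if (dither > 0 && n_total > 0) {
    out <- out + with_seed(20201L, runif(n_total, -dither, dither))
  }
  waveform(out, sample_rate)
}

#' Write a waveform as a 16-bit mono PCM WAV file
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(round(pmin(pmax(w$samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(w$sample_rate, con, size = 4, endian = "little")
  writeBin(w$sample_rate * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit mono PCM WAV file
#'
#' @param path WAV file path.
#' @return A [waveform()] with samples rescaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) abort(sprintf("'%s' is not a RIFF file", path))
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) abort(sprintf("'%s' is not a WAV file", path))
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) abort(sprintf("no data chunk found in '%s'", path))
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", len - 8L)
      if (fmt != 1L || ch != 1L) abort("only 16-bit mono PCM WAV is supported")
    } else if (id == "data") {
      pcm <- readBin(con, "integer", len %/% 2L, size = 2, endian = "little", signed = TRUE)
      if (is.null(sample_rate)) abort(sprintf("data chunk before fmt chunk in '%s'", path))
      return(waveform(pcm / 32767, sample_rate))
    } else {
      readBin(con, "raw", len)
    }
  }
}
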