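# Mel-frequency cepstral coefficients for waveform summarization.
#
# Standard chain: pre-emphasis, fixed-size Hamming-windowed frames, power
# spectrum, triangular mel filterbank, log, orthonormal DCT-II. No liftering
# and no delta coefficients.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular filterbank matrix (n_filters x (nfft/2 + 1)) over 0..sr/2.
mel_filterbank <- function(n_filters, nfft, sample_rate) {
  pts <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                       length.out = n_filters + 2L))
  bins <- floor((nfft + 1) * pts / sample_rate)
  fb <- matrix(0, n_filters, nfft %/% 2L + 1L)
  for (j in seq_len(n_filters)) {
    lo <- bins[j]; mid <- bins[j + 1L]; hi <- bins[j + 2L]
    if (mid > lo) {
      k <- lo:(mid - 1L)
      fb[j, k + 1L] <- (k - lo) / (mid - lo)
    }
    if (hi > mid) {
      k <- mid:(hi - 1L)
      fb[j, k + 1L] <- (hi - k) / (hi - mid)
    }
  }
  fb
}

# Orthonormal DCT-II matrix (n_coeff x m).
dct_matrix <- function(n_coeff, m) {
  k <- seq_len(n_coeff) - 1L
  j <- seq_len(m) - 1L
  d <- sqrt(2 / m) * cos(pi * outer(k, 2 * j + 1) / (2 * m))
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

#' Number of analysis frames for a framed signal
#' @param n_samples Signal length in samples.
#' @param window,hop Frame and hop sizes in samples.
#' @return `floor((n_samples - window) / hop) + 1` (0 when the signal is
#'   shorter than one window).
#' @export
n_frames <- function(n_samples, window, hop) {
  if (n_samples < window) return(0L)
  as.integer((n_samples - window) %/% hop + 1L)
}

#' Extract MFCC frames from a waveform
#'
#' Applies pre-emphasis (coefficient 0.97), splits the signal into
#' Hamming-windowed frames, takes the periodogram power spectrum, passes it
#' through a triangular mel filterbank, logs the filter energies and applies
#' an orthonormal DCT-II, keeping the first `n_coeff` coefficients.
#' Coefficient 0 carries overall log energy; the rest describe spectral
#' shape.
#'
#' @param w A [waveform()].
#' @param n_coeff Number of cepstral coefficients to keep (30 at this
#'   package's default operating point).
#' @param window_ms,hop_ms Frame and hop lengths in milliseconds.
#' @param n_filters Number of mel filters; defaults to `max(26, n_coeff)`
#'   since the DCT of `M` filter energies has at most `M` coefficients.
#' @param preemphasis Pre-emphasis coefficient.
#'
#' @return An `mfcc_matrix` with fields `frames` (F x `n_coeff` matrix),
#'   `window_ms`, `hop_ms`, `n_coeff`, `sample_rate`.
#' @export
extract_mfcc <- function(w, n_coeff = 30, window_ms = 25, hop_ms = 10,
                         n_filters = NULL, preemphasis = 0.97) {
  stopifnot(inherits(w, "waveform"))
  n_coeff <- as.integer(n_coeff)
  if (is.null(n_filters)) n_filters <- max(26L, n_coeff)
  n_filters <- as.integer(n_filters)
  if (n_coeff < 1L || n_coeff > n_filters) {
    abort("need 1 <= n_coeff <= n_filters")
  }
  window <- as.integer(round(window_ms / 1000 * w$sample_rate))
  hop <- as.integer(round(hop_ms / 1000 * w$sample_rate))
  if (window < 2L || hop < 1L) abort("window/hop too small at this sample rate")
  x <- w$samples
  n <- length(x)
  nf <- n_frames(n, window, hop)
  if (nf < 1L) {
    abort(sprintf("waveform too short for MFCC: %d samples < one %d-sample window", n, window))
  }
  x <- c(x[1], x[-1] - preemphasis * x[-n])

  nfft <- 2^ceiling(log2(window))
  idx <- outer(seq_len(window), (seq_len(nf) - 1L) * hop, `+`) # window x F
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(window) - 1L) / (window - 1L))
  frames <- matrix(x[idx], nrow = window) * ham
  frames <- rbind(frames, matrix(0, nfft - window, nf))
  spec <- mvfft(frames)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  pow <- (Mod(spec)^2) / nfft # (nfft/2+1) x F

  fb <- mel_filterbank(n_filters, nfft, w$sample_rate)
  energies <- fb %*% pow # n_filters x F
  energies[energies < .Machine$double.eps] <- .Machine$double.eps
  cep <- dct_matrix(n_coeff, n_filters) %*% log(energies) # n_coeff x F

  structure(
    list(frames = t(cep), window_ms = window_ms, hop_ms = hop_ms,
         n_coeff = n_coeff, sample_rate = w$sample_rate),
    class = "mfcc_matrix"
  )
}

#' @export
print.mfcc_matrix <- function(x, ...) {
  cat(sprintf("<mfcc_matrix> %d frames x %d coefficients (%g ms window, %g ms hop)\n",
              nrow(x$frames), x$n_coeff, x$window_ms, x$hop_ms))
  invisible(x)
}
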