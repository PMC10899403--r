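# Zero-phase FIR filtering backbone.
#
# All temporal filters in the package are linear-phase Hamming windowed-sinc
# FIR filters (designed with signal::fir1) applied by FFT convolution with the
# group delay removed, i.e. exactly zero-phase. Windowed-sinc designs keep the
# passband flat (ripple well below 0.5 dB) — something a low-order IIR cannot
# do near its corners — and are the standard choice in EEG toolchains.

# Odd FIR length for a given transition width (Hz); the 3.3/tw rule for a
# Hamming window, bounded so short recordings stay filterable.
.fir_length <- function(sfreq, trans_hz) {
  n <- ceiling(3.3 * sfreq / trans_hz)
  if (n %% 2 == 0) n <- n + 1
  n
}

# Band-pass taps with -6 dB points at lo/hi Hz. The taps are DC-corrected
# (mean subtracted) so a constant offset is nulled exactly, not merely
# attenuated by the window's finite stopband.
fir_bandpass_taps <- function(lo, hi, sfreq, trans_hz = 2) {
  nyq <- sfreq / 2
  stopifnot(lo > 0, lo < hi)
  if (hi >= nyq) stop("band-pass upper edge must be below the Nyquist frequency")
  n <- .fir_length(sfreq, trans_hz)
  taps <- signal::fir1(n - 1, c(lo, hi) / nyq, type = "pass", window = signal::hamming(n))
  taps - mean(taps)
}

# Band-stop taps; edges are the -6 dB points, so callers should widen the
# printed stop band by the transition width to guarantee depth at its centre.
fir_bandstop_taps <- function(lo, hi, sfreq, trans_hz = 2) {
  nyq <- sfreq / 2
  if (lo <= 0 || hi >= nyq) stop("stop band must lie strictly inside (0, Nyquist)")
  n <- .fir_length(sfreq, trans_hz)
  signal::fir1(n - 1, c(lo, hi) / nyq, type = "stop", window = signal::hamming(n))
}

# Apply a (symmetric, odd-length) FIR filter to every column of x with zero
# phase: mirror-pad both ends by the group delay, FFT-convolve, then drop the
# delay. Columns are packed in complex pairs so 19 channels cost 10 FFTs.
fir_apply <- function(x, taps) {
  x <- as.matrix(x)
  n <- nrow(x); nc <- ncol(x)
  L <- length(taps)
  p <- (L - 1L) / 2L
  if (n <= p) stop("recording too short for this filter length")
  # mirror padding (without repeating the edge sample)
  xp <- x[c(seq(p + 1L, 2L), seq_len(n), seq(n - 1L, n - p)), , drop = FALSE]
  np <- nrow(xp)
  nfft <- stats::nextn(np + L - 1L, c(2, 3, 5))
  H <- .fir_response(taps, nfft)
  # pack real columns pairwise into complex columns
  npair <- nc %/% 2L
  z <- matrix(0+0i, nfft, npair + nc %% 2L)
  if (npair > 0) {
    z[seq_len(np), seq_len(npair)] <-
      xp[, 2L * seq_len(npair) - 1L, drop = FALSE] +
      1i * xp[, 2L * seq_len(npair), drop = FALSE]
  }
  if (nc %% 2L == 1L) z[seq_len(np), npair + 1L] <- xp[, nc]
  Z <- stats::mvfft(z) * H
  w <- stats::mvfft(Z, inverse = TRUE) / nfft
  out <- matrix(0, n, nc, dimnames = dimnames(x))
  rows <- seq(2L * p + 1L, 2L * p + n)
  if (npair > 0) {
    out[, 2L * seq_len(npair) - 1L] <- Re(w[rows, seq_len(npair), drop = FALSE])
    out[, 2L * seq_len(npair)] <- Im(w[rows, seq_len(npair), drop = FALSE])
  }
  if (nc %% 2L == 1L) out[, nc] <- Re(w[rows, npair + 1L])
  out
}

# Memoized FFT of zero-padded taps: a pipeline applies one filter design to
# every recording of a cohort, so the response is computed once per design.
.fir_cache <- new.env(parent = emptyenv())
.fir_response <- function(taps, nfft) {
  key <- sprintf("%d_%d", length(taps), nfft)
  hit <- .fir_cache[[key]]
  if (!is.null(hit) && identical(hit$taps, taps)) return(hit$H)
  H <- stats::fft(c(taps, numeric(nfft - length(taps))))
  .fir_cache[[key]] <- list(taps = taps, H = H)
  H
}

# Convolve several linear-phase FIR filters into one (still symmetric, odd
# length), so a filter cascade costs a single FFT pass.
fir_cascade_taps <- function(taps_list) {
  Reduce(function(a, b) stats::convolve(a, rev(b), type = "open"), taps_list)
}
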