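#' Zero-phase band-pass filter
#'
#' Applies a zero-phase 1-40 Hz band-pass (Hamming windowed-sinc FIR, applied
#' by FFT convolution with the group delay removed). The passband gain is flat
#' within +/-0.5 dB over 2-35 Hz; DC and slow drifts are strongly attenuated.
#'
#' @param rec An [eeg_recording()].
#' @param lo_hz,hi_hz Band edges in Hz (-6 dB points).
#' @param trans_hz Transition bandwidth in Hz.
#' @return The filtered recording, with provenance appended.
#' @export
bandpass_filter <- function(rec, lo_hz = 1, hi_hz = 40, trans_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (hi_hz >= rec$sfreq / 2) stop("hi_hz must be below the Nyquist frequency")
  if (lo_hz >= hi_hz) stop("lo_hz must be below hi_hz")
  taps <- fir_bandpass_taps(lo_hz, hi_hz, rec$sfreq, trans_hz)
  rec$samples <- fir_apply(rec$samples, taps)
  add_provenance(rec, "bandpass_filter",
    list(lo_hz = lo_hz, hi_hz = hi_hz, trans_hz = trans_hz, n_taps = length(taps))
  )
}

#' Zero-phase notch (band-stop) filter
#'
#' Suppresses mains interference. The stop band is widened internally by the
#' transition width so the printed band is attenuated by at least 20 dB at its
#' centre while frequencies 5 Hz away change by less than 3 dB.
#'
#' @param rec An [eeg_recording()].
#' @param stop_hz Length-2 numeric, the stop band in Hz (default 49-51).
#' @param trans_hz Transition bandwidth in Hz.
#' @return The filtered recording, with provenance appended.
#' @export
notch_filter <- function(rec, stop_hz = c(49, 51), trans_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"), length(stop_hz) == 2)
  nyq <- rec$sfreq / 2
  if (stop_hz[1] <= 0 || stop_hz[2] >= nyq) {
    stop("stop band must lie strictly inside (0, Nyquist)")
  }
  taps <- fir_bandstop_taps(stop_hz[1] - trans_hz, stop_hz[2] + trans_hz,
    rec$sfreq,
    trans_hz = trans_hz
  )
  rec$samples <- fir_apply(rec$samples, taps)
  add_provenance(rec, "notch_filter",
    list(stop_hz = stop_hz, trans_hz = trans_hz, n_taps = length(taps))
  )
}

#' Downsample a band-limited recording
#'
#' Decimates by an integer factor. The recording must already be band-limited
#' below the target Nyquist frequency (apply [bandpass_filter()] first), so
#' plain decimation is alias-free.
#'
#' @param rec An [eeg_recording()].
#' @param target_hz Target sampling rate; must divide the current rate.
#' @return The decimated recording.
#' @export
downsample <- function(rec, target_hz = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_hz >= rec$sfreq) stop("target rate must be below the current rate")
  if (rec$sfreq %% target_hz != 0) {
    stop("current sampling rate must be an integer multiple of target_hz")
  }
  k <- rec$sfreq / target_hz
  rec$samples <- rec$samples[seq(1, nrow(rec$samples), by = k), , drop = FALSE]
  rec$sfreq <- target_hz
  add_provenance(rec, "downsample", list(target_hz = target_hz, factor = k))
}

#' Cut a recording into consecutive fixed-length epochs
#'
#' Non-overlapping contiguous epochs; a trailing partial epoch is discarded.
#' All epochs start out retained.
#'
#' @param rec An [eeg_recording()].
#' @param length_s Epoch length in seconds (default 2).
#' @return An [eeg_epochs()] object.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(length_s * rec$sfreq)
  n <- nrow(rec$samples)
  n_ep <- n %/% spe
  if (n_ep < 1) stop("recording shorter than one epoch")
  x <- rec$samples[seq_len(n_ep * spe), , drop = FALSE]
  # (time, channel) -> (sample-in-epoch, epoch, channel) -> (s, ch, epoch)
  data <- aperm(array(x, dim = c(spe, n_ep, ncol(x))), c(1, 3, 2))
  prov <- c(rec$provenance, list(list(
    step = "epoch",
    params = list(length_s = length_s, n_epochs = n_ep, discarded_s = (n - n_ep * spe) / rec$sfreq)
  )))
  eeg_epochs(data, rec$sfreq, rec$channels, length_s,
    subject_id = rec$subject_id, eye_state = rec$eye_state, provenance = prov
  )
}

#' Reject epochs with voltage excursions
#'
#' Marks every epoch containing any sample with absolute amplitude strictly
#' beyond the threshold as not retained. A sample exactly at the threshold is
#' kept ("beyond" is read strictly). Sample values are never modified; the
#' rejection log records the peak channel and amplitude of each rejected
#' epoch. Rejection is intended on the original (pre-average) reference.
#'
#' @param es An [eeg_epochs()] object.
#' @param threshold_uv Rejection threshold in uV (default 150).
#' @return The epoch set with an updated retention mask and rejection log.
#' @export
reject_epochs <- function(es, threshold_uv = 150) {
  stopifnot(inherits(es, "eeg_epochs"))
  n_ep <- dim(es$data)[3]
  log_rows <- list()
  for (e in seq_len(n_ep)) {
    m <- abs(es$data[, , e])
    peak <- max(m)
    if (peak > threshold_uv) {
      es$retained[e] <- FALSE
      ch <- es$channels[which(m == peak, arr.ind = TRUE)[1, 2]]
      log_rows[[length(log_rows) + 1]] <-
        tibble::tibble(epoch = e, channel = ch, peak_uv = peak)
    }
  }
  if (length(log_rows)) {
    es$rejection_log <- dplyr::bind_rows(es$rejection_log, log_rows)
  }
  if (!any(es$retained)) {
    stop(
      "all epochs rejected at ", threshold_uv,
      " uV; review the threshold or the artifact content of the recording"
    )
  }
  es$provenance <- c(es$provenance, list(list(
    step = "reject_epochs",
    params = list(threshold_uv = threshold_uv, n_rejected = sum(!es$retained))
  )))
  es
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every time point of every epoch, the instantaneous mean
#' across channels. Idempotent: re-referencing twice equals re-referencing
#' once.
#'
#' @param es An [eeg_epochs()] object with at least two channels.
#' @return The re-referenced epoch set (`reference = "average"`).
#' @export
rereference_average <- function(es) {
  stopifnot(inherits(es, "eeg_epochs"))
  nc <- dim(es$data)[2]
  if (nc < 2) stop("average reference requires at least 2 channels")
  # instantaneous channel mean, per (sample, epoch)
  mu <- colSums(aperm(es$data, c(2, 1, 3)), dims = 1) / nc
  for (ch in seq_len(nc)) es$data[, ch, ] <- es$data[, ch, ] - mu
  es$reference <- "average"
  es$provenance <- c(es$provenance, list(list(step = "rereference_average", params = list())))
  es
}
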