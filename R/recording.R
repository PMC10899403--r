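#' Construct an EEG recording object
#'
#' A recording is one subject/eye-state multichannel resting-state time
#' series. Samples are stored time-by-channel (one column per electrode) in
#' microvolts, together with the sampling rate, the (canonical 10-20) channel
#' labels and an ordered provenance log of every operation applied so far.
#'
#' @param samples Numeric matrix, time points x channels, in uV.
#' @param sfreq Sampling rate in Hz; must exceed 80 Hz (twice the highest
#'   analysis frequency of 40 Hz).
#' @param channels Channel labels; normalized via [normalize_channel_labels()].
#' @param subject_id Subject identifier.
#' @param eye_state `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @param provenance Optional list of prior processing steps.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sfreq, channels = montage_1020,
                          subject_id = "S000", eye_state = c("EC", "EO"),
                          provenance = list()) {
  eye_state <- match.arg(eye_state)
  samples <- as.matrix(samples)
  channels <- normalize_channel_labels(channels)
  if (ncol(samples) != length(channels)) {
    stop("ncol(samples) must equal length(channels)")
  }
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 80) {
    stop("sfreq must be a single value > 80 Hz (twice the 40 Hz analysis limit)")
  }
  if (anyNA(samples)) stop("recording contains NaN/NA samples")
  colnames(samples) <- channels
  structure(
    list(
      subject_id = subject_id, eye_state = eye_state,
      sfreq = sfreq, channels = channels, samples = samples,
      provenance = provenance
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s), %d processing step(s)\n",
    x$subject_id, x$eye_state, length(x$channels), nrow(x$samples),
    x$sfreq, nrow(x$samples) / x$sfreq, length(x$provenance)
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$sfreq

# Seeded operations use a private RNG scope: the caller's global RNG stream
# is saved on entry and restored on exit, so seeding a recording or a
# resampling loop never perturbs surrounding user code. Usage:
#   old <- save_rng(); on.exit(restore_rng(old), add = TRUE); set.seed(seed)
save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Append one provenance entry (step name + parameter list) to a recording or
# epoch set; entries are plain lists so the history serializes to JSON.
add_provenance <- function(x, step, params = list()) {
  x$provenance <- c(x$provenance, list(list(step = step, params = params)))
  x
}

#' Construct an epoch set
#'
#' Consecutive fixed-length epochs cut from one recording, with a per-epoch
#' retention mask, a rejection log and the current reference scheme.
#' Epoch data are stored as a 3-d array indexed
#' `[sample, channel, epoch]` in uV.
#'
#' @param data 3-d numeric array, samples x channels x epochs.
#' @param sfreq Sampling rate (Hz).
#' @param channels Canonical channel labels.
#' @param epoch_length_s Epoch length in seconds.
#' @param subject_id,eye_state Carried over from the source recording.
#' @param provenance Processing history inherited from the recording.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sfreq, channels, epoch_length_s,
                       subject_id = "S000", eye_state = "EC",
                       provenance = list()) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != round(epoch_length_s * sfreq)) {
    stop("samples per epoch must equal epoch_length_s * sfreq exactly")
  }
  structure(
    list(
      data = data, sfreq = sfreq, channels = channels,
      epoch_length_s = epoch_length_s,
      retained = rep(TRUE, dim(data)[3]),
      rejection_log = tibble::tibble(
        epoch = integer(), channel = character(), peak_uv = numeric()
      ),
      reference = "original",
      subject_id = subject_id, eye_state = eye_state,
      provenance = provenance
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %s [%s]: %d epochs (%d retained) x %d ch x %d samples @ %g Hz, ref=%s\n",
    x$subject_id, x$eye_state, d[3], sum(x$retained), d[2], d[1],
    x$sfreq, x$reference
  ))
  invisible(x)
}
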