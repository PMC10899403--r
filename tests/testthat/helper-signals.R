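# Shared fixtures: small deterministic recordings built in code.

# Single- or multi-channel sinusoid recording on the canonical montage subset.
sine_recording <- function(freq_hz, duration_s = 10, sfreq = 250, amp = 1,
                           channels = c("Fp1", "Fp2", "Cz", "O1"),
                           eye_state = "EC") {
  t <- seq(0, duration_s - 1 / sfreq, by = 1 / sfreq)
  x <- matrix(amp * sin(2 * pi * freq_hz * t), length(t), length(channels))
  eeg_recording(x, sfreq, channels, subject_id = "SINE", eye_state = eye_state)
}

# White-noise recording (seeded).
noise_recording <- function(duration_s = 10, sfreq = 250, sd = 1,
                            channels = c("Fp1", "Fp2", "Cz", "O1"),
                            seed = 1) {
  set.seed(seed)
  n <- round(duration_s * sfreq)
  x <- matrix(rnorm(n * length(channels), 0, sd), n, length(channels))
  eeg_recording(x, sfreq, channels, subject_id = "NOISE")
}

# RMS of the central portion of a signal (trims filter edge effects).
trimmed_rms <- function(x, trim_frac = 0.1) {
  n <- length(x)
  i <- seq(floor(n * trim_frac) + 1, ceiling(n * (1 - trim_frac)))
  sqrt(mean(x[i]^2))
}

# Six-band absolute powers of one channel of a recording, averaged over
# consecutive epochs.
band_powers_of_channel <- function(rec, channel, epoch_s = 2) {
  keep <- eeg_recording(rec$samples[, channel, drop = FALSE], rec$sfreq,
    channels = channel,
    subject_id = rec$subject_id, eye_state = rec$eye_state
  )
  band_powers_of(keep, epoch_s)
}

# Six-band absolute powers of a single-channel recording, averaged over
# consecutive epochs.
band_powers_of <- function(rec, epoch_s = 2) {
  es <- epoch_recording(rec, epoch_s)
  d <- dim(es$data)
  flat <- matrix(es$data, d[1], d[2] * d[3])
  ps <- epoch_psd(flat, es$sfreq)
  colMeans(band_powers(ps$psd, ps$freq))
}

# Tiny deterministic simulation spec for structural tests.
tiny_spec <- function(...) {
  args <- list(
    n_mdd = 3, n_hc = 3, duration_s = 12, sampling_rate_hz = 250,
    blink_rate_hz = 0, excursion_rate_per_min = 0, seed = 42
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_spec, args)
}
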