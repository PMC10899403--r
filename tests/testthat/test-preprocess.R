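test_that("band-pass keeps the passband, removes drift and DC, with zero phase", {
  rec10 <- sine_recording(10, duration_s = 20)
  out <- bandpass_filter(rec10)
  expect_lt(
    abs(trimmed_rms(out$samples[, 1]) / trimmed_rms(rec10$samples[, 1]) - 1),
    0.05
  )
  # zero phase: cross-correlation peak at lag 0
  mid <- 1000:4000
  cc <- ccf(rec10$samples[mid, 1], out$samples[mid, 1], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  drift <- sine_recording(0.2, duration_s = 30)
  outd <- bandpass_filter(drift)
  expect_lt(trimmed_rms(outd$samples[, 1]) / trimmed_rms(drift$samples[, 1]), 0.10)

  dc <- eeg_recording(matrix(50, 5000, 2), 250, c("Fp1", "Fp2"))
  outdc <- bandpass_filter(dc)
  trim <- 500:4500
  expect_lt(mean(abs(outdc$samples[trim, 1])), 1e-6 * 50)

  expect_error(bandpass_filter(sine_recording(10), hi_hz = 130), "Nyquist")
  expect_equal(out$provenance[[length(out$provenance)]]$step, "bandpass_filter")
})

test_that("band-pass passband is flat within 0.5 dB over 2-35 Hz", {
  for (f in c(2, 5, 20, 30, 35)) {
    rec <- sine_recording(f, duration_s = 30)
    out <- bandpass_filter(rec)
    gain_db <- 20 * log10(trimmed_rms(out$samples[, 1]) / trimmed_rms(rec$samples[, 1]))
    expect_lt(abs(gain_db), 0.5)
  }
})

test_that("notch attenuates 50 Hz deeply and leaves 10 and 45 Hz nearly untouched", {
  r50 <- sine_recording(50, duration_s = 20)
  out50 <- notch_filter(r50)
  expect_lt(trimmed_rms(out50$samples[, 1]) / trimmed_rms(r50$samples[, 1]), 0.10)

  r10 <- sine_recording(10, duration_s = 20)
  out10 <- notch_filter(r10)
  expect_lt(abs(trimmed_rms(out10$samples[, 1]) / trimmed_rms(r10$samples[, 1]) - 1), 0.02)

  r45 <- sine_recording(45, duration_s = 20)
  out45 <- notch_filter(r45)
  gain_db <- 20 * log10(trimmed_rms(out45$samples[, 1]) / trimmed_rms(r45$samples[, 1]))
  expect_gt(gain_db, -3)

  silent <- eeg_recording(matrix(0, 5000, 2), 250, c("Fp1", "Fp2"))
  expect_equal(max(abs(notch_filter(silent)$samples)), 0)
  expect_error(notch_filter(sine_recording(10), stop_hz = c(120, 130)), "Nyquist")
})

test_that("downsampling preserves counts, waveforms and band structure", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), ncol = 1), 1000, "Cz")
  out <- downsample(rec, 500)
  expect_equal(nrow(out$samples), 5000)
  expect_equal(out$sfreq, 500)
  ideal <- sin(2 * pi * 10 * seq(0, 10 - 1 / 500, by = 1 / 500))
  expect_gt(cor(out$samples[, 1], ideal), 0.999)

  # six-band relative power invariant under decimation of a band-limited signal
  set.seed(3)
  noisy <- eeg_recording(matrix(rnorm(20000), ncol = 1), 1000, "Cz")
  noisy <- bandpass_filter(noisy)
  ds <- downsample(noisy, 500)
  rel_full <- relative_powers(band_powers_of(noisy, 2))
  rel_ds <- relative_powers(band_powers_of(ds, 2))
  expect_lt(max(abs(rel_full - rel_ds)), 0.01)

  expect_error(downsample(rec, 1000), "below")
  expect_error(downsample(rec, 300), "multiple")
})

test_that("epoching uses floor division and rejects too-short recordings", {
  rec <- noise_recording(duration_s = 61, sfreq = 250)
  es <- epoch_recording(rec)
  expect_equal(dim(es$data), c(500, 4, 30))
  expect_true(all(es$retained))
  # epochs are contiguous, non-overlapping cuts of the source
  expect_equal(es$data[, 1, 2], rec$samples[501:1000, 1])

  # the acquisition protocol: 600 s at 500 Hz gives exactly 300 epochs
  long <- eeg_recording(matrix(0, 300000, 2), 500, c("Fp1", "Fp2"))
  expect_equal(dim(epoch_recording(long)$data)[3], 300)

  short <- eeg_recording(matrix(0, 475, 2), 250, c("Fp1", "Fp2"))
  expect_error(epoch_recording(short), "shorter")
})

test_that("rejection is strictly 'beyond' the threshold and logs the offender", {
  x <- matrix(0, 1500, 4)
  x[700, 3] <- 200 # one 200 uV sample on the third channel in epoch 2
  rec <- eeg_recording(x, 250, c("Fp1", "Fp2", "T3", "O1"))
  es <- reject_epochs(epoch_recording(rec))
  expect_equal(es$retained, c(TRUE, FALSE, TRUE))
  expect_equal(es$rejection_log$channel, "T3")
  expect_equal(es$rejection_log$peak_uv, 200)
  expect_equal(es$rejection_log$epoch, 2L)

  # exactly +150 uV is retained; amplitudes within the bound are retained
  x2 <- matrix(0, 1000, 2)
  x2[100, 1] <- 150
  x2[600, 2] <- -150
  es2 <- reject_epochs(epoch_recording(eeg_recording(x2, 250, c("Fp1", "Fp2"))))
  expect_true(all(es2$retained))

  x3 <- matrix(200, 1000, 2)
  expect_error(
    reject_epochs(epoch_recording(eeg_recording(x3, 250, c("Fp1", "Fp2")))),
    "threshold"
  )
})

test_that("average re-reference zeroes the channel mean and is idempotent", {
  es <- epoch_recording(noise_recording(duration_s = 8))
  ref <- rereference_average(es)
  expect_equal(ref$reference, "average")
  sums <- apply(ref$data, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  twice <- rereference_average(ref)
  expect_equal(twice$data, ref$data, tolerance = 1e-12)

  # two identical channels become exactly zero
  x <- matrix(rnorm(500), 500, 1)[, c(1, 1)]
  es2 <- epoch_recording(eeg_recording(x, 250, c("Fp1", "Fp2")))
  expect_lt(max(abs(rereference_average(es2)$data)), 1e-12)

  one <- eeg_epochs(array(0, c(500, 1, 1)), 250, "Cz", 2)
  expect_error(rereference_average(one), "2 channels")
})

test_that("the full chain runs in order and records provenance end to end", {
  spec <- tiny_spec()
  rec <- generate_recording(spec, list(subject_id = "S1", group = "HC"), "EC", 5)
  es <- preprocess_recording(rec, preprocess_config(resample_hz = NULL, ica = FALSE))
  steps <- vapply(es$provenance, function(s) s$step, "")
  expect_equal(
    steps,
    c(
      "simulate", "bandpass_filter", "notch_filter", "downsample_skipped",
      "epoch", "reject_epochs", "rereference_average"
    )
  )
  expect_equal(es$reference, "average")
})
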