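test_that("epoch PSD concentrates a sinusoid and satisfies Parseval", {
  sfreq <- 250
  t <- seq(0, 2 - 1 / sfreq, by = 1 / sfreq)
  x <- sin(2 * pi * 10 * t)
  ps <- epoch_psd(x, sfreq)
  expect_equal(ps$freq[2] - ps$freq[1], 0.5)
  inb <- ps$freq >= 9 & ps$freq <= 11
  broad <- ps$freq >= 1 & ps$freq <= 40
  expect_gt(sum(ps$psd[inb, 1]) / sum(ps$psd[broad, 1]), 0.95)

  # Parseval: integral of the PSD matches the tapered signal's mean square
  set.seed(2)
  for (i in 1:5) {
    w <- rnorm(500)
    psw <- epoch_psd(w, sfreq)
    w_taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 499) / 499)
    target <- sum(w^2 * w_taper^2) / sum(w_taper^2)
    expect_lt(abs(sum(psw$psd[, 1]) * 0.5 / target - 1), 1e-9)
  }

  expect_equal(max(epoch_psd(numeric(500), sfreq)$psd), 0)
  expect_error(epoch_psd(c(NA, numeric(499)), sfreq), "NaN")
})

test_that("band powers split a flat spectrum by bin count and detect a pure tone", {
  freq <- seq(0, 125, by = 0.5)
  flat <- matrix(1, length(freq), 1)
  bp <- band_powers(flat, freq)
  # half-open bins [lo, hi): 6/8/8/8/16 bins, final band closed: 33
  expect_equal(as.vector(bp) / 0.5, c(6, 8, 8, 8, 16, 33))

  t <- seq(0, 2 - 1 / 250, by = 1 / 250)
  ps <- epoch_psd(sin(2 * pi * 10 * t), 250)
  bpa <- band_powers(ps$psd, ps$freq)
  expect_gt(bpa[1, "alpha"], 20 * max(bpa[1, colnames(bpa) != "alpha"]))

  expect_error(band_powers(flat[1:20, , drop = FALSE], freq[1:20]), "cover")
})

test_that("FFT-integration and analytic-signal band power agree on band-limited noise", {
  set.seed(8)
  sfreq <- 250
  for (band in list(c(16, 24), c(8, 12))) {
    x <- rnorm(sfreq * 240)
    bf <- signal::butter(4, band / (sfreq / 2), type = "pass")
    xb <- signal::filtfilt(bf, x)
    rec <- eeg_recording(matrix(xb, ncol = 1), sfreq, "Cz")
    p_fft <- sum(band_powers_of(rec)) # total power of a band-limited signal
    p_hil <- hilbert_band_power(xb, sfreq, 1, 40)
    expect_lt(abs(p_fft / p_hil - 1), 0.10)
  }
})

test_that("relative powers are scale-invariant fractions summing to one", {
  bp <- c(delta = 2, theta = 2, alpha = 2, beta1 = 2, beta2 = 2, beta3 = 2)
  expect_equal(unname(relative_powers(bp)), rep(1 / 6, 6))
  bp2 <- c(0.1, 0.2, 5, 0.05, 0.1, 0.05)
  expect_equal(relative_powers(bp2), relative_powers(bp2 * 2))
  expect_equal(sum(relative_powers(bp2)), 1)
  expect_gt(relative_powers(c(0.001, 0.001, 1, 0.001, 0.001, 0.001))[3], 0.95)
  expect_error(relative_powers(numeric(6)), "degenerate")
})

test_that("ROI aggregation is the channel mean, renormalized", {
  bands <- band_scheme()$band
  m <- matrix(1 / 6, 3, 6, dimnames = list(c("Fp1", "Fp2", "Fz"), bands))
  m["Fp1", "alpha"] <- 0.4
  m["Fp2", "alpha"] <- 0.2
  m["Fz", "alpha"] <- 0.3
  m <- m / rowSums(m)
  v <- roi_relative_power(m, c("Fp1", "Fp2", "Fz"))
  direct <- colMeans(m)
  expect_equal(v, direct / sum(direct))
  expect_equal(sum(v), 1)
  # identical channels: ROI equals the common vector
  mm <- matrix(rep(relative_powers(runif(6)), each = 3), 3, 6,
    dimnames = list(c("F7", "T3", "T5"), bands)
  )
  expect_equal(unname(roi_relative_power(mm, c("F7", "T3", "T5"))), unname(mm[1, ]))
  expect_error(roi_relative_power(m, c("Fp1", "O9")), "O9")
})

test_that("asymmetry is the exact right-minus-left difference and antisymmetric", {
  bands <- band_scheme()$band
  set.seed(4)
  roi <- t(replicate(10, relative_powers(runif(6))))
  dimnames(roi) <- list(names(roi_scheme()), bands)
  a <- asymmetry_scores(roi)
  expect_equal(colnames(a), c("theta", "alpha", "beta1", "beta2", "beta3"))
  expect_equal(a["RT-LT", "alpha"], roi["RT", "alpha"] - roi["LT", "alpha"])
  # swapping hemispheres flips every score
  swapped <- roi
  swapped[c("RMFC", "LMFC", "RMOC", "LMOC", "RT", "LT"), ] <-
    roi[c("LMFC", "RMFC", "LMOC", "RMOC", "LT", "RT"), ]
  expect_equal(asymmetry_scores(swapped), -a)
  # identical hemispheres: all zero
  same <- roi
  same[c("LMFC", "LMOC", "LT"), ] <- roi[c("RMFC", "RMOC", "RT"), ]
  expect_equal(max(abs(asymmetry_scores(same))), 0)
})

test_that("subject features are epoch-order invariant and consistent in the long run", {
  spec <- tiny_spec(duration_s = 120)
  rec <- generate_recording(spec, list(subject_id = "S1", group = "HC"), "EO", 3)
  es <- epoch_recording(rec)
  f1 <- subject_features(es)
  # permuting epochs leaves the average untouched
  es_perm <- es
  set.seed(1)
  es_perm$data <- es_perm$data[, , sample(dim(es$data)[3])]
  expect_equal(subject_features(es_perm)$value, f1$value, tolerance = 1e-12)

  # all epochs identical: features equal the single-epoch features
  es_same <- es
  for (e in seq_len(dim(es$data)[3])) es_same$data[, , e] <- es$data[, , 1]
  es_one <- eeg_epochs(es$data[, , 1, drop = FALSE], es$sfreq, es$channels, 2,
    subject_id = es$subject_id, eye_state = es$eye_state
  )
  expect_equal(subject_features(es_same)$value, subject_features(es_one)$value,
    tolerance = 1e-12
  )

  # a stationary process: 60 vs 300 epochs agree within Monte-Carlo error
  spec_long <- tiny_spec(duration_s = 600)
  rec_long <- generate_recording(spec_long, list(subject_id = "S1", group = "HC"),
    "EO",
    subject_seed = 3
  )
  f_long <- subject_features(epoch_recording(rec_long))
  pw <- f1$feature_type == "power"
  expect_lt(max(abs(f1$value[pw] - f_long$value[pw])), 0.04)
})

test_that("every simulated subject satisfies sum-to-one and exact asymmetry identities", {
  spec <- tiny_spec()
  cohort <- generate_cohort(spec, artifacts = FALSE)
  for (sub in cohort$recordings) {
    for (st in c("EO", "EC")) {
      f <- subject_features(epoch_recording(sub[[st]]))
      sums <- tapply(
        f$value[f$feature_type == "power"],
        f$region[f$feature_type == "power"], sum
      )
      expect_lt(max(abs(sums - 1)), 1e-6)
      for (pr in names(roi_pairs())) {
        lr <- roi_pairs()[[pr]]
        for (b in c("theta", "alpha", "beta1", "beta2", "beta3")) {
          pick <- function(reg) {
            f$value[f$feature_type == "power" & f$region == reg & f$band == b]
          }
          expect_equal(
            f$value[f$feature_type == "asymmetry" & f$region == pr & f$band == b],
            pick(lr[1]) - pick(lr[2])
          )
        }
      }
    }
  }
})
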