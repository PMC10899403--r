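#' Default per-region base oscillation amplitudes
#'
#' Baseline RMS amplitude (uV) of each band-limited oscillation by coarse
#' scalp region, for the eyes-open state. Values are in the range typical of
#' adult resting EEG: posterior-dominant alpha, low-amplitude fast activity.
#'
#' @return Named list (`frontal`, `central`, `posterior`) of named 6-vectors.
#' @export
default_band_amplitudes <- function() {
  list(
    frontal = c(delta = 3.5, theta = 2.5, alpha = 3.0, beta1 = 1.4, beta2 = 1.2, beta3 = 1.0),
    central = c(delta = 3.0, theta = 2.5, alpha = 3.5, beta1 = 1.5, beta2 = 1.2, beta3 = 0.9),
    posterior = c(delta = 2.5, theta = 2.5, alpha = 4.5, beta1 = 1.5, beta2 = 1.2, beta3 = 1.0)
  )
}

#' Default group effect multipliers
#'
#' Multiplicative amplitude effects applied to the patient group, realizing
#' the qualitative regional pattern of the depressed resting EEG modelled by
#' the package: eyes-open frontal/central beta2 elevation (strongest over
#' PFC/RMFC/LMFC), eyes-open occipital beta3 reduction, eyes-closed RMFC
#' beta2 elevation, right-temporal alpha elevation and right-occipital beta3
#' reduction. Magnitudes are calibrated so cohort-level Cohen's d of the key
#' relative-power contrasts falls in the 0.3-0.8 range at the default cohort
#' size, with the eyes-open frontal beta2 elevation the dominant contrast.
#'
#' @return Tibble with columns `group`, `eye_state`, `target` (ROI or channel
#'   name), `band`, `multiplier`.
#' @export
default_effect_multipliers <- function() {
  tibble::tribble(
    ~group, ~eye_state, ~target, ~band, ~multiplier,
    "MDD", "EO", "PFC", "beta2", 1.22,
    "MDD", "EO", "RMFC", "beta2", 1.22,
    "MDD", "EO", "LMFC", "beta2", 1.22,
    "MDD", "EO", "CC", "beta2", 1.06,
    "MDD", "EO", "MOC", "beta3", 0.89,
    "MDD", "EC", "RMFC", "beta2", 1.10,
    "MDD", "EC", "RT", "alpha", 1.05,
    "MDD", "EC", "RMOC", "beta3", 0.93
  )
}

#' Default hemispheric asymmetry shifts
#'
#' Signed fractional amplitude differentials between the right and left
#' members of an ROI pair: a shift `s` scales the right ROI's channel
#' amplitudes by `1 + s/2` and the left ROI's by `1 - s/2` in the given band.
#' Defaults realize the temporal asymmetry pattern modelled by the package:
#' under eyes open the patient group shifts rightward in alpha and beta1 and
#' leftward in beta2/beta3 relative to controls; under eyes closed patients
#' show a larger rightward alpha asymmetry and a reduced theta asymmetry.
#'
#' @return Tibble with columns `group`, `eye_state`, `pair`, `band`, `shift`.
#' @export
default_asymmetry_shifts <- function() {
  tibble::tribble(
    ~group, ~eye_state, ~pair, ~band, ~shift,
    "HC", "EO", "RT-LT", "alpha", -0.025,
    "MDD", "EO", "RT-LT", "alpha", 0.020,
    "HC", "EO", "RT-LT", "beta1", -0.015,
    "MDD", "EO", "RT-LT", "beta1", 0.040,
    "HC", "EO", "RT-LT", "beta2", 0.025,
    "MDD", "EO", "RT-LT", "beta2", -0.010,
    "HC", "EO", "RT-LT", "beta3", 0.025,
    "MDD", "EO", "RT-LT", "beta3", -0.010,
    "HC", "EC", "RT-LT", "alpha", 0.005,
    "MDD", "EC", "RT-LT", "alpha", 0.020,
    "HC", "EC", "RT-LT", "theta", 0.015,
    "MDD", "EC", "RT-LT", "theta", 0.000
  )
}

#' Specify a synthetic two-group EEG cohort
#'
#' Collects every knob of the generator: cohort size, recording protocol,
#' background and oscillation amplitudes, group effects, artifact rates and
#' the coupling between frontal beta2 amplitude and the depression severity
#' score. The default "desk" preset (60 s per eye state at 250 Hz, 40
#' subjects per group) runs the full pipeline in seconds; the acquisition
#' protocol it emulates (600 s per eye state at 1000 Hz, 86/83 subjects) is
#' available by overriding `duration_s`, `sampling_rate_hz`, `n_mdd`, `n_hc`.
#' An identical spec (including `seed`) always reproduces the identical
#' cohort.
#'
#' @param n_mdd,n_hc Subjects per group (>= 2).
#' @param duration_s Seconds per eye-state recording.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param noise_exponent Spectral slope chi of the 1/f^chi background.
#' @param pink_rms RMS amplitude (uV) of the broadband background over 1-40 Hz.
#' @param base_band_amplitudes See [default_band_amplitudes()].
#' @param effect_multipliers Tibble of group effects
#'   ([default_effect_multipliers()]); `NULL` for none.
#' @param asymmetry_shifts Tibble of asymmetry shifts
#'   ([default_asymmetry_shifts()]); `NULL` for none.
#' @param alpha_reactivity Eyes-closed/eyes-open alpha amplitude ratio (>= 1),
#'   applied in full over posterior channels and at half strength elsewhere.
#' @param blink_rate_hz Ocular blink rate (events/s).
#' @param excursion_rate_per_min High-amplitude excursion burst rate.
#' @param clinical_coupling Severity-score points per SD of the subject's
#'   latent frontal beta2 amplitude factor; the default is calibrated so the
#'   cohort-level Pearson r between the severity score and eyes-open PFC
#'   beta2 relative power is near 0.23.
#' @param clinical_base,clinical_noise_sd Location/noise of the severity score
#'   above its floor of 17, giving a patient-group mean near 24.1 and SD near
#'   4.8.
#' @param subject_band_sd,subject_channel_sd,subject_pink_sd Log-scale SDs of
#'   the per-subject amplitude factors (trait variability shared across eye
#'   states): global per-band, per-channel-by-band, and background factors.
#' @param seed Integer master seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_mdd = 40, n_hc = 40, duration_s = 60,
                            sampling_rate_hz = 250, noise_exponent = 1.3,
                            pink_rms = 4,
                            base_band_amplitudes = default_band_amplitudes(),
                            effect_multipliers = default_effect_multipliers(),
                            asymmetry_shifts = default_asymmetry_shifts(),
                            alpha_reactivity = 1.5,
                            blink_rate_hz = 0.2, excursion_rate_per_min = 0.5,
                            clinical_coupling = 1.5, clinical_base = 7.3,
                            clinical_noise_sd = 4.5,
                            subject_band_sd = 0.20, subject_channel_sd = 0.11,
                            subject_pink_sd = 0.10,
                            seed = 1) {
  if (is.null(effect_multipliers)) {
    effect_multipliers <- default_effect_multipliers()[0, ]
  }
  if (is.null(asymmetry_shifts)) {
    asymmetry_shifts <- default_asymmetry_shifts()[0, ]
  }
  stopifnot(
    n_mdd >= 2, n_hc >= 2, duration_s > 0, sampling_rate_hz > 80,
    noise_exponent >= 0, pink_rms >= 0, alpha_reactivity >= 1,
    blink_rate_hz >= 0, excursion_rate_per_min >= 0,
    clinical_noise_sd >= 0, subject_band_sd >= 0, subject_channel_sd >= 0,
    subject_pink_sd >= 0
  )
  amps <- unlist(base_band_amplitudes)
  stopifnot(all(amps >= 0))
  bad <- setdiff(
    effect_multipliers$target,
    c(names(roi_scheme()), montage_1020)
  )
  if (length(bad)) {
    stop("unknown channel set in effect_multipliers: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      n_mdd = n_mdd, n_hc = n_hc, duration_s = duration_s,
      sampling_rate_hz = sampling_rate_hz, noise_exponent = noise_exponent,
      pink_rms = pink_rms, base_band_amplitudes = base_band_amplitudes,
      effect_multipliers = effect_multipliers,
      asymmetry_shifts = asymmetry_shifts,
      alpha_reactivity = alpha_reactivity,
      blink_rate_hz = blink_rate_hz,
      excursion_rate_per_min = excursion_rate_per_min,
      clinical_coupling = clinical_coupling, clinical_base = clinical_base,
      clinical_noise_sd = clinical_noise_sd,
      subject_band_sd = subject_band_sd,
      subject_channel_sd = subject_channel_sd,
      subject_pink_sd = subject_pink_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' Null variant of a simulation spec
#'
#' Strips all group effects, asymmetry shifts, clinical coupling and
#' artifacts, making the two groups exchangeable draws from one population.
#'
#' @param spec A [simulation_spec()].
#' @return The null spec.
#' @export
null_simulation_spec <- function(spec = simulation_spec()) {
  spec$effect_multipliers <- spec$effect_multipliers[0, ]
  spec$asymmetry_shifts <- spec$asymmetry_shifts[0, ]
  spec$clinical_coupling <- 0
  spec$blink_rate_hz <- 0
  spec$excursion_rate_per_min <- 0
  spec
}

# Draw the trait-like per-subject amplitude factors (log-normal).
draw_subject_factors <- function(spec) {
  bands <- band_scheme()$band
  nb <- length(bands)
  nc <- length(montage_1020)
  band_f <- stats::setNames(exp(stats::rnorm(nb, 0, spec$subject_band_sd)), bands)
  chan_f <- matrix(exp(stats::rnorm(nc * nb, 0, spec$subject_channel_sd)),
    nc, nb,
    dimnames = list(montage_1020, bands)
  )
  pink_f <- exp(stats::rnorm(1, 0, spec$subject_pink_sd))
  list(band = band_f, chan = chan_f, pink = pink_f)
}

# Resolve spec + group + eye state + subject factors into per-channel,
# per-band oscillation RMS amplitudes and the per-channel background RMS.
channel_band_amplitudes <- function(spec, group, eye_state, factors) {
  bands <- band_scheme()$band
  chans <- montage_1020
  rois <- roi_scheme()
  amp <- t(vapply(chans, function(ch) {
    spec$base_band_amplitudes[[.region_class[[ch]]]][bands]
  }, numeric(length(bands))))
  dimnames(amp) <- list(chans, bands)
  if (eye_state == "EC") {
    ar <- spec$alpha_reactivity
    post <- chans %in% .posterior_channels
    amp[post, "alpha"] <- amp[post, "alpha"] * ar
    amp[!post, "alpha"] <- amp[!post, "alpha"] * (1 + (ar - 1) / 2)
  }
  em <- spec$effect_multipliers
  em <- em[em$group == group & em$eye_state == eye_state, , drop = FALSE]
  if (nrow(em)) {
    # collect all applicable multipliers per (channel, band); a channel shared
    # between several targeted ROIs receives the mean of their multipliers
    acc <- array(list(), dim = c(length(chans), length(bands)),
      dimnames = list(chans, bands))
    for (i in seq_len(nrow(em))) {
      tgt <- em$target[i]
      tchans <- if (tgt %in% names(rois)) rois[[tgt]] else tgt
      for (ch in tchans) {
        acc[[ch, em$band[i]]] <- c(acc[[ch, em$band[i]]], em$multiplier[i])
      }
    }
    for (ch in chans) {
      for (b in bands) {
        v <- acc[[ch, b]]
        if (length(v)) amp[ch, b] <- amp[ch, b] * mean(v)
      }
    }
  }
  as_ <- spec$asymmetry_shifts
  as_ <- as_[as_$group == group & as_$eye_state == eye_state, , drop = FALSE]
  if (nrow(as_)) {
    prs <- roi_pairs()
    for (i in seq_len(nrow(as_))) {
      pr <- prs[[as_$pair[i]]]
      if (is.null(pr)) stop("unknown asymmetry pair: ", as_$pair[i])
      s <- as_$shift[i]
      amp[rois[[pr[1]]], as_$band[i]] <- amp[rois[[pr[1]]], as_$band[i]] * (1 + s / 2)
      amp[rois[[pr[2]]], as_$band[i]] <- amp[rois[[pr[2]]], as_$band[i]] * (1 - s / 2)
    }
  }
  amp <- amp * matrix(factors$band[bands], nrow(amp), length(bands), byrow = TRUE)
  amp <- amp * factors$chan[chans, bands]
  list(amp = amp, pink_rms = spec$pink_rms * factors$pink)
}

# Cache of the PSD shape basis: identical for every recording of a cohort.
.shape_cache <- new.env(parent = emptyenv())

# Normalized two-sided PSD shapes on the half grid f (Hz, excluding DC):
# one column per band plus the 1/f^chi background, each integrating to one
# over the two-sided spectrum (background normalized over 1-40 Hz so
# pink_rms is the broadband RMS). Band profiles are flat-top raised-cosine
# windows whose 1 Hz roll-offs lie entirely inside the band, so each
# band-limited component deposits power only in its own band and the
# zero-sum structure of relative power is exact.
psd_shapes <- function(f, df, noise_exponent) {
  key <- sprintf("%d_%.9g_%.9g", length(f), df, noise_exponent)
  hit <- .shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  sch <- band_scheme()
  shapes <- matrix(0, length(f), nrow(sch) + 1)
  for (b in seq_len(nrow(sch))) {
    lo <- sch$lo[b]; hi <- sch$hi[b]
    h2 <- numeric(length(f))
    h2[f >= lo + 1 & f <= hi - 1] <- 1
    rise <- f >= lo & f < lo + 1
    h2[rise] <- 0.5 - 0.5 * cos(pi * (f[rise] - lo))
    fall <- f > hi - 1 & f <= hi
    h2[fall] <- 0.5 - 0.5 * cos(pi * (hi - f[fall]))
    shapes[, b] <- h2 / (2 * sum(h2) * df)
  }
  pk <- 1 / pmax(f, 1)^noise_exponent
  inband <- f >= 1 & f <= 40
  shapes[, nrow(sch) + 1] <- pk / (2 * sum(pk[inband]) * df)
  .shape_cache[[key]] <- shapes
  shapes
}

#' Generate one synthetic resting-state EEG recording
#'
#' Each channel is a stationary Gaussian process whose power spectrum is the
#' sum of a 1/f^chi background and six band-limited components (4th-order
#' Butterworth band-pass profiles), with per-channel amplitudes resolved from
#' the spec's base amplitudes, group effect multipliers, asymmetry shifts,
#' eyes-closed alpha reactivity and the subject's trait amplitude factors.
#' The process is synthesized in the frequency domain (Hermitian complex
#' Gaussian spectrum, inverse FFT), which is distributionally identical to
#' band-pass-filtering white noise and fully determined by `subject_seed`.
#'
#' @param spec A [simulation_spec()].
#' @param meta List or one-row data frame with at least `subject_id` and
#'   `group` (`"MDD"`/`"HC"`).
#' @param eye_state `"EO"` or `"EC"`.
#' @param subject_seed Integer seed for this recording.
#' @param factors Optional subject factor list (shared across eye states when
#'   generating a cohort); drawn from `subject_seed` when `NULL`.
#' @return An [eeg_recording()], artifact-free.
#' @export
generate_recording <- function(spec, meta, eye_state = c("EC", "EO"),
                               subject_seed = 1, factors = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  eye_state <- match.arg(eye_state)
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(as.integer(subject_seed))
  if (is.null(factors)) factors <- draw_subject_factors(spec)
  res <- channel_band_amplitudes(spec, meta$group, eye_state, factors)
  fs <- spec$sampling_rate_hz
  n_out <- round(spec$duration_s * fs)
  n <- n_out + n_out %% 2 # synthesize an even length, trim the spare sample
  k <- n / 2
  f <- seq_len(k) * fs / n
  df <- fs / n
  shapes <- psd_shapes(f, df, spec$noise_exponent) # k x 7
  coefs <- rbind(t(res$amp^2), pink = rep(res$pink_rms^2, length(montage_1020)))
  S <- shapes %*% coefs # k x channels target two-sided PSD
  nc <- ncol(S)
  # Hermitian complex Gaussian spectrum per channel: var of bin k is
  # S_k * fs * n / 2. Two channels are packed into one complex column
  # (x1 = Re, x2 = Im of one inverse FFT), halving the FFT count; the packed
  # spectrum is assembled directly in real arithmetic.
  re <- matrix(stats::rnorm((k - 1) * nc), k - 1, nc)
  im <- matrix(stats::rnorm((k - 1) * nc), k - 1, nc)
  nyq <- stats::rnorm(nc)
  scale_k <- sqrt(S[seq_len(k - 1), , drop = FALSE] * fs * n / 4)
  P <- re * scale_k
  Q <- im * scale_k
  tn <- nyq * sqrt(S[k, ] * fs * n / 2)
  npair <- nc %/% 2L
  m <- npair + nc %% 2L
  Rp <- matrix(0, n, m)
  Ip <- matrix(0, n, m)
  pos <- 2:k # positive-frequency bins
  neg <- n:(k + 2) # mirrored bins
  if (npair > 0) {
    o <- 2L * seq_len(npair) - 1L # odd channel of each pair
    e <- 2L * seq_len(npair) # even channel
    Rp[pos, seq_len(npair)] <- P[, o] - Q[, e]
    Ip[pos, seq_len(npair)] <- Q[, o] + P[, e]
    Rp[neg, seq_len(npair)] <- P[, o] + Q[, e]
    Ip[neg, seq_len(npair)] <- P[, e] - Q[, o]
    Rp[k + 1, seq_len(npair)] <- tn[o]
    Ip[k + 1, seq_len(npair)] <- tn[e]
  }
  if (nc %% 2L == 1L) {
    Rp[pos, m] <- P[, nc]
    Ip[pos, m] <- Q[, nc]
    Rp[neg, m] <- P[, nc]
    Ip[neg, m] <- -Q[, nc]
    Rp[k + 1, m] <- tn[nc]
  }
  Zp <- matrix(complex(real = Rp, imaginary = Ip), n, m)
  w <- stats::mvfft(Zp, inverse = TRUE)[seq_len(n_out), , drop = FALSE] / n
  x <- matrix(0, n_out, nc)
  if (npair > 0) {
    x[, 2L * seq_len(npair) - 1L] <- Re(w[, seq_len(npair), drop = FALSE])
    x[, 2L * seq_len(npair)] <- Im(w[, seq_len(npair), drop = FALSE])
  }
  if (nc %% 2L == 1L) x[, nc] <- Re(w[, m])
  eeg_recording(x, fs,
    channels = montage_1020,
    subject_id = as.character(meta$subject_id), eye_state = eye_state,
    provenance = list(list(step = "simulate", params = list(
      group = meta$group, eye_state = eye_state, seed = as.integer(subject_seed)
    )))
  )
}

#' Inject ocular and excursion artifacts into a clean recording
#'
#' Adds (a) blink transients: 0.3-1 s smooth positive bumps of 100-300 uV
#' peak at Fp1/Fp2, decaying posteriorly over the scalp; and (b) excursion
#' bursts: 0.2-0.5 s bumps of 200-400 uV on a random single channel at the
#' spec's per-minute rate. Returns the contaminated recording together with
#' the ground-truth artifact table.
#'
#' @param rec A clean [eeg_recording()].
#' @param spec A [simulation_spec()] (supplies the rates).
#' @param seed Integer seed.
#' @return List with `recording` and `artifacts` (tibble: `subject_id`,
#'   `eye_state`, `start_s`, `end_s`, `kind`, `channel`, `peak_uv`).
#' @export
inject_artifacts <- function(rec, spec, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(as.integer(seed))
  fs <- rec$sfreq
  dur <- recording_duration(rec)
  n <- nrow(rec$samples)
  rows <- list()
  blink_w <- c(
    Fp1 = 1, Fp2 = 1, F7 = 0.45, F3 = 0.45, Fz = 0.45, F4 = 0.45, F8 = 0.45,
    T3 = 0.15, C3 = 0.15, Cz = 0.15, C4 = 0.15, T4 = 0.15,
    T5 = 0.06, P3 = 0.06, Pz = 0.06, P4 = 0.06, T6 = 0.06, O1 = 0.03, O2 = 0.03
  )[rec$channels]
  n_blink <- stats::rpois(1, spec$blink_rate_hz * dur)
  if (n_blink > 0) {
    for (i in seq_len(n_blink)) {
      d <- stats::runif(1, 0.3, 1)
      t0 <- stats::runif(1, 0, max(dur - d, 0))
      peak <- stats::runif(1, 100, 300)
      idx <- seq(floor(t0 * fs) + 1, min(floor((t0 + d) * fs), n))
      bump <- peak * sin(pi * seq_along(idx) / length(idx))^2
      rec$samples[idx, ] <- rec$samples[idx, ] + outer(bump, blink_w)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = rec$subject_id, eye_state = rec$eye_state,
        start_s = t0, end_s = t0 + d, kind = "blink",
        channel = NA_character_, peak_uv = peak
      )
    }
  }
  # Excursion bursts are placed wholly inside one 2-s analysis epoch with
  # peaks well beyond the 150 uV rejection threshold, so the set of epochs a
  # rejection stage must drop is exactly determined by the ground-truth table.
  n_exc <- stats::rpois(1, spec$excursion_rate_per_min * dur / 60)
  n_ep2 <- floor(dur / 2)
  if (n_exc > 0 && n_ep2 > 0) {
    for (i in seq_len(n_exc)) {
      d <- stats::runif(1, 0.2, 0.5)
      ep <- sample.int(n_ep2, 1)
      t0 <- (ep - 1) * 2 + stats::runif(1, 0, 2 - d)
      ch <- sample(length(rec$channels), 1)
      peak <- stats::runif(1, 250, 400) * sample(c(-1, 1), 1)
      idx <- seq(floor(t0 * fs) + 1, min(floor((t0 + d) * fs), n))
      rec$samples[idx, ch] <- rec$samples[idx, ch] +
        peak * sin(pi * seq_along(idx) / length(idx))^2
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = rec$subject_id, eye_state = rec$eye_state,
        start_s = t0, end_s = t0 + d, kind = "excursion",
        channel = rec$channels[ch], peak_uv = abs(peak)
      )
    }
  }
  artifacts <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    subject_id = character(), eye_state = character(), start_s = numeric(),
    end_s = numeric(), kind = character(), channel = character(),
    peak_uv = numeric()
  )
  exc <- artifacts[artifacts$kind == "excursion", , drop = FALSE]
  n_ep <- floor(dur / 2)
  if (n_ep > 0) {
    hit <- unique(unlist(lapply(seq_len(nrow(exc)), function(i) {
      seq(floor(exc$start_s[i] / 2), min(floor(exc$end_s[i] / 2), n_ep - 1))
    })))
    if ((n_ep - length(hit)) / n_ep < 0.1) {
      warning("artifact rates leave fewer than 10% of epochs clean")
    }
  }
  rec <- add_provenance(rec, "inject_artifacts", list(
    seed = as.integer(seed), n_blink = n_blink, n_excursion = n_exc
  ))
  list(recording = rec, artifacts = artifacts)
}

# Deterministic subject metadata, latent factors and per-recording seeds for
# one cohort. Shared by generate_cohort() and run_study() so both produce the
# identical cohort for a given spec.
cohort_plan <- function(spec) {
  if (spec$n_mdd < 2 || spec$n_hc < 2) {
    stop("at least 2 subjects per group are required")
  }
  old_rng <- save_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_mdd + spec$n_hc
  group <- c(rep("MDD", spec$n_mdd), rep("HC", spec$n_hc))
  subject_id <- sprintf("S%03d", seq_len(n))
  sex_p <- ifelse(group == "MDD", 31 / 86, 37 / 83)
  sex <- ifelse(stats::runif(n) < sex_p, "male", "female")
  age <- ifelse(group == "MDD",
    stats::rnorm(n, 26.16, 6.29), stats::rnorm(n, 26.41, 8.24)
  )
  age <- pmin(65, pmax(18, round(age)))
  hama <- ifelse(group == "MDD", pmax(0, round(stats::rnorm(n, 20.09, 7.00))), NA_real_)
  factors <- lapply(seq_len(n), function(i) draw_subject_factors(spec))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n), n, 2,
    dimnames = list(subject_id, c("EO", "EC"))
  )
  art_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n), n, 2,
    dimnames = list(subject_id, c("EO", "EC"))
  )
  # severity score: floor 17 plus a component driven by the subject's latent
  # frontal beta2 amplitude factor, plus noise
  frontal <- roi_scheme()$PFC
  latent_beta2 <- vapply(factors, function(fc) {
    log(fc$band[["beta2"]] * mean(fc$chan[frontal, "beta2"]))
  }, numeric(1))
  z <- as.numeric(scale(latent_beta2))
  hdrs <- ifelse(group == "MDD",
    17 + pmax(0, round(
      spec$clinical_base + spec$clinical_coupling * z +
        stats::rnorm(n, 0, spec$clinical_noise_sd)
    )),
    NA_real_
  )
  meta <- tibble::tibble(
    subject_id = subject_id, group = group, sex = sex, age = age,
    hdrs17 = hdrs, hama = hama
  )
  list(meta = meta, factors = factors, seeds = seeds, art_seeds = art_seeds)
}

#' Generate a full synthetic cohort
#'
#' Produces the subject metadata table and, for every subject, one eyes-open
#' and one eyes-closed recording (with artifacts injected when the spec's
#' rates are positive), together with the ground-truth artifact table. The
#' whole cohort is a pure function of the spec, including its seed.
#'
#' For large cohorts prefer [run_study()], which streams subjects through the
#' pipeline without materializing all recordings.
#'
#' @param spec A [simulation_spec()].
#' @param artifacts Logical; inject artifacts (default `TRUE`; rates of zero
#'   also yield clean recordings).
#' @return List with `meta` (tibble), `recordings` (per-subject list of
#'   `EO`/`EC` recordings) and `artifacts` (ground-truth tibble).
#' @export
generate_cohort <- function(spec, artifacts = TRUE) {
  plan <- cohort_plan(spec)
  n <- nrow(plan$meta)
  recs <- vector("list", n)
  names(recs) <- plan$meta$subject_id
  art <- list()
  for (i in seq_len(n)) {
    meta_i <- plan$meta[i, ]
    pair <- list()
    for (st in c("EO", "EC")) {
      r <- generate_recording(spec, meta_i, st,
        subject_seed = plan$seeds[i, st], factors = plan$factors[[i]]
      )
      if (artifacts && (spec$blink_rate_hz > 0 || spec$excursion_rate_per_min > 0)) {
        inj <- inject_artifacts(r, spec, seed = plan$art_seeds[i, st])
        r <- inj$recording
        if (nrow(inj$artifacts)) art[[length(art) + 1]] <- inj$artifacts
      }
      pair[[st]] <- r
    }
    recs[[i]] <- pair
  }
  list(
    meta = plan$meta, recordings = recs,
    artifacts = if (length(art)) dplyr::bind_rows(art) else NULL
  )
}
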