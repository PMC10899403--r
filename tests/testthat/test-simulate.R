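test_that("spec validation catches bad configurations", {
  expect_error(simulation_spec(n_mdd = 1), "n_mdd")
  expect_error(simulation_spec(alpha_reactivity = 0.8), "alpha_reactivity")
  expect_error(
    simulation_spec(effect_multipliers = tibble::tibble(
      group = "MDD", eye_state = "EO", target = "XYZ", band = "beta2",
      multiplier = 1.2
    )),
    "XYZ"
  )
})

test_that("generation is deterministic and spec-shaped", {
  spec <- tiny_spec()
  meta <- list(subject_id = "S1", group = "MDD")
  a <- generate_recording(spec, meta, "EC", subject_seed = 77)
  b <- generate_recording(spec, meta, "EC", subject_seed = 77)
  expect_identical(a$samples, b$samples)
  expect_equal(dim(a$samples), c(12 * 250, 19))
  expect_equal(a$channels, montage_1020)

  cohort1 <- generate_cohort(tiny_spec())
  cohort2 <- generate_cohort(tiny_spec())
  expect_identical(cohort1$meta, cohort2$meta)
  expect_identical(
    cohort1$recordings$S001$EO$samples,
    cohort2$recordings$S001$EO$samples
  )
})

test_that("spectra realize the configured amplitudes, slopes and alpha reactivity", {
  spec <- tiny_spec(duration_s = 60, subject_band_sd = 0, subject_channel_sd = 0,
    subject_pink_sd = 0)
  meta <- list(subject_id = "S1", group = "HC")
  eo <- generate_recording(spec, meta, "EO", 11)
  ec <- generate_recording(spec, meta, "EC", 12)
  bp_eo <- band_powers_of_channel(eo, "O1")
  bp_ec <- band_powers_of_channel(ec, "O1")
  # posterior alpha power gains ~ alpha_reactivity^2 (eyes closed)
  alpha_gain <- bp_ec["alpha"] / bp_eo["alpha"]
  expect_gt(alpha_gain, spec$alpha_reactivity^2 * 0.7)
  expect_lt(alpha_gain, spec$alpha_reactivity^2 * 1.4)
  # other bands unaffected by eye state
  expect_lt(abs(bp_ec[["beta2"]] / bp_eo[["beta2"]] - 1), 0.35)
})

test_that("a band multiplier raises that band's relative power and lowers the rest", {
  base <- tiny_spec(duration_s = 40, subject_band_sd = 0, subject_channel_sd = 0,
    subject_pink_sd = 0, effect_multipliers = NULL, asymmetry_shifts = NULL)
  boosted <- base
  boosted$effect_multipliers <- tibble::tibble(
    group = "MDD", eye_state = "EO", target = "PFC", band = "beta2",
    multiplier = 1.6
  )
  meta <- list(subject_id = "S1", group = "MDD")
  f0 <- subject_features(epoch_recording(
    generate_recording(base, meta, "EO", 5)
  ))
  f1 <- subject_features(epoch_recording(
    generate_recording(boosted, meta, "EO", 5)
  ))
  pfc0 <- f0[f0$region == "PFC" & f0$feature_type == "power", ]
  pfc1 <- f1[f1$region == "PFC" & f1$feature_type == "power", ]
  expect_gt(
    pfc1$value[pfc1$band == "beta2"],
    pfc0$value[pfc0$band == "beta2"]
  )
  # zero-sum normalization: every other band must go down
  for (b in setdiff(band_scheme()$band, "beta2")) {
    expect_lt(pfc1$value[pfc1$band == b], pfc0$value[pfc0$band == b])
  }
})

test_that("null configuration makes the groups exchangeable", {
  # two-sample t on a fixed ROI/band feature rejects at ~nominal rate
  spec <- null_simulation_spec(tiny_spec(n_mdd = 6, n_hc = 6, duration_s = 12))
  set.seed(99)
  pvals <- replicate(12, {
    spec$seed <- sample.int(1e6, 1)
    cohort <- generate_cohort(spec, artifacts = FALSE)
    vals <- vapply(cohort$recordings, function(pair) {
      f <- subject_features(epoch_recording(pair$EO))
      f$value[f$feature_type == "power" & f$region == "PFC" & f$band == "alpha"]
    }, numeric(1))
    g <- cohort$meta$group
    two_sample_t(vals[g == "MDD"], vals[g == "HC"])$p
  })
  # with 12 null cohorts, seeing 0-3 rejections at alpha = .05 is the
  # plausible range; systematic group separation would reject everywhere
  expect_lte(sum(pvals < 0.05), 3)
  expect_gt(mean(pvals), 0.2)
})

test_that("metadata respects the clinical structure", {
  spec <- simulation_spec(n_mdd = 60, n_hc = 50, duration_s = 4, seed = 8)
  plan <- restpower:::cohort_plan(spec)
  m <- plan$meta
  expect_equal(nrow(m), 110)
  expect_true(all(m$hdrs17[m$group == "MDD"] >= 17))
  expect_true(all(is.na(m$hdrs17[m$group == "HC"])))
  expect_true(all(m$age >= 18 & m$age <= 65))
  # severity distribution near the configured location/scale
  expect_lt(abs(mean(m$hdrs17, na.rm = TRUE) - 24.1), 2.5)
  expect_lt(abs(sd(m$hdrs17, na.rm = TRUE) - 4.8), 2)
})

test_that("artifact injection is additive, seeded and truthful", {
  spec <- tiny_spec(blink_rate_hz = 0.3, excursion_rate_per_min = 4)
  rec <- generate_recording(spec, list(subject_id = "S1", group = "HC"), "EO", 21)

  # zero rates: identity
  spec0 <- tiny_spec()
  out0 <- inject_artifacts(rec, spec0, seed = 5)
  expect_identical(out0$recording$samples, rec$samples)
  expect_equal(nrow(out0$artifacts), 0)

  out <- inject_artifacts(rec, spec, seed = 5)
  out_b <- inject_artifacts(rec, spec, seed = 5)
  expect_identical(out$recording$samples, out_b$recording$samples)
  expect_true(all(out$artifacts$kind %in% c("blink", "excursion")))

  # blinks strictly increase frontopolar slow power
  blink_only <- spec
  blink_only$excursion_rate_per_min <- 0
  outbl <- inject_artifacts(rec, blink_only, seed = 9)
  if (any(outbl$artifacts$kind == "blink")) {
    p_before <- hilbert_band_power(rec$samples[, "Fp1"], rec$sfreq, 1, 4)
    p_after <- hilbert_band_power(outbl$recording$samples[, "Fp1"], rec$sfreq, 1, 4)
    expect_gt(p_after, p_before)
  }
})

test_that("rejection recovers exactly the injected excursion epochs", {
  spec <- tiny_spec(duration_s = 60, excursion_rate_per_min = 6)
  for (seed in c(3, 14)) {
    rec <- generate_recording(spec, list(subject_id = "S1", group = "HC"), "EO", seed)
    out <- inject_artifacts(rec, spec, seed = seed + 100)
    es <- reject_epochs(epoch_recording(out$recording))
    exc <- out$artifacts[out$artifacts$kind == "excursion", ]
    truth_epochs <- sort(unique(as.integer(floor(exc$start_s / 2) + 1)))
    expect_identical(which(!es$retained), truth_epochs)
  }
})

test_that("severity coupling shows up as the configured correlation sign", {
  spec <- simulation_spec(n_mdd = 60, n_hc = 2, duration_s = 4, seed = 31)
  plan <- restpower:::cohort_plan(spec)
  frontal <- roi_scheme()$PFC
  lat <- vapply(plan$factors, function(fc) {
    log(fc$band[["beta2"]] * mean(fc$chan[frontal, "beta2"]))
  }, numeric(1))
  mdd <- plan$meta$group == "MDD"
  r <- cor(lat[mdd], plan$meta$hdrs17[mdd])
  expect_gt(r, 0.05)

  # with coupling off the latent factor carries no information
  spec0 <- spec
  spec0$clinical_coupling <- 0
  plan0 <- restpower:::cohort_plan(spec0)
  r0 <- cor(lat[mdd], plan0$meta$hdrs17[mdd])
  expect_lt(abs(r0), 0.35)
})
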