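test_that("generate_beat reproduces the sum-of-Gaussians model exactly", {
  # zero amplitudes -> zero waveform
  p0 <- beat_morphology(wave_amplitudes = matrix(0, 12, 5))
  b0 <- generate_beat(p0, fs = 500, window = c(-0.25, 0.45))
  expect_equal(dim(b0$waveform), c(350L, 12L))
  expect_true(all(b0$waveform == 0))

  # a lone R Gaussian of amplitude 1 mV peaks at exactly 1.0 at t = 0
  amps <- matrix(0, 12, 5); amps[, 3] <- 1
  p1 <- beat_morphology(wave_widths = c(P = 0.02, Q = 0.007, R = 0.02,
                                        S = 0.007, T = 0.05),
                        wave_amplitudes = amps)
  b1 <- generate_beat(p1, fs = 500, window = c(-0.25, 0.45))
  expect_equal(b1$r_index, 125L)
  expect_equal(unname(b1$waveform[b1$r_index + 1, "II"]), 1.0)
  expect_equal(max(b1$waveform[, "V5"]), 1.0)

  # default parameters, 500 Hz, (-0.25, 0.45) s -> 350 samples
  bd <- generate_beat(beat_morphology(), fs = 500, window = c(-0.25, 0.45))
  expect_equal(nrow(bd$waveform), 350L)

  # window excluding a wave is rejected with an explicit message
  expect_error(generate_beat(beat_morphology(), fs = 500,
                             window = c(-0.1, 0.45)),
               "excludes")
})

test_that("beat morphology validates its invariants", {
  expect_error(beat_morphology(wave_centers = c(P = -0.1, Q = -0.2, R = 0,
                                                S = 0.02, T = 0.3)),
               "ordered")
  expect_error(beat_morphology(wave_widths = c(P = 0.02, Q = -0.01,
                                               R = 0.02, S = 0.01,
                                               T = 0.05)),
               "positive")
  expect_error(beat_morphology(heart_rate = 20), "30")
})

test_that("covariate sampling follows the effect model and is seeded", {
  # pure-intercept model with no noise collapses LVM to the intercept
  eff <- effect_model(gamma_height = 0, gamma_weight = 0, gamma_sex = 0,
                      gamma_intercept = 120, lvm_noise_sd = 0)
  rows <- sample_covariates(25, eff, seed = 4)
  expect_true(all(rows$lvm_truth == 120))

  # seeded determinism
  a <- sample_covariates(15, seed = 9)
  b <- sample_covariates(15, seed = 9)
  expect_identical(a, b)

  # extensibility: a longer cohort shares its prefix
  c30 <- sample_covariates(30, seed = 9)
  expect_identical(a, c30[1:15, ])

  expect_error(sample_covariates(0), ">= 1")
})

test_that("default cohort reproduces the documented correlation structure", {
  rows <- fixture("rows1000", sample_covariates(1000, seed = 7))
  expect_gt(cor(rows$lvm_truth, rows$height), 0.4)
  expect_gt(cor(rows$lvm_truth, rows$weight), 0.4)
  expect_gt(cor(rows$lvm_truth, rows$qrs_duration), 0.3)
  expect_lt(cor(rows$lvm_truth, rows$r_axis), 0)
  # sex difference in the LVM distribution
  expect_gt(mean(rows$lvm_truth[rows$sex == "male"]),
            mean(rows$lvm_truth[rows$sex == "female"]) + 10)
})

test_that("waveform coupling scales the R amplitude by 1 + beta * excess", {
  eff <- effect_model(beta_r_amp = 0.5, beta_qrs_width = 0,
                      beta_st_shift = 0, lvm_ref = 100, amp_jitter_sd = 0)
  r1 <- ecglvm:::record_from_row(manual_row(100), eff, i = 1,
                                 noise_sd = 0, drift_amp = 0)$record
  r2 <- ecglvm:::record_from_row(manual_row(200, record_id = "M2"), eff,
                                 i = 2, noise_sd = 0, drift_amp = 0)$record
  ratio <- max(r2$waveform[, "V5"]) / max(r1$waveform[, "V5"])
  expect_equal(ratio, 1.5, tolerance = 1e-2)

  # with all couplings off, the waveform is independent of LVM
  eff0 <- effect_model(beta_r_amp = 0, beta_qrs_width = 0,
                       beta_st_shift = 0, amp_jitter_sd = 0)
  w1 <- ecglvm:::record_from_row(manual_row(80), eff0, i = 1,
                                 noise_sd = 0, drift_amp = 0)$record
  w2 <- ecglvm:::record_from_row(manual_row(180), eff0, i = 1,
                                 noise_sd = 0, drift_amp = 0)$record
  expect_identical(w1$waveform, w2$waveform)
})

test_that("R amplitude increases monotonically with LVM when coupled", {
  eff <- effect_model(beta_r_amp = 0.4, amp_jitter_sd = 0)
  peaks <- vapply(seq(70, 190, by = 30), function(lvm) {
    r <- ecglvm:::record_from_row(manual_row(lvm), eff, i = 1,
                                  noise_sd = 0, drift_amp = 0)$record
    max(r$waveform[, "V5"])
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("cohorts are deterministic, regenerable and carry exact fiducials", {
  a <- synthesize_cohort(4, seed = 13)
  b <- synthesize_cohort(4, seed = 13)
  expect_identical(a$rows, b$rows)
  expect_identical(a$records[[3]]$waveform, b$records[[3]]$waveform)

  expect_equal(nrow(a$rows), 4L)
  expect_length(a$records, 4)
  expect_setequal(unique(a$fiducials$record_id), a$rows$record_id)

  # lazy regeneration is bit-identical to the stored record
  lazy <- synthesize_cohort(4, seed = 13, store_waveforms = FALSE)
  expect_null(lazy$records)
  expect_identical(cohort_record(lazy, 2)$waveform,
                   a$records[[2]]$waveform)

  # fiducials match the Gaussian-boundary definition: for a noiseless
  # record, the stored R-peak sample is the lead-II argmax of its beat
  co <- clean_cohort()
  fid <- co$fiducials[co$fiducials$record_id == "R00001", ]
  wf <- co$records[[1]]$waveform[, "II"]
  for (rp in fid$sample[fid$landmark == "r_peak"]) {
    loc <- (rp - 10):(rp + 10) + 1
    expect_equal(rp, (rp - 10) + which.max(wf[loc]) - 1)
  }
})
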