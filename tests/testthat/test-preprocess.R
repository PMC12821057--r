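make_sine_record <- function(freq, fs = 500, dur = 4, amp = 1) {
  t <- (0:(fs * dur - 1)) / fs
  wf <- matrix(amp * sin(2 * pi * freq * t), ncol = 12, nrow = length(t))
  colnames(wf) <- ecg_leads()
  ecg_record(wf, fs = fs, record_id = sprintf("sine%g", freq))
}

test_that("band-pass filter rejects DC, passes 10 Hz, attenuates 100 Hz", {
  fs <- 500
  const <- ecg_record(matrix(1, 5000, 12,
                             dimnames = list(NULL, ecg_leads())), fs = fs)
  f <- bandpass_filter(const)
  mid <- 2000:3000   # away from both filtfilt edge transients
  expect_lt(max(abs(f$waveform[mid, ])), 0.01)

  s10 <- bandpass_filter(make_sine_record(10))
  expect_equal(max(s10$waveform[800:1200, "V2"]), 1, tolerance = 0.05)

  s100 <- bandpass_filter(make_sine_record(100))
  expect_lt(max(abs(s100$waveform[800:1200, "V2"])), 0.1)

  expect_error(bandpass_filter(const, low = 40, high = 0.5), "invalid band")
  expect_error(bandpass_filter(const, low = 0.5, high = 400),
               "invalid band")
})

test_that("the filter is linear and length-preserving", {
  rec <- clean_cohort()$records[[2]]
  f1 <- bandpass_filter(rec)
  rec3 <- rec; rec3$waveform <- rec$waveform * 3
  f3 <- bandpass_filter(rec3)
  expect_equal(nrow(f1$waveform), nrow(rec$waveform))
  # sup-norm relative to the signal scale; the tiny residual comes from
  # the zero-phase filter's initial-condition solve
  expect_lt(max(abs(f3$waveform - 3 * f1$waveform)),
            1e-8 * max(abs(f1$waveform)))
})

test_that("R-peak detection recovers the simulator's R peaks", {
  co <- clean_cohort()
  for (i in 1:4) {
    rec <- co$records[[i]]
    filt <- bandpass_filter(rec)
    peaks <- detect_r_peaks(filt)
    truth <- co$fiducials$sample[co$fiducials$record_id == rec$record_id &
                                   co$fiducials$landmark == "r_peak"]
    expect_length(peaks, length(truth))
    expect_lte(max(abs(peaks - truth)) / rec$fs * 1000, 10)  # within 10 ms
    expect_true(all(diff(peaks) >= 0.2 * rec$fs))            # refractory
  }

  zero <- ecg_record(matrix(0, 2500, 12,
                            dimnames = list(NULL, ecg_leads())))
  expect_error(detect_r_peaks(zero), "signal-quality")
})

test_that("a 75 bpm 10-s record yields 12 or 13 detected beats", {
  eff <- effect_model(amp_jitter_sd = 0)
  rec <- ecglvm:::record_from_row(manual_row(110, heart_rate = 75), eff,
                                  i = 1, noise_sd = 0,
                                  drift_amp = 0)$record
  peaks <- detect_r_peaks(bandpass_filter(rec))
  expect_true(length(peaks) %in% c(12L, 13L))
})

test_that("single-beat extraction picks the middle eligible peak", {
  co <- clean_cohort()
  rec <- bandpass_filter(co$records[[1]])
  peaks <- detect_r_peaks(rec)
  seg <- extract_single_beat(rec, peaks)
  expect_equal(nrow(seg$waveform), 350L)
  expect_equal(seg$r_index, 125L)
  n_el <- sum(peaks - 125 >= 0 & peaks + 225 <= nrow(rec$waveform))
  chosen <- peaks[floor(n_el / 2) + 1]
  expect_equal(seg$start_sample, chosen - 125L)

  # five eligible peaks -> 0-based peak #2; one eligible -> that one
  fake <- rec
  expect_equal(extract_single_beat(fake, c(500, 1000, 1500, 2000,
                                           2500))$start_sample,
               1500L - 125L)
  expect_equal(extract_single_beat(fake, 1000)$start_sample, 1000L - 125L)
  expect_error(extract_single_beat(fake, 10), "no R peak")
})

test_that("every representation slices all 12 leads synchronously", {
  # index-valued dummy signal: lead k at time t holds t + k/100
  L <- 5000
  wf <- outer(0:(L - 1), (1:12) / 100, `+`)
  colnames(wf) <- ecg_leads()
  dummy <- ecg_record(wf, fs = 500, record_id = "dummy")

  seg <- extract_single_beat(dummy, peaks = 2000)
  base <- seg$waveform[, 1] - 1 / 100
  for (k in 1:12) {
    expect_equal(seg$waveform[, k] - k / 100, base)
  }

  crop <- random_length_crop(dummy, 2, 5, seed = 42)
  basec <- crop$waveform[, 1] - 1 / 100
  for (k in 1:12) {
    expect_equal(crop$waveform[, k] - k / 100, basec)
  }
})

test_that("random crops are bounded, deterministic and identity at limits", {
  rec <- noisy_cohort()$records[[1]]
  idc <- random_length_crop(rec, 10, 10, seed = 1)
  expect_equal(idc$waveform, rec$waveform)

  a <- random_length_crop(rec, 2, 5, seed = 7)
  b <- random_length_crop(rec, 2, 5, seed = 7)
  expect_identical(attr(a, "crop"), attr(b, "crop"))
  expect_equal(a$waveform, b$waveform)

  for (s in 1:200) {
    cr <- attr(random_length_crop(rec, 2, 5, seed = s), "crop")
    expect_gte(cr[["length"]], 2 * rec$fs)
    expect_lte(cr[["length"]], 5 * rec$fs)
    expect_gte(cr[["start"]], 0)
    expect_lte(cr[["start"]] + cr[["length"]], nrow(rec$waveform))
  }

  expect_error(random_length_crop(rec, 2, 11), "duration")
})

test_that("lead groupings partition the 12 leads", {
  el <- lead_grouping("electrical")
  an <- lead_grouping("anatomical")
  expect_equal(vapply(el$groups, length, 0L), c(limb = 6L, precordial = 6L))
  expect_equal(vapply(an$groups, length, 0L),
               c(LAD = 4L, LCx = 4L, RCA = 3L, LM = 1L))
  for (g in list(el, an, lead_grouping("none"))) {
    expect_setequal(unlist(g$groups), ecg_leads())
    expect_equal(anyDuplicated(unlist(g$groups)), 0L)
  }
  expect_error(lead_grouping("coronal"))

  seg <- extract_single_beat(bandpass_filter(clean_cohort()$records[[1]]),
                             detect_r_peaks(
                               bandpass_filter(clean_cohort()$records[[1]])))
  gl <- group_leads(seg, an)
  expect_named(gl, c("LAD", "LCx", "RCA", "LM"))
  expect_equal(gl$LCx, seg$waveform[, c("I", "aVL", "V5", "V6")])
  rebuilt <- do.call(cbind, unname(gl))[, ecg_leads()]
  expect_equal(rebuilt, seg$waveform)
  none <- group_leads(seg, "none")
  expect_equal(none$all, seg$waveform)
})

test_that("landmark delineation matches simulator truth within 20 ms", {
  co <- clean_cohort()
  for (i in 1:6) {
    rec <- bandpass_filter(co$records[[i]])
    peaks <- detect_r_peaks(rec)
    seg <- extract_single_beat(rec, peaks)
    ann <- annotate_landmarks(seg)
    expect_false(ann$flagged)
    fid <- co$fiducials[co$fiducials$record_id == rec$record_id, ]
    rp <- fid[fid$landmark == "r_peak", ]
    hit <- rp$beat_index[abs(rp$sample -
                               (seg$start_sample + seg$r_index)) <= 15][1]
    tru <- fid[fid$beat_index == hit & fid$landmark != "r_peak", ]
    local <- stats::setNames(tru$sample - seg$start_sample, tru$landmark)
    err_ms <- (ann$landmarks[names(local)] - local) / rec$fs * 1000
    expect_lte(max(abs(err_ms)), 20)
  }
})

test_that("ground-truth landmarks override detection; failures fall back", {
  co <- clean_cohort()
  rec <- bandpass_filter(co$records[[1]])
  seg <- extract_single_beat(rec, detect_r_peaks(rec))
  truth <- c(p_onset = 20L, qrs_onset = 101L, qrs_offset = 149L,
             t_offset = 330L)
  ann <- annotate_landmarks(seg, truth = truth)
  expect_identical(ann$landmarks, truth)
  expect_false(ann$flagged)

  # an all-flat beat cannot be delineated -> flagged fixed offsets
  flat <- beat_segment(matrix(0, 350, 12,
                              dimnames = list(NULL, ecg_leads())),
                       fs = 500, r_index = 125L, source_record_id = "flat")
  fb <- annotate_landmarks(flat)
  expect_true(fb$flagged)
  expect_identical(fb$landmarks,
                   c(p_onset = 25L, qrs_onset = 100L, qrs_offset = 150L,
                     t_offset = 325L))
})

test_that("beat extraction succeeds across a noiseless cohort", {
  co <- synthesize_cohort(20, seed = 99, noise_sd = 0, drift_amp = 0,
                          store_waveforms = FALSE)
  ok <- 0
  for (i in 1:20) {
    rec <- bandpass_filter(cohort_record(co, i))
    seg <- extract_single_beat(rec, detect_r_peaks(rec))
    ann <- annotate_landmarks(seg)
    lm <- ann$landmarks
    ok <- ok + (!ann$flagged && lm[["p_onset"]] < lm[["qrs_onset"]] &&
                  lm[["t_offset"]] > lm[["qrs_offset"]])
  }
  expect_gte(ok / 20, 0.99)
})

test_that("decimation preserves geometry and rescales landmarks", {
  co <- clean_cohort()
  rec <- bandpass_filter(co$records[[1]])
  seg <- annotate_landmarks(extract_single_beat(rec, detect_r_peaks(rec)))
  d4 <- decimate_segment(seg, 4L)
  expect_equal(nrow(d4$waveform), length(seq(1, 350, by = 4)))
  expect_equal(d4$fs, 125)
  expect_equal(d4$r_index, seg$r_index %/% 4L)
  expect_equal(d4$landmarks, seg$landmarks %/% 4L)
  expect_equal(d4$waveform[2, ], seg$waveform[5, ])
})
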