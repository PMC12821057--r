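# Synthetic 12-lead ECG cohort simulator.
#
# Beats are sums of Gaussians (one per wave P, Q, R, S, T), projected onto
# the 12 leads by a fixed physiologic amplitude matrix (aVR predominantly
# negative, V1 rS, V5-V6 tall R). Left-ventricular mass modulates the
# morphology: R-wave amplitude and QRS width scale with the fractional LVM
# excess over a reference mass, and an ST-level shift is added. Fiducial
# landmarks are defined as wave-center +/- 3 sigma boundaries, so every
# downstream stage (R-peak detection, delineation, segment masks, saliency
# aggregation) can be checked against exact ground truth.

#' Beat morphology parameters
#'
#' Default morphology of one synthetic heartbeat: Gaussian wave centers
#' (seconds relative to the R peak, which sits at 0), Gaussian widths
#' (sigma, seconds), and a 12-lead x 5-wave amplitude matrix (millivolts)
#' with physiologic polarity. Fiducial landmarks are defined from these
#' parameters as `center - 3*sigma` (onsets) and `center + 3*sigma`
#' (offsets).
#'
#' @param wave_centers Named numeric (P, Q, R, S, T), seconds; must be
#'   ordered P < Q < R < S < T with R at 0.
#' @param wave_widths Named numeric, Gaussian sigma per wave, seconds (> 0).
#' @param wave_amplitudes 12 x 5 matrix, rows = canonical leads, columns =
#'   waves, millivolts.
#' @param heart_rate Beats per minute, in \[30, 180\].
#' @param noise_sd Additive Gaussian noise, millivolts.
#' @param baseline_drift_amp,baseline_drift_freq Sinusoidal baseline wander
#'   amplitude (millivolts) and frequency (Hz).
#' @return Object of class `beat_morphology`.
#' @export
beat_morphology <- function(wave_centers = c(P = -0.16, Q = -0.025, R = 0,
                                             S = 0.025, T = 0.28),
                            wave_widths = c(P = 0.020, Q = 0.007, R = 0.018,
                                            S = 0.007, T = 0.050),
                            wave_amplitudes = default_wave_amplitudes(),
                            heart_rate = 70,
                            noise_sd = 0,
                            baseline_drift_amp = 0,
                            baseline_drift_freq = 0.25) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(wave_centers), waves),
            setequal(names(wave_widths), waves))
  wave_centers <- wave_centers[waves]
  wave_widths <- wave_widths[waves]
  if (any(diff(wave_centers) <= 0) || wave_centers[["R"]] != 0) {
    stop("wave centers must be ordered P < Q < R < S < T with R at 0")
  }
  if (any(wave_widths <= 0)) stop("wave widths must be strictly positive")
  if (heart_rate < 30 || heart_rate > 180) {
    stop("heart_rate must lie in [30, 180] bpm")
  }
  wave_amplitudes <- as.matrix(wave_amplitudes)
  if (!all(dim(wave_amplitudes) == c(12L, 5L))) {
    stop("wave_amplitudes must be a 12 x 5 matrix (leads x waves)")
  }
  rownames(wave_amplitudes) <- ecg_leads()
  colnames(wave_amplitudes) <- waves
  structure(list(wave_centers = wave_centers, wave_widths = wave_widths,
                 wave_amplitudes = wave_amplitudes, heart_rate = heart_rate,
                 noise_sd = noise_sd,
                 baseline_drift_amp = baseline_drift_amp,
                 baseline_drift_freq = baseline_drift_freq),
            class = "beat_morphology")
}

#' Default 12-lead wave amplitude matrix
#'
#' Fixed projection of the five waves onto the 12 leads (millivolts),
#' giving physiologic polarity: aVR predominantly negative, V1 an rS
#' pattern, V4--V6 a tall-R qR pattern.
#'
#' @return A 12 x 5 numeric matrix (leads x P,Q,R,S,T).
#' @export
default_wave_amplitudes <- function() {
  m <- rbind(
    I   = c(0.08, -0.04, 0.60, -0.10, 0.20),
    II  = c(0.12, -0.05, 1.00, -0.15, 0.30),
    III = c(0.05, -0.02, 0.50, -0.10, 0.12),
    aVR = c(-0.10, 0.03, -0.70, 0.10, -0.22),
    aVL = c(0.03, -0.02, 0.30, -0.08, 0.08),
    aVF = c(0.09, -0.04, 0.70, -0.12, 0.22),
    V1  = c(0.04, -0.01, 0.15, -0.80, 0.10),
    V2  = c(0.05, -0.02, 0.30, -0.70, 0.25),
    V3  = c(0.06, -0.03, 0.60, -0.45, 0.30),
    V4  = c(0.07, -0.06, 1.20, -0.30, 0.35),
    V5  = c(0.07, -0.08, 1.40, -0.20, 0.32),
    V6  = c(0.06, -0.06, 1.10, -0.12, 0.28)
  )
  colnames(m) <- c("P", "Q", "R", "S", "T")
  m
}

#' Covariate and waveform-coupling effect model
#'
#' Parameters tying left-ventricular mass (LVM) to the scalar covariates
#' and to waveform morphology. LVM is generated as
#' `gamma_intercept + gamma_height*height + gamma_weight*weight +
#' gamma_sex*male + Normal(0, lvm_noise_sd)`. The fractional LVM excess
#' `d = (LVM - lvm_ref)/lvm_ref` then modulates morphology: R amplitude by
#' `1 + beta_r_amp*d`, QRS Gaussian widths by `1 + beta_qrs_width*d`, and
#' an ST-level shift of `beta_st_shift*d` millivolts. Per-patient
#' log-normal factors emulate morphological variability that is
#' independent of LVM: a global voltage factor (`amp_jitter_sd`, body
#' habitus and electrode placement), an independent amplitude factor per
#' wave (`wave_jitter_sd`, so amplitude ratios such as R/T are noisy, as
#' in real cohorts), a QRS-width factor (`width_jitter_sd`,
#' inter-individual conduction variability), and an additive ST-level
#' offset (`st_jitter_sd`, millivolts) so the ST level is not a noiseless
#' readout of LVM.
#'
#' Defaults are chosen so that a cohort of n = 1000 shows moderate-to-strong
#' positive LVM correlations with height, weight and QRS duration, a weak
#' negative correlation with R axis, a clear male-female LVM difference,
#' and a clinically plausible LVH prevalence (roughly a third of a
#' referral cohort) under the 72/55 g/m^2 indexed-LVM thresholds.
#'
#' @param gamma_height g per cm. @param gamma_weight g per kg.
#' @param gamma_sex g (male offset). @param gamma_intercept g.
#' @param lvm_noise_sd g (>= 0). @param beta_r_amp Fractional R-amplitude
#'   gain per fractional LVM excess. @param beta_qrs_width Fractional QRS
#'   width gain. @param beta_st_shift mV per fractional LVM excess.
#' @param lvm_ref Reference LVM, g (> 0). @param amp_jitter_sd Log-scale SD
#'   of the per-patient global voltage factor (>= 0).
#' @param wave_jitter_sd Log-scale SD of the independent per-wave
#'   amplitude factors (>= 0).
#' @param width_jitter_sd Log-scale SD of the per-patient QRS-width
#'   factor (>= 0).
#' @param st_jitter_sd SD of the per-patient additive ST-level offset,
#'   millivolts (>= 0).
#' @return Object of class `effect_model`.
#' @export
effect_model <- function(gamma_height = 1.2, gamma_weight = 0.8,
                         gamma_sex = 25, gamma_intercept = -155,
                         lvm_noise_sd = 15,
                         beta_r_amp = 0.4, beta_qrs_width = 0.2,
                         beta_st_shift = -0.05, lvm_ref = 110,
                         amp_jitter_sd = 0.12, wave_jitter_sd = 0.12,
                         width_jitter_sd = 0.08, st_jitter_sd = 0.03) {
  if (lvm_noise_sd < 0) stop("lvm_noise_sd must be >= 0")
  if (lvm_ref <= 0) stop("lvm_ref must be > 0")
  if (amp_jitter_sd < 0 || wave_jitter_sd < 0 || width_jitter_sd < 0 ||
      st_jitter_sd < 0) {
    stop("jitter SDs must be >= 0")
  }
  structure(list(gamma_height = gamma_height, gamma_weight = gamma_weight,
                 gamma_sex = gamma_sex, gamma_intercept = gamma_intercept,
                 lvm_noise_sd = lvm_noise_sd, beta_r_amp = beta_r_amp,
                 beta_qrs_width = beta_qrs_width,
                 beta_st_shift = beta_st_shift, lvm_ref = lvm_ref,
                 amp_jitter_sd = amp_jitter_sd,
                 wave_jitter_sd = wave_jitter_sd,
                 width_jitter_sd = width_jitter_sd,
                 st_jitter_sd = st_jitter_sd),
            class = "effect_model")
}

# Deterministic per-row child seed from one global seed (splittable-RNG
# contract: row i's draws never depend on n). All arithmetic stays exact
# in doubles (< 2^53) and the result fits a 32-bit R integer seed.
child_seed <- function(seed, i, stream = 0L) {
  m <- 2147483647
  as.integer((((seed %% m) * 1000003) %% m + i * 7919 + stream * 104729) %% m)
}

#' Generate one synthetic heartbeat
#'
#' Evaluates the sum-of-Gaussians beat model on a sample grid and returns a
#' synchronized 12-lead single-beat window together with its ground-truth
#' fiducial landmarks (wave-center +/- 3 sigma boundaries, expressed as
#' 0-based sample offsets within the window).
#'
#' @param params A [beat_morphology()] object.
#' @param fs Sampling rate, Hz.
#' @param window Length-2 numeric, window start/end in seconds relative to
#'   the R peak; must contain every wave center +/- 3 sigma.
#' @return A [beat_segment] with `waveform` (`L x 12` mV matrix,
#'   `L = round((window[2]-window[1])*fs)`), `r_index`, and `landmarks`
#'   (`p_onset`, `qrs_onset`, `qrs_offset`, `t_offset`).
#' @examples
#' b <- generate_beat(beat_morphology(), fs = 500, window = c(-0.25, 0.45))
#' dim(b$waveform)  # 350 x 12
#' @export
generate_beat <- function(params, fs = 500, window = c(-0.25, 0.45)) {
  stopifnot(inherits(params, "beat_morphology"), fs > 0)
  mu <- params$wave_centers; sg <- params$wave_widths
  lo <- min(mu - 3 * sg); hi <- max(mu + 3 * sg)
  if (window[1] > lo + 1e-12 || window[2] < hi - 1e-12) {
    stop(sprintf(paste0("window [%g, %g] s excludes part of a wave: need ",
                        "[%g, %g] (all wave centers +/- 3 sigma)"),
                 window[1], window[2], lo, hi))
  }
  L <- round((window[2] - window[1]) * fs)
  t <- window[1] + (0:(L - 1)) / fs
  profiles <- vapply(seq_along(mu),
                     function(w) exp(-(t - mu[w])^2 / (2 * sg[w]^2)),
                     numeric(L))
  wf <- profiles %*% t(params$wave_amplitudes)
  if (params$baseline_drift_amp > 0) {
    wf <- wf + params$baseline_drift_amp *
      sin(2 * pi * params$baseline_drift_freq * t)
  }
  if (params$noise_sd > 0) {
    wf <- wf + matrix(stats::rnorm(length(wf), sd = params$noise_sd),
                      nrow = L)
  }
  colnames(wf) <- ecg_leads()
  to_samp <- function(x) as.integer(round((x - window[1]) * fs))
  lm <- c(p_onset = to_samp(mu[["P"]] - 3 * sg[["P"]]),
          qrs_onset = to_samp(mu[["Q"]] - 3 * sg[["Q"]]),
          qrs_offset = to_samp(mu[["S"]] + 3 * sg[["S"]]),
          t_offset = to_samp(mu[["T"]] + 3 * sg[["T"]]))
  beat_segment(wf, fs = fs, r_index = to_samp(0), landmarks = lm,
               source_record_id = "synthetic")
}

#' Sample synthetic cohort covariates
#'
#' Draws `n` patients' scalar covariates and ground-truth LVM under an
#' [effect_model()]. Sex is Bernoulli(0.5); height is sex-conditional
#' Normal (male 172 +/- 7 cm, female 159 +/- 7 cm); weight is Normal given
#' height (`0.45*height - 8 + N(0, 9)` kg); LVM follows the effect model.
#' Derived automatic ECG parameters are consistent with the morphology the
#' LVM induces: QRS duration is read off the scaled QRS Gaussian
#' boundaries (plus 3 ms measurement noise), and the R axis carries a weak
#' negative LVM association. Each row uses its own child seed, so the
#' table is extensible without perturbing earlier rows.
#'
#' @param n Number of patients (>= 1).
#' @param effect An [effect_model()].
#' @param seed Integer global seed.
#' @param morphology Base [beat_morphology()] used to derive QRS duration.
#' @return `data.frame` with one row per patient: identifiers, age, sex,
#'   height, weight, automatic ECG parameters, `lvm_truth`, `lvm_source`,
#'   timestamps, `rhythm_flags`, `heart_rate` and `amp_scale`.
#' @export
sample_covariates <- function(n, effect = effect_model(), seed = 1,
                              morphology = beat_morphology()) {
  if (n < 1) stop("n must be >= 1")
  mu <- morphology$wave_centers; sg <- morphology$wave_widths
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(child_seed(seed, i))
    male <- stats::runif(1) < 0.5
    height <- stats::rnorm(1, if (male) 172 else 159, 7)
    weight <- 0.45 * height - 8 + stats::rnorm(1, 0, 9)
    age <- min(90, max(20, stats::rnorm(1, 62, 11)))
    hr <- stats::runif(1, 55, 95)
    lvm <- effect$gamma_intercept + effect$gamma_height * height +
      effect$gamma_weight * weight + effect$gamma_sex * male +
      stats::rnorm(1, 0, effect$lvm_noise_sd)
    lvm <- max(lvm, 30)
    d <- (lvm - effect$lvm_ref) / effect$lvm_ref
    width_scale <- exp(stats::rnorm(1, 0, effect$width_jitter_sd))
    s_qrs <- max(0.2, (1 + effect$beta_qrs_width * d) * width_scale)
    qrs_ms <- 1000 * ((mu[["S"]] + 3 * sg[["S"]] * s_qrs) -
                        (mu[["Q"]] - 3 * sg[["Q"]] * s_qrs)) +
      stats::rnorm(1, 0, 3)
    r_axis <- 40 - 20 * d + stats::rnorm(1, 0, 15)
    p_axis <- stats::rnorm(1, 45, 12)
    t_axis <- stats::rnorm(1, 40, 15)
    amp_scale <- exp(stats::rnorm(1, 0, effect$amp_jitter_sd))
    wave_scale <- exp(stats::rnorm(5, 0, effect$wave_jitter_sd))
    st_jitter <- stats::rnorm(1, 0, effect$st_jitter_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%05d", i), record_id = sprintf("R%05d", i),
      age = age, sex = if (male) "male" else "female",
      height = height, weight = weight,
      qrs_duration = qrs_ms, p_axis = p_axis, r_axis = r_axis,
      t_axis = t_axis, lvm_truth = lvm, lvm_source = "ct",
      ct_time = "2024-01-01T08:00:00", ecg_time = "2024-01-01T09:00:00",
      rhythm_flags = "", heart_rate = hr, amp_scale = amp_scale,
      width_scale = width_scale,
      wave_scale_P = wave_scale[1], wave_scale_Q = wave_scale[2],
      wave_scale_R = wave_scale[3], wave_scale_S = wave_scale[4],
      wave_scale_T = wave_scale[5], st_jitter = st_jitter,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Morphology for one cohort row: LVM-coupled scaling of R amplitude and
# QRS widths, plus the row's LVM-independent jitter factors (global
# voltage, per-wave amplitude, QRS width; all default to 1 when a
# hand-built row omits them) and heart rate.
row_morphology <- function(row, effect, base = beat_morphology()) {
  col_or <- function(nm, default = 1) {
    if (!is.null(row[[nm]])) row[[nm]] else default
  }
  d <- (row$lvm_truth - effect$lvm_ref) / effect$lvm_ref
  amp <- base$wave_amplitudes
  amp[, "R"] <- amp[, "R"] * max(0.1, 1 + effect$beta_r_amp * d)
  for (w in c("P", "Q", "R", "S", "T")) {
    amp[, w] <- amp[, w] * col_or(paste0("wave_scale_", w))
  }
  amp <- amp * col_or("amp_scale")
  sg <- base$wave_widths
  s_qrs <- max(0.2, (1 + effect$beta_qrs_width * d) * col_or("width_scale"))
  sg[c("Q", "R", "S")] <- sg[c("Q", "R", "S")] * s_qrs
  beat_morphology(wave_centers = base$wave_centers, wave_widths = sg,
                  wave_amplitudes = amp, heart_rate = row$heart_rate,
                  noise_sd = base$noise_sd,
                  baseline_drift_amp = base$baseline_drift_amp,
                  baseline_drift_freq = base$baseline_drift_freq)
}

# Build the full record for one row: tile the beat template at the row's
# heart rate, add the ST-level shift, drift and noise. Bit-identical for a
# fixed (seed, effect, row index).
record_from_row <- function(row, effect, seed = 1, i = 1, fs = 500,
                            duration = 10, base = beat_morphology(),
                            noise_sd = 0.01, drift_amp = 0.05,
                            drift_freq = 0.25) {
  morph <- row_morphology(row, effect, base)
  tmpl_window <- c(-0.3, 0.5)
  tmpl <- generate_beat(morph, fs = fs, window = tmpl_window)
  d <- (row$lvm_truth - effect$lvm_ref) / effect$lvm_ref
  st_j <- if (!is.null(row$st_jitter)) row$st_jitter else 0
  amp_sc <- if (!is.null(row$amp_scale)) row$amp_scale else 1
  st_amp <- (effect$beta_st_shift * d + st_j) * amp_sc
  if (st_amp != 0) {
    tt <- tmpl_window[1] + (0:(nrow(tmpl$waveform) - 1)) / fs
    st_bump <- st_amp * exp(-(tt - 0.12)^2 / (2 * 0.05^2))
    tmpl$waveform <- tmpl$waveform + st_bump  # column recycling: same shift on every lead
  }
  L <- round(fs * duration)
  wf <- matrix(0, L, 12, dimnames = list(NULL, ecg_leads()))
  period <- round(fs * 60 / row$heart_rate)
  r0 <- round(0.5 * fs)
  r_peaks <- seq(r0, round((duration - 0.56) * fs), by = period)
  off_lo <- tmpl$r_index                      # samples before R in template
  n_tmpl <- nrow(tmpl$waveform)
  for (r in r_peaks) {
    a <- r - off_lo + 1
    wf[a:(a + n_tmpl - 1), ] <- wf[a:(a + n_tmpl - 1), ] + tmpl$waveform
  }
  set.seed(child_seed(seed, i, stream = 1L))
  if (drift_amp > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    tgrid <- (0:(L - 1)) / fs
    wf <- wf + drift_amp * sin(2 * pi * drift_freq * tgrid + phi)
  }
  if (noise_sd > 0) {
    wf <- wf + matrix(stats::rnorm(L * 12, sd = noise_sd), L, 12)
  }
  fid <- do.call(rbind, lapply(seq_along(r_peaks), function(k) {
    r <- r_peaks[k]
    data.frame(record_id = row$record_id, beat_index = k - 1L,
               landmark = c("r_peak", names(tmpl$landmarks)),
               sample = c(r, r - off_lo + as.integer(tmpl$landmarks)),
               stringsAsFactors = FALSE)
  }))
  rec <- ecg_record(wf, fs = fs, record_id = row$record_id,
                    acquired_at = row$ecg_time)
  list(record = rec, fiducials = fid)
}

#' Synthesize a full seeded ECG cohort
#'
#' Generates `n` patients (via [sample_covariates()]) together with one
#' 12-lead record each: the row's beat template (morphology coupled to its
#' LVM) tiled at the row's heart rate over `duration` seconds, plus
#' baseline drift and additive noise. Ground-truth per-beat fiducial
#' landmarks are stored as 0-based sample indices into the record.
#'
#' @inheritParams sample_covariates
#' @param fs Sampling rate, Hz (default 500).
#' @param duration Record length, seconds (default 10); must fit >= 3
#'   beats at the sampled heart rate.
#' @param store_waveforms Keep the generated records in the returned
#'   object (default). With `FALSE`, only rows and fiducials are kept and
#'   [cohort_record()] regenerates any record bit-identically on demand --
#'   useful for large cohorts.
#' @param noise_sd,drift_amp Record-level additive noise and baseline
#'   wander amplitude, millivolts.
#' @return Object of class `ecg_cohort`: `rows`, `records` (list of
#'   [ecg_record] or `NULL`), `fiducials`, `seed`, `effect`.
#' @examples
#' co <- synthesize_cohort(3, seed = 7)
#' length(co$records)
#' @export
synthesize_cohort <- function(n, effect = effect_model(), seed = 1,
                              fs = 500, duration = 10,
                              store_waveforms = TRUE,
                              noise_sd = 0.01, drift_amp = 0.05) {
  if (duration < 3 * 60 / 55 + 1.1) {
    stop("duration too short: need room for >= 3 beats plus template margins")
  }
  rows <- sample_covariates(n, effect, seed)
  recs <- vector("list", n)
  fids <- vector("list", n)
  for (i in seq_len(n)) {
    rf <- record_from_row(rows[i, ], effect, seed = seed, i = i, fs = fs,
                          duration = duration, noise_sd = noise_sd,
                          drift_amp = drift_amp)
    if (store_waveforms) recs[[i]] <- rf$record
    fids[[i]] <- rf$fiducials
  }
  structure(list(rows = rows,
                 records = if (store_waveforms) recs else NULL,
                 fiducials = do.call(rbind, fids),
                 seed = seed, effect = effect, fs = fs,
                 duration = duration, noise_sd = noise_sd,
                 drift_amp = drift_amp),
            class = "ecg_cohort")
}

#' Fetch (or regenerate) one cohort record
#'
#' Returns record `i` of a synthetic cohort. If waveforms were not stored
#' at synthesis time the record is regenerated from `(seed, effect, i)` --
#' bit-identical to what [synthesize_cohort()] would have stored.
#'
#' @param cohort An `ecg_cohort`.
#' @param i Row index.
#' @return An [ecg_record].
#' @export
cohort_record <- function(cohort, i) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  if (!is.null(cohort$records)) return(cohort$records[[i]])
  record_from_row(cohort$rows[i, ], cohort$effect, seed = cohort$seed,
                  i = i, fs = cohort$fs, duration = cohort$duration,
                  noise_sd = cohort$noise_sd,
                  drift_amp = cohort$drift_amp)$record
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat("Synthetic ECG cohort:", nrow(x$rows), "patients, fs =", x$fs,
      "Hz,", x$duration, "s records",
      if (is.null(x$records)) "(waveforms regenerated on demand)" else "",
      "\n")
  cat(sprintf("  LVM %.0f-%.0f g (mean %.0f), %d male / %d female\n",
              min(x$rows$lvm_truth), max(x$rows$lvm_truth),
              mean(x$rows$lvm_truth), sum(x$rows$sex == "male"),
              sum(x$rows$sex == "female")))
  invisible(x)
}
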