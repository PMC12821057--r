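# Signal conditioning and the three input representations: full length,
# synchronized random-length crop, and the synchronized middle single
# heartbeat. Sample indexing is 0-based and windows are half-open
# [start, end), matching the landmark convention used throughout.

#' Zero-phase band-pass filter
#'
#' Applies a 3rd-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`, zero phase) to every lead. The default 0.5--40 Hz
#' band removes baseline wander and high-frequency noise while preserving
#' ST-T morphology.
#'
#' @param record An [ecg_record].
#' @param low,high Band edges, Hz; require `0 < low < high < fs/2`.
#' @param order Butterworth order (default 3).
#' @return Filtered [ecg_record] of identical length.
#' @export
bandpass_filter <- function(record, low = 0.5, high = 40, order = 3) {
  stopifnot(inherits(record, "ecg_record"))
  if (!(low > 0 && low < high && high < record$fs / 2)) {
    stop("invalid band: need 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (record$fs / 2), type = "pass")
  wf <- apply(record$waveform, 2, function(x) signal::filtfilt(bf, x))
  colnames(wf) <- ecg_leads()
  record$waveform <- wf
  record
}

#' Detect R peaks
#'
#' Derivative--squaring--moving-integration detection (Pan--Tompkins
#' style) on lead II, falling back to V5 when lead II is flat. Candidate
#' QRS regions are taken where the integrated energy exceeds an adaptive
#' threshold; each peak is refined to the absolute-amplitude maximum of the
#' reference lead and a 200 ms refractory period is enforced.
#'
#' @param record A filtered [ecg_record] of duration >= 2 s.
#' @param refractory Minimum peak spacing, seconds.
#' @return Strictly increasing 0-based sample indices of the R peaks.
#' @export
detect_r_peaks <- function(record, refractory = 0.2) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  L <- nrow(record$waveform)
  if (L / fs < 2) stop("record too short for R-peak detection (< 2 s)")
  x <- record$waveform[, "II"]
  if (max(abs(x)) < 0.05) x <- record$waveform[, "V5"]
  if (max(abs(x)) < 0.05) stop("signal-quality error: reference leads flat")
  d <- c(0, diff(x)) * fs
  s <- d^2
  nw <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(s, rep(1 / nw, nw), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.25 * stats::quantile(integ, 0.99)
  if (thr <= 0) stop("signal-quality error: no QRS energy detected")
  above <- integ > thr
  # contiguous above-threshold regions -> one refined peak each
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- cbind(starts[r$values], ends[r$values])
  if (nrow(regions) == 0) stop("signal-quality error: no peaks found")
  half <- round(0.05 * fs)
  peaks <- apply(regions, 1, function(rg) {
    a <- max(1, rg[1] - half); b <- min(L, rg[2] + half)
    a + which.max(abs(x[a:b])) - 1L
  })
  peaks <- sort(unique(peaks))
  # refractory: keep the larger-amplitude peak of any pair closer than 200 ms
  keep <- rep(TRUE, length(peaks))
  last <- 1
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - peaks[last] < refractory * fs) {
      if (abs(x[peaks[i]]) > abs(x[peaks[last]])) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  as.integer(peaks[keep]) - 1L
}

#' Extract the synchronized middle single heartbeat
#'
#' Slices a fixed window around the middle eligible R peak, applying the
#' same sample range to all 12 leads (synchrony). Eligible peaks are those
#' whose full window lies inside the record; among `n` of them (temporal
#' order) the `floor(n/2)`-th (0-based) is chosen.
#'
#' @param record A (filtered) [ecg_record].
#' @param peaks 0-based R-peak sample indices from [detect_r_peaks()].
#' @param window Window around the R peak, seconds (default -0.25 to
#'   +0.45, which contains P, QRS and T at <= 100 bpm).
#' @return A [beat_segment] with `W = round(diff(window)*fs)` samples,
#'   `r_index = round(-window[1]*fs)`, and `start_sample` recording the
#'   0-based offset of the window within the record.
#' @export
extract_single_beat <- function(record, peaks, window = c(-0.25, 0.45)) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  L <- nrow(record$waveform)
  pre <- round(-window[1] * fs)
  W <- round((window[2] - window[1]) * fs)
  post <- W - pre
  eligible <- peaks[peaks - pre >= 0 & peaks + post <= L]
  if (length(eligible) == 0) {
    stop("no R peak with a full beat window inside record ",
         record$record_id)
  }
  p <- eligible[floor(length(eligible) / 2) + 1]  # middle, 0-based rule
  a <- p - pre + 1                                # 1-based slice start
  seg <- record$waveform[a:(a + W - 1), , drop = FALSE]
  out <- beat_segment(seg, fs = fs, r_index = pre,
                      source_record_id = record$record_id)
  out$start_sample <- as.integer(p - pre)
  out
}

#' Random-length synchronized crop
#'
#' Draws one (start, length) pair -- length uniform in `[min_s, max_s]`
#' seconds, start uniform over the feasible range -- and applies it
#' identically to all 12 leads.
#'
#' @param record An [ecg_record].
#' @param min_s,max_s Length bounds, seconds; `min_s <= max_s <= duration`.
#' @param seed Optional integer making the draw deterministic (the global
#'   RNG state is restored afterwards).
#' @return Cropped [ecg_record]; the 0-based crop start and length in
#'   samples are attached as the `crop` attribute.
#' @export
random_length_crop <- function(record, min_s, max_s, seed = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  L <- nrow(record$waveform)
  dur <- L / fs
  if (!(min_s <= max_s)) stop("min_s must be <= max_s")
  if (max_s > dur + 1e-9) stop("max_s exceeds record duration")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  len <- round(stats::runif(1, min_s, max_s) * fs)
  len <- min(max(len, 1L), L)
  start <- floor(stats::runif(1, 0, L - len + 1))  # 0-based
  start <- min(start, L - len)
  record$waveform <- record$waveform[(start + 1):(start + len), ,
                                     drop = FALSE]
  attr(record, "crop") <- c(start = start, length = len)
  record
}

#' Annotate beat landmarks
#'
#' Locates `p_onset`, `qrs_onset`, `qrs_offset` and `t_offset` (0-based
#' sample offsets) on the reference lead II of a single-beat segment using
#' amplitude-threshold rules relative to the local wave peaks. When
#' simulator ground truth is supplied it overrides detection. On
#' delineation failure the segment is flagged and fixed offsets relative
#' to the R peak are substituted (-200, -50, +50, +400 ms, clipped to the
#' window).
#'
#' @param segment A [beat_segment].
#' @param truth Optional named vector of ground-truth landmarks (0-based
#'   sample offsets within the window).
#' @param fallback_ms Fixed-offset fallback landmarks, ms relative to R.
#' @return The segment with `landmarks` set (and `flagged = TRUE` if the
#'   fallback was used).
#' @export
annotate_landmarks <- function(segment, truth = NULL,
                               fallback_ms = c(p_onset = -200,
                                               qrs_onset = -50,
                                               qrs_offset = 50,
                                               t_offset = 400)) {
  stopifnot(inherits(segment, "beat_segment"))
  fs <- segment$fs
  W <- nrow(segment$waveform)
  r0 <- segment$r_index
  if (!is.null(truth)) {
    return(beat_segment(segment$waveform, fs, r0, landmarks = truth,
                        source_record_id = segment$source_record_id))
  }
  x <- segment$waveform[, "II"]
  samp <- function(sec) round(sec * fs)
  # slope-based rules: thresholds on the smoothed derivative are immune to
  # the baseline offsets a zero-phase high-pass leaves between waves
  nw <- max(3L, samp(0.01))
  if (nw %% 2 == 0) nw <- nw + 1L
  s <- as.numeric(stats::filter(x, rep(1 / nw, nw), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  d <- c(0, (s[-(1:2)] - s[-((W - 1):W)]) / 2 * fs, 0)  # central difference
  ad <- abs(d)
  # scanning from `from` towards `to`: first index opening a run of `run`
  # samples with |derivative| below `frac` of the local maximum slope
  scan_d <- function(from, to, dmax, frac = 0.04, run = 3L) {
    idx <- from:to  # descends when from > to
    below <- ad[idx + 1] < frac * dmax
    n <- length(below)
    if (n < run) return(NA_integer_)
    for (j in seq_len(n - run + 1L)) {
      if (all(below[j:(j + run - 1L)])) return(idx[j])
    }
    NA_integer_
  }
  argmax_d <- function(a, b) a + which.max(ad[(a + 1):(b + 1)]) - 1L
  fail <- FALSE
  la <- max(0, r0 - samp(0.12)); rb <- min(W - 1, r0 + samp(0.12))
  lpk <- argmax_d(la, r0)            # steepest upstroke
  rpk <- argmax_d(r0, rb)            # steepest downstroke
  qrs_on <- scan_d(lpk, la, ad[lpk + 1])
  qrs_off <- scan_d(rpk, rb, ad[rpk + 1])
  if (is.na(qrs_on) || is.na(qrs_off)) fail <- TRUE
  # T offset and P onset tolerate neighbouring-beat overlap at high heart
  # rates: shorter runs and (for P) a laxer slope fraction let the scan
  # settle in the inter-wave slope minimum instead of failing outright
  t_off <- NA_integer_
  if (!fail) {
    ta <- min(W - 2, qrs_off + samp(0.06)); tb <- W - 1
    tpk <- argmax_d(ta, tb)
    t_off <- scan_d(tpk, tb, ad[tpk + 1], frac = 0.05, run = 2L)
    if (is.na(t_off) || t_off <= qrs_off) fail <- TRUE
  }
  p_on <- NA_integer_
  if (!fail) {
    pa <- max(0, r0 - samp(0.30)); pb <- max(0, qrs_on - samp(0.02))
    if (pb <= pa + 2) fail <- TRUE else {
      ppk <- argmax_d(pa, pb)
      p_on <- scan_d(ppk, pa, ad[ppk + 1], frac = 0.10, run = 2L)
      if (is.na(p_on) || p_on >= qrs_on) fail <- TRUE
    }
  }
  if (fail) {
    lm <- r0 + vapply(fallback_ms / 1000, samp, 0)
    lm <- pmin(pmax(lm, 0), W - 1)
    names(lm) <- names(fallback_ms)
    return(beat_segment(segment$waveform, fs, r0, landmarks = lm,
                        source_record_id = segment$source_record_id,
                        flagged = TRUE))
  }
  lm <- c(p_onset = p_on, qrs_onset = qrs_on, qrs_offset = qrs_off,
          t_offset = t_off)
  beat_segment(segment$waveform, fs, r0, landmarks = lm,
               source_record_id = segment$source_record_id)
}

#' Decimate a beat segment
#'
#' Keeps every `factor`-th sample of a band-limited beat. After the
#' default 0.5--40 Hz band-pass, decimation by up to 4 (to 125 Hz) is
#' information-preserving (Nyquist 62.5 Hz > 40 Hz) and shrinks the
#' encoder input proportionally. Landmarks and the R index are rescaled.
#'
#' @param segment A [beat_segment].
#' @param factor Positive integer decimation factor.
#' @return Decimated [beat_segment] at `fs / factor`.
#' @export
decimate_segment <- function(segment, factor = 1L) {
  factor <- as.integer(factor)
  stopifnot(inherits(segment, "beat_segment"), factor >= 1)
  if (factor == 1L) return(segment)
  W <- nrow(segment$waveform)
  keep <- seq(1L, W, by = factor)
  lm <- segment$landmarks
  if (!is.null(lm)) lm <- stats::setNames(as.integer(lm %/% factor), names(lm))
  out <- beat_segment(segment$waveform[keep, , drop = FALSE],
                      fs = segment$fs / factor,
                      r_index = segment$r_index %/% factor,
                      landmarks = lm,
                      source_record_id = segment$source_record_id,
                      flagged = segment$flagged)
  out$start_sample <- segment$start_sample
  out
}
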