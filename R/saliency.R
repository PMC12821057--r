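# Gradient-based saliency and ECG-segment importance aggregation.
#
# The saliency of input sample (lead l, time t) is |d prediction / d x[l,t]|,
# obtained from the same backward pass used in training (scalar-branch
# gradients are ignored: only waveform attribution is tabulated). Per-beat
# segment masks (PR / QRS / ST-T / TP from the fiducial landmarks)
# partition the window; importance is summed per (segment x lead group)
# cell, normalized to 100 % per map, then averaged across maps.

#' Per-sample segment labels from landmarks
#'
#' Partitions the half-open window `[0, W)` into PR `[p_onset, qrs_onset)`,
#' QRS `[qrs_onset, qrs_offset)`, ST-T `[qrs_offset, t_offset)` and TP
#' (the remainder: both flanks). Degenerate (empty) intervals are allowed;
#' landmark ordering violations are an error.
#'
#' @param x A [beat_segment] with landmarks, or a named landmark vector
#'   (0-based sample offsets).
#' @param W Window length in samples (required when `x` is a vector).
#' @return Factor of length `W` with levels `PR`, `QRS`, `STT`, `TP`.
#' @export
build_segment_masks <- function(x, W = NULL) {
  if (inherits(x, "beat_segment")) {
    if (is.null(x$landmarks)) stop("segment has no landmarks")
    W <- nrow(x$waveform)
    lm <- x$landmarks
  } else {
    if (is.null(W)) stop("W is required when passing a landmark vector")
    lm <- x
  }
  p_on <- lm[["p_onset"]]; q_on <- lm[["qrs_onset"]]
  q_off <- lm[["qrs_offset"]]; t_off <- lm[["t_offset"]]
  if (!(p_on <= q_on && q_on <= q_off && q_off <= t_off)) {
    stop("landmark ordering violated: need p_onset <= qrs_onset <= ",
         "qrs_offset <= t_offset")
  }
  if (p_on < 0 || t_off > W) stop("landmarks outside [0, W)")
  lab <- rep("TP", W)
  samp <- 0:(W - 1)
  lab[samp >= p_on & samp < q_on] <- "PR"
  lab[samp >= q_on & samp < q_off] <- "QRS"
  lab[samp >= q_off & samp < t_off] <- "STT"
  factor(lab, levels = c("PR", "QRS", "STT", "TP"))
}

#' Gradient saliency map for one input
#'
#' Runs an evaluation-mode forward pass and a backward pass of the
#' prediction with respect to the waveform input of a single beat,
#' returning absolute gradients per (time sample, lead), reassembled into
#' the canonical 12-lead layout.
#'
#' @param model A trained `lvm_tcn`.
#' @param batch A single-sample batch (`B = 1`), as built by the training
#'   pipeline.
#' @param masks Optional segment-label factor (see
#'   [build_segment_masks()]) stored with the map.
#' @return Object of class `saliency_map`: `values` (`W x 12` non-negative
#'   matrix), `masks`, `lead_group_of` (limb/precordial per lead) and the
#'   prediction.
#' @export
saliency_map <- function(model, batch, masks = NULL) {
  if (batch$B != 1) stop("saliency_map expects a single-sample batch")
  fw <- model_forward(model, batch, train = FALSE, keep_cache = TRUE)
  bw <- model_backward(model, batch, fw$cache, dpred = 1,
                       input_grad = TRUE)
  W <- model$W
  vals <- matrix(0, W, 12, dimnames = list(NULL, ecg_leads()))
  groups <- model$spec$grouping$groups
  for (g in seq_along(groups)) {
    vals[, groups[[g]]] <- abs(bw$d_inputs[[g]])
  }
  lead_group <- stats::setNames(rep(c("limb", "precordial"), each = 6),
                                ecg_leads())
  structure(list(values = vals, masks = masks,
                 lead_group_of = lead_group, pred = fw$pred),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("Saliency map: %d samples x 12 leads, prediction %.1f g\n",
              nrow(x$values), x$pred))
  invisible(x)
}

#' Segment-wise importance table
#'
#' For each saliency map, sums the absolute gradients over the eight
#' (segment x lead group) cells -- segments PR, QRS, ST-T, TP crossed with
#' limb and precordial leads -- normalizes each map's cells to 100 %, and
#' averages the percentages across maps. Maps with all-zero saliency are
#' excluded with a warning (their normalization is undefined).
#'
#' @param maps List of [saliency_map()] objects (each with `masks` set).
#' @return Object of class `segment_importance`: `percentages` (4 x 2
#'   matrix summing to 100) and `n_samples` (maps averaged).
#' @export
segment_importance <- function(maps) {
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  cells <- lapply(maps, function(m) {
    if (is.null(m$masks)) stop("saliency map lacks segment masks")
    tot <- sum(m$values)
    if (tot <= 0) return(NULL)
    seg <- m$masks
    grp <- m$lead_group_of[colnames(m$values)]
    out <- matrix(0, 4, 2, dimnames = list(levels(seg),
                                           c("limb", "precordial")))
    for (s in levels(seg)) {
      sel <- seg == s
      for (gp in colnames(out)) {
        out[s, gp] <- sum(m$values[sel, grp == gp, drop = FALSE])
      }
    }
    100 * out / tot
  })
  drop <- vapply(cells, is.null, TRUE)
  if (any(drop)) {
    warning(sum(drop), " all-zero saliency map(s) excluded from the table")
    cells <- cells[!drop]
  }
  if (!length(cells)) stop("no usable saliency maps")
  pct <- Reduce(`+`, cells) / length(cells)
  structure(list(percentages = pct, n_samples = length(cells)),
            class = "segment_importance")
}

#' @export
print.segment_importance <- function(x, ...) {
  cat(sprintf("ECG-segment importance (%%), averaged over %d sample(s):\n",
              x$n_samples))
  tab <- rbind(x$percentages, Total = colSums(x$percentages))
  print(round(tab, 1))
  invisible(x)
}

#' Select low / middle / high LVM strata
#'
#' Splits the cohort into LVM tertiles (or explicit bounds) and draws `m`
#' samples per stratum, seeded.
#'
#' @param rows Cohort rows with `lvm_truth`.
#' @param m Samples per stratum (default 5).
#' @param bounds Optional length-2 numeric `(low_upper, middle_upper)`
#'   overriding the tertile bounds.
#' @param seed Integer seed for the draws.
#' @return Named list of index vectors `low`, `middle`, `high`.
#' @export
stratify_by_lvm <- function(rows, m = 5, bounds = NULL, seed = 1) {
  lvm <- rows$lvm_truth
  if (is.null(bounds)) {
    bounds <- stats::quantile(lvm, c(1 / 3, 2 / 3), names = FALSE)
  }
  strata <- list(low = which(lvm <= bounds[1]),
                 middle = which(lvm > bounds[1] & lvm <= bounds[2]),
                 high = which(lvm > bounds[2]))
  short <- vapply(strata, length, 0L) < m
  if (any(short)) {
    stop("stratum/strata too small for m = ", m, ": ",
         paste(sprintf("%s (n=%d)", names(strata)[short],
                       vapply(strata[short], length, 0L)), collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  lapply(strata, function(ix) sort(sample(ix, m)))
}

#' Stratified segment-importance analysis of a fitted network
#'
#' Draws `m` samples per LVM stratum from a fold's test set, computes their
#' saliency maps and aggregates one importance table per stratum.
#'
#' @param fit An `lvm_net` from [fit_lvm_net()].
#' @param m Samples per stratum.
#' @param seed Seed for the stratum draws.
#' @param fold Which trained fold to analyse.
#' @return Named list (`low`, `middle`, `high`) of [segment_importance()]
#'   tables.
#' @export
segment_saliency <- function(fit, m = 5, seed = 1, fold = 1) {
  stopifnot(inherits(fit, "lvm_net"))
  f <- fit$fits[[paste0("fold", fold)]]
  if (is.null(f)) f <- fit$fits[[1]]
  ds <- fit$dataset
  test_rows <- ds$rows[f$test_ids, , drop = FALSE]
  strata <- stratify_by_lvm(test_rows, m = m, seed = seed)
  lapply(strata, function(ix) {
    ids <- f$test_ids[ix]
    maps <- lapply(ids, function(i) {
      batch <- make_batch(ds, i, f$model)
      masks <- build_segment_masks(ds$landmarks[i, ], W = ds$W)
      saliency_map(f$model, batch, masks = masks)
    })
    segment_importance(maps)
  })
}
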