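# Dataset preparation, the seeded training loop with validation-based
# model selection, and the user-facing fitting front-end.

#' Training control parameters
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience: training stops after this many
#'   consecutive epochs without a validation-MAE improvement (0 stops at
#'   the first non-improving epoch).
#' @param seed Integer seed driving weight initialization, shuffling and
#'   dropout.
#' @param eval_batch Batch size for evaluation passes.
#' @param verbose Print per-epoch progress.
#' @return Object of class `train_control`.
#' @export
train_control <- function(epochs = 40, batch_size = 64, lr = 2e-3,
                          patience = 8, seed = 1, eval_batch = 128,
                          verbose = FALSE) {
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 patience = patience, seed = seed, eval_batch = eval_batch,
                 verbose = verbose), class = "train_control")
}

#' Prepare model-ready inputs from a cohort
#'
#' Runs the single-heartbeat pipeline for every record: zero-phase
#' band-pass, R-peak detection, synchronized middle-beat extraction,
#' landmark annotation (simulator ground truth when available, else
#' threshold delineation with fixed-offset fallback), optional decimation,
#' and lead grouping. Scalar features are assembled alongside.
#'
#' @param cohort An `ecg_cohort` (or a list with `rows` plus a `records`
#'   list of [ecg_record]s).
#' @param grouping A [lead_grouping()] or scheme name.
#' @param window Beat window around the R peak, seconds.
#' @param low,high Band-pass edges, Hz.
#' @param decimate Integer decimation factor applied to the extracted beat
#'   (see [decimate_segment()]).
#' @param use_truth_landmarks Use the cohort's ground-truth fiducials for
#'   landmarks when present.
#' @return Object of class `lvm_dataset`: stacked per-group waveform
#'   matrices (`(n*W) x n_g`), scalar feature table, targets, landmarks
#'   and geometry.
#' @export
prepare_inputs <- function(cohort, grouping = lead_grouping("electrical"),
                           window = c(-0.25, 0.45), low = 0.5, high = 40,
                           decimate = 1L, use_truth_landmarks = TRUE) {
  if (is.character(grouping)) grouping <- lead_grouping(grouping)
  rows <- cohort$rows
  n <- nrow(rows)
  fid <- cohort$fiducials
  seg1 <- NULL
  seg_wfs <- vector("list", n)
  lm_mat <- matrix(NA_integer_, n, 4,
                   dimnames = list(NULL, c("p_onset", "qrs_onset",
                                           "qrs_offset", "t_offset")))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    rec <- cohort_record(cohort, i)
    filt <- bandpass_filter(rec, low, high)
    peaks <- detect_r_peaks(filt)
    seg <- extract_single_beat(filt, peaks, window)
    truth <- NULL
    if (use_truth_landmarks && !is.null(fid)) {
      rf <- fid[fid$record_id == rec$record_id, , drop = FALSE]
      rp <- rf[rf$landmark == "r_peak", , drop = FALSE]
      g_r <- seg$start_sample + seg$r_index
      hit <- rp$beat_index[abs(rp$sample - g_r) <= round(0.03 * filt$fs)]
      if (length(hit) == 1) {
        lm <- rf[rf$beat_index == hit & rf$landmark != "r_peak", ]
        cand <- stats::setNames(lm$sample - seg$start_sample, lm$landmark)
        W0 <- nrow(seg$waveform)
        if (all(cand >= 0 & cand < W0)) truth <- cand
      }
    }
    seg <- annotate_landmarks(seg, truth = truth)
    seg <- decimate_segment(seg, decimate)
    seg_wfs[[i]] <- seg$waveform
    lm_mat[i, ] <- seg$landmarks[colnames(lm_mat)]
    flagged[i] <- seg$flagged
    if (is.null(seg1)) seg1 <- seg
  }
  W <- nrow(seg1$waveform)
  big <- do.call(rbind, seg_wfs)            # (n*W) x 12, canonical leads
  groups <- lapply(grouping$groups, function(leads)
    big[, leads, drop = FALSE])
  scal <- data.frame(
    age = rows$age, sex_male = as.numeric(rows$sex == "male"),
    height = rows$height, weight = rows$weight,
    qrs_duration = rows$qrs_duration, p_axis = rows$p_axis,
    r_axis = rows$r_axis, t_axis = rows$t_axis
  )
  structure(list(groups = groups, W = W, fs = seg1$fs,
                 r_index = seg1$r_index, grouping = grouping,
                 scalars = scal, y = rows$lvm_truth, rows = rows,
                 landmarks = lm_mat, flagged = flagged, n = n,
                 decimate = as.integer(decimate)),
            class = "lvm_dataset")
}

#' @export
print.lvm_dataset <- function(x, ...) {
  cat(sprintf(paste0("LVM dataset: %d beats x %d samples @ %g Hz, ",
                     "grouping '%s'%s\n"),
              x$n, x$W, x$fs, x$grouping$name,
              if (any(x$flagged))
                sprintf(" (%d fallback landmark sets)", sum(x$flagged))
              else ""))
  invisible(x)
}

# assemble a batch for given sample ids; scalars standardized with the
# model's stored training statistics
make_batch <- function(dataset, ids, model) {
  W <- dataset$W
  ridx <- rep((ids - 1L) * W, each = W) + rep(seq_len(W), times = length(ids))
  groups <- lapply(dataset$groups, function(gm) gm[ridx, , drop = FALSE])
  batch <- list(groups = groups, B = length(ids))
  for (br in active_branches(model$spec$input_set)) {
    feats <- branch_features(br, model$spec$sex_scope)
    v <- as.matrix(dataset$scalars[ids, feats, drop = FALSE])
    sc <- model$scalers[[br]]
    v <- sweep(sweep(v, 2, sc$mean, `-`), 2, sc$sd, `/`)
    batch[[br]] <- v
  }
  batch
}

# evaluation-mode predictions over ids, chunked
predict_ids <- function(model, dataset, ids, eval_batch = 128) {
  out <- numeric(length(ids))
  for (s in split(seq_along(ids), ceiling(seq_along(ids) / eval_batch))) {
    out[s] <- predict_lvm(model, make_batch(dataset, ids[s], model))
  }
  out
}

#' Train one cross-validation fold
#'
#' Trains the network on a fold's training set with Adam on the MAE loss,
#' evaluating on the validation set each epoch and keeping the parameters
#' with minimum validation MAE (early stopping on `patience`). Sex-specific
#' specifications filter the train/validation/test ids to the target sex
#' before training. All stochastic operations (initialization, shuffling,
#' dropout) are seeded, so identical configurations reproduce identical
#' histories.
#'
#' @param dataset An `lvm_dataset` from [prepare_inputs()].
#' @param spec A [model_spec()].
#' @param split A [make_folds()] split of the dataset's LVM values.
#' @param fold Fold number, 1..k.
#' @param control A [train_control()].
#' @return Object of class `lvm_fold_fit`: the trained model, the training
#'   `history` (per-epoch train/val MAE, plus a training-batch checksum),
#'   the id sets and test-set predictions and metrics.
#' @export
train_fold <- function(dataset, spec = model_spec(), split, fold = 1,
                       control = train_control()) {
  stopifnot(inherits(dataset, "lvm_dataset"), inherits(split, "fold_split"))
  f <- split$folds[[fold]]
  train_ids <- f$train_ids; val_ids <- f$val_ids; test_ids <- f$test_ids
  if (spec$sex_scope != "all") {
    sexsel <- dataset$rows$sex == spec$sex_scope
    train_ids <- train_ids[sexsel[train_ids]]
    val_ids <- val_ids[sexsel[val_ids]]
    test_ids <- test_ids[sexsel[test_ids]]
    if (!length(train_ids) || !length(val_ids) || !length(test_ids)) {
      stop(sprintf(paste0("empty %s partition after sex filtering ",
                          "(train %d, val %d, test %d)"), spec$sex_scope,
                   length(train_ids), length(val_ids), length(test_ids)))
    }
  }
  imp <- impute_scalars(dataset$scalars, train_ids,
                        columns = names(dataset$scalars))
  dataset$scalars <- imp$rows
  model <- build_model(spec, dataset$W, seed = control$seed)
  model$scalers <- list()
  for (br in active_branches(spec$input_set)) {
    feats <- branch_features(br, spec$sex_scope)
    v <- as.matrix(dataset$scalars[train_ids, feats, drop = FALSE])
    mu <- colMeans(v); sd <- apply(v, 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    model$scalers[[br]] <- list(mean = mu, sd = sd)
  }
  # start the output at the training-mean LVM: the net then learns the
  # residual structure instead of the gross scale
  nl <- length(model$params$reg)
  model$params$reg[[nl]]$b <- mean(dataset$y[train_ids])
  state <- adam_init(model$params)
  y <- dataset$y
  best <- list(val = Inf, params = model$params, epoch = 0L)
  bad <- 0L
  hist <- vector("list", control$epochs)
  checksum <- 0
  set.seed(control$seed)
  for (ep in seq_len(control$epochs)) {
    ord <- sample(train_ids)
    nb <- ceiling(length(ord) / control$batch_size)
    tr_abs <- 0
    for (b in seq_len(nb)) {
      ids <- ord[((b - 1) * control$batch_size + 1):
                   min(b * control$batch_size, length(ord))]
      batch <- make_batch(dataset, ids, model)
      checksum <- checksum + sum(vapply(batch$groups, sum, 0)) +
        sum(y[ids])
      fw <- model_forward(model, batch, train = TRUE, keep_cache = TRUE)
      resid <- fw$pred - y[ids]
      tr_abs <- tr_abs + sum(abs(resid))
      dpred <- sign(resid) / length(ids)
      bw <- model_backward(model, batch, fw$cache, dpred)
      st <- adam_step(model$params, bw$grads, state, lr = control$lr)
      model$params <- st$params
      state <- st$state
    }
    val_pred <- predict_ids(model, dataset, val_ids, control$eval_batch)
    val_mae <- mean(abs(val_pred - y[val_ids]))
    train_mae <- tr_abs / length(ord)
    hist[[ep]] <- data.frame(epoch = ep, train_mae = train_mae,
                             val_mae = val_mae)
    if (control$verbose) {
      message(sprintf("epoch %3d  train MAE %7.2f  val MAE %7.2f",
                      ep, train_mae, val_mae))
    }
    if (val_mae < best$val - 1e-10) {
      best <- list(val = val_mae, params = model$params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > control$patience) break
    }
  }
  model$params <- best$params
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  attr(history, "checksum") <- checksum
  test_pred <- predict_ids(model, dataset, test_ids, control$eval_batch)
  metrics <- evaluate_lvm(test_pred, y[test_ids])
  structure(list(model = model, history = history, fold = fold,
                 train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, test_pred = test_pred,
                 best_epoch = best$epoch, metrics = metrics,
                 control = control),
            class = "lvm_fold_fit")
}

#' Fit the ECG left-ventricular-mass network
#'
#' The package's modelling front-end: prepares single-beat inputs from a
#' cohort, builds the LVM-sorted systematic fold split, trains the
#' requested folds with validation-based model selection, and returns a
#' fitted `lvm_net` object with the usual methods (`print`, `summary`,
#' `coef`, `predict`, `fitted`, `residuals`, `plot`).
#'
#' @param cohort An `ecg_cohort`, or a prepared `lvm_dataset`.
#' @param input_set Input combination: `"ecg_only"`, `"ecg_demo"`,
#'   `"ecg_params"` or `"ecg_demo_params"` (waveforms + demographics +
#'   automatic ECG parameters; the default, full model).
#' @param grouping Lead grouping scheme (default electrical orientation:
#'   limb vs precordial encoders).
#' @param sex `"all"`, `"male"` or `"female"`: sex-specific models are
#'   trained on the target sex only.
#' @param tcn A [tcn_config()].
#' @param k Number of folds.
#' @param folds Which folds to train (default 1; `seq_len(k)` for full
#'   cross-validation).
#' @param control A [train_control()].
#' @param decimate,window Passed to [prepare_inputs()] when `cohort` is
#'   not already a dataset.
#' @param ... Further arguments to [model_spec()].
#' @return Object of class `lvm_net`.
#' @examples
#' \donttest{
#' co <- synthesize_cohort(60, seed = 1)
#' fit <- fit_lvm_net(co, input_set = "ecg_demo",
#'                    tcn = tcn_config(n_blocks = 4, channels = 8),
#'                    decimate = 4L,
#'                    control = train_control(epochs = 3, verbose = FALSE))
#' print(fit)
#' }
#' @export
fit_lvm_net <- function(cohort, input_set = "ecg_demo_params",
                        grouping = "electrical", sex = "all",
                        tcn = tcn_config(), k = 5, folds = 1,
                        control = train_control(), decimate = 1L,
                        window = c(-0.25, 0.45), ...) {
  cl <- match.call()
  dataset <- if (inherits(cohort, "lvm_dataset")) cohort else
    prepare_inputs(cohort, grouping = grouping, window = window,
                   decimate = decimate)
  spec <- model_spec(grouping = dataset$grouping, tcn = tcn,
                     input_set = input_set, sex_scope = sex, ...)
  split <- make_folds(dataset$y, k = k)
  fits <- lapply(folds, function(f)
    train_fold(dataset, spec, split, fold = f, control = control))
  names(fits) <- paste0("fold", folds)
  mae <- vapply(fits, function(f) f$metrics$mae, 0)
  mape <- vapply(fits, function(f) f$metrics$mape, 0)
  structure(list(call = cl, spec = spec, split = split, fits = fits,
                 folds = folds, dataset = dataset,
                 mae = mean(mae), mae_sd = stats::sd(mae),
                 mape = mean(mape), mape_sd = stats::sd(mape)),
            class = "lvm_net")
}

#' @export
print.lvm_net <- function(x, ...) {
  cat("ECG LVM network fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  input set %s, grouping %s, sex scope %s, %d fold(s)\n",
              x$spec$input_set, x$spec$grouping$name, x$spec$sex_scope,
              length(x$folds)))
  if (length(x$folds) > 1) {
    cat(sprintf("  test MAE %.1f (+/- %.1f) g, MAPE %.1f (+/- %.1f) %%\n",
                x$mae, x$mae_sd, x$mape, x$mape_sd))
  } else {
    cat(sprintf("  test MAE %.1f g, MAPE %.1f %%\n", x$mae, x$mape))
  }
  invisible(x)
}

#' @export
summary.lvm_net <- function(object, ...) {
  x <- object
  per_fold <- do.call(rbind, lapply(x$fits, function(f) {
    rows <- x$dataset$rows[f$test_ids, , drop = FALSE]
    lm <- lvh_metrics(f$test_pred, rows)
    data.frame(fold = f$fold, n_test = length(f$test_ids),
               best_epoch = f$best_epoch, mae = f$metrics$mae,
               mape = f$metrics$mape, lvh_accuracy = lm$accuracy,
               lvh_sensitivity = lm$sensitivity,
               lvh_specificity = lm$specificity,
               lvh_c_statistic = as.numeric(lm$c_statistic))
  }))
  rownames(per_fold) <- NULL
  out <- list(call = x$call, input_set = x$spec$input_set,
              sex_scope = x$spec$sex_scope, per_fold = per_fold,
              mae = x$mae, mae_sd = x$mae_sd, mape = x$mape,
              mape_sd = x$mape_sd)
  class(out) <- "summary.lvm_net"
  out
}

#' @export
print.summary.lvm_net <- function(x, ...) {
  cat("ECG LVM network fit --", x$input_set, "/", x$sex_scope, "\n\n")
  print(x$per_fold, digits = 3)
  cat(sprintf("\n  across folds: MAE %.1f (+/- %.1f) g, MAPE %.1f (+/- %.1f) %%\n",
              x$mae, x$mae_sd, x$mape, x$mape_sd))
  invisible(x)
}

#' @export
coef.lvm_net <- function(object, ...) {
  # coefficients of the final linear prediction head
  f <- object$fits[[1]]
  nl <- length(f$model$params$reg)
  list(weights = f$model$params$reg[[nl]]$w,
       bias = f$model$params$reg[[nl]]$b)
}

#' @export
fitted.lvm_net <- function(object, ...) {
  # out-of-sample predictions on the trained folds' test sets
  unlist(lapply(object$fits, function(f)
    stats::setNames(f$test_pred, f$test_ids)))
}

#' @export
residuals.lvm_net <- function(object, ...) {
  unlist(lapply(object$fits, function(f)
    stats::setNames(object$dataset$y[f$test_ids] - f$test_pred,
                    f$test_ids)))
}

#' Predict LVM from a fitted network
#'
#' @param object An `lvm_net` fit.
#' @param newdata Optional `ecg_cohort` or `lvm_dataset`; when omitted the
#'   test-fold predictions are returned.
#' @param fold Which trained fold's model to use (default the first).
#' @param ... Unused.
#' @return Numeric vector of predicted LVM, grams.
#' @export
predict.lvm_net <- function(object, newdata = NULL, fold = 1, ...) {
  f <- object$fits[[paste0("fold", fold)]]
  if (is.null(f)) f <- object$fits[[1]]
  if (is.null(newdata)) return(fitted(object))
  ds <- if (inherits(newdata, "lvm_dataset")) newdata else
    prepare_inputs(newdata, grouping = object$spec$grouping,
                   decimate = object$dataset$decimate)
  if (ds$W != f$model$W) {
    stop(sprintf("input length mismatch: model expects W = %d, got %d",
                 f$model$W, ds$W))
  }
  predict_ids(f$model, ds, seq_len(ds$n), f$control$eval_batch)
}

#' @export
plot.lvm_net <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  f <- x$fits[[1]]
  truth <- x$dataset$y[f$test_ids]
  graphics::plot(truth, f$test_pred, xlab = "true LVM (g)",
                 ylab = "predicted LVM (g)",
                 main = sprintf("fold %d test set", f$fold), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6))
  graphics::abline(0, 1, lty = 2)
  h <- f$history
  graphics::matplot(h$epoch, cbind(h$train_mae, h$val_mae), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MAE (g)", main = "training")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Writes the trained weights (flattened, full precision) and a JSON
#' sidecar with the specification, input geometry, standardization
#' statistics and seed to a directory; `load_checkpoint` reconstructs the
#' model bit-identically.
#'
#' @param model An `lvm_tcn` (e.g. `fit$fits[[1]]$model`).
#' @param dir Checkpoint directory.
#' @return `dir` (save) or the restored `lvm_tcn` (load).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- unlist(tree_map(as.numeric, model$params), use.names = FALSE)
  writeLines(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
             file.path(dir, "weights.txt"))
  sp <- model$spec
  side <- list(grouping = sp$grouping$name, tcn = unclass(sp$tcn),
               scalar_branches = sp$scalar_branches,
               projection_dim = sp$projection_dim,
               regressor_hidden = sp$regressor_hidden,
               input_set = sp$input_set, sex_scope = sp$sex_scope,
               W = model$W, seed = model$seed,
               scalers = model$scalers)
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  spec <- model_spec(grouping = lead_grouping(side$grouping),
                     tcn = do.call(tcn_config, side$tcn),
                     scalar_branches = as.list(side$scalar_branches),
                     projection_dim = side$projection_dim,
                     regressor_hidden = side$regressor_hidden,
                     input_set = side$input_set,
                     sex_scope = side$sex_scope)
  model <- build_model(spec, side$W, seed = side$seed)
  flat <- as.numeric(readLines(file.path(dir, "weights.txt")))
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    k <- length(p)
    v <- flat[(pos + 1L):(pos + k)]
    pos <<- pos + k
    array(v, dim = if (is.null(dim(p))) k else dim(p),
          dimnames = dimnames(p))
  }
  model$params <- fill(model$params)
  if (pos != length(flat)) stop("checkpoint weight count mismatch")
  if (!is.null(side$scalers)) {
    model$scalers <- lapply(side$scalers, function(s)
      list(mean = unlist(s$mean), sd = unlist(s$sd)))
  }
  model
}
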