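# The LVM regression network: one temporal convolutional encoder per lead
# group, global-average-pooled into per-group embeddings, concatenated and
# projected; scalar features (demographics, automatic ECG parameters) pass
# through their own MLP branches; the fused vector feeds an MLP regressor
# with a single linear output (grams). Trained with MAE loss.

#' TCN encoder configuration
#'
#' Each residual block holds two dilated "same" convolutions (dilation of
#' block `i` is `dilation_base^(i-1)`), ReLU activations, dropout, and an
#' identity (or 1x1-convolution) skip connection. The receptive field
#' `R = 1 + sum_i 2*(kernel_size-1)*dilation_base^(i-1)` must cover the
#' input window; this is enforced at model construction.
#'
#' @param n_blocks Number of residual blocks.
#' @param channels Channels per block.
#' @param kernel_size Convolution kernel length (odd).
#' @param dilation_base Dilation growth factor.
#' @param dropout Dropout probability in \[0, 1).
#' @param embedding_dim Per-group embedding width.
#' @return Object of class `tcn_config`.
#' @export
tcn_config <- function(n_blocks = 5, channels = 32, kernel_size = 7,
                       dilation_base = 2, dropout = 0.1,
                       embedding_dim = 64) {
  stopifnot(n_blocks >= 1, channels >= 1, kernel_size >= 1,
            kernel_size %% 2 == 1, dilation_base >= 1,
            dropout >= 0, dropout < 1, embedding_dim >= 1)
  structure(list(n_blocks = n_blocks, channels = channels,
                 kernel_size = kernel_size, dilation_base = dilation_base,
                 dropout = dropout, embedding_dim = embedding_dim),
            class = "tcn_config")
}

#' Receptive field of a TCN configuration
#'
#' @param tcn A [tcn_config()].
#' @return Receptive field in samples:
#'   `1 + sum_i 2*(kernel_size-1)*dilation_base^(i-1)`.
#' @export
receptive_field <- function(tcn) {
  dil <- tcn$dilation_base^(seq_len(tcn$n_blocks) - 1)
  1 + sum(2 * (tcn$kernel_size - 1) * dil)
}

#' Model specification
#'
#' @param grouping A [lead_grouping()] (or scheme name); one TCN encoder is
#'   instantiated per group.
#' @param tcn A [tcn_config()].
#' @param scalar_branches Named list of hidden-layer sizes for the scalar
#'   branches `demographics` and `ecg_params`.
#' @param projection_dim Width of the projection layer aggregating the
#'   concatenated group embeddings.
#' @param regressor_hidden Hidden sizes of the final MLP regressor (a
#'   single linear output unit is appended).
#' @param input_set Which inputs the model consumes: waveforms only
#'   (`ecg_only`), plus demographics (`ecg_demo`), plus automatic ECG
#'   parameters (`ecg_demo_params`), or waveforms + parameters
#'   (`ecg_params`).
#' @param sex_scope `all`, `male` or `female`; sex-specific models drop
#'   the (constant) sex indicator from the demographics branch.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(grouping = lead_grouping("electrical"),
                       tcn = tcn_config(),
                       scalar_branches = list(demographics = c(32, 32),
                                              ecg_params = c(32, 32)),
                       projection_dim = 128,
                       regressor_hidden = c(128, 64),
                       input_set = c("ecg_demo_params", "ecg_only",
                                     "ecg_demo", "ecg_params"),
                       sex_scope = c("all", "male", "female")) {
  if (is.character(grouping)) grouping <- lead_grouping(grouping)
  input_set <- match.arg(input_set)
  sex_scope <- match.arg(sex_scope)
  structure(list(grouping = grouping, tcn = tcn,
                 scalar_branches = scalar_branches,
                 projection_dim = projection_dim,
                 regressor_hidden = regressor_hidden,
                 input_set = input_set, sex_scope = sex_scope),
            class = "model_spec")
}

# which scalar branches an input set activates
active_branches <- function(input_set) {
  switch(input_set,
         ecg_only = character(),
         ecg_demo = "demographics",
         ecg_params = "ecg_params",
         ecg_demo_params = c("demographics", "ecg_params"))
}

#' Scalar feature columns per branch
#'
#' Demographics are age, sex (male = 1, female = 0; dropped in
#' sex-specific models), height and weight; automatic ECG parameters are
#' QRS duration and the P/R/T axes.
#'
#' @param branch `"demographics"` or `"ecg_params"`.
#' @param sex_scope Model sex scope.
#' @return Character vector of column names.
#' @export
branch_features <- function(branch, sex_scope = "all") {
  switch(branch,
         demographics = if (sex_scope == "all")
           c("age", "sex_male", "height", "weight")
         else c("age", "height", "weight"),
         ecg_params = c("qrs_duration", "p_axis", "r_axis", "t_axis"),
         stop("unknown branch ", branch))
}

#' Build an untrained LVM regressor
#'
#' Instantiates all parameters (fan-in-scaled uniform initialization,
#' seeded) for a given specification and input window length, enforcing
#' the receptive-field inequality.
#'
#' @param spec A [model_spec()].
#' @param input_length Samples per beat window (W).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `lvm_tcn` holding the parameter tree, the
#'   specification and (once trained) the scalar standardization
#'   statistics.
#' @export
build_model <- function(spec, input_length, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  tc <- spec$tcn
  rf <- receptive_field(tc)
  if (rf < input_length) {
    stop(sprintf(paste0("receptive field %d < input length %d: need 1 + ",
                        "sum_i 2*(kernel_size-1)*dilation_base^i >= W; ",
                        "increase n_blocks, kernel_size or dilation_base"),
                 rf, input_length))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  K <- tc$kernel_size; C <- tc$channels
  conv_par <- function(cin, cout) {
    list(w = lapply(seq_len(K), function(k) init_mat(cin * K, cin, cout)),
         b = numeric(cout))
  }
  groups <- spec$grouping$groups
  params <- list()
  params$groups <- lapply(groups, function(leads) {
    cin <- length(leads)
    blocks <- vector("list", tc$n_blocks)
    for (i in seq_len(tc$n_blocks)) {
      bl <- list()
      c_in <- if (i == 1) cin else C
      cv1 <- conv_par(c_in, C); cv2 <- conv_par(C, C)
      bl$w1 <- cv1$w; bl$b1 <- cv1$b
      bl$w2 <- cv2$w; bl$b2 <- cv2$b
      if (c_in != C) {
        bl$ws <- init_mat(c_in, c_in, C)
        bl$bs <- numeric(C)
      }
      blocks[[i]] <- bl
    }
    list(blocks = blocks,
         emb = list(w = init_mat(C, C, tc$embedding_dim),
                    b = numeric(tc$embedding_dim)))
  })
  params$proj <- list(
    w = init_mat(length(groups) * tc$embedding_dim,
                 length(groups) * tc$embedding_dim, spec$projection_dim),
    b = numeric(spec$projection_dim))
  branches <- active_branches(spec$input_set)
  params$branch <- list()
  for (br in branches) {
    d_in <- length(branch_features(br, spec$sex_scope))
    hs <- spec$scalar_branches[[br]]
    layers <- list(); prev <- d_in
    for (h in hs) {
      layers[[length(layers) + 1]] <- list(w = init_mat(prev, prev, h),
                                           b = numeric(h))
      prev <- h
    }
    params$branch[[br]] <- layers
  }
  fuse_dim <- spec$projection_dim +
    sum(vapply(branches, function(br)
      utils::tail(spec$scalar_branches[[br]], 1), 0))
  layers <- list(); prev <- fuse_dim
  for (h in spec$regressor_hidden) {
    layers[[length(layers) + 1]] <- list(w = init_mat(prev, prev, h),
                                         b = numeric(h))
    prev <- h
  }
  layers[[length(layers) + 1]] <- list(w = init_mat(prev, prev, 1),
                                       b = numeric(1))
  params$reg <- layers
  structure(list(spec = spec, W = as.integer(input_length),
                 params = params,
                 group_sizes = vapply(groups, length, 0L),
                 scalers = NULL, seed = seed),
            class = "lvm_tcn")
}

#' @export
print.lvm_tcn <- function(x, ...) {
  np <- sum(unlist(tree_map(length, x$params)))
  cat(sprintf(paste0("LVM TCN regressor: %d lead group(s) [%s], W = %d, ",
                     "input set '%s', sex scope '%s', %d parameters\n"),
              length(x$group_sizes), x$spec$grouping$name, x$W,
              x$spec$input_set, x$spec$sex_scope, np))
  invisible(x)
}

# validate a batch against the model contract
check_batch <- function(model, batch) {
  G <- length(model$group_sizes)
  if (length(batch$groups) != G) {
    stop(sprintf("grouping mismatch: expected %d group matrices, got %d",
                 G, length(batch$groups)))
  }
  for (g in seq_len(G)) {
    got <- ncol(batch$groups[[g]])
    if (got != model$group_sizes[g]) {
      stop(sprintf("group %d: expected %d leads, got %d",
                   g, model$group_sizes[g], got))
    }
    if (nrow(batch$groups[[g]]) != batch$B * model$W) {
      stop(sprintf("group %d: expected %d rows (B=%d x W=%d), got %d",
                   g, batch$B * model$W, batch$B, model$W,
                   nrow(batch$groups[[g]])))
    }
  }
  for (br in active_branches(model$spec$input_set)) {
    v <- batch[[br]]
    if (is.null(v)) stop("input set '", model$spec$input_set,
                         "' requires the ", br, " matrix")
    if (anyNA(v)) stop(br, " contains NA: impute before encoding")
    want <- length(branch_features(br, model$spec$sex_scope))
    if (ncol(v) != want) {
      stop(sprintf("%s: expected %d features, got %d", br, want, ncol(v)))
    }
  }
  invisible(TRUE)
}

# forward pass; returns prediction vector and (optionally) all caches
model_forward <- function(model, batch, train = FALSE, keep_cache = FALSE) {
  check_batch(model, batch)
  sp <- model$spec; tc <- sp$tcn
  B <- batch$B; W <- model$W
  p <- model$params
  G <- length(p$groups)
  cache <- list(groups = vector("list", G))
  embs <- vector("list", G)
  for (g in seq_len(G)) {
    X <- batch$groups[[g]]
    nb <- tc$n_blocks
    bl_caches <- vector("list", nb)
    for (i in seq_len(nb)) {
      bl <- p$groups[[g]]$blocks[[i]]
      dil <- tc$dilation_base^(i - 1)
      c1 <- conv1d_fw(X, bl$w1, bl$b1, dil, B, W)
      a1 <- relu_fw(c1$Y)
      d1 <- dropout_fw(a1, tc$dropout, train)
      c2 <- conv1d_fw(d1$Y, bl$w2, bl$b2, dil, B, W)
      a2 <- relu_fw(c2$Y)
      d2 <- dropout_fw(a2, tc$dropout, train)
      sk <- if (!is.null(bl$ws)) dense_fw(X, bl$ws, bl$bs) else X
      out <- relu_fw(d2$Y + sk)
      bl_caches[[i]] <- list(c1 = c1, a1 = a1, m1 = d1$mask, c2 = c2,
                             a2 = a2, m2 = d2$mask, X = X, out = out)
      X <- out
    }
    P <- pool_fw(X, B, W)
    Epre <- dense_fw(P, p$groups[[g]]$emb$w, p$groups[[g]]$emb$b)
    E <- relu_fw(Epre)
    embs[[g]] <- E
    cache$groups[[g]] <- list(blocks = bl_caches, P = P, E = E)
  }
  EC <- do.call(cbind, embs)
  Pr <- relu_fw(dense_fw(EC, p$proj$w, p$proj$b))
  cache$EC <- EC; cache$Pr <- Pr
  fused <- list(Pr)
  cache$branch <- list()
  for (br in active_branches(sp$input_set)) {
    H <- batch[[br]]
    layer_caches <- list()
    for (ly in p$branch[[br]]) {
      Hin <- H
      H <- relu_fw(dense_fw(Hin, ly$w, ly$b))
      layer_caches[[length(layer_caches) + 1]] <- list(X = Hin, out = H)
    }
    cache$branch[[br]] <- layer_caches
    fused[[length(fused) + 1]] <- H
  }
  Z <- do.call(cbind, fused)
  cache$Z <- Z
  nl <- length(p$reg)
  reg_caches <- vector("list", nl)
  H <- Z
  for (j in seq_len(nl)) {
    Hin <- H
    H <- dense_fw(Hin, p$reg[[j]]$w, p$reg[[j]]$b)
    if (j < nl) H <- relu_fw(H)
    reg_caches[[j]] <- list(X = Hin, out = H)
  }
  cache$reg <- reg_caches
  pred <- as.numeric(H)
  if (keep_cache) list(pred = pred, cache = cache) else list(pred = pred)
}

# backward pass: gradient tree wrt parameters and, optionally, wrt the
# waveform inputs (for saliency)
model_backward <- function(model, batch, cache, dpred,
                           input_grad = FALSE) {
  sp <- model$spec; tc <- sp$tcn
  B <- batch$B; W <- model$W
  p <- model$params
  g_tree <- list()
  dH <- matrix(dpred, ncol = 1)
  nl <- length(p$reg)
  g_reg <- vector("list", nl)
  for (j in rev(seq_len(nl))) {
    rc <- cache$reg[[j]]
    if (j < nl) dH <- relu_bw(dH, rc$out)
    bw <- dense_bw(dH, rc$X, p$reg[[j]]$w)
    g_reg[[j]] <- list(w = bw$dw, b = bw$db)
    dH <- bw$dX
  }
  g_tree$reg <- g_reg
  dZ <- dH
  off <- ncol(cache$Pr)
  dPr <- dZ[, seq_len(off), drop = FALSE]
  g_tree$branch <- list()
  for (br in active_branches(sp$input_set)) {
    hs <- p$branch[[br]]
    wd <- ncol(cache$branch[[br]][[length(hs)]]$out)
    dBr <- dZ[, off + seq_len(wd), drop = FALSE]
    off <- off + wd
    g_ly <- vector("list", length(hs))
    for (j in rev(seq_along(hs))) {
      lc <- cache$branch[[br]][[j]]
      dBr <- relu_bw(dBr, lc$out)
      bw <- dense_bw(dBr, lc$X, hs[[j]]$w)
      g_ly[[j]] <- list(w = bw$dw, b = bw$db)
      dBr <- bw$dX
    }
    g_tree$branch[[br]] <- g_ly
  }
  dPr <- relu_bw(dPr, cache$Pr)
  bw <- dense_bw(dPr, cache$EC, p$proj$w)
  g_tree$proj <- list(w = bw$dw, b = bw$db)
  dEC <- bw$dX
  G <- length(p$groups)
  g_groups <- vector("list", G)
  names(g_groups) <- names(p$groups)
  d_inputs <- if (input_grad) vector("list", G) else NULL
  col0 <- 0
  for (g in seq_len(G)) {
    gc <- cache$groups[[g]]
    ed <- tc$embedding_dim
    dE <- dEC[, col0 + seq_len(ed), drop = FALSE]
    col0 <- col0 + ed
    dE <- relu_bw(dE, gc$E)
    bw <- dense_bw(dE, gc$P, p$groups[[g]]$emb$w)
    g_emb <- list(w = bw$dw, b = bw$db)
    dX <- pool_bw(bw$dX, B, W)
    nb <- tc$n_blocks
    g_blocks <- vector("list", nb)
    for (i in rev(seq_len(nb))) {
      bl <- p$groups[[g]]$blocks[[i]]
      bc <- gc$blocks[[i]]
      dil <- tc$dilation_base^(i - 1)
      dz <- relu_bw(dX, bc$out)
      if (!is.null(bl$ws)) {
        sk_bw <- dense_bw(dz, bc$X, bl$ws)
        dX_skip <- sk_bw$dX
        g_sk <- list(ws = sk_bw$dw, bs = sk_bw$db)
      } else {
        dX_skip <- dz
        g_sk <- NULL
      }
      da2 <- dropout_bw(dz, bc$m2)
      dc2 <- relu_bw(da2, bc$a2)
      bw2 <- conv1d_bw(dc2, bc$c2, bl$w2, dil, B, W)
      da1 <- dropout_bw(bw2$dX, bc$m1)
      dc1 <- relu_bw(da1, bc$a1)
      bw1 <- conv1d_bw(dc1, bc$c1, bl$w1, dil, B, W)
      gb <- list(w1 = bw1$dw, b1 = bw1$db, w2 = bw2$dw, b2 = bw2$db)
      if (!is.null(g_sk)) { gb$ws <- g_sk$ws; gb$bs <- g_sk$bs }
      g_blocks[[i]] <- gb
      dX <- bw1$dX + dX_skip
    }
    g_groups[[g]] <- list(blocks = g_blocks, emb = g_emb)
    if (input_grad) d_inputs[[g]] <- dX
  }
  g_tree$groups <- g_groups
  # reorder to match the parameter tree layout exactly
  g_tree <- g_tree[names(p)[names(p) %in% names(g_tree)]]
  list(grads = g_tree, d_inputs = d_inputs)
}

#' Mean absolute error loss
#'
#' @param pred,truth Numeric vectors of equal positive length (grams).
#' @return `mean(abs(pred - truth))`.
#' @export
mae_loss <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    stop("pred and truth must be non-empty vectors of equal length")
  }
  mean(abs(pred - truth))
}

#' Encode a scalar feature vector
#'
#' Standardizes a raw feature vector with the model's stored training-fold
#' statistics and passes it through the requested scalar branch,
#' returning the deterministic embedding (dropout is never applied to the
#' scalar branches).
#'
#' @param model A built (and typically trained) `lvm_tcn`.
#' @param values Named numeric vector or single-row matrix with the
#'   branch's features (see [branch_features()]).
#' @param branch `"demographics"` or `"ecg_params"`.
#' @return Numeric embedding vector.
#' @export
encode_scalars <- function(model, values, branch = "demographics") {
  if (!branch %in% names(model$params$branch)) {
    stop("model input set '", model$spec$input_set,
         "' has no '", branch, "' branch")
  }
  if (anyNA(values)) stop("NA in scalar input: impute before encoding")
  v <- matrix(as.numeric(values), nrow = 1)
  if (!is.null(model$scalers[[branch]])) {
    sc <- model$scalers[[branch]]
    v <- sweep(sweep(v, 2, sc$mean, `-`), 2, sc$sd, `/`)
  }
  H <- v
  for (ly in model$params$branch[[branch]]) {
    H <- relu_fw(dense_fw(H, ly$w, ly$b))
  }
  as.numeric(H)
}

#' Predict LVM for a batch of model-ready inputs
#'
#' Evaluation-mode forward pass (deterministic: dropout disabled).
#'
#' @param model A `lvm_tcn`.
#' @param batch Batch list with `groups` (stacked per-group waveform
#'   matrices), optional `demographics`/`ecg_params` matrices
#'   (standardized), and `B`.
#' @return Numeric vector of predicted LVM, grams.
#' @export
predict_lvm <- function(model, batch) {
  model_forward(model, batch, train = FALSE)$pred
}
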