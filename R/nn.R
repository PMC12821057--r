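# Minimal neural-network primitives for the TCN regressor.
#
# Batches of 1-D multichannel signals are stored stacked sample-major: a
# batch of B windows of length W with C channels is a (B*W) x C matrix
# (rows: sample 1..W of window 1, then window 2, ...). A dilated "same"
# convolution is then K shifted-row gathers followed by K (Cin x Cout)
# matmuls, which keeps all heavy arithmetic inside BLAS. Zero padding is
# per-window: a gather index pointing outside its window maps to an extra
# all-zero row appended to the input.

# memoized per-window shift indices for the stacked layout
.shift_cache <- new.env(parent = emptyenv())

shift_idx <- function(B, W, off) {
  key <- paste(B, W, off, sep = "_")
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  src <- (1:W) + off
  src[src < 1 | src > W] <- NA
  idx <- rep(src, times = B) + rep((0:(B - 1)) * W, each = W)
  idx[is.na(idx)] <- B * W + 1L
  idx <- as.integer(idx)
  .shift_cache[[key]] <- idx
  idx
}

# w: list of K (Cin x Cout) matrices; acausal "same" conv, center (K+1)/2
conv1d_fw <- function(X, w, b, dil, B, W) {
  K <- length(w)
  ctr <- (K + 1) / 2
  Xp <- rbind(X, 0)
  Y <- matrix(rep(b, each = nrow(X)), nrow(X))
  for (k in seq_len(K)) {
    idx <- shift_idx(B, W, as.integer((k - ctr) * dil))
    Y <- Y + Xp[idx, , drop = FALSE] %*% w[[k]]
  }
  list(Y = Y, X = X)
}

conv1d_bw <- function(dY, cache, w, dil, B, W) {
  K <- length(w)
  ctr <- (K + 1) / 2
  Xp <- rbind(cache$X, 0)
  dYp <- rbind(dY, 0)
  dX <- matrix(0, nrow(dY), nrow(w[[1]]))
  dw <- vector("list", K)
  for (k in seq_len(K)) {
    off <- as.integer((k - ctr) * dil)
    idx <- shift_idx(B, W, off)
    dw[[k]] <- crossprod(Xp[idx, , drop = FALSE], dY)
    ridx <- shift_idx(B, W, -off)
    dX <- dX + dYp[ridx, , drop = FALSE] %*% t(w[[k]])
  }
  list(dX = dX, dw = dw, db = colSums(dY))
}

relu_fw <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

relu_bw <- function(dY, Y) {
  dY * (Y > 0)
}

dropout_fw <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

dropout_bw <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

dense_fw <- function(X, w, b) {
  Y <- X %*% w
  sweep(Y, 2, b, `+`)
}

dense_bw <- function(dY, X, w) {
  list(dX = dY %*% t(w), dw = crossprod(X, dY), db = colSums(dY))
}

# global average pool over time: (B*W) x C -> B x C
pool_fw <- function(X, B, W) {
  grp <- rep(seq_len(B), each = W)
  rowsum(X, grp, reorder = FALSE) / W
}

pool_bw <- function(dY, B, W) {
  dY[rep(seq_len(B), each = W), , drop = FALSE] / W
}

# fan-in-scaled uniform initialization
init_mat <- function(nin_eff, nr, nc) {
  lim <- sqrt(1 / nin_eff)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- nested parameter trees -------------------------------------------

tree_map <- function(f, p) {
  if (is.list(p)) lapply(p, function(e) tree_map(f, e)) else f(p)
}

tree_map2 <- function(f, p, q) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- tree_map2(f, p[[i]], q[[i]])
    out
  } else f(p, q)
}

tree_zero <- function(p) tree_map(function(x) x * 0, p)

tree_add <- function(p, q) tree_map2(`+`, p, q)

# Adam with bias correction over a parameter tree
adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
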