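# LVM-sorted systematic cross-validation folds.

#' Sorted systematic k-fold split
#'
#' Sorts the samples by LVM (ties stable by original index) and assigns
#' sorted position `j` (0-based) to fold `j mod k`, so every fold sees an
#' even LVM distribution. For each test fold, the remaining samples (in
#' sorted order) form the training portion, from which every
#' `val_every`-th sample (0-based positions `val_every-1`,
#' `2*val_every-1`, ...) becomes the validation set.
#'
#' With n = 1459 and k = 5 this yields test folds of 292/292/292/292/291
#' and, per fold, 1051 training and 116 validation samples.
#'
#' @param lvm Numeric vector of ground-truth LVM values (finite).
#' @param k Number of folds (default 5); requires `length(lvm) >= k`.
#' @param val_every Validation thinning step within the sorted training
#'   portion (default 10).
#' @return Object of class `fold_split`: `k`, `fold_assignments` (0-based
#'   fold id per sample) and `folds`, a list of `k` lists with disjoint
#'   `train_ids`, `val_ids`, `test_ids` (1-based indices).
#' @export
make_folds <- function(lvm, k = 5, val_every = 10) {
  n <- length(lvm)
  if (n < k) stop("need at least k samples (n = ", n, ", k = ", k, ")")
  if (any(!is.finite(lvm))) stop("LVM values must be finite")
  ord <- order(lvm)                      # stable: ties by original index
  fold_of <- integer(n)
  fold_of[ord] <- (seq_len(n) - 1L) %% k # sorted position j -> j mod k
  folds <- lapply(seq_len(k) - 1L, function(f) {
    test_ids <- ord[fold_of[ord] == f]
    train_sorted <- ord[fold_of[ord] != f]   # sorted order preserved
    pos <- seq_along(train_sorted) - 1L
    val_sel <- (pos %% val_every) == (val_every - 1L)
    list(train_ids = train_sorted[!val_sel],
         val_ids = train_sorted[val_sel],
         test_ids = test_ids)
  })
  structure(list(k = k, fold_assignments = fold_of, folds = folds),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test_ids), 0L)
  cat(sprintf("Sorted systematic %d-fold split of %d samples\n",
              x$k, length(x$fold_assignments)))
  cat("  test fold sizes:", paste(sizes, collapse = ", "), "\n")
  f1 <- x$folds[[1]]
  cat(sprintf("  per fold: %d train / %d validation / %d test\n",
              length(f1$train_ids), length(f1$val_ids),
              length(f1$test_ids)))
  invisible(x)
}
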