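# LVM regression metrics, LVH classification and the echo-to-CT
# recalibration hook.

#' MAE and MAPE between predicted and true LVM
#'
#' @param pred,truth Numeric vectors of equal positive length, grams.
#'   All `truth` must be > 0 (MAPE divides by it).
#' @return List with `mae` (grams) and `mape` (percent):
#'   `mae = mean(|pred - truth|)`,
#'   `mape = 100 * mean(|pred - truth| / truth)`.
#' @examples
#' evaluate_lvm(c(90, 220), c(100, 200))  # mae 15, mape 10
#' @export
evaluate_lvm <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    stop("pred and truth must be non-empty vectors of equal length")
  }
  if (any(truth <= 0)) stop("MAPE requires all truth values > 0")
  list(mae = mean(abs(pred - truth)),
       mape = 100 * mean(abs(pred - truth) / truth))
}

#' Body surface area
#'
#' @param height cm (> 0). @param weight kg (> 0).
#' @param formula `"mosteller"` (`sqrt(height*weight/3600)`) or
#'   `"dubois"` (`0.007184 * height^0.725 * weight^0.425`).
#' @return BSA in m^2.
#' @export
bsa <- function(height, weight, formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  if (any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive")
  }
  switch(formula,
         mosteller = sqrt(height * weight / 3600),
         dubois = 0.007184 * height^0.725 * weight^0.425)
}

#' Indexed LVM (g/m^2)
#'
#' @param lvm Grams (>= 0). @inheritParams bsa
#' @return `lvm / bsa(height, weight)`.
#' @examples
#' indexed_lvm(144, 180, 80)  # BSA = 2 m^2 -> 72 g/m^2
#' @export
indexed_lvm <- function(lvm, height, weight,
                        formula = c("mosteller", "dubois")) {
  lvm / bsa(height, weight, formula)
}

#' Classify left ventricular hypertrophy
#'
#' LVH is an indexed LVM strictly greater than 72 g/m^2 for men or
#' 55 g/m^2 for women (the boundary value itself is not LVH).
#'
#' @param indexed Indexed LVM, g/m^2 (vectorized).
#' @param sex `"male"` or `"female"` (vectorized, recycled).
#' @param thresholds Named vector of sex-specific cutoffs.
#' @return Logical vector.
#' @export
classify_lvh <- function(indexed, sex,
                         thresholds = c(male = 72, female = 55)) {
  if (!all(sex %in% names(thresholds))) {
    stop("unknown sex value(s): ",
         paste(setdiff(unique(sex), names(thresholds)), collapse = ", "))
  }
  indexed > unname(thresholds[sex])
}

#' Rank-based c-statistic (AUROC)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted 0.5 -- computed from ranks, equivalent to
#' counting concordant pairs.
#'
#' @param score Continuous scores.
#' @param label Logical (or 0/1) true labels.
#' @return AUROC in \[0, 1\]; `NA` (with a `reason` attribute) when only
#'   one class is present.
#' @export
c_statistic <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) {
    return(structure(NA_real_,
                     reason = "c-statistic undefined: single-class truth"))
  }
  r <- rank(score)                        # average ranks on ties -> 0.5
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' LVH classification metrics from predicted LVM
#'
#' Derives predicted and true LVH labels by indexing the predicted and
#' ground-truth LVM to body surface area and applying the sex-specific
#' thresholds, then computes the hard-label metrics and the c-statistic
#' (continuous predicted indexed LVM as score).
#'
#' @param pred_lvm Predicted LVM, grams.
#' @param rows Cohort rows with `lvm_truth`, `height`, `weight`, `sex`.
#' @param bsa_formula BSA formula for indexation.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `f1`, `c_statistic`, `n`, `n_positive`.
#' @export
lvh_metrics <- function(pred_lvm, rows, bsa_formula = "mosteller") {
  idx_true <- indexed_lvm(rows$lvm_truth, rows$height, rows$weight,
                          bsa_formula)
  idx_pred <- indexed_lvm(pred_lvm, rows$height, rows$weight, bsa_formula)
  y <- classify_lvh(idx_true, rows$sex)
  yhat <- classify_lvh(idx_pred, rows$sex)
  tp <- sum(yhat & y); fn <- sum(!yhat & y)
  tn <- sum(!yhat & !y); fp <- sum(yhat & !y)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn); ppv <- safe(tp, tp + fp)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = sens,
       specificity = safe(tn, tn + fp),
       ppv = ppv,
       f1 = if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
            else 2 * sens * ppv / (sens + ppv),
       c_statistic = c_statistic(idx_pred, y),
       n = length(y), n_positive = sum(y))
}

#' Recalibrate echocardiography-derived LVM to CT scale
#'
#' Linear recalibration hook for cohorts whose ground truth comes from
#' echocardiography (which overestimates LVM relative to CT/MR). The
#' coefficients are supplied by configuration.
#'
#' @param echo_lvm Echo-derived LVM, grams (vectorized).
#' @param coefficients Numeric `(slope, intercept)`; slope must be > 0.
#' @return `slope * echo_lvm + intercept`, grams.
#' @examples
#' recalibrate_echo_lvm(200, c(0.8, 5))  # 165
#' @export
recalibrate_echo_lvm <- function(echo_lvm, coefficients) {
  slope <- coefficients[[1]]; intercept <- coefficients[[2]]
  if (slope <= 0) stop("recalibration slope must be positive")
  slope * echo_lvm + intercept
}
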