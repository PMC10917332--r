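#' Two-class confusion matrix with fixed orientation
#'
#' Tallies a binary classification with class 2 (the diver class) as
#' positive. Orientation is fixed and documented: rows are the true class,
#' columns the predicted class. Some circulating discriminant code reports
#' the transpose of this layout; [transposed_legacy()] reproduces that view
#' for comparison.
#'
#' @param truth,predicted Equal-length vectors of labels in `{1, 2}`.
#' @return Object of class `"confusion_matrix"` with fields `tp`, `fn`,
#'   `fp`, `tn` and a 2x2 `table` (rows = truth).
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.integer(as.character(truth))
  predicted <- as.integer(as.character(predicted))
  if (length(truth) != length(predicted)) abort("label vectors differ in length")
  if (!all(c(truth, predicted) %in% c(1L, 2L))) {
    abort("labels must be in {1, 2}")
  }
  tp <- sum(truth == 2L & predicted == 2L)
  fn <- sum(truth == 2L & predicted == 1L)
  fp <- sum(truth == 1L & predicted == 2L)
  tn <- sum(truth == 1L & predicted == 1L)
  tab <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                dimnames = list(truth = c("1", "2"), predicted = c("1", "2")))
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, table = tab),
            class = "confusion_matrix")
}

#' Legacy (transposed) view of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return The transposed 2x2 table (rows = predicted class).
#' @export
transposed_legacy <- function(cm) {
  t(cm$table)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = predicted; positive = class 2)\n")
  print(x$table)
  invisible(x)
}

#' Classification performance metrics
#'
#' Computes accuracy `A`, balanced accuracy `B` (mean of per-class recalls),
#' the Matthews correlation coefficient `MCC`, true/false positive rates, and
#' the equivalent random-classification fraction `p_rand = 2 (1 - A)` -- the
#' probability with which a half-random/half-correct classifier would match
#' the observed accuracy. `p_rand` is clipped to `[0, 1]`: below-chance
#' accuracy would push the raw heuristic past 1, where it is no longer
#' meaningful. `MCC` is 0 for any constant classifier.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row tibble: `accuracy`, `balanced_accuracy`, `mcc`, `p_rand`,
#'   `tpr`, `fpr`.
#' @export
classification_metrics <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) abort("empty confusion matrix")
  acc <- (cm$tp + cm$tn) / n
  rec2 <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  rec1 <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  bal <- mean(c(rec1, rec2), na.rm = TRUE)
  denom <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
  mcc <- if (denom == 0) 0 else {
    (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(denom)
  }
  tibble::tibble(
    accuracy = acc,
    balanced_accuracy = bal,
    mcc = mcc,
    p_rand = p_rand(acc),
    tpr = rec2,
    fpr = if (cm$tn + cm$fp > 0) cm$fp / (cm$tn + cm$fp) else NA_real_
  )
}

#' Equivalent random-classification fraction
#'
#' `p_rand = 2 (1 - A)`, clipped to `[0, 1]`: the fraction of cases that a
#' classifier which is random with probability `p_rand` and always correct
#' otherwise would need to randomize to achieve training accuracy `A`.
#' `p_rand(0.85) = 0.3`; the conventional 5% randomness threshold corresponds
#' to `A >= 0.975`.
#'
#' @param accuracy Training-set accuracy in `[0, 1]`.
#' @return Value in `[0, 1]`.
#' @export
p_rand <- function(accuracy) {
  pmin(1, pmax(0, 2 * (1 - accuracy)))
}

#' Metrics across a grid of posterior thresholds
#'
#' Recomputes the confusion matrix and metric set while sweeping the
#' classification threshold on the class-2 posterior, ROC style. A record is
#' called class 2 when its posterior is greater than or equal to the
#' threshold, so the true-positive rate is non-increasing in the threshold.
#'
#' @param truth True labels in `{1, 2}`.
#' @param p2 Posterior probabilities of class 2, in `[0, 1]`.
#' @param thresholds Numeric grid of thresholds.
#' @return Tibble with one metric row per threshold.
#' @export
threshold_sweep <- function(truth, p2, thresholds = seq(0, 1, by = 0.05)) {
  if (length(thresholds) == 0) abort("threshold grid is empty")
  if (any(p2 < 0 | p2 > 1)) abort("posteriors must lie in [0, 1]")
  purrr::map_dfr(thresholds, function(th) {
    pred <- ifelse(p2 >= th, 2L, 1L)
    dplyr::mutate(classification_metrics(confusion_matrix(truth, pred)),
                  threshold = th, .before = 1)
  })
}
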