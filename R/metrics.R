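#' Binary classification metrics from confusion counts
#'
#' Computes the six conventional metrics from TP/TN/FP/FN tallies:
#' accuracy, precision, sensitivity (recall), specificity, F1, and the
#' Matthews correlation coefficient reported on a x100 scale. The default
#' MCC uses the standard numerator `TP*TN - FP*FN`; `mcc_variant =
#' "tp_fn"` selects the `TP*TN - TP*FN` numerator sometimes seen in the
#' applied literature. Any metric whose denominator is zero is reported as 0
#' and flagged as degenerate rather than NaN, the convention used when, for
#' example, a classifier never predicts the positive class.
#'
#' @param tp,tn,fp,fn Non-negative integer tallies.
#' @param mcc_variant `"standard"` (default) or `"tp_fn"`.
#' @return A one-row tibble: `acc`, `prc`, `sns`, `spc`, `f1` in [0, 1],
#'   `mcc` in [-100, 100], and `degenerate` (logical: any zero-division
#'   fallback was used).
#' @examples
#' confusion_metrics(tp = 90, tn = 85, fp = 15, fn = 10)
#' @export
confusion_metrics <- function(tp, tn, fp, fn,
                              mcc_variant = c("standard", "tp_fn")) {
  mcc_variant <- match.arg(mcc_variant)
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    abort("`tp`, `tn`, `fp`, `fn` must be non-negative integers.")
  }
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  prc <- safe_div(tp, tp + fp)
  sns <- safe_div(tp, tp + fn)
  spc <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * prc * sns, prc + sns)
  mcc_num <- if (mcc_variant == "standard") tp * tn - fp * fn else tp * tn - tp * fn
  mcc <- 100 * safe_div(mcc_num,
                        sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  tibble(acc = acc, prc = prc, sns = sns, spc = spc, f1 = f1, mcc = mcc,
         degenerate = degenerate)
}

#' Tally confusion counts from label vectors
#'
#' @param truth,pred Vectors of equal length; `positive` names the positive
#'   class.
#' @param positive The positive-class label, default `"case"`.
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred, positive = "case") {
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length.")
  }
  t_pos <- truth == positive
  p_pos <- pred == positive
  tibble(
    tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
    fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos)
  )
}
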