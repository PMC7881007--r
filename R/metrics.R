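#' Confusion counts with the abnormal class as positive
#'
#' @param predicted,truth equal-length 0/1 vectors; 1 is the abnormal
#'   (positive) class.
#' @return object of class `confusion_counts`: named integer vector with
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
tally <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("length mismatch")
  if (length(predicted) < 1) abort("empty inputs")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    abort("labels must be 0 or 1")
  structure(c(
    TP = sum(predicted == 1 & truth == 1),
    TN = sum(predicted == 0 & truth == 0),
    FP = sum(predicted == 1 & truth == 0),
    FN = sum(predicted == 0 & truth == 1)
  ), class = "confusion_counts")
}

#' The five evaluation indices from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1
#' `2*Pre*Sen/(Pre+Sen)`. A metric whose denominator is zero is reported as
#' `NA` with a warning, never silently as 0.
#'
#' @param counts a [tally()] result, or a named vector with TP/TN/FP/FN.
#' @return one-row tibble with columns `acc`, `sen`, `spe`, `pre`, `f1`
#'   (fractions in `[0, 1]`).
#' @export
report <- function(counts) {
  cts <- as.numeric(counts[c("TP", "TN", "FP", "FN")])
  if (any(is.na(cts)) || any(cts < 0)) abort("counts must be non-negative TP/TN/FP/FN")
  TP <- cts[1]; TN <- cts[2]; FP <- cts[3]; FN <- cts[4]
  safe <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  acc <- safe(TP + TN, TP + TN + FP + FN, "accuracy")
  sen <- safe(TP, TP + FN, "sensitivity")
  spe <- safe(TN, TN + FP, "specificity")
  pre <- safe(TP, TP + FP, "precision")
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) {
    warn("F1 undefined: precision + sensitivity is zero or undefined")
    NA_real_
  } else 2 * pre * sen / (pre + sen)
  tibble::tibble(acc = acc, sen = sen, spe = spe, pre = pre, f1 = f1)
}

#' Evaluate predictions directly
#'
#' @param predicted,truth 0/1 vectors.
#' @return one-row tibble as from [report()], with the counts attached as
#'   attribute `"counts"`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  cts <- tally(predicted, truth)
  out <- report(cts)
  attr(out, "counts") <- cts
  out
}

#' Serialise an evaluation to JSON
#'
#' Writes the confusion counts and the five indices as a JSON object.
#'
#' @param metrics result of [evaluate_predictions()].
#' @param path output file.
#' @export
write_metrics_json <- function(metrics, path) {
  cts <- attr(metrics, "counts")
  obj <- c(as.list(cts), as.list(metrics))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
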