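# Confusion matrices and the imbalance-aware performance statistics, with
# the minority class (substrate) as the positive class.

#' Confusion matrix with substrate as the positive class
#'
#' @param y_true,y_pred vectors (factor or character) with values
#'   `"substrate"` / `"non-substrate"`, equal length.
#' @return Object of class `qsar_confusion` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths")
  if (!length(y_true)) stop("empty label vectors")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  ok <- c("substrate", "non-substrate")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok))
    stop("labels must be 'substrate' or 'non-substrate'")
  new_confusion(tp = sum(y_true == "substrate" & y_pred == "substrate"),
                fp = sum(y_true == "non-substrate" & y_pred == "substrate"),
                tn = sum(y_true == "non-substrate" & y_pred == "non-substrate"),
                fn = sum(y_true == "substrate" & y_pred == "non-substrate"))
}

#' @rdname confusion
#' @param tp,fp,tn,fn cell counts.
#' @export
new_confusion <- function(tp, fp, tn, fn) {
  cm <- list(tp = as.numeric(tp), fp = as.numeric(fp),
             tn = as.numeric(tn), fn = as.numeric(fn))
  if (any(unlist(cm) < 0)) stop("confusion-matrix cells must be non-negative")
  structure(cm, class = "qsar_confusion")
}

#' @export
print.qsar_confusion <- function(x, ...) {
  cat(sprintf("          pred:S  pred:NS\n true:S  %6d  %7d\n true:NS %6d  %7d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' @export
`+.qsar_confusion` <- function(e1, e2) {
  new_confusion(e1$tp + e2$tp, e1$fp + e2$fp, e1$tn + e2$tn, e1$fn + e2$fn)
}

.safe_div <- function(num, den) {
  if (den == 0) list(v = 0, undef = TRUE) else list(v = num / den, undef = FALSE)
}

#' Performance statistics from a confusion matrix
#'
#' Computes specificity, sensitivity (recall), precision, G-mean, Matthews
#' correlation coefficient and standard accuracy exactly as conventionally
#' defined, plus balanced accuracy `(sensitivity + specificity) / 2` and the
#' F-measure.  Any statistic with a zero denominator is reported as 0 and
#' listed in the `undefined` field.
#'
#' @param cm a `qsar_confusion`.
#' @return Object of class `qsar_metrics`; rate statistics are fractions in
#'   `[0, 1]` (multiply by 100 for the percent scale).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "qsar_confusion"))
  undef <- character(0)
  spec <- .safe_div(cm$tn, cm$tn + cm$fp)
  sens <- .safe_div(cm$tp, cm$tp + cm$fn)
  prec <- .safe_div(cm$tp, cm$tp + cm$fp)
  acc <- .safe_div(cm$tn + cm$tp, cm$tp + cm$fp + cm$tn + cm$fn)
  if (spec$undef) undef <- c(undef, "specificity")
  if (sens$undef) undef <- c(undef, "sensitivity")
  if (prec$undef) undef <- c(undef, "precision")
  if (acc$undef) undef <- c(undef, "accuracy_standard")
  g <- sqrt(sens$v * spec$v)
  mcc_den <- sqrt((cm$tp + cm$fp)) * sqrt((cm$tp + cm$fn)) *
             sqrt((cm$tn + cm$fp)) * sqrt((cm$tn + cm$fn))
  if (mcc_den == 0) { mcc <- 0; undef <- c(undef, "mcc") }
  else mcc <- (cm$tp * cm$tn - cm$fp * cm$fn) / mcc_den
  f_den <- prec$v + sens$v
  fmeas <- if (f_den == 0) 0 else 2 * prec$v * sens$v / f_den
  structure(list(
    specificity = spec$v, sensitivity = sens$v, precision = prec$v,
    g_mean = g, mcc = mcc, accuracy_standard = acc$v,
    accuracy_balanced = (sens$v + spec$v) / 2,
    f_measure = fmeas,
    confusion = cm, undefined = undef), class = "qsar_metrics")
}

#' @export
print.qsar_metrics <- function(x, ...) {
  cat(sprintf(paste0("specificity %.2f%%  sensitivity %.2f%%  precision %.2f\n",
                     "G-mean %.2f  MCC %.2f  accuracy %.2f%%  balanced accuracy %.2f%%\n"),
              100 * x$specificity, 100 * x$sensitivity, x$precision,
              x$g_mean, x$mcc, 100 * x$accuracy_standard,
              100 * x$accuracy_balanced))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
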