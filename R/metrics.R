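# Binary classification metrics from confusion-matrix counts.
# Positive class = tumor (glioma); negative class = non-tumor.

#' Construct a binary confusion matrix
#'
#' @param TP,FP,TN,FN Non-negative integer counts; the positive class is the
#'   tumor (glioma) class.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("confusion-matrix counts must be non-negative finite numbers",
         call. = FALSE)
  }
  structure(as.list(round(counts)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("          predicted+  predicted-\n")
  cat(sprintf("actual+   %9d  %9d\n", x$TP, x$FN))
  cat(sprintf("actual-   %9d  %9d\n", x$FP, x$TN))
  invisible(x)
}

#' Reconstruct a confusion matrix from test composition and rates
#'
#' Given the number of positive and negative test images and the reported
#' sensitivity and specificity, recovers the integer confusion matrix
#' (`TP = round(sens * n_pos)`, `TN = round(spec * n_neg)`), which is exact
#' whenever the rates were themselves computed from integer counts.
#'
#' @param n_pos,n_neg Positive / negative test-set sizes.
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @return A [confusion_matrix()].
#' @export
confusion_from_rates <- function(n_pos, n_neg, sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  TP <- round(sensitivity * n_pos)
  TN <- round(specificity * n_neg)
  confusion_matrix(TP = TP, FP = n_neg - TN, TN = TN, FN = n_pos - TP)
}

# Safe ratio: an explicit undefined marker (NA) on zero denominators,
# never a silent 0.
safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Round half away from zero
#'
#' Plain decimal rounding with ties going up (0.9865 -> 0.987 at 3 digits),
#' matching how results tables are conventionally printed; R's `round()`
#' rounds ties to even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Compute binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, per-class precision
#' (`TP/(TP+FP)` for the tumor class, `TN/(TN+FN)` for the non-tumor class),
#' per-class F1 (harmonic mean of precision and recall), Matthews correlation
#' coefficient and accuracy. Any metric with a zero denominator is reported as
#' `NA` (explicitly undefined), never silently 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report`: named list of raw (unrounded)
#'   metric values plus the input counts. The print method shows 3 decimals
#'   (half-up).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  sens <- safe_div(TP, TP + FN)
  spec <- safe_div(TN, TN + FP)
  prec_pos <- safe_div(TP, TP + FP)
  prec_neg <- safe_div(TN, TN + FN)
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
  }
  f1_pos <- f1(prec_pos, sens)
  f1_neg <- f1(prec_neg, spec)
  denom <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (denom == 0) NA_real_ else (TP * TN - FP * FN) / denom
  structure(list(sensitivity = sens, specificity = spec,
                 precision_pos = prec_pos, precision_neg = prec_neg,
                 f1_pos = f1_pos, f1_neg = f1_neg,
                 mcc = mcc, accuracy = (TP + TN) / total,
                 counts = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  fields <- c("sensitivity", "specificity", "precision_pos", "precision_neg",
              "f1_pos", "f1_neg", "mcc", "accuracy")
  vals <- vapply(fields, function(f) {
    v <- x[[f]]
    if (is.na(v)) NA_real_ else round_half_up(v, digits)
  }, numeric(1))
  for (f in fields) {
    cat(sprintf("%-14s %s\n", f,
                ifelse(is.na(vals[[f]]), "undefined",
                       formatC(vals[[f]], format = "f", digits = digits))))
  }
  invisible(x)
}

#' Serialise a metrics report to JSON
#'
#' @param report A [compute_metrics()] result.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param digits Decimal digits for rounding (half-up); `NA` for full
#'   precision.
#' @return JSON string (invisibly if written to file).
#' @export
metrics_to_json <- function(report, path = NULL, digits = 3L) {
  stopifnot(inherits(report, "metrics_report"))
  fields <- c("sensitivity", "specificity", "precision_pos", "precision_neg",
              "f1_pos", "f1_neg", "mcc", "accuracy")
  out <- lapply(fields, function(f) {
    v <- report[[f]]
    if (!is.na(digits) && !is.na(v)) v <- round_half_up(v, digits)
    v
  })
  names(out) <- fields
  out$counts <- unclass(report$counts)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
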