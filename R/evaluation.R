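#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (anyNA(v) || any(v < 0)) stopf("exudatekit_bad_counts", "counts must be >= 0")
  if (sum(v) == 0) stopf("exudatekit_bad_counts", "at least one count must be positive")
  structure(as.list(v), class = "confusion_counts")
}

#' Validation metrics from confusion counts
#'
#' The standard validation parameters: accuracy
#' `(TP + TN) / (TP + TN + FP + FN)`, error rate `1 - accuracy`, positive
#' predictive value `TP / (TP + FP)`, sensitivity `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)`. A metric whose denominator is zero is
#' reported as `NA` (undefined), never coerced to 0.
#'
#' @param c a [confusion_counts()] object.
#' @return named list: `accuracy`, `error_rate`, `ppv`, `sensitivity`,
#'   `specificity`.
#' @examples
#' confusion_metrics(confusion_counts(46, 0, 0, 6))$sensitivity  # 46/52
#' @export
confusion_metrics <- function(c) {
  if (!inherits(c, "confusion_counts")) c <- do.call(confusion_counts, as.list(c))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  tot <- c$TP + c$TN + c$FP + c$FN
  acc <- rat(c$TP + c$TN, tot)
  list(accuracy = acc,
       error_rate = if (is.na(acc)) NA_real_ else 1 - acc,
       ppv = rat(c$TP, c$TP + c$FP),
       sensitivity = rat(c$TP, c$TP + c$FN),
       specificity = rat(c$TN, c$TN + c$FP))
}

#' Binned survival-fraction ROC table
#'
#' Builds the binned ROC representation used for classifier evaluation: the
#' per-bin true/false observation counts are accumulated down the bins and
#' both curve coordinates are survival fractions of their class totals,
#' `x_k = 1 - cumT_k / T` and `y_k = 1 - cumF_k / F`, with the point (1, 1)
#' prepended (row 0, zero cumulative counts). Note these columns are
#' conventionally labelled "FPR" and "TPR" in this table layout even though
#' they are survival fractions of the true and false counts respectively.
#' The AUC is the left-endpoint rectangle rule
#' `sum_k (x_k - x_{k+1}) * y_k`, each segment's area attributed to its
#' upper row; a trapezoidal alternative is available via `method`.
#'
#' @param bins a data.frame (or 2-column matrix) with per-bin `true` and
#'   `false` counts, ordered by bin.
#' @param method `"left_rectangle"` (default) or `"trapezoid"`.
#' @return a `binned_roc_table`: data.frame with columns `bin`,
#'   `observed_true`, `observed_false`, `cumulative_true`,
#'   `cumulative_false`, `x`, `y`, `auc_contrib`, plus attribute
#'   `auc_total`.
#' @examples
#' tab <- binned_roc(data.frame(true = c(1, 0), false = c(0, 1)))
#' attr(tab, "auc_total")  # 1: perfect separation
#' @export
binned_roc <- function(bins, method = c("left_rectangle", "trapezoid")) {
  method <- match.arg(method)
  bins <- as.data.frame(bins)
  if (ncol(bins) < 2L || nrow(bins) < 1L)
    stopf("exudatekit_bad_bins", "bins needs >= 1 row of (true, false) counts")
  tr <- as.numeric(bins[[1]]); fa <- as.numeric(bins[[2]])
  if (anyNA(tr) || anyNA(fa) || any(tr < 0) || any(fa < 0))
    stopf("exudatekit_bad_bins", "counts must be non-negative")
  T_tot <- sum(tr); F_tot <- sum(fa)
  if (T_tot == 0 || F_tot == 0)
    stopf("exudatekit_degenerate_bins",
          "need both true and false observations (got T=%g, F=%g)", T_tot, F_tot)
  cumT <- c(0, cumsum(tr)); cumF <- c(0, cumsum(fa))
  x <- 1 - cumT / T_tot
  y <- 1 - cumF / F_tot
  k <- length(x)
  contrib <- switch(method,
    left_rectangle = c((x[-k] - x[-1]) * y[-k], 0),
    trapezoid = c((x[-k] - x[-1]) * (y[-k] + y[-1]) / 2, 0))
  out <- data.frame(bin = 0:(k - 1L),
                    observed_true = c(NA, tr), observed_false = c(NA, fa),
                    cumulative_true = cumT, cumulative_false = cumF,
                    x = x, y = y, auc_contrib = contrib)
  structure(out, auc_total = sum(contrib), method = method,
            class = c("binned_roc_table", "data.frame"))
}

#' @export
print.binned_roc_table <- function(x, digits = 6, ...) {
  df <- as.data.frame(x)
  num <- c("x", "y", "auc_contrib")
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits, format = "f"))
  print(df, row.names = FALSE)
  cat(sprintf("AUC (%s rule): %s\n", attr(x, "method"),
              formatC(attr(x, "auc_total"), digits = digits, format = "f")))
  invisible(x)
}

#' Total AUC of a binned ROC table
#' @param table a `binned_roc_table`.
#' @return the scalar AUC in `[0, 1]`.
#' @export
auc_total <- function(table) attr(table, "auc_total")

#' Write a binned ROC table to CSV
#'
#' Mirrors the printed table layout: one row per bin (row 0 is the (1,1)
#' anchor) with observed and cumulative counts, both survival-fraction
#' coordinates to six decimals, per-segment AUC contributions, and a final
#' total row whose AUC cell is the rectangle-rule total.
#'
#' @param table a `binned_roc_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
roc_report <- function(table, path) {
  df <- as.data.frame(table)
  fmt <- function(v) formatC(v, digits = 6, format = "f")
  out <- data.frame(bin = c(df$bin, NA),
                    observed_true = c(df$observed_true, sum(df$observed_true, na.rm = TRUE)),
                    observed_false = c(df$observed_false, sum(df$observed_false, na.rm = TRUE)),
                    cumulative_true = c(df$cumulative_true, NA),
                    cumulative_false = c(df$cumulative_false, NA),
                    FPR = c(fmt(df$x), ""), TPR = c(fmt(df$y), ""),
                    AUC = c(fmt(df$auc_contrib), fmt(attr(table, "auc_total"))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-bin count table from CSV
#'
#' Schema: columns `bin`, `observed_true`, `observed_false` (extra columns
#' ignored). The packaged reference tables are available via
#' `system.file("extdata", "table8_bins.csv", package = "exudatekit")` and
#' `"table9_bins.csv"`.
#'
#' @param path CSV path.
#' @return data.frame with columns `true` and `false`, ordered by bin.
#' @export
read_bins_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("observed_true", "observed_false")
  if (!all(need %in% names(df)))
    stopf("exudatekit_bad_bins", "bins CSV needs columns: %s", paste(need, collapse = ", "))
  if ("bin" %in% names(df)) df <- df[order(df$bin), ]
  data.frame(true = df$observed_true, false = df$observed_false)
}
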