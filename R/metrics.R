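#' Classification metrics from confusion counts
#'
#' Computes accuracy, positive predictive value, sensitivity and specificity
#' (as percentages) and the Dice similarity index (a ratio in \[0, 1\]) from
#' binary confusion counts:
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `PPV = TP / (TP + FP)`,
#' `SEN = TP / (TP + FN)`, `SPE = TN / (TN + FP)`,
#' `Dice = 2 TP / (2 TP + FP + FN)` (the harmonic mean of PPV and SEN).
#' Values are returned unrounded; presentation rounding to the 2-decimal
#' table convention is [round_half_up()]. A metric whose denominator is zero
#' is returned as `NA` rather than silently 0.
#'
#' @param tp,tn,fp,fn Non-negative integer vectors (recycled to a common
#'   length), or `tp` may be a data frame holding columns `tp`, `tn`, `fp`,
#'   `fn`.
#' @return Tibble with columns `tp`, `tn`, `fp`, `fn`, `acc`, `ppv`, `sen`,
#'   `spe` (percent), `dice`.
#' @examples
#' metrics_from_counts(37, 21, 1, 6)  # acc 89.23, ppv 97.37, ...
#' @export
metrics_from_counts <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    df <- tp
    if (!all(c("tp", "tn", "fp", "fn") %in% names(df))) {
      abort("Data frame input needs columns tp, tn, fp, fn.")
    }
    tp <- df$tp; tn <- df$tn; fp <- df$fp; fn <- df$fn
  }
  n <- max(length(tp), length(tn), length(fp), length(fn))
  tp <- rep_len(tp, n); tn <- rep_len(tn, n)
  fp <- rep_len(fp, n); fn <- rep_len(fn, n)
  if (any(c(tp, tn, fp, fn) < 0)) abort("Confusion counts must be non-negative.")
  tot <- tp + tn + fp + fn
  if (any(tot == 0)) abort("All four confusion counts are zero.")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         acc = 100 * safe_div(tp + tn, tot),
         ppv = 100 * safe_div(tp, tp + fp),
         sen = 100 * safe_div(tp, tp + fn),
         spe = 100 * safe_div(tn, tn + fp),
         dice = safe_div(2 * tp, 2 * tp + fp + fn))
}

#' Average per-fold metrics into a summary row
#'
#' Sums the confusion counts and takes the arithmetic mean of each per-fold
#' metric. Means are taken over the unrounded per-fold values; rounding the
#' per-fold metrics first and then averaging does not reproduce standard
#' published averages.
#'
#' @param folds Tibble as produced by [metrics_from_counts()] (one row per
#'   fold).
#' @return One-row tibble with summed counts and averaged metrics.
#' @export
aggregate_folds <- function(folds) {
  if (nrow(folds) < 1) abort("Need at least one fold.")
  tibble(tp = sum(folds$tp), tn = sum(folds$tn),
         fp = sum(folds$fp), fn = sum(folds$fn),
         acc = mean(folds$acc), ppv = mean(folds$ppv),
         sen = mean(folds$sen), spe = mean(folds$spe),
         dice = mean(folds$dice))
}

#' Reference per-fold confusion tables
#'
#' Returns the per-fold TP/TN/FP/FN counts and the tabulated metric values
#' for the four SVM kernels of the reference 10-fold experiment, as shipped
#' in `inst/extdata/svm_fold_tables.csv`. These serve as golden fixtures
#' for the metric arithmetic.
#'
#' @return Tibble with columns `kernel`, `fold`, `tp`, `tn`, `fp`, `fn`,
#'   `acc`, `ppv`, `sen`, `spe`, `dice` (the tabulated, rounded values).
#' @export
stroke_fold_tables <- function() {
  path <- system.file("extdata", "svm_fold_tables.csv", package = "stroketex")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Reference kernel-comparison summary
#'
#' The tabulated fold-averaged metrics per SVM kernel (the comparison-table
#' layout), from `inst/extdata/svm_summary_table.csv`.
#'
#' @return Tibble with columns `kernel`, `sen`, `spe`, `ppv`, `acc`, `dice`.
#' @export
stroke_summary_table <- function() {
  path <- system.file("extdata", "svm_summary_table.csv", package = "stroketex")
  readr::read_csv(path, show_col_types = FALSE)
}
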