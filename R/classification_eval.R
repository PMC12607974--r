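# Classification evaluation arithmetic: confusion-matrix metrics, macro and
# support-weighted aggregation, and two-factor ANOVA without replication.

#' Construct a confusion matrix object
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param counts Square matrix of nonnegative integer counts.
#' @param classes Class labels (defaults to the matrix dimnames or C1..Cn).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(counts, classes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0 || nrow(counts) != ncol(counts))
    stop("confusion matrix must be square and nonempty")
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts)))
    stop("confusion matrix entries must be nonnegative integers")
  if (is.null(classes)) classes <- rownames(counts)
  if (is.null(classes)) classes <- paste0("C", seq_len(nrow(counts)))
  dimnames(counts) <- list(true = classes, predicted = classes)
  structure(list(counts = counts, classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$counts)
  invisible(x)
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' precision_c = TP_c / column-sum_c (defined as 0 when the class is never
#' predicted), recall_c = TP_c / row-sum_c, F1 the harmonic mean of the two,
#' accuracy = trace / total.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metrics_table`: data frame with class, precision, recall, f1
#'   and support columns, with the overall `accuracy` as an attribute.
#' @export
metrics_from_confusion <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
  m <- cm$counts
  tp <- diag(m)
  colsum <- colSums(m)
  rowsum <- rowSums(m)
  if (sum(m) == 0) stop("confusion matrix has no observations")
  zero_pred <- colsum == 0
  if (any(zero_pred))
    log_event("metrics: %d class(es) never predicted; precision set to 0",
              sum(zero_pred))
  precision <- ifelse(zero_pred, 0, tp / colsum)
  recall <- ifelse(rowsum == 0, 0, tp / rowsum)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  out <- data.frame(class = cm$classes, precision = precision,
                    recall = recall, f1 = f1, support = as.integer(rowsum),
                    row.names = NULL)
  structure(out, accuracy = sum(tp) / sum(m),
            class = c("metrics_table", "data.frame"))
}

#' Overall accuracy implied by per-class recalls and supports
#'
#' Uses the exact identity accuracy = sum(n_c * recall_c) / N, which lets a
#' published per-class recall column be audited against its printed overall
#' accuracy without access to the underlying confusion matrix.
#'
#' @param recalls Per-class recall values.
#' @param supports Per-class test-set sizes (positive, same length).
#' @return Scalar accuracy in \[0, 1\].
#' @export
weighted_accuracy_from_recalls <- function(recalls, supports) {
  if (length(recalls) != length(supports))
    stop("recalls and supports must have the same length")
  if (any(supports <= 0)) stop("supports must be positive")
  sum(supports * recalls) / sum(supports)
}

#' Aggregate a metrics table into summary precision/recall/F1
#'
#' @param table A `metrics_table` from [metrics_from_confusion()].
#' @param mode `"macro"` (unweighted class mean) or `"weighted"`
#'   (support-weighted mean).
#' @return Named numeric triple (precision, recall, f1).
#' @export
aggregate_metrics <- function(table, mode = c("macro", "weighted")) {
  mode <- match.arg(mode)
  w <- if (mode == "macro") rep(1, nrow(table)) else table$support
  w <- w / sum(w)
  c(precision = sum(w * table$precision), recall = sum(w * table$recall),
    f1 = sum(w * table$f1))
}

#' Round half away from zero at a displayed precision
#'
#' The convention used when comparing computed metrics against printed
#' percentage cells (so 0.919 prints as 92%, 0.865 as 86.5%).
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded values.
#' @export
round_display <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Two-factor ANOVA without replication
#'
#' Classical additive decomposition of a complete r x c table:
#' SS_total = SS_rows + SS_cols + SS_residual with degrees of freedom
#' (r-1), (c-1) and (r-1)(c-1); F statistics test each factor against the
#' residual mean square, with upper-tail p-values from the F distribution.
#' Per-column means and standard deviations are reported alongside.
#'
#' @param values Complete r x c numeric matrix (r, c >= 2, no missing
#'   cells — the no-replication design has no way to estimate error
#'   otherwise).
#' @param row_labels,col_labels Optional level names.
#' @return A `savehsi_anova` list: the ANOVA table (data frame with source,
#'   ss, df, ms, f, p) and `column_summary` (mean, sd per column level).
#' @export
anova_two_factor_no_rep <- function(values, row_labels = NULL,
                                    col_labels = NULL) {
  values <- as.matrix(values)
  r <- nrow(values); cc <- ncol(values)
  if (r < 2 || cc < 2) stop("ANOVA table needs at least 2 rows and 2 columns")
  if (any(!is.finite(values)))
    stop("ANOVA without replication requires a complete table (no missing cells)")
  if (is.null(row_labels)) row_labels <- rownames(values)
  if (is.null(col_labels)) col_labels <- colnames(values)
  if (is.null(row_labels)) row_labels <- paste0("R", seq_len(r))
  if (is.null(col_labels)) col_labels <- paste0("C", seq_len(cc))

  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_rows <- cc * sum((rowMeans(values) - grand)^2)
  ss_cols <- r * sum((colMeans(values) - grand)^2)
  ss_res <- ss_total - ss_rows - ss_cols
  df_rows <- r - 1; df_cols <- cc - 1; df_res <- df_rows * df_cols
  ms_rows <- ss_rows / df_rows
  ms_cols <- ss_cols / df_cols
  ms_res <- ss_res / df_res
  # a factor with zero between-level variation has no effect by definition
  # (F = 0, p = 1), even when the residual is also degenerate
  f_rows <- if (ss_rows == 0) 0 else ms_rows / ms_res
  f_cols <- if (ss_cols == 0) 0 else ms_cols / ms_res
  tab <- data.frame(
    source = c("rows", "columns", "residual", "total"),
    ss = c(ss_rows, ss_cols, ss_res, ss_total),
    df = c(df_rows, df_cols, df_res, r * cc - 1),
    ms = c(ms_rows, ms_cols, ms_res, NA),
    f = c(f_rows, f_cols, NA, NA),
    p = c(stats::pf(f_rows, df_rows, df_res, lower.tail = FALSE),
          stats::pf(f_cols, df_cols, df_res, lower.tail = FALSE), NA, NA))
  colsum <- data.frame(level = col_labels, mean = colMeans(values),
                       sd = apply(values, 2, stats::sd), row.names = NULL)
  structure(list(table = tab, column_summary = colsum,
                 row_labels = row_labels, col_labels = col_labels),
            class = "savehsi_anova")
}

#' @export
print.savehsi_anova <- function(x, ...) {
  cat("Two-factor ANOVA without replication\n")
  print(x$table, row.names = FALSE, digits = 5)
  cat("Column-level means:\n")
  print(x$column_summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Read a labelled confusion matrix from CSV
#'
#' First column holds the true-class labels; remaining column names the
#' predicted classes (must match, same order).
#'
#' @param path CSV file path.
#' @return A [confusion_matrix()].
#' @export
read_confusion <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  classes <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (!identical(colnames(counts), classes))
    stop("confusion CSV row and column class labels do not match")
  if (any(counts < 0)) stop("confusion CSV contains a negative cell")
  mode(counts) <- "numeric"
  confusion_matrix(counts, classes)
}

#' Write a confusion matrix as labelled CSV
#' @param cm A [confusion_matrix()].
#' @param path Output CSV path.
#' @export
write_confusion <- function(cm, path) {
  df <- data.frame(class = cm$classes, cm$counts, check.names = FALSE)
  colnames(df) <- c("class", cm$classes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a metrics table as CSV in the standard report layout
#'
#' Columns: Class, Precision, Recall, F1, with overall Accuracy repeated in
#' a final column (mirroring the usual published layout).
#'
#' @param table A `metrics_table`.
#' @param path Output CSV path.
#' @export
write_metrics <- function(table, path) {
  out <- data.frame(Class = table$class,
                    Precision = table$precision,
                    Recall = table$recall,
                    F1 = table$f1,
                    Accuracy = attr(table, "accuracy"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
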