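# Segmentation evaluation: pixel confusion counts, overlap metrics
# (IoU, Dice, precision), ROC/AUC, fold aggregation and the two-sample
# comparison used in the ablation tables.

#' Pixel confusion counts
#'
#' @param pred_mask,truth_mask binary arrays/matrices of identical shape
#'   with values in \{0, 1\}
#' @return a `confusion_counts` object with fields `TP`, `FP`, `FN`, `TN`
#' @export
confusion_counts <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask)) ||
      length(pred_mask) != length(truth_mask))
    stop("prediction and truth must have identical shapes")
  p <- as.numeric(pred_mask); t <- as.numeric(truth_mask)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("masks must be binary (values in {0, 1})")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%g FP=%g FN=%g TN=%g (total %g)\n",
              x$TP, x$FP, x$FN, x$TN, x$TP + x$FP + x$FN + x$TN))
  invisible(x)
}

# degenerate-denominator convention: 1 when prediction and truth are both
# empty, else 0
safe_ratio <- function(num, den, c) {
  if (den > 0) return(num / den)
  if (c$TP + c$FP + c$FN == 0) 1 else 0
}

#' Overlap metrics from confusion counts
#'
#' `iou` is TP/(TP+FP+FN), `dice` is 2TP/(2TP+FP+FN), `precision` is
#' TP/(TP+FP). When a denominator is zero the metric is 1 if prediction
#' and truth are both empty, else 0. The identity
#' `dice == 2*iou/(1+iou)` holds for every confusion table.
#'
#' @param c a [confusion_counts()] object
#' @return a value in \[0, 1\]
#' @export
iou <- function(c) safe_ratio(c$TP, c$TP + c$FP + c$FN, c)

#' @rdname iou
#' @export
dice <- function(c) safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN, c)

#' @rdname iou
#' @export
precision <- function(c) {
  if (c$TP + c$FP > 0) return(c$TP / (c$TP + c$FP))
  if (c$TP + c$FP + c$FN == 0) 1 else 0
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all score thresholds;
#' tied scores are handled by the midrank convention, so the result
#' equals the Mann-Whitney pairwise-comparison fraction. 0.5 corresponds
#' to an uninformative scorer, 1.0 to perfect separation.
#'
#' @param scores numeric vector of per-pixel probabilities in \[0, 1\]
#' @param truth binary vector/array of the same length
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, truth) {
  s <- as.numeric(scores); y <- as.numeric(truth)
  if (length(s) != length(y)) stop("scores and truth must have equal length")
  if (!all(y %in% c(0, 1))) stop("truth must be binary")
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    stop("AUC undefined: truth contains a single class")
  pts <- roc_points(s, y)
  # trapezoid over (FPR, TPR); points are ordered by descending threshold
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold (plus the (0,0) and
#' (1,1) anchors), ordered by descending threshold; suitable for export
#' and plotting.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`
#' @export
roc_points <- function(scores, truth) {
  s <- as.numeric(scores); y <- as.numeric(truth)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  ctp <- cumsum(y == 1); cfp <- cumsum(y == 0)
  last <- which(diff(s) != 0)           # last index of each tied block
  idx <- c(last, length(s))
  data.frame(threshold = c(Inf, s[idx]),
             fpr = c(0, cfp[idx] / nneg),
             tpr = c(0, ctp[idx] / npos))
}

#' Independent two-sample t test
#'
#' Classical pooled-variance two-sample t test with a two-sided p-value,
#' as used for pairwise comparison of per-fold metric values between
#' architectures.
#'
#' @param a,b numeric vectors with at least 2 values each
#' @return list with elements `t` (statistic), `p` (two-sided p-value),
#'   `df` (degrees of freedom)
#' @export
two_sample_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0)
    stop("samples are constant; t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Aggregate per-fold metric values
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator; 0 for
#' a single value), the "M +- SD" convention of cross-validated reports.
#'
#' @param values numeric vector of per-fold metric values (>= 1)
#' @param metric metric name carried into the report
#' @return a `metric_report` with fields `metric`, `values`, `mean`, `sd`
#' @export
aggregate_folds <- function(values, metric = "IoU") {
  if (length(values) == 0) stop("no values to aggregate")
  structure(list(metric = metric, values = as.numeric(values),
                 mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else 0),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s: %.4f ± %.4f (%d folds)\n",
              x$metric, x$mean, x$sd, length(x$values)))
  invisible(x)
}

#' @export
format.metric_report <- function(x, digits = 3, ...) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), x$mean, x$sd)
}

# ---- report writers --------------------------------------------------------

#' Write an ablation/metric table to CSV or JSON
#'
#' Rows are architecture (or block) names; columns hold per-metric
#' mean/SD pairs and optional p-values, mirroring the layout of
#' cross-validated ablation tables.
#'
#' @param table a data.frame (e.g. from [run_ablation()]'s `$table`)
#' @param path output path; format chosen by extension (`.csv` or `.json`)
#' @export
write_metric_table <- function(table, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(table, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else stop("unsupported table format: .", ext)
  invisible(path)
}

#' Write ROC curve points to CSV
#'
#' @param points data.frame from [roc_points()]
#' @param path output CSV path
#' @export
write_roc_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}
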