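#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with half credit for ties; equal to
#' the trapezoidal area under the empirical ROC curve and invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels in `{0, 1}`; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: only one class present", call. = FALSE)
  r <- rank(scores)  # midranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' A score at or above the threshold is called positive (class 1, PDAC);
#' the default threshold is 0.5. PPV/NPV are reported as `NA` when the
#' corresponding predicted class is empty.
#'
#' @param scores Numeric scores in `[0, 1]` (or binary calls).
#' @param labels Binary labels in `{0, 1}`.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `eus_binmetrics`: counts `tp`, `fp`, `tn`,
#'   `fn` and metrics `auroc` (NA if one class absent), `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, plus `threshold`,
#'   `n_positive`, `n_negative`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  n1 <- tp + fn; n0 <- tn + fp
  div <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 auroc = if (n1 > 0L && n0 > 0L) auroc(scores, labels)
                         else NA_real_,
                 accuracy = div(tp + tn, length(labels)),
                 sensitivity = div(tp, n1), specificity = div(tn, n0),
                 ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
                 threshold = threshold, n_positive = n1, n_negative = n0),
            class = "eus_binmetrics")
}

#' @export
print.eus_binmetrics <- function(x, ...) {
  cat(sprintf("Binary metrics (threshold %.2f): TP %d FP %d TN %d FN %d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  m <- c(auroc = x$auroc, accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, ppv = x$ppv, npv = x$npv)
  print(round(m, 3))
  invisible(x)
}

#' Mean metrics over the five test groups
#'
#' Unweighted arithmetic mean of each metric over exactly five per-fold
#' metric sets; folds where a metric is undefined (empty predicted class)
#' are excluded from that metric's mean and flagged.
#'
#' @param folds List of exactly five `eus_binmetrics`.
#' @return A list with `mean` (named numeric), `n_defined` (folds entering
#'   each mean) and `incomplete` (metrics averaged over fewer than five
#'   folds).
#' @export
aggregate_folds <- function(folds) {
  if (length(folds) != 5L)
    stop(sprintf("expected exactly 5 fold metric sets, got %d",
                 length(folds)), call. = FALSE)
  metrics <- c("auroc", "accuracy", "sensitivity", "specificity",
               "ppv", "npv")
  vals <- vapply(folds, function(f) unlist(f[metrics]), numeric(6))
  m <- rowMeans(vals, na.rm = TRUE)
  n_def <- rowSums(!is.na(vals))
  list(mean = m, n_defined = n_def,
       incomplete = metrics[n_def < 5L & n_def > 0L])
}

#' Exact two-sided Wilcoxon rank-sum comparison of fold metrics
#'
#' Compares the five per-fold values of one metric between two datasets
#' (for example ordered versus balanced divisions of the same factor) by
#' the exact Wilcoxon rank-sum test: the rank sum uses midranks for ties
#' and the p-value enumerates all `choose(n + m, n)` assignments of the
#' pooled values (252 for 5 + 5), counting those whose rank-sum deviation
#' from its permutation mean is at least the observed one.
#'
#' @param a,b Numeric vectors of equal length (the per-fold metric values
#'   of the two datasets).
#' @return Two-sided exact p-value.
#' @export
compare_fold_scores <- function(a, b) {
  if (length(a) != length(b))
    stop("both sides must have the same number of folds", call. = FALSE)
  n <- length(a); m <- length(b)
  if (n < 1L) stop("empty samples", call. = FALSE)
  if (choose(n + m, n) > 2e5)
    stop("too many splits for exact enumeration", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  mu <- n * mean(r)
  splits <- utils::combn(n + m, n)
  w_all <- colSums(matrix(r[splits], nrow = n))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Standard two-sided Fisher's exact test (sum of hypergeometric
#' probabilities not exceeding the observed table's); a thin wrapper kept
#' as the package's single point of choice for categorical cohort
#' comparisons. `method = "chisq"` instead applies Pearson's chi-squared
#' test without continuity correction.
#'
#' @param a1,n1 Successes and size of group 1.
#' @param a2,n2 Successes and size of group 2.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(a1, n1, a2, n2, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  tab <- matrix(c(a1, n1 - a1, a2, n2 - a2), 2L, byrow = TRUE)
  if (method == "fisher") stats::fisher.test(tab)$p.value
  else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Cohort characteristics table
#'
#' Summarizes patient metadata by class the way clinical baseline tables
#' do: continuous variables as median (range) per class with a two-sided
#' Wilcoxon rank-sum p-value; categorical variables as count (percent) per
#' class with a two-sided test of each category against the rest on the
#' 2 x 2 table (`method = "fisher"`, the default, uses Fisher's exact
#' test; `"chisq"` uses uncorrected Pearson chi-squared).
#'
#' @param metadata Data frame with a binary `label` column (1 = positive
#'   class listed first) and covariate columns.
#' @param continuous,categorical Character vectors of column names; by
#'   default every numeric column except `label` is treated as continuous
#'   and every character/factor column as categorical.
#' @param method Test for categorical rows, `"fisher"` or `"chisq"`.
#' @return A data frame of class `eus_cohort_table` with columns
#'   `variable`, `level`, `positive`, `negative`, `p_value`.
#' @export
cohort_table <- function(metadata, continuous = NULL, categorical = NULL,
                         method = c("fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot("label" %in% names(metadata))
  lab <- as.integer(metadata$label)
  if (!any(lab == 1L) || !any(lab == 0L))
    stop("both classes must be present", call. = FALSE)
  candidates <- setdiff(names(metadata), c("label", "patient_id"))
  if (is.null(continuous))
    continuous <- candidates[vapply(metadata[candidates], is.numeric,
                                    logical(1))]
  if (is.null(categorical))
    categorical <- setdiff(candidates, continuous)
  rows <- list()
  fmt_cont <- function(x) sprintf("%.3g (%.3g-%.3g)", stats::median(x),
                                  min(x), max(x))
  for (v in continuous) {
    x1 <- metadata[[v]][lab == 1L]; x0 <- metadata[[v]][lab == 0L]
    p <- suppressWarnings(stats::wilcox.test(x1, x0)$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", positive = fmt_cont(x1),
      negative = fmt_cont(x0), p_value = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- as.character(metadata[[v]])
    for (lev in sort(unique(x))) {
      a1 <- sum(x == lev & lab == 1L); a0 <- sum(x == lev & lab == 0L)
      n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
      p <- fisher_2x2(a1, n1, a0, n0, method)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev,
        positive = sprintf("%d (%.1f)", a1, 100 * a1 / n1),
        negative = sprintf("%d (%.1f)", a0, 100 * a0 / n0),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eus_cohort_table", "data.frame")
  out
}

#' @export
print.eus_cohort_table <- function(x, ...) {
  y <- x
  y$p_value <- signif(y$p_value, 3)
  class(y) <- "data.frame"
  print(y, row.names = FALSE)
  invisible(x)
}

#' Compare ordered and balanced runs of one factor
#'
#' Builds the per-factor comparison: per-fold metrics of the two division
#' manners side by side, their means, and exact Wilcoxon rank-sum
#' p-values per metric over the 5 + 5 fold values.
#'
#' @param cv_ordered,cv_balanced `eus_cv` runs of the same factor under
#'   the two division manners.
#' @param threshold Decision threshold.
#' @return A list of class `eus_dataset_comparison`: `factor`, `ordered`
#'   and `balanced` ([summary.eus_cv()] objects) and `p_values` (named
#'   vector over the metrics).
#' @export
compare_modes <- function(cv_ordered, cv_balanced, threshold = 0.5) {
  stopifnot(inherits(cv_ordered, "eus_cv"), inherits(cv_balanced, "eus_cv"))
  so <- summary(cv_ordered, threshold); sb <- summary(cv_balanced, threshold)
  metrics <- c("auroc", "accuracy", "sensitivity", "specificity",
               "ppv", "npv")
  p <- vapply(metrics, function(m) {
    a <- so$per_fold[[m]]; b <- sb$per_fold[[m]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) return(NA_real_)
    compare_fold_scores(a[ok], b[ok])
  }, numeric(1))
  structure(list(factor = cv_ordered$factor, ordered = so, balanced = sb,
                 p_values = p),
            class = "eus_dataset_comparison")
}

#' @export
print.eus_dataset_comparison <- function(x, ...) {
  cat(sprintf("Ordered vs balanced division, factor %s\n",
              toupper(x$factor)))
  tab <- rbind(ordered = x$ordered$per_fold[, -1] |> colMeans(na.rm = TRUE),
               balanced = x$balanced$per_fold[, -1] |> colMeans(na.rm = TRUE),
               p = x$p_values)
  print(round(tab, 3))
  invisible(x)
}
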