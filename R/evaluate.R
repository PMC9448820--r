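#' @title Diagnostic performance reporting
#' @description Confusion counts with malignant as the positive class,
#'   sensitivity / specificity / PPV / NPV / accuracy with 95% Wilson score
#'   intervals, rank-based ROC/AUC, Bayes re-projection of predictive values
#'   to an assumed prevalence, and per-stratum accuracy tables.
#' @name evaluate
NULL

as_malignant01 <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(x %in% c(0, 1)))
    return(as.integer(x))
  }
  x <- as.character(x)
  stopifnot(all(x %in% c("benign", "malignant")))
  as.integer(x == "malignant")
}

#' Confusion counts (positive = malignant)
#'
#' @param truth,predicted equal-length binary vectors: 0/1 with 1 =
#'   malignant, or `"benign"`/`"malignant"` strings.
#' @return object of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  t1 <- as_malignant01(truth); p1 <- as_malignant01(predicted)
  structure(list(TP = sum(t1 == 1 & p1 == 1),
                 TN = sum(t1 == 0 & p1 == 0),
                 FP = sum(t1 == 0 & p1 == 1),
                 FN = sum(t1 == 1 & p1 == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (positive = malignant): TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' The uncorrected score interval (no continuity correction): the set of `p`
#' for which the score statistic `|phat - p| / sqrt(p(1-p)/n)` does not
#' exceed the normal quantile, in closed form.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `> 0`.
#' @param level confidence level (default 0.95).
#' @return named vector `c(estimate, lower, upper)`.
#' @export
wilson_interval <- function(k, n, level = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  # the score interval's endpoints are exactly 0 (k = 0) and 1 (k = n);
  # snap them so rounding cannot push the bound past the point estimate
  c(estimate = phat,
    lower = if (k == 0) 0 else max(0, center - half),
    upper = if (k == n) 1 else min(1, center + half))
}

#' Diagnostic metrics with Wilson intervals
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)` and accuracy, each with its Wilson score interval. A
#' metric with a zero denominator is reported as `NA` (undefined), not 0.
#' Prevalence is the malignant fraction of the cohort.
#'
#' @param counts a [confusion()] result.
#' @param level confidence level.
#' @param auc optional AUC to carry along in the report.
#' @return object of class `metrics_report`: a list of `c(estimate, lower,
#'   upper)` vectors plus `prevalence`, `n`, and `auc`.
#' @export
diagnostic_metrics <- function(counts, level = 0.95, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  one <- function(k, d) {
    if (d == 0) return(c(estimate = NA_real_, lower = NA_real_,
                         upper = NA_real_))
    wilson_interval(k, d, level)
  }
  structure(list(
    sensitivity = one(counts$TP, counts$TP + counts$FN),
    specificity = one(counts$TN, counts$TN + counts$FP),
    ppv = one(counts$TP, counts$TP + counts$FP),
    npv = one(counts$TN, counts$TN + counts$FN),
    accuracy = one(counts$TP + counts$TN, n),
    prevalence = (counts$TP + counts$FN) / n,
    n = n, auc = auc, level = level, counts = counts),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (anyNA(v)) "undefined"
    else sprintf("%.1f%% (%.1f-%.1f)", 100 * v[1], 100 * v[2], 100 * v[3])
  cat(sprintf("metrics_report (n = %d, prevalence = %.1f%%)\n",
              x$n, 100 * x$prevalence))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    cat(sprintf("  %-12s %s\n", m, fmt(x[[m]])))
  if (!is.na(x$auc)) cat(sprintf("  %-12s %.3f\n", "auc", x$auc))
  invisible(x)
}

#' Re-project PPV and NPV to an assumed prevalence
#'
#' Bayes' rule with fixed sensitivity and specificity:
#' `PPV = sens*p / (sens*p + (1-spec)(1-p))` and
#' `NPV = spec*(1-p) / (spec*(1-p) + (1-sens)*p)`. At the printed prospective
#' operating point (sensitivity 92%, specificity 71%) and a prevalence of
#' 30%, the NPV rounds to 95%.
#'
#' @param sensitivity,specificity,prevalence fractions in `[0, 1]`.
#' @return named vector `c(ppv, npv)`; a degenerate 0/0 ratio yields `NA`.
#' @export
prevalence_adjusted <- function(sensitivity, specificity, prevalence) {
  sensitivity <- unname(sensitivity)
  specificity <- unname(specificity)
  prevalence <- unname(prevalence)
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  p <- prevalence
  ppv_den <- sensitivity * p + (1 - specificity) * (1 - p)
  npv_den <- specificity * (1 - p) + (1 - sensitivity) * p
  c(ppv = if (ppv_den == 0) NA_real_ else sensitivity * p / ppv_den,
    npv = if (npv_den == 0) NA_real_ else specificity * (1 - p) / npv_den)
}

#' Rank-based ROC curve and AUC
#'
#' AUC by the Mann-Whitney formulation with tie correction (ties between a
#' malignant and a benign score count 1/2), plus ROC points at every distinct
#' score threshold. Higher scores must indicate malignancy.
#'
#' @param scores malignancy scores.
#' @param truth binary truth (1 or `"malignant"` = positive).
#' @return list with `auc` and a `roc` data frame (`threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(scores, truth) {
  t1 <- as_malignant01(truth)
  if (length(scores) != length(t1)) stop("length mismatch")
  n_pos <- sum(t1 == 1); n_neg <- sum(t1 == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[t1 == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(s) sum(scores >= s & t1 == 1) / n_pos,
                      numeric(1))),
    fpr = c(0, vapply(thr, function(s) sum(scores >= s & t1 == 0) / n_neg,
                      numeric(1))))
  list(auc = auc, roc = roc)
}

#' Per-stratum accuracy table
#'
#' Correct / total counts and accuracy per level of an annotation column.
#' With `relabel` (default maps the Hurthle-cell types onto their follicular
#' counterparts, HCA -> FA and HCC -> FTC) strata are merged before counting.
#'
#' @param truth,predicted binary vectors as in [confusion()].
#' @param annotation data frame aligned with the predictions.
#' @param key annotation column to stratify on.
#' @param relabel named character vector mapping stratum -> stratum, or
#'   `NULL` for no merging.
#' @return data frame with `stratum`, `correct`, `total`, `accuracy`.
#' @export
stratified_accuracy <- function(truth, predicted, annotation, key,
                                relabel = NULL) {
  if (!key %in% names(annotation)) stop("unknown annotation key: ", key)
  stopifnot(nrow(annotation) == length(truth),
            length(truth) == length(predicted))
  strata <- as.character(annotation[[key]])
  if (!is.null(relabel)) {
    hit <- strata %in% names(relabel)
    strata[hit] <- relabel[strata[hit]]
  }
  ok <- as_malignant01(truth) == as_malignant01(predicted)
  out <- do.call(rbind, lapply(sort(unique(strata)), function(s) {
    sel <- strata == s
    data.frame(stratum = s, correct = sum(ok[sel]), total = sum(sel),
               accuracy = mean(ok[sel]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default histotype relabeling for stratified reporting
#'
#' HCA is counted under FA and HCC under FTC.
#' @export
histotype_relabel <- function() c(HCA = "FA", HCC = "FTC")
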