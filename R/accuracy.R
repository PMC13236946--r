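#' Confusion counts for referral decisions vs expert judgment
#'
#' @param tp,fp,fn,tn non-negative integer counts: tool-positive/
#'   expert-positive, tool-positive/expert-negative, tool-negative/
#'   expert-positive, tool-negative/expert-negative.
#' @return An object of class `dentale_confusion`.
#' @examples
#' confusion_counts(tp = 53, fp = 3, fn = 0, tn = 27) # n = 83 pilot layout
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  out <- as.list(as.integer(counts))
  names(out) <- names(counts)
  out$n <- sum(counts)
  class(out) <- "dentale_confusion"
  out
}

# one-decimal percent, half away from zero (94.55 -> 94.6)
percent1 <- function(p) {
  ifelse(is.na(p), NA_real_, sign(p) * floor(abs(p) * 1000 + 0.5) / 10)
}

wilson_ci <- function(x, denom, conf_level) {
  if (is.na(denom) || denom == 0) return(c(NA_real_, NA_real_))
  as.numeric(suppressWarnings(
    stats::prop.test(x, denom, conf.level = conf_level,
                     correct = FALSE))$conf.int)
}

#' Diagnostic accuracy of the referral rule
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)` from a
#' 2x2 confusion table of tool referrals against the expert reference
#' standard, each with a Wilson score 95% interval. A metric whose
#' denominator is zero is reported as `NA` (not applicable), never as 0 or
#' 1. Percentages are rounded to one decimal, half away from zero.
#'
#' @param counts a `dentale_confusion` object (see [confusion_counts()]).
#' @param conf_level confidence level for the Wilson intervals.
#' @return An object of class `dentale_accuracy`: a data frame with one
#'   row per metric and columns `metric`, `estimate` (proportion),
#'   `percent` (one decimal), `ci_low`, `ci_high`, `numerator`,
#'   `denominator`.
#' @examples
#' diagnostic_accuracy(confusion_counts(53, 3, 0, 27))
#' @export
diagnostic_accuracy <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "dentale_confusion"))
  defs <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    ppv = c(counts$tp, counts$tp + counts$fp),
    npv = c(counts$tn, counts$tn + counts$fn)
  )
  rows <- lapply(names(defs), function(metric) {
    num <- defs[[metric]][1]; den <- defs[[metric]][2]
    est <- if (den == 0) NA_real_ else num / den
    ci <- if (den == 0) c(NA_real_, NA_real_) else
      wilson_ci(num, den, conf_level)
    data.frame(metric = metric, estimate = est,
               percent = percent1(est),
               ci_low = ci[1], ci_high = ci[2],
               numerator = num, denominator = den,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- counts
  attr(out, "conf_level") <- conf_level
  class(out) <- c("dentale_accuracy", "data.frame")
  out
}

#' Extract one metric from a `dentale_accuracy` table
#' @param accuracy a `dentale_accuracy` object.
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`.
#' @param as either the raw proportion or the one-decimal percentage.
#' @return A single number (`NA` if the metric was not applicable).
#' @export
accuracy_metric <- function(accuracy, metric,
                            as = c("proportion", "percent")) {
  as <- match.arg(as)
  i <- match(metric, accuracy$metric)
  if (is.na(i)) stop("unknown metric: ", metric, call. = FALSE)
  if (as == "percent") accuracy$percent[i] else accuracy$estimate[i]
}

#' @export
print.dentale_accuracy <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Diagnostic accuracy (tp=", counts$tp, ", fp=", counts$fp,
      ", fn=", counts$fn, ", tn=", counts$tn, "; n=", counts$n, ")\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s not applicable (zero denominator)\n",
                  x$metric[i]))
    } else {
      cat(sprintf("  %-12s %5.1f%%  (95%% CI %.1f-%.1f%%)  [%d/%d]\n",
                  x$metric[i], x$percent[i], 100 * x$ci_low[i],
                  100 * x$ci_high[i], x$numerator[i], x$denominator[i]))
    }
  }
  invisible(x)
}

#' Sweep referral thresholds against expert labels
#'
#' For each candidate threshold, referrals are recomputed with the
#' inclusive rule (`total >= threshold`), tallied against the expert
#' labels, and summarized. The selected threshold follows the published
#' selection logic — patient safety first, then minimal over-referral:
#' among thresholds reaching sensitivity 1, those with maximal specificity,
#' tie-broken to the smallest such threshold. The smallest threshold with
#' sensitivity 1 is also reported.
#'
#' @param totals numeric vector of final DENTALE totals.
#' @param expert_labels logical vector, `TRUE` when the expert judged the
#'   survivor to need specialized dental care. Both classes must occur.
#' @param thresholds candidate thresholds (default the piloted set
#'   14, 16, 18, 20).
#' @param conf_level confidence level passed to [diagnostic_accuracy()].
#' @return An object of class `dentale_sweep`: a data frame with one row
#'   per threshold (`threshold`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`) with attributes `selected_threshold` and
#'   `smallest_sens1_threshold` (each `NA` when no threshold reaches
#'   sensitivity 1).
#' @export
sweep_thresholds <- function(totals, expert_labels,
                             thresholds = c(14, 16, 18, 20),
                             conf_level = 0.95) {
  stopifnot(length(totals) == length(expert_labels),
            is.logical(expert_labels), !anyNA(expert_labels),
            all(is.finite(totals)), length(thresholds) >= 1L)
  if (all(expert_labels) || !any(expert_labels)) {
    stop("degenerate expert labels: need at least one positive and one ",
         "negative", call. = FALSE)
  }
  thresholds <- sort(unique(thresholds))
  rows <- lapply(thresholds, function(t) {
    refer <- totals >= t
    cc <- confusion_counts(tp = sum(refer & expert_labels),
                           fp = sum(refer & !expert_labels),
                           fn = sum(!refer & expert_labels),
                           tn = sum(!refer & !expert_labels))
    acc <- diagnostic_accuracy(cc, conf_level)
    data.frame(threshold = t, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               tn = cc$tn,
               sensitivity = accuracy_metric(acc, "sensitivity"),
               specificity = accuracy_metric(acc, "specificity"),
               ppv = accuracy_metric(acc, "ppv"),
               npv = accuracy_metric(acc, "npv"))
  })
  out <- do.call(rbind, rows)
  sens1 <- !is.na(out$sensitivity) & out$sensitivity == 1
  if (any(sens1)) {
    best_spec <- max(out$specificity[sens1])
    sel <- min(out$threshold[sens1 & out$specificity == best_spec])
    smallest <- min(out$threshold[sens1])
  } else {
    sel <- NA_real_; smallest <- NA_real_
  }
  attr(out, "selected_threshold") <- sel
  attr(out, "smallest_sens1_threshold") <- smallest
  class(out) <- c("dentale_sweep", "data.frame")
  out
}

#' @export
print.dentale_sweep <- function(x, ...) {
  cat("Referral-threshold sweep (inclusive comparison)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("selected threshold (sens = 1, max specificity):",
      attr(x, "selected_threshold"), "\n")
  invisible(x)
}
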