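#' Intraclass correlation for interobserver reliability
#'
#' Computes the ICC from a complete subjects-by-raters matrix of DENTALE
#' totals (or subscale totals), as used to quantify how closely independent
#' dentists agree when reading the same set of orthopantomograms.
#'
#' The default model is ICC(2,1): two-way random effects, absolute
#' agreement, single measure — raters are treated as a random sample, every
#' rater scores every subject, and the unit of analysis is one rater's
#' score. The estimate is formed from the two-way ANOVA mean squares
#' (subjects `MSR`, raters `MSC`, residual `MSE`):
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' Confidence bounds use the McGraw–Wong F-based method, and the p-value
#' tests ICC = 0 via `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of
#' freedom. Average-measure and consistency variants are available for
#' sensitivity analysis.
#'
#' @param m numeric matrix, subjects in rows, raters in columns; no missing
#'   cells (missing data are rejected, not imputed), `n >= 2` subjects and
#'   `k >= 2` raters.
#' @param model one of `"icc2_1"` (default; two-way random, absolute
#'   agreement, single measure), `"icc2_k"` (absolute agreement, average of
#'   k raters), `"icc3_1"`, `"icc3_k"` (consistency, single / average).
#' @param conf_level confidence level for the interval.
#' @return An object of class `dentale_icc`: list with `estimate`,
#'   `ci_low`, `ci_high`, `model`, `p_value`, `n_subjects`, `k_raters`,
#'   and the mean squares.
#' @examples
#' m <- matrix(c(10, 12, 11,
#'               20, 21, 19,
#'               5,  6,  5,
#'               30, 33, 31), nrow = 4, byrow = TRUE)
#' icc_two_way(m)
#' @export
icc_two_way <- function(m, model = c("icc2_1", "icc2_k", "icc3_1", "icc3_k"),
                        conf_level = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("rating matrix must be numeric", call. = FALSE)
  if (anyNA(m)) {
    stop("rating matrix has missing cells; the design must be complete ",
         "(no imputation is performed)", call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters (got ", n, " x ", k, ")",
         call. = FALSE)
  }
  if (stats::var(as.vector(m)) == 0) {
    stop("all ratings identical: total variance is zero, the ICC is ",
         "undefined", call. = FALSE)
  }

  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]

  alpha <- 1 - conf_level
  est <- switch(model,
    icc2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    icc2_k = (msr - mse) / (msr + (msc - mse) / n),
    icc3_1 = (msr - mse) / (msr + (k - 1) * mse),
    icc3_k = (msr - mse) / msr
  )

  ci <- icc_confint(model, msr, msc, mse, n, k, alpha)
  p <- if (mse == 0) 0 else
    stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  out <- list(estimate = est, ci_low = ci[1], ci_high = ci[2],
              model = model,
              model_label = switch(model,
                icc2_1 = "two-way random, absolute agreement, single measure",
                icc2_k = "two-way random, absolute agreement, average measure",
                icc3_1 = "two-way mixed, consistency, single measure",
                icc3_k = "two-way mixed, consistency, average measure"),
              p_value = p, n_subjects = n, k_raters = k,
              ms_subjects = msr, ms_raters = msc, ms_error = mse,
              conf_level = conf_level)
  class(out) <- "dentale_icc"
  out
}

# McGraw-Wong confidence bounds; degenerate perfect-agreement matrices
# (mse == 0 and msc == 0) collapse to [1, 1].
icc_confint <- function(model, msr, msc, mse, n, k, alpha) {
  if (model %in% c("icc2_1", "icc2_k")) {
    r1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (!is.finite(r1) || r1 >= 1) return(c(1, 1))
    a <- k * r1 / (n * (1 - r1))
    b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    if (model == "icc2_k") {       # Spearman-Brown step-up of the bounds
      lo <- k * lo / (1 + (k - 1) * lo)
      hi <- k * hi / (1 + (k - 1) * hi)
    }
  } else {
    if (mse == 0) return(c(1, 1))
    f <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, n - 1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, n - 1)
    if (model == "icc3_1") {
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    } else {
      lo <- 1 - 1 / fl
      hi <- 1 - 1 / fu
    }
  }
  c(max(-1, min(lo, 1)), max(-1, min(hi, 1)))
}

#' @export
print.dentale_icc <- function(x, ...) {
  cat("ICC (", x$model_label, ")\n", sep = "")
  cat(sprintf("  estimate %.3f, %d%% CI %.3f-%.3f, p = %.3g\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_value))
  cat("  design:", x$n_subjects, "subjects x", x$k_raters, "raters\n")
  invisible(x)
}
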