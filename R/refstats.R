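# Validation statistics and the normative reference-value procedure:
# Dice overlap, Bland-Altman agreement with paired t-tests, error-detection
# summaries (sensitivity/specificity/balanced accuracy), stratified reference
# intervals with a priori 3-IQR outlier exclusion, age regression with
# Bonferroni correction, and mean-absolute-error group comparisons.

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical/integer arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b))
    stop("masks must have the same shape")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Bland-Altman agreement analysis
#'
#' Differences are `auto - manual`; limits of agreement are
#' `bias +/- 1.96 sd(diff)`; the bias is tested against zero with a
#' two-sided paired t-test. With zero-variance differences the t-test is
#' degenerate: p is reported as 1 for zero bias and 0 for an exact nonzero
#' shift.
#'
#' @param x_auto,x_manual paired measurements (n >= 3).
#' @return object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `p_vs_zero`, `n`.
#' @export
bland_altman <- function(x_auto, x_manual) {
  if (length(x_auto) != length(x_manual)) stop("inputs must be paired")
  if (length(x_auto) < 3) stop("need at least 3 pairs")
  d <- x_auto - x_manual
  bias <- mean(d); s <- stats::sd(d)
  p <- if (s < 1e-12) {
    if (abs(bias) < 1e-12) 1 else 0
  } else stats::t.test(d)$p.value
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 p_vs_zero = p, n = length(d)), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman: bias %.3g [LoA %.3g, %.3g], p=%.3g, n=%d>\n",
              x$bias, x$loa_low, x$loa_high, x$p_vs_zero, x$n))
  invisible(x)
}

#' Error-detection summary
#'
#' Sensitivity = % of truly erroneous output flagged; specificity = % of
#' error-free output not flagged; balanced accuracy = their mean.
#'
#' @param pipeline_flags logical vector, `TRUE` where the pipeline flagged.
#' @param truth_labels logical vector, `TRUE` where output is truly erroneous.
#' @return object of class `error_detection_summary` with counts `tp`, `fp`,
#'   `tn`, `fn` and percentages `sensitivity`, `specificity`, `bacc`.
#' @export
error_detection_summary <- function(pipeline_flags, truth_labels) {
  if (length(pipeline_flags) == 0) stop("empty input")
  if (length(pipeline_flags) != length(truth_labels))
    stop("inputs must have equal length")
  f <- as.logical(pipeline_flags); t <- as.logical(truth_labels)
  tp <- sum(f & t); fp <- sum(f & !t); tn <- sum(!f & !t); fn <- sum(!f & t)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 bacc = (sens + spec) / 2),
            class = "error_detection_summary")
}

#' Balanced accuracy from sensitivity and specificity percentages
#'
#' @param sensitivity,specificity percentages.
#' @return balanced accuracy, %.
#' @export
bacc_from_rates <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

age_decade_bins <- c(45, 55, 65, 75)
age_decade_labels <- c("45-54", "55-64", "65-74")

# 3-IQR outlier rule (type-7 quartiles), returning a keep mask
iqr3_keep <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  x >= q[1] - 3 * iqr & x <= q[2] + 3 * iqr
}

# Gaussian t-based 95% prediction interval
prediction_interval <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  if (n < 2 || s < 1e-12) return(c(low = m, mean = m, high = m))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  half <- tq * s * sqrt(1 + 1 / n)
  c(low = m - half, mean = m, high = m + half)
}

#' Stratified normative reference values
#'
#' For every sex x age-decade stratum (45-54, 55-64, 65-74) and parameter:
#' values beyond 3 interquartile ranges below Q1 or above Q3 (type-7
#' quartiles) are removed a priori, then the mean and 95% prediction
#' interval `mean +/- t_{0.975, n-1} s sqrt(1 + 1/n)` are reported. A
#' percentile-based interval (empirical 2.5/97.5 quantiles) is available via
#' `pi_method = "percentile"`.
#'
#' @param cohort data frame with columns `sex` (`"M"`/`"F"`), `age` (years)
#'   and one column per parameter.
#' @param parameters character vector of parameter column names.
#' @param min_n strata smaller than this emit a warning (interval
#'   instability); empty strata are marked unavailable.
#' @param pi_method `"gaussian"` (default) or `"percentile"`.
#' @return data frame of class `reference_table`: one row per
#'   sex x age-group x parameter with `n`, `outliers_removed`, `mean`,
#'   `pi_low`, `pi_high`.
#' @export
reference_values <- function(cohort, parameters, min_n = 20L,
                             pi_method = c("gaussian", "percentile")) {
  pi_method <- match.arg(pi_method)
  stopifnot(all(c("sex", "age") %in% names(cohort)),
            all(parameters %in% names(cohort)))
  grid <- expand.grid(sex = c("M", "F"), age_group = age_decade_labels,
                      parameter = parameters, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    band <- which(age_decade_labels == g$age_group)
    sel <- cohort$sex == g$sex &
      cohort$age >= age_decade_bins[band] & cohort$age < age_decade_bins[band + 1]
    x <- cohort[[g$parameter]][sel]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(g, n = 0L, outliers_removed = 0L, mean = NA_real_,
                        pi_low = NA_real_, pi_high = NA_real_,
                        available = FALSE))
    keep <- iqr3_keep(x)
    removed <- sum(!keep)
    x <- x[keep]
    if (length(x) < min_n)
      warning(sprintf("stratum %s/%s/%s has n=%d < %d; interval unstable",
                      g$sex, g$age_group, g$parameter, length(x), min_n))
    pi <- if (pi_method == "gaussian") prediction_interval(x)
    else c(low = unname(stats::quantile(x, 0.025, type = 7)),
           mean = mean(x),
           high = unname(stats::quantile(x, 0.975, type = 7)))
    data.frame(g, n = length(x), outliers_removed = removed,
               mean = pi[["mean"]], pi_low = pi[["low"]],
               pi_high = pi[["high"]], available = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reference_table", class(out))
  out
}

#' Per-sex linear age regression with Bonferroni correction
#'
#' Ordinary least squares of each parameter on age, fitted separately per
#' sex; p-values for the age slope are Bonferroni-adjusted within each
#' sex-specific family (`m` = number of parameters tested).
#'
#' @param cohort data frame with `sex`, `age` and parameter columns.
#' @param parameters parameter column names.
#' @param alpha family-wise significance level (0.05).
#' @return data frame: sex, parameter, slope (per year), intercept, p,
#'   p_adjusted, significant.
#' @export
age_regression <- function(cohort, parameters, alpha = 0.05) {
  m <- length(parameters)
  rows <- list()
  for (sx in unique(cohort$sex)) {
    sub <- cohort[cohort$sex == sx, ]
    if (stats::sd(sub$age) < 1e-12) stop("age is constant within sex ", sx)
    for (p in parameters) {
      fit <- stats::lm(sub[[p]] ~ sub$age)
      sm <- summary(fit)$coefficients
      pval <- sm[2, 4]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, parameter = p,
        slope = unname(sm[2, 1]), intercept = unname(sm[1, 1]),
        p = pval, p_adjusted = min(1, pval * m),
        significant = min(1, pval * m) < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Compare mean absolute errors between two groups
#'
#' Summaries (mean +/- sd of |error|) per group and a two-sample test:
#' paired t-test when `paired = TRUE` (equal lengths required), Welch
#' otherwise.
#'
#' @param errors_group_a,errors_group_b error vectors (absolute values are
#'   taken).
#' @param paired logical.
#' @return list with per-group `mean`, `sd`, `n`, the test `p`, and `method`.
#' @export
mae_compare <- function(errors_group_a, errors_group_b, paired = FALSE) {
  a <- abs(errors_group_a); b <- abs(errors_group_b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  p <- if (isTRUE(all.equal(a, b))) 1
  else stats::t.test(a, b, paired = paired)$p.value
  list(group_a = list(mean = mean(a), sd = stats::sd(a), n = length(a)),
       group_b = list(mean = mean(b), sd = stats::sd(b), n = length(b)),
       p = p, method = if (paired) "paired t-test" else "Welch t-test")
}
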