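rate_point <- function(x, what) {
  if (inherits(x, "rate_estimate")) return(x$point)
  stopifnot_probability(x, what)
  x
}

#' Correct the label distribution and confusion matrix for label errors
#'
#' Extrapolates the adjudicated stratum error rates to the full strata:
#' `pn = fnr * FN` labels are expected to flip positive -> negative and
#' `np = fpr * FP` to flip negative -> positive, giving corrected totals
#' `total_positive = label_positive + np - pn` (and symmetrically for
#' negatives) and the corrected confusion matrix
#' `tp' = tp + np`, `fp' = fp - np`, `tn' = tn + pn`, `fn' = fn - pn`.
#' Expected counts stay fractional internally; reporting rounds them.
#'
#' Error rates for the concordant cells default to 0 (no correction of
#' TP/TN labels); non-zero `tp_error_rate`/`tn_error_rate` extend the same
#' flip logic to those cells.
#'
#' @param cm a [confusion_counts()] object (pre-correction).
#' @param fnr label-error rate in the FN stratum: a `rate_estimate` from
#'   [estimate_error_rate()] or a bare proportion.
#' @param fpr label-error rate in the FP stratum, likewise.
#' @param tp_error_rate,tn_error_rate optional label-error rates for the
#'   concordant cells (default 0).
#' @return an object of class `correction_result`: `pn`, `np`,
#'   `total_positive`, `total_negative`, `corrected_cm`,
#'   `corrected_metrics`, `overall_error_rate` (point value
#'   `(pn + np) / N`; see [propagate_uncertainty()] for its interval),
#'   input rates and `level`.
#' @export
correct_labels <- function(cm, fnr, fpr, tp_error_rate = 0, tn_error_rate = 0) {
  stopifnot(inherits(cm, "confusion_counts"))
  fnr_p <- rate_point(fnr, "fnr")
  fpr_p <- rate_point(fpr, "fpr")
  stopifnot_probability(tp_error_rate, "tp_error_rate")
  stopifnot_probability(tn_error_rate, "tn_error_rate")

  # expected flips out of each cell
  pn <- fnr_p * cm$fn + tp_error_rate * cm$tp   # positive -> negative
  np <- fpr_p * cm$fp + tn_error_rate * cm$tn   # negative -> positive

  corrected_cm <- confusion_counts(
    tp = cm$tp - tp_error_rate * cm$tp + fpr_p * cm$fp,
    fp = cm$fp - fpr_p * cm$fp + tp_error_rate * cm$tp,
    tn = cm$tn - tn_error_rate * cm$tn + fnr_p * cm$fn,
    fn = cm$fn - fnr_p * cm$fn + tn_error_rate * cm$tn,
    level = cm$level
  )
  structure(list(
    pn = pn, np = np,
    total_positive = cm$label_positive + np - pn,
    total_negative = cm$label_negative + pn - np,
    corrected_cm = corrected_cm,
    corrected_metrics = compute_metrics(corrected_cm),
    overall_error_rate = list(point = (pn + np) / cm$n, se = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_),
    fnr = fnr_p, fpr = fpr_p,
    tp_error_rate = tp_error_rate, tn_error_rate = tn_error_rate,
    precorrection_cm = cm, level = cm$level
  ), class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("Label correction (%s level, N = %s)\n", x$level,
              format(x$precorrection_cm$n)))
  cat(sprintf("  expected flips: pn = %s (pos->neg), np = %s (neg->pos), total %s\n",
              format(round_half_up(x$pn)), format(round_half_up(x$np)),
              format(round_half_up(x$pn + x$np))))
  cat(sprintf("  corrected totals: %s positive / %s negative\n",
              format(round_half_up(x$total_positive)),
              format(round_half_up(x$total_negative))))
  cat(sprintf("  overall label-error rate: %s%%\n",
              format(round_half_up(100 * x$overall_error_rate$point, 1), nsmall = 1)))
  print(x$corrected_metrics)
  invisible(x)
}

#' Propagate stratum-rate uncertainty through the correction
#'
#' The corrected quantities are deterministic functions of the two sampled
#' error rates, so their uncertainty comes from the binomial sampling of
#' `k_overturned` in each stratum. Two methods:
#' \describe{
#'   \item{bootstrap (default)}{resamples `k* ~ Binomial(n, k/n)` per
#'     stratum, recomputes the full correction per replicate, and takes
#'     percentile intervals.}
#'   \item{delta}{first-order propagation. For the overall error rate the
#'     gradient is analytic: `Var = (fn^2 Var(fnr) + fp^2 Var(fpr)) / N^2`;
#'     for the corrected metrics and totals the gradient is evaluated
#'     numerically.}
#' }
#'
#' @param cm pre-correction [confusion_counts()].
#' @param fnr,fpr `rate_estimate` objects (k and n are required).
#' @param method `"bootstrap"` or `"delta"`.
#' @param replicates bootstrap replicates (>= 2; default 1000).
#' @param seed seed for the bootstrap.
#' @param conf_level confidence level.
#' @return list with one element per quantity (`overall_error_rate`,
#'   `total_positive`, `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, `f1`), each a list `point`, `se`, `ci_low`, `ci_high`;
#'   plus `method`, `replicates`, `seed`, `conf_level`.
#' @export
propagate_uncertainty <- function(cm, fnr, fpr,
                                  method = c("bootstrap", "delta"),
                                  replicates = 1000L, seed = 1L,
                                  conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "confusion_counts"),
            inherits(fnr, "rate_estimate"), inherits(fpr, "rate_estimate"))
  if (method == "bootstrap" && replicates < 2) {
    stop("bootstrap needs at least 2 replicates", call. = FALSE)
  }

  quantities <- function(fnr_p, fpr_p) {
    pn <- fnr_p * cm$fn
    np <- fpr_p * cm$fp
    tp <- cm$tp + np; fp <- cm$fp - np; tn <- cm$tn + pn; fn <- cm$fn - pn
    tot_pos <- tp + fn
    c(overall_error_rate = (pn + np) / cm$n,
      total_positive = tot_pos,
      sensitivity = tp / tot_pos,
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / cm$n,
      precision = tp / (tp + fp),
      f1 = 2 * tp / (2 * tp + fp + fn))
  }
  point <- quantities(fnr$point, fpr$point)
  alpha <- 1 - conf_level

  if (method == "bootstrap") {
    draws <- with_seed(seed, {
      fnr_star <- stats::rbinom(replicates, fnr$n, fnr$point) / fnr$n
      fpr_star <- stats::rbinom(replicates, fpr$n, fpr$point) / fpr$n
      mapply(quantities, fnr_star, fpr_star)
    })
    summarise <- function(nm) {
      v <- draws[nm, ]
      ci <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      list(point = point[[nm]], se = stats::sd(v), ci_low = ci[1], ci_high = ci[2])
    }
  } else {
    var_fnr <- fnr$point * (1 - fnr$point) / fnr$n
    var_fpr <- fpr$point * (1 - fpr$point) / fpr$n
    h1 <- max(1e-6, fnr$point * 1e-4)
    h2 <- max(1e-6, fpr$point * 1e-4)
    g_fnr <- (quantities(fnr$point + h1, fpr$point) -
              quantities(fnr$point - h1, fpr$point)) / (2 * h1)
    g_fpr <- (quantities(fnr$point, fpr$point + h2) -
              quantities(fnr$point, fpr$point - h2)) / (2 * h2)
    z <- stats::qnorm(1 - alpha / 2)
    summarise <- function(nm) {
      se <- sqrt(g_fnr[[nm]]^2 * var_fnr + g_fpr[[nm]]^2 * var_fpr)
      list(point = point[[nm]], se = se,
           ci_low = point[[nm]] - z * se, ci_high = point[[nm]] + z * se)
    }
  }
  out <- lapply(stats::setNames(names(point), names(point)), summarise)
  c(out, list(method = method,
              replicates = if (method == "bootstrap") replicates else NA_integer_,
              seed = if (method == "bootstrap") as.integer(seed) else NA_integer_,
              conf_level = conf_level))
}

#' Lab versus real-world operating-point gap
#'
#' Differences, in percentage points, between the laboratory-validated
#' sensitivity/specificity and the values observed against field labels,
#' before and after label correction.
#'
#' @param pre,post `metrics_set` objects (or lists with `sensitivity` and
#'   `specificity` in \[0, 1\]).
#' @param lab_sensitivity,lab_specificity laboratory reference operating
#'   point, proportions in \[0, 1\].
#' @return object of class `gap_report` with `lab_sensitivity`,
#'   `lab_specificity`, `pre_gap_sens`, `pre_gap_spec`, `post_gap_sens`,
#'   `post_gap_spec` (lab minus observed, percentage points).
#' @export
gap_analysis <- function(pre, post, lab_sensitivity, lab_specificity) {
  stopifnot_probability(lab_sensitivity, "lab_sensitivity")
  stopifnot_probability(lab_specificity, "lab_specificity")
  for (m in list(pre, post)) {
    stopifnot_probability(m$sensitivity, "sensitivity")
    stopifnot_probability(m$specificity, "specificity")
  }
  structure(list(
    lab_sensitivity = lab_sensitivity, lab_specificity = lab_specificity,
    pre_gap_sens = 100 * (lab_sensitivity - pre$sensitivity),
    pre_gap_spec = 100 * (lab_specificity - pre$specificity),
    post_gap_sens = 100 * (lab_sensitivity - post$sensitivity),
    post_gap_spec = 100 * (lab_specificity - post$specificity)
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Lab vs real-world gap (percentage points, lab minus observed)\n")
  cat(sprintf("  sensitivity: %.1f (pre) -> %.1f (post)\n",
              round_half_up(x$pre_gap_sens, 1), round_half_up(x$post_gap_sens, 1)))
  cat(sprintf("  specificity: %.1f (pre) -> %.1f (post)\n",
              round_half_up(x$pre_gap_spec, 1), round_half_up(x$post_gap_spec, 1)))
  invisible(x)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square test (df = 1) on the 2x2 table
#' `(x1, n1 - x1; x2, n2 - x2)`, optionally with the Yates continuity
#' correction. Counts may be fractional (expected counts from the
#' correction); they are used as given.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param continuity apply the Yates correction (default `FALSE`).
#' @return object of class `comparison_result`: `statistic`, `df`,
#'   `p_value`, `continuity_correction`.
#' @export
compare_proportions <- function(x1, n1, x2, n2, continuity = FALSE) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("need 0 <= x <= n and n >= 1 in both groups", call. = FALSE)
  }
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) {
    stop("a margin of the 2x2 table is empty (expected cell 0); ",
         "the chi-square approximation does not apply - use an exact test",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, continuity_correction = continuity),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Chi-square test: X^2 = %.3f, df = %d, p %s%s\n",
              x$statistic, x$df,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value),
              if (x$continuity_correction) " (continuity-corrected)" else ""))
  invisible(x)
}
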