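#' Binomial proportion estimate with confidence interval
#'
#' Point estimate `k/n`, Wald standard error `sqrt(p(1-p)/n)`, and a
#' confidence interval by one of three methods. The default is the exact
#' Clopper-Pearson interval (beta-distribution quantiles); Wilson score and
#' Wald intervals are selectable.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (n >= 1).
#' @param conf_level confidence level, default 0.95.
#' @param method `"clopper_pearson"` (default), `"wilson"` or `"wald"`.
#' @param rate_name optional tag naming the estimated rate (e.g. `"fnr"`).
#' @return an object of class `rate_estimate`: `k`, `n`, `point`, `se`,
#'   `ci_low`, `ci_high`, `ci_method`, `conf_level`, `rate_name`.
#' @examples
#' binomial_interval(560, 880)
#' @export
binomial_interval <- function(k, n, conf_level = 0.95,
                              method = c("clopper_pearson", "wilson", "wald"),
                              rate_name = NA_character_) {
  method <- match.arg(method)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop("k and n must be single non-missing numbers", call. = FALSE)
  }
  if (n < 1 || k < 0 || k > n) {
    stop(sprintf("invalid binomial counts: k = %s, n = %s (need 0 <= k <= n, n >= 1)",
                 format(k), format(n)), call. = FALSE)
  }
  stopifnot_probability(conf_level, "conf_level")
  p <- k / n
  se <- sqrt(p * (1 - p) / n)
  alpha <- 1 - conf_level
  ci <- switch(method,
    clopper_pearson = c(
      if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
      if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
    ),
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    wald = {
      z <- stats::qnorm(1 - alpha / 2)
      c(max(0, p - z * se), min(1, p + z * se))
    }
  )
  structure(list(k = k, n = n, point = p, se = se,
                 ci_low = ci[1], ci_high = ci[2],
                 ci_method = method, conf_level = conf_level,
                 rate_name = rate_name),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  nm <- if (is.na(x$rate_name)) "proportion" else x$rate_name
  cat(sprintf("%s: %s%% (k = %s / n = %s; SE %s%%; %d%% CI [%s, %s]%%, %s)\n",
              nm,
              format(round_half_up(100 * x$point, 1), nsmall = 1),
              format(x$k), format(x$n),
              format(round_half_up(100 * x$se, 1), nsmall = 1),
              round(100 * x$conf_level),
              format(round_half_up(100 * x$ci_low, 1), nsmall = 1),
              format(round_half_up(100 * x$ci_high, 1), nsmall = 1),
              x$ci_method))
  invisible(x)
}
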