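#' Paired-method agreement (Pearson correlation)
#'
#' Agreement between two paired value series (e.g. HR derived from the
#' pulse sensor versus the ECG reference), as the Pearson correlation with a
#' two-sided p-value from the t transform.
#'
#' @param a,b Equal-length numeric vectors (length >= 3, finite).
#' @return A one-row tibble with `pearson_r`, `p_value`, `n`.
#' @export
paired_agreement <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  if (length(a) < 3L) abort("need at least 3 paired values")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("values must be finite")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("correlation undefined: one series has zero variance")
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
         n = length(a))
}

#' Per-variable group difference tests between MDD and healthy subjects
#'
#' For each of the nine screening variables: group means and SDs, unpaired
#' two-sample t-tests (Student's equal-variance and Welch's, both reported),
#' a variance-ratio F-test, and a significance tier at the 0.05 / 0.01
#' levels (on the Student p-value). The groups are independent, so unpaired
#' tests are the only valid choice even though some published tables label
#' such comparisons "paired". The F ratio numerator/denominator convention
#' is configurable; the default places the healthy-group variance in the
#' numerator.
#'
#' @param data Cohort tibble with `label` and the nine canonical features
#'   (>= 2 subjects per group).
#' @param f_convention `"healthy_over_mdd"` (default) or
#'   `"mdd_over_healthy"`.
#' @return A tibble with one row per variable.
#' @export
group_difference_tests <- function(data,
                                   f_convention = c("healthy_over_mdd",
                                                    "mdd_over_healthy")) {
  check_cohort(data)
  f_convention <- match.arg(f_convention)
  if (any(table(data$label) < 2L)) {
    abort("each group needs at least 2 subjects")
  }
  ord <- canonical_feature_order()
  rows <- lapply(ord, function(v) {
    x_m <- data[[v]][data$label == "MDD"]
    x_h <- data[[v]][data$label == "healthy"]
    ts <- stats::t.test(x_m, x_h, var.equal = TRUE)
    tw <- stats::t.test(x_m, x_h, var.equal = FALSE)
    if (f_convention == "healthy_over_mdd") {
      f <- var(x_h) / var(x_m)
      df1 <- length(x_h) - 1L; df2 <- length(x_m) - 1L
    } else {
      f <- var(x_m) / var(x_h)
      df1 <- length(x_m) - 1L; df2 <- length(x_h) - 1L
    }
    p_f <- 2 * min(pf(f, df1, df2), 1 - pf(f, df1, df2))
    p <- ts$p.value
    tibble(variable = v,
           mean_mdd = mean(x_m), sd_mdd = sd(x_m),
           mean_healthy = mean(x_h), sd_healthy = sd(x_h),
           t_student = unname(ts$statistic), p_student = p,
           t_welch = unname(tw$statistic), p_welch = tw$p.value,
           f_stat = f, p_f = min(p_f, 1),
           significance = if (p < 0.01) "**" else if (p < 0.05) "*" else "ns")
  })
  bind_rows(rows)
}

# Asymptotic CDF of the Anderson-Darling statistic for a fully specified
# continuous null (Marsaglia's adinf approximation).
ad_cdf <- function(z) {
  if (z <= 0) return(0)
  if (z < 2) {
    z^(-0.5) * exp(-1.2337141 / z) *
      (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
        (0.011672 - 0.00168691 * z) * z) * z) * z) * z)
  } else {
    exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
      (0.008056 - 0.0003146 * z) * z) * z) * z) * z))
  }
}

#' Anderson-Darling test against the standard normal (fully specified)
#'
#' The case with both parameters known: no mean or variance is estimated
#' from the sample, appropriate for randomized quantile residuals, which are
#' exactly standard normal under a correct model. The p-value uses the
#' standard asymptotic approximation to the null distribution.
#'
#' @param x Numeric vector (n >= 3, finite).
#' @return A one-row tibble with `statistic` (the A^2 value), `p_value`, `n`.
#' @export
ad_test_normal <- function(x) {
  if (length(x) < 3L || any(!is.finite(x))) {
    abort("need at least 3 finite values")
  }
  n <- length(x)
  u <- stats::pnorm(sort(x))
  u <- pmin(pmax(u, 1e-300), 1 - 1e-16)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  tibble(statistic = a2, p_value = 1 - ad_cdf(a2), n = n)
}

#' Randomized quantile residual diagnostics of a screening model
#'
#' For each subject with fitted healthy-probability `p` and outcome `y`
#' (healthy = 1), a uniform variate is drawn on the Bernoulli CDF jump
#' `(F(y-), F(y)]` and mapped through the standard-normal quantile. Under a
#' correctly specified model these residuals are exactly standard normal;
#' the Anderson-Darling test against the fully specified standard normal
#' quantifies the fit. Seeded and reproducible.
#'
#' @param model A `logit_model` whose scores are healthy-high logits.
#' @param data Labeled cohort tibble.
#' @param seed Integer seed for the uniform randomization.
#' @return An object of class `residual_diagnostics` with per-subject
#'   residuals, the A statistic, its p-value and the seed.
#' @export
quantile_residual_diagnostics <- function(model, data, seed = NULL) {
  check_cohort(data, require_both = FALSE)
  p <- plogis(logit_score(data, model))
  if (any(p <= 0 | p >= 1)) {
    warn("fitted probabilities at 0 or 1 clamped to [1e-12, 1 - 1e-12]")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  y <- as.numeric(data$label == "healthy")
  # Bernoulli CDF: F(0) = 1 - p, F(1) = 1; jump interval for the outcome
  lo <- ifelse(y == 1, 1 - p, 0)
  hi <- ifelse(y == 1, 1, 1 - p)
  u <- with_seed(seed, lo + runif(length(p)) * (hi - lo))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- qnorm(u)
  ad <- ad_test_normal(r)
  structure(list(
    residuals = tibble(
      subject_id = if ("subject_id" %in% names(data)) data$subject_id
                   else sprintf("s%03d", seq_len(nrow(data))),
      label = data$label, fitted_p_healthy = p, residual = r),
    statistic = ad$statistic, p_value = ad$p_value, seed = seed),
    class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Randomized quantile residuals (n = %d): A = %.3f, p = %.3f\n",
    nrow(x$residuals), x$statistic, x$p_value))
  invisible(x)
}

#' Per-subject residual table
#'
#' @param x A `residual_diagnostics`.
#' @param ... Unused.
#' @return Tibble of per-subject fitted probabilities and residuals.
#' @method tidy residual_diagnostics
#' @export
tidy.residual_diagnostics <- function(x, ...) x$residuals

#' One-row residual diagnostic summary
#'
#' @param x A `residual_diagnostics`.
#' @param ... Unused.
#' @return Tibble with the Anderson-Darling statistic and p-value.
#' @method glance residual_diagnostics
#' @export
glance.residual_diagnostics <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n = nrow(x$residuals))
}
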