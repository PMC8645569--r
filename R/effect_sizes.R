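new_effect_size <- function(estimate, method, n1, n2, ci = NULL,
                            ci_level = NA_real_) {
  structure(
    list(estimate = estimate, method = method, n1 = n1, n2 = n2,
         ci_low = if (is.null(ci)) NA_real_ else ci[1],
         ci_high = if (is.null(ci)) NA_real_ else ci[2],
         ci_level = ci_level),
    class = "ocl_effect_size")
}

#' @export
print.ocl_effect_size <- function(x, ...) {
  lbl <- c(glass_delta = "Glass's Delta", cohens_d_independent = "Cohen's d",
           cohens_d_paired = "Cohen's d (paired)")[x$method]
  cat(sprintf("%s = %.3f", lbl, x$estimate))
  if (!is.na(x$ci_low)) {
    cat(sprintf(", %d%% CI [%.3f, %.3f]", round(100 * x$ci_level),
                x$ci_low, x$ci_high))
  }
  cat(sprintf("  (n1 = %d, n2 = %d)\n", x$n1, x$n2))
  invisible(x)
}

#' @export
tidy.ocl_effect_size <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate,
         ci_low = x$ci_low, ci_high = x$ci_high, ci_level = x$ci_level,
         n1 = x$n1, n2 = x$n2)
}

#' Glass's delta
#'
#' Between-group effect size standardized by the control group's SD alone:
#' `(mean(control) - mean(patient)) / sd(control)`, so impairment in the
#' patient group is positive. Used when the patient group's variance cannot
#' be assumed equal to the control variance. The confidence interval is a
#' seeded nonparametric bootstrap (percentile method, resampling each group
#' independently).
#'
#' @param control,patient Numeric score vectors (each n >= 2).
#' @param ci_level Confidence level for the bootstrap CI.
#' @param n_boot Bootstrap resamples (default 10000; 0 skips the CI).
#' @param seed Optional seed for the bootstrap.
#' @return An `ocl_effect_size`; see also [tidy()].
#' @examples
#' glass_delta(c(1.0, 1.2), c(0.8, 0.8), n_boot = 0)  # 2.121
#' @export
glass_delta <- function(control, patient, ci_level = 0.95, n_boot = 10000L,
                        seed = NULL) {
  if (length(control) < 2 || length(patient) < 2) {
    abort("Both groups need at least 2 observations.")
  }
  s_c <- sd(control)
  if (s_c <= 0) abort("Control group has zero variance; delta is undefined.")
  est <- (mean(control) - mean(patient)) / s_c
  ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(i) {
        cb <- sample(control, replace = TRUE)
        pb <- sample(patient, replace = TRUE)
        sc <- sd(cb)
        if (sc <= 0) return(NA_real_)
        (mean(cb) - mean(pb)) / sc
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c((1 - ci_level) / 2, (1 + ci_level) / 2),
                          na.rm = TRUE))
  }
  new_effect_size(est, "glass_delta", length(control), length(patient),
                  ci, ci_level)
}

#' Cohen's d
#'
#' Independent-groups d uses the pooled SD (n - 1 denominators); paired d is
#' the mean within-pair difference divided by the SD of the differences.
#'
#' @param x,y Numeric score vectors; equal length when `paired`.
#' @param paired Compute the paired variant?
#' @inheritParams glass_delta
#' @return An `ocl_effect_size`.
#' @examples
#' cohens_d(c(0, 0, 1, 1), c(1, 1, 2, 2))  # -1.732
#' @export
cohens_d <- function(x, y, paired = FALSE, ci_level = 0.95, n_boot = 0L,
                     seed = NULL) {
  if (paired) {
    if (length(x) != length(y)) abort("Paired groups must have equal length.")
    d <- x - y
    s <- sd(d)
    # constant shifts leave only float jitter in the differences
    if (s <= 1e-10 * (abs(mean(d)) + .Machine$double.eps)) {
      abort("Zero SD of paired differences; d is undefined.")
    }
    est <- mean(d) / s
    method <- "cohens_d_paired"
    boot_fun <- function() {
      i <- sample.int(length(d), replace = TRUE)
      if (sd(d[i]) <= 0) return(NA_real_)
      mean(d[i]) / sd(d[i])
    }
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) abort("Both groups need at least 2 observations.")
    pooled <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    if (pooled <= 0) abort("Zero pooled SD; d is undefined.")
    est <- (mean(x) - mean(y)) / pooled
    method <- "cohens_d_independent"
    boot_fun <- function() {
      xb <- sample(x, replace = TRUE); yb <- sample(y, replace = TRUE)
      pb <- sqrt(((n1 - 1) * var(xb) + (n2 - 1) * var(yb)) / (n1 + n2 - 2))
      if (pb <= 0) return(NA_real_)
      (mean(xb) - mean(yb)) / pb
    }
  }
  ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed_if(seed, vapply(seq_len(n_boot),
                                       function(i) boot_fun(), numeric(1)))
    ci <- unname(quantile(boots, c((1 - ci_level) / 2, (1 + ci_level) / 2),
                          na.rm = TRUE))
  }
  new_effect_size(est, method, length(x), length(y), ci, ci_level)
}

#' Unstandardized group-by-form interaction
#'
#' Difference-in-differences of four cell means: how much larger the
#' easy-minus-hard form advantage is in controls than in patients. Equals
#' the group x form interaction coefficient of a two-factor cell-means
#' model.
#'
#' @param control_easy,control_hard,patient_easy,patient_hard Cell means on
#'   the transformed scale.
#' @return A single number (same units as the scores).
#' @examples
#' interaction_effect(1.09, 1.00, 0.80, 0.80)  # 0.09
#' @export
interaction_effect <- function(control_easy, control_hard,
                               patient_easy, patient_hard) {
  check_number(control_easy, "control_easy", len = 1)
  check_number(control_hard, "control_hard", len = 1)
  check_number(patient_easy, "patient_easy", len = 1)
  check_number(patient_hard, "patient_hard", len = 1)
  (control_easy - control_hard) - (patient_easy - patient_hard)
}

#' Two-group t contrast with automatic Welch correction
#'
#' Convenience wrapper used to decompose interactions: a paired t-test for
#' within-subject contrasts, and for independent groups an F test of
#' variance equality decides between the pooled and the Welch
#' degrees-of-freedom approximation.
#'
#' @param x,y Numeric vectors.
#' @param paired Paired contrast?
#' @param var_alpha Significance level of the variance-ratio pre-test.
#' @return A one-row tibble: `estimate`, `t`, `df`, `p_value`, `method`.
#' @examples
#' group_contrast(rnorm(20, 1), rnorm(20, 0.5))
#' @export
group_contrast <- function(x, y, paired = FALSE, var_alpha = 0.05) {
  if (paired) {
    ht <- t.test(x, y, paired = TRUE)
    method <- "paired"
  } else {
    welch <- var.test(x, y)$p.value < var_alpha
    ht <- t.test(x, y, var.equal = !welch)
    method <- if (welch) "welch" else "pooled"
  }
  est <- if (paired) mean(x - y) else mean(x) - mean(y)
  tibble(estimate = est,
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, method = method)
}
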