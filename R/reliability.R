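#' Intraclass correlation for repeated sessions
#'
#' Variance-component reliability of a subjects-by-sessions score table.
#' The default is the one-way random, single-measure ICC,
#' `(MSB - MSW) / (MSB + (k - 1) MSW)`, with an F-based confidence
#' interval; two-way consistency (ICC(3,1)) and two-way agreement
#' (ICC(2,1), McGraw-Wong CI) are selectable. Per-subject standard
#' deviations across sessions and their mean (the within-subject SD) are
#' returned alongside.
#'
#' Input may be a numeric matrix (subjects x sessions), a wide data frame
#' (an optional subject-id column plus one column per session), or a long
#' tibble such as the output of [simulate_retest()] (columns named by the
#' `subject`, `session`, `score` arguments). Incomplete subjects are
#' dropped.
#'
#' @param x Score table.
#' @param model `"oneway"`, `"twoway_consistency"` or `"twoway_agreement"`.
#' @param ci_level Confidence level.
#' @param subject,session,score Column names used when `x` is long.
#' @param ... Passed between methods.
#' @return An `ocl_icc` list: `icc`, `ci_low`, `ci_high`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `model`, `n`, `k`, `wsd` (per-subject tibble) and
#'   `wsd_mean`.
#' @examples
#' m <- cbind(a = c(0.9, 1.1, 1.3), b = c(1.0, 1.1, 1.2),
#'            c = c(0.9, 1.2, 1.3))
#' icc(m)
#' @export
icc <- function(x, ...) UseMethod("icc")

#' @rdname icc
#' @export
icc.matrix <- function(x, model = c("oneway", "twoway_consistency",
                                    "twoway_agreement"),
                       ci_level = 0.95, ...) {
  model <- match.arg(model)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) abort("Need at least 2 complete subjects and 2 sessions.")

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  msb <- ss_rows / (n - 1)

  alpha <- 1 - ci_level
  if (model == "oneway") {
    msw <- (ss_total - ss_rows) / (n * (k - 1))
    df1 <- n - 1; df2 <- n * (k - 1)
    if (msw <= 0) {
      est <- 1; f_stat <- Inf; p <- 0; ci <- c(NA_real_, NA_real_)
    } else {
      f_stat <- msb / msw
      est <- (f_stat - 1) / (f_stat + k - 1)
      p <- pf(f_stat, df1, df2, lower.tail = FALSE)
      fl <- f_stat / qf(1 - alpha / 2, df1, df2)
      fu <- f_stat * qf(1 - alpha / 2, df2, df1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    mse <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    if (mse <= 0) {
      est <- 1; f_stat <- Inf; p <- 0; ci <- c(NA_real_, NA_real_)
    } else {
      f_stat <- msb / mse
      p <- pf(f_stat, df1, df2, lower.tail = FALSE)
      if (model == "twoway_consistency") {
        est <- (msb - mse) / (msb + (k - 1) * mse)
        fl <- f_stat / qf(1 - alpha / 2, df1, df2)
        fu <- f_stat * qf(1 - alpha / 2, df2, df1)
        ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
      } else {
        msc <- ss_cols / (k - 1)
        est <- (msb - mse) /
          (msb + (k - 1) * mse + k * (msc - mse) / n)
        # McGraw & Wong (1996) approximate CI for ICC(A,1)
        a <- k * est / (n * (1 - est))
        b <- 1 + k * est * (n - 1) / (n * (1 - est))
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        f_l <- qf(1 - alpha / 2, n - 1, v)
        f_u <- qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msb - f_l * mse) /
          (f_l * (k * msc + (k * n - k - n) * mse) + n * msb)
        hi <- n * (f_u * msb - mse) /
          (k * msc + (k * n - k - n) * mse + n * f_u * msb)
        ci <- c(lo, hi)
      }
    }
  }
  wsd <- apply(x, 1, sd)
  structure(
    list(icc = est, ci_low = ci[1], ci_high = ci[2], ci_level = ci_level,
         f_stat = f_stat, df1 = df1, df2 = df2, p_value = p, model = model,
         n = n, k = k,
         wsd = tibble(subject = rownames(x) %||% as.character(seq_len(n)),
                      wsd = unname(wsd)),
         wsd_mean = mean(wsd)),
    class = "ocl_icc")
}

#' @rdname icc
#' @export
icc.data.frame <- function(x, model = "oneway", ci_level = 0.95,
                           subject = "subject_id", session = "session",
                           score = "s_overall", ...) {
  if (all(c(subject, session, score) %in% names(x))) {
    wide <- x |>
      select(all_of(c(subject, session, score))) |>
      pivot_wider(names_from = all_of(session), values_from = all_of(score))
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide[[1]])
  } else {
    is_id <- vapply(x, function(col) is.character(col) || is.factor(col),
                    logical(1))
    m <- as.matrix(x[, !is_id, drop = FALSE])
    if (any(is_id)) rownames(m) <- as.character(x[[which(is_id)[1]]])
  }
  icc(m, model = model, ci_level = ci_level)
}

#' @export
print.ocl_icc <- function(x, ...) {
  cat(sprintf(
    "ICC(%s) = %.3f, %d%% CI [%.3f, %.3f]; F(%d, %d) = %.3f, p = %.3g\n",
    x$model, x$icc, round(100 * x$ci_level), x$ci_low, x$ci_high,
    x$df1, x$df2, x$f_stat, x$p_value))
  cat(sprintf("mean within-subject SD = %.3f (n = %d subjects, k = %d sessions)\n",
              x$wsd_mean, x$n, x$k))
  invisible(x)
}

#' @export
tidy.ocl_icc <- function(x, ...) x$wsd

#' @export
glance.ocl_icc <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
         f_stat = x$f_stat, df1 = x$df1, df2 = x$df2, p_value = x$p_value,
         model = x$model, n = x$n, k = x$k, wsd_mean = x$wsd_mean)
}

#' Hotelling T-squared profile analysis
#'
#' Tests whether mean performance differs across repeated sessions by a
#' one-sample Hotelling T-squared on the k - 1 adjacent-session difference
#' scores: flatness of the profile means all differences are zero. The F
#' conversion is `F = T2 (n - k + 1) / ((n - 1)(k - 1))` on
#' (k - 1, n - k + 1) degrees of freedom.
#'
#' @inheritParams icc
#' @return An `ocl_profile` list: `t2`, `f_stat`, `df1`, `df2`, `p_value`,
#'   `n`, `k`, `degenerate`.
#' @examples
#' m <- matrix(rnorm(66, 1.1, 0.1), 22, 3)
#' hotelling_profile(m)
#' @export
hotelling_profile <- function(x, ...) UseMethod("hotelling_profile")

#' @rdname hotelling_profile
#' @export
hotelling_profile.matrix <- function(x, ...) {
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2) abort("Need at least 2 sessions.")
  if (n <= k - 1) abort("Need more subjects than difference scores (n > k - 1).")
  d <- x[, -1, drop = FALSE] - x[, -k, drop = FALSE]
  dbar <- colMeans(d)
  s <- cov(d)
  if (all(abs(d) < 1e-12)) {
    return(structure(
      list(t2 = 0, f_stat = 0, df1 = k - 1, df2 = n - k + 1, p_value = 1,
           n = n, k = k, degenerate = TRUE),
      class = "ocl_profile"))
  }
  qr_s <- qr(s)
  if (qr_s$rank < k - 1) {
    abort("Covariance of difference scores is singular; T2 is undefined.")
  }
  t2 <- n * drop(crossprod(dbar, solve(s, dbar)))
  f_stat <- hotelling_f(t2, n, k)
  structure(
    list(t2 = t2, f_stat = f_stat, df1 = k - 1, df2 = n - k + 1,
         p_value = pf(f_stat, k - 1, n - k + 1, lower.tail = FALSE),
         n = n, k = k, degenerate = FALSE),
    class = "ocl_profile")
}

#' @rdname hotelling_profile
#' @inheritParams icc.data.frame
#' @export
hotelling_profile.data.frame <- function(x, subject = "subject_id",
                                         session = "session",
                                         score = "s_overall", ...) {
  if (all(c(subject, session, score) %in% names(x))) {
    wide <- x |>
      select(all_of(c(subject, session, score))) |>
      pivot_wider(names_from = all_of(session), values_from = all_of(score))
    m <- as.matrix(wide[, -1, drop = FALSE])
  } else {
    is_id <- vapply(x, function(col) is.character(col) || is.factor(col),
                    logical(1))
    m <- as.matrix(x[, !is_id, drop = FALSE])
  }
  hotelling_profile(m)
}

#' T-squared to F conversion for a profile analysis
#'
#' @param t2 Hotelling statistic on k - 1 difference scores.
#' @param n Number of subjects.
#' @param k Number of repeated sessions.
#' @return The F statistic on (k - 1, n - k + 1) degrees of freedom.
#' @examples
#' hotelling_f(0.50, n = 22, k = 3)  # 0.238 -> displays as 0.24
#' @export
hotelling_f <- function(t2, n, k) {
  check_number(t2, "t2", lower = 0, len = 1)
  t2 * (n - k + 1) / ((n - 1) * (k - 1))
}

#' @export
print.ocl_profile <- function(x, ...) {
  cat(sprintf("Hotelling T2 = %.3f, F(%d, %d) = %.3f, p = %.3g%s\n",
              x$t2, x$df1, x$df2, x$f_stat, x$p_value,
              if (x$degenerate) " [degenerate: identical sessions]" else ""))
  invisible(x)
}

#' @export
glance.ocl_profile <- function(x, ...) {
  tibble(t2 = x$t2, f_stat = x$f_stat, df1 = x$df1, df2 = x$df2,
         p_value = x$p_value, n = x$n, k = x$k, degenerate = x$degenerate)
}

#' @export
tidy.ocl_profile <- function(x, ...) glance(x)
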