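#' The equating score grid
#'
#' Scores are equated on a fixed grid from chance (0.79) to maximum (1.57)
#' at 0.01 intervals: 79 points on the 2-decimal display scale of the
#' transformed scores.
#'
#' @return Numeric vector of 79 strictly increasing grid points.
#' @examples
#' range(score_grid()); length(score_grid())
#' @export
score_grid <- function() seq(79L, 157L) / 100

grid_index <- function(x, tol = 1e-6) {
  j <- as.integer(round((x - 0.79) * 100))
  ok <- abs(x - (0.79 + j / 100)) < tol & j >= 0L & j <= 78L
  if (!all(ok)) abort("Scores must lie on the 0.79..1.57 grid.")
  j + 1L
}

new_freqdist <- function(counts, clamped = 0L) {
  if (length(counts) != 79L || any(counts < 0)) {
    abort("A frequency distribution needs 79 non-negative counts.")
  }
  structure(
    tibble(score = score_grid(), count = as.numeric(counts)),
    n = sum(counts), clamped = clamped,
    class = c("ocl_freqdist", class(tibble())))
}

#' Clamp raw scores and bin them onto the equating grid
#'
#' Transformed scores below chance are assigned the chance value 0.79
#' (below-chance performance is not meaningful for equating and clamping
#' avoids discarding those records); every score is then assigned to the
#' nearest grid point, with exact midpoints rounded up.
#'
#' @param scores Transformed scores in \[0, pi/2\].
#' @return An `ocl_freqdist`: a 79-row tibble (`score`, `count`) with
#'   attributes `n` (total) and `clamped` (how many scores were raised to
#'   0.79).
#' @examples
#' clamp_and_bin(c(0.60, 0.79, 1.05))
#' @export
clamp_and_bin <- function(scores) {
  if (length(scores)) check_number(scores, "scores", 0, pi / 2)
  clamped <- sum(scores < 0.79)
  x <- pmax(scores, 0.79)
  j <- pmin(floor((x - 0.79) * 100 + 0.5) + 1L, 79L)
  new_freqdist(tabulate(j, nbins = 79L), clamped = clamped)
}

freq_n <- function(dist) attr(dist, "n")

check_freqdist <- function(dist, arg = "dist") {
  if (!inherits(dist, "ocl_freqdist")) {
    abort(sprintf("`%s` must be an `ocl_freqdist` (see clamp_and_bin()).", arg))
  }
  if (freq_n(dist) <= 0) {
    abort(sprintf("`%s` is empty (n = 0); nothing to equate.", arg))
  }
  invisible(dist)
}

#' Loglinear presmoothing of a score distribution
#'
#' Fits a loglinear (polynomial exponential-family) model to the grid
#' counts by Poisson maximum likelihood: log expected count is a polynomial
#' of the score of the given degree. The fit preserves the total count and
#' the first `degree` raw moments of the distribution (they are the
#' model's sufficient statistics), while smoothing away sampling noise
#' before equating. Degree 3 (mean, variance, skewness) is the standard
#' equating default.
#'
#' @param dist An `ocl_freqdist`.
#' @param degree Polynomial degree (>= 1).
#' @return A smoothed `ocl_freqdist` with fractional expected counts.
#' @examples
#' d <- clamp_and_bin(pmin(rnorm(500, 1.05, 0.1), pi / 2))
#' loglinear_presmooth(d, degree = 3)
#' @export
loglinear_presmooth <- function(dist, degree = 3L) {
  check_freqdist(dist)
  check_number(degree, "degree", lower = 1, len = 1)
  degree <- as.integer(degree)
  z <- (seq_len(79L) - 40) / 23  # centred/scaled grid index for conditioning
  basis <- stats::poly(z, degree = degree, raw = TRUE)
  fit <- suppressWarnings(
    glm(dist$count ~ basis, family = poisson(),
        control = list(epsilon = 1e-10, maxit = 200)))
  if (!fit$converged) {
    abort(sprintf("Loglinear presmoothing of degree %d did not converge.",
                  degree))
  }
  new_freqdist(fitted(fit), clamped = attr(dist, "clamped"))
}

#' Percentile ranks on the equating grid
#'
#' Half-count convention: the rank of a grid point is the percentage of the
#' distribution strictly below it plus half the percentage exactly at it.
#'
#' @param dist An `ocl_freqdist`.
#' @param x Grid scores (each must lie on [score_grid()]).
#' @return Percentile ranks in \[0, 100\].
#' @examples
#' d <- clamp_and_bin(rep(1.05, 10))
#' percentile_rank(d, 1.05)  # 50
#' @export
percentile_rank <- function(dist, x = score_grid()) {
  check_freqdist(dist)
  j <- grid_index(x)
  cum <- c(0, cumsum(dist$count))
  100 * (cum[j] + 0.5 * dist$count[j]) / freq_n(dist)
}

# inverse of the continuized cdf on the grid-index scale.
# counts: 79 values; p: rank fractions in [0, 1]. Piecewise-linear
# continuization over [j - 0.5, j + 0.5]; when p sits exactly on a
# cumulative plateau (zero-count run) the midpoint of the flat interval is
# returned.
inverse_rank_index <- function(p, counts) {
  n <- sum(counts)
  g_cum <- cumsum(counts)
  tol <- 1e-9 * max(n, 1)
  vapply(p, function(pp) {
    pn <- pp * n
    if (pn >= n - tol) {
      j_lo <- match(TRUE, g_cum >= n - tol)
      return((j_lo + 0.5 + 79.5) / 2)
    }
    if (pn <= tol && counts[1] > 0) {
      return(0.5 + pn / counts[1])
    }
    j_hi <- match(TRUE, g_cum > pn + tol)
    j_lo <- match(TRUE, g_cum >= pn - tol)
    if (j_lo < j_hi) {
      # exact plateau: set-valued inverse, return the interval midpoint
      return(((j_lo + 0.5) + (j_hi - 0.5)) / 2)
    }
    prev <- if (j_hi == 1L) 0 else g_cum[j_hi - 1L]
    j_hi - 0.5 + (pn - prev) / counts[j_hi]
  }, numeric(1))
}

index_to_score <- function(e) {
  pmin(pmax(0.79 + (e - 1) / 100, 0.79), 1.57)
}

#' Equipercentile equating between two forms
#'
#' Maps every grid score on form X to the form-Y score with the same
#' continuized percentile rank, allowing the difficulty relation between
#' forms to be non-linear. Ranks use the half-count convention with linear
#' interpolation between grid points; results are clipped to the grid range
#' and are non-decreasing by construction.
#'
#' @param dist_x,dist_y `ocl_freqdist`s on the same grid (ideally
#'   presmoothed, see [loglinear_presmooth()]).
#' @return An `ocl_equating` tibble: `x_score`, `equated_y`.
#' @examples
#' x <- loglinear_presmooth(clamp_and_bin(pmin(rnorm(400, 1.07, 0.11), pi/2)))
#' y <- loglinear_presmooth(clamp_and_bin(pmin(rnorm(400, 0.99, 0.10), pi/2)))
#' equipercentile(x, y)
#' @export
equipercentile <- function(dist_x, dist_y) {
  check_freqdist(dist_x, "dist_x")
  check_freqdist(dist_y, "dist_y")
  p <- percentile_rank(dist_x, score_grid()) / 100
  e <- inverse_rank_index(p, dist_y$count)
  out <- tibble(x_score = score_grid(),
                equated_y = cummax(index_to_score(e)))
  class(out) <- c("ocl_equating", class(tibble()))
  out
}

#' Equate two forms from paired scores, with bootstrap standard errors
#'
#' Full single-group equating pipeline for subjects who took both forms:
#' clamp and bin each margin, presmooth, equate in both directions, and
#' attach nonparametric bootstrap standard errors obtained by resampling
#' subjects (pairs, preserving the dependence between forms) with
#' replacement and repeating the whole clamp/smooth/equate pipeline per
#' replicate. The summary `mean_se` averages the SE over the grid;
#' `weighted_mean_se` weights each grid point by the observed relative
#' frequency of the X form, so sparsely populated extremes do not dominate.
#'
#' @param paired Data frame with one row per subject and the two forms'
#'   transformed scores.
#' @param x,y Names of the score columns (form X equated to form Y).
#' @param degree Presmoothing degree (see [loglinear_presmooth()]).
#' @param B Bootstrap replicates (>= 100 recommended; < 100 warns; 0 skips
#'   SEs).
#' @param seed Seed for the bootstrap.
#' @return An `ocl_equating_fit` list: `x_to_y` and `y_to_x` tibbles
#'   (`x_score`, `equated_y`, `se_boot`), per-direction `mean_se` and
#'   `weighted_mean_se`, `n`, `B`, `degree`, and the number of skipped
#'   degenerate replicates.
#' @examples
#' paired <- tibble::tibble(score_x = pmin(rnorm(200, 1.07, 0.11), pi / 2),
#'                          score_y = pmin(rnorm(200, 0.99, 0.10), pi / 2))
#' fit <- equate_forms(paired, B = 100, seed = 1)
#' glance(fit)
#' @export
equate_forms <- function(paired, x = "score_x", y = "score_y", degree = 3L,
                         B = 1000L, seed = NULL) {
  if (!all(c(x, y) %in% names(paired))) {
    abort(sprintf("`paired` needs columns `%s` and `%s`.", x, y))
  }
  paired <- paired[complete.cases(paired[, c(x, y)]), ]
  n <- nrow(paired)
  if (n < 2) abort("Need at least 2 subjects with both forms.")
  if (B > 0 && B < 100) {
    warn("B < 100 bootstrap replicates gives unstable standard errors.")
  }
  sx <- paired[[x]]
  sy <- paired[[y]]
  dist_x <- clamp_and_bin(sx)
  dist_y <- clamp_and_bin(sy)
  eq_pair <- function(dx, dy) {
    sm_x <- loglinear_presmooth(dx, degree)
    sm_y <- loglinear_presmooth(dy, degree)
    list(xy = equipercentile(sm_x, sm_y)$equated_y,
         yx = equipercentile(sm_y, sm_x)$equated_y)
  }
  point <- eq_pair(dist_x, dist_y)

  se_xy <- se_yx <- rep(NA_real_, 79L)
  n_skipped <- 0L
  if (B > 0) {
    reps_xy <- matrix(NA_real_, B, 79L)
    reps_yx <- matrix(NA_real_, B, 79L)
    with_seed_if(seed, {
      for (b in seq_len(B)) {
        i <- sample.int(n, replace = TRUE)
        res <- tryCatch(eq_pair(clamp_and_bin(sx[i]), clamp_and_bin(sy[i])),
                        error = function(e) NULL)
        if (is.null(res)) {
          n_skipped <- n_skipped + 1L
        } else {
          reps_xy[b, ] <- res$xy
          reps_yx[b, ] <- res$yx
        }
      }
    })
    se_xy <- apply(reps_xy, 2, sd, na.rm = TRUE)
    se_yx <- apply(reps_yx, 2, sd, na.rm = TRUE)
  }
  mk <- function(eq, se) {
    out <- tibble(x_score = score_grid(), equated_y = eq, se_boot = se)
    class(out) <- c("ocl_equating", class(tibble()))
    out
  }
  w_x <- dist_x$count / freq_n(dist_x)
  w_y <- dist_y$count / freq_n(dist_y)
  structure(
    list(x_to_y = mk(point$xy, se_xy), y_to_x = mk(point$yx, se_yx),
         mean_se = c(x_to_y = mean(se_xy), y_to_x = mean(se_yx)),
         weighted_mean_se = c(x_to_y = sum(w_x * se_xy),
                              y_to_x = sum(w_y * se_yx)),
         n = n, B = as.integer(B), degree = as.integer(degree),
         n_skipped = n_skipped),
    class = "ocl_equating_fit")
}

#' @export
print.ocl_equating_fit <- function(x, ...) {
  cat(sprintf(
    "<ocl_equating_fit> n = %d pairs, degree %d presmoothing, B = %d bootstrap\n",
    x$n, x$degree, x$B))
  cat(sprintf("  X -> Y: mean SE = %.4f, weighted mean SE = %.4f\n",
              x$mean_se["x_to_y"], x$weighted_mean_se["x_to_y"]))
  cat(sprintf("  Y -> X: mean SE = %.4f, weighted mean SE = %.4f\n",
              x$mean_se["y_to_x"], x$weighted_mean_se["y_to_x"]))
  if (x$n_skipped > 0) {
    cat(sprintf("  %d degenerate bootstrap replicates skipped\n", x$n_skipped))
  }
  invisible(x)
}

#' @export
tidy.ocl_equating_fit <- function(x, direction = c("x_to_y", "y_to_x"), ...) {
  direction <- match.arg(direction)
  as_tibble(x[[direction]])
}

#' @export
glance.ocl_equating_fit <- function(x, ...) {
  tibble(n = x$n, B = x$B, degree = x$degree, n_skipped = x$n_skipped,
         mean_se_xy = unname(x$mean_se["x_to_y"]),
         weighted_mean_se_xy = unname(x$weighted_mean_se["x_to_y"]),
         mean_se_yx = unname(x$mean_se["y_to_x"]),
         weighted_mean_se_yx = unname(x$weighted_mean_se["y_to_x"]))
}

#' Map grid scores back to attainable correct counts
#'
#' For a form with `n_trials` trials, returns the grid points that equal the
#' 2-decimal display value of `asin(sqrt(k / n_trials))` together with the
#' corresponding `n_correct = k`, for annotating equating tables.
#'
#' @param n_trials Number of trials on the form.
#' @return A tibble `n_correct`, `score` (only attainable, on-grid scores at
#'   or above chance).
#' @examples
#' head(score_to_n_correct(48))
#' @export
score_to_n_correct <- function(n_trials) {
  k <- 0:n_trials
  s <- round_half_up(transform_proportion(k / n_trials), 2)
  keep <- s >= 0.79 - 1e-9
  tibble(n_correct = k[keep], score = pmin(s[keep], 1.57))
}
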