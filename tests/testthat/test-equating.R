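test_that("clamping and binning follow the chance-floor rule", {
  d <- clamp_and_bin(c(0.60, 0.79, 1.05))
  expect_equal(attr(d, "n"), 3)
  expect_equal(attr(d, "clamped"), 1)
  expect_equal(d$count[d$score == 0.79], 2)
  expect_equal(d$count[d$score == 1.05], 1)
  expect_equal(sum(d$count), 3)
  # the exact maximum bins at the top grid point
  top <- clamp_and_bin(pi / 2)
  expect_equal(top$count[79], 1)
  # midpoints round up
  mid <- clamp_and_bin(0.795)
  expect_equal(mid$count[mid$score == 0.80], 1)
})

test_that("empty distributions are refused downstream", {
  empty <- clamp_and_bin(numeric(0))
  expect_equal(attr(empty, "n"), 0)
  expect_error(percentile_rank(empty, 1.05), "empty")
  expect_error(loglinear_presmooth(empty), "empty")
  expect_error(equipercentile(empty, empty), "empty")
})

test_that("percentile ranks use the half-count convention", {
  one_point <- clamp_and_bin(rep(1.05, 10))
  expect_equal(percentile_rank(one_point, 1.05), 50)
  uniform <- freqdist_from_counts(rep(5, 79))
  expect_equal(percentile_rank(uniform, score_grid()[40]), 50)
  # zero mass at the lowest point, everything above
  above <- freqdist_from_counts(c(0, rep(1, 78)))
  expect_equal(percentile_rank(above, 0.79), 0)
  expect_error(percentile_rank(one_point, 1.051), "grid")
})

test_that("equating a distribution to itself is the identity on all 79 points", {
  counts <- smooth_counts(1.07, 0.11)
  d <- freqdist_from_counts(counts)
  eq <- equipercentile(d, d)
  expect_equal(eq$equated_y, eq$x_score, tolerance = 1e-9)
  # also exact for integer raw counts with full support
  d2 <- freqdist_from_counts(withr::with_seed(101, rpois(79, 30) + 1))
  eq2 <- equipercentile(d2, d2)
  expect_equal(eq2$equated_y, eq2$x_score, tolerance = 1e-9)
})

test_that("a constant shift between forms is recovered within a grid step", {
  counts_x <- smooth_counts(1.00, 0.08)
  counts_y <- c(rep(1e-8, 8), counts_x[1:71])  # Y sits 0.08 higher
  eq <- equipercentile(freqdist_from_counts(counts_x),
                       freqdist_from_counts(counts_y))
  mid <- which(score_grid() >= 0.90 & score_grid() <= 1.10)
  expect_lt(max(abs(eq$equated_y[mid] - (eq$x_score[mid] + 0.08))), 0.0101)
})

test_that("equated scores are monotone and stay on the score range", {
  withr::with_seed(71, {
    for (i in 1:25) {
      cx <- rpois(79, rexp(79, 1 / 20))
      cy <- rpois(79, rexp(79, 1 / 20))
      if (sum(cx) == 0 || sum(cy) == 0) next
      eq <- equipercentile(freqdist_from_counts(cx), freqdist_from_counts(cy))
      expect_true(all(diff(eq$equated_y) >= 0))
      expect_true(all(eq$equated_y >= 0.79 & eq$equated_y <= 1.57))
    }
  })
})

test_that("presmoothing preserves n and the first `degree` moments", {
  scores <- withr::with_seed(73, pmin(pmax(rnorm(400, 1.05, 0.12), 0), pi / 2))
  d <- clamp_and_bin(scores)
  g <- score_grid()
  for (degree in 1:4) {
    sm <- loglinear_presmooth(d, degree)
    expect_equal(sum(sm$count), sum(d$count), tolerance = 1e-6)
    for (j in seq_len(degree)) {
      raw_m <- sum(d$count * g^j) / sum(d$count)
      sm_m <- sum(sm$count * g^j) / sum(sm$count)
      expect_equal(sm_m, raw_m, tolerance = 1e-6)
    }
  }
})

test_that("a geometric distribution is a fixed point of degree-1 smoothing", {
  counts <- 1e4 * 0.93^(0:78)
  d <- freqdist_from_counts(counts)
  sm <- loglinear_presmooth(d, degree = 1)
  expect_lt(max(abs(sm$count - counts) / counts), 1e-4)
})

test_that("degree-3 smoothing of a unimodal sample is strictly positive", {
  scores <- withr::with_seed(79, pmin(pmax(rnorm(2000, 1.07, 0.11), 0), pi / 2))
  sm <- loglinear_presmooth(clamp_and_bin(scores), 3)
  expect_true(all(sm$count > 0))
})

test_that("round-trip equating of smoothed large samples is near identity", {
  withr::with_seed(83, {
    sx <- pmin(pmax(rnorm(5000, 1.07, 0.11), 0), pi / 2)
    sy <- pmin(pmax(rnorm(5000, 0.99, 0.10), 0), pi / 2)
  })
  dx <- loglinear_presmooth(clamp_and_bin(sx), 3)
  dy <- loglinear_presmooth(clamp_and_bin(sy), 3)
  fwd <- equipercentile(dx, dy)
  bwd <- equipercentile(dy, dx)
  # compose on well-populated mid-range X points
  mid <- which(score_grid() >= 0.90 & score_grid() <= 1.25)
  y_vals <- fwd$equated_y[mid]
  back <- stats::approx(bwd$x_score, bwd$equated_y, xout = y_vals)$y
  expect_lt(max(abs(back - fwd$x_score[mid])), 0.0101)
})

test_that("the paired bootstrap is deterministic and flags degenerate input", {
  withr::with_seed(89, {
    paired <- tibble::tibble(
      score_x = pmin(pmax(rnorm(150, 1.07, 0.11), 0), pi / 2),
      score_y = pmin(pmax(rnorm(150, 0.99, 0.10), 0), pi / 2))
  })
  f1 <- equate_forms(paired, B = 120, seed = 7)
  f2 <- equate_forms(paired, B = 120, seed = 7)
  expect_identical(f1$x_to_y$se_boot, f2$x_to_y$se_boot)
  expect_true(all(f1$x_to_y$se_boot >= 0, na.rm = TRUE))
  expect_warning(equate_forms(paired, B = 50, seed = 1), "B < 100")
  # identical subjects leave no resampling variance at the mass point
  degen <- tibble::tibble(score_x = rep(1.05, 20), score_y = rep(1.0, 20))
  fd <- suppressWarnings(equate_forms(degen, B = 100, seed = 3))
  g <- score_grid()
  expect_lt(fd$x_to_y$se_boot[g == 1.05], 1e-8)
})

test_that("bootstrap SEs grow toward the top of the scale", {
  withr::with_seed(97, {
    paired <- tibble::tibble(
      score_x = pmin(pmax(rnorm(400, 1.07, 0.11), 0), pi / 2),
      score_y = pmin(pmax(rnorm(400, 0.99, 0.10), 0), pi / 2))
  })
  fit <- equate_forms(paired, B = 200, seed = 11)
  se <- fit$x_to_y$se_boot
  g <- score_grid()
  top <- mean(se[g >= 1.40])
  mid <- mean(se[g >= 1.00 & g <= 1.15])
  expect_gt(top, mid)
  # the weighted mean SE discounts the sparse extremes
  expect_lt(fit$weighted_mean_se["x_to_y"], fit$mean_se["x_to_y"])
})

test_that("attainable correct counts map onto their display scores", {
  lookup <- score_to_n_correct(48)
  expect_equal(lookup$score[lookup$n_correct == 24], 0.79)
  expect_equal(lookup$score[lookup$n_correct == 36], 1.05)
  expect_equal(lookup$score[lookup$n_correct == 48], 1.57)
  expect_equal(nrow(lookup), 25)
})
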