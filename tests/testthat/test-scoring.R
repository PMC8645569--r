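test_that("the transform maps chance and ceiling to the published bounds", {
  expect_equal(transform_proportion(0.5), pi / 4, tolerance = 1e-12)
  expect_equal(transform_proportion(1), pi / 2, tolerance = 1e-12)
  expect_equal(format_score(transform_proportion(0.5)), "0.79")
  expect_equal(format_score(transform_proportion(1)), "1.57")
  expect_equal(format_score(transform_proportion(36 / 48)), "1.05")
  expect_equal(chance_score(), transform_proportion(0.5))
  expect_equal(max_score(), transform_proportion(1))
  expect_error(transform_proportion(1.2), "lie in")
  expect_error(transform_proportion(-0.1), "lie in")
})

test_that("the transform is strictly increasing with an exact inverse", {
  p <- seq(0, 1, by = 0.001)
  s <- transform_proportion(p)
  expect_true(all(diff(s) > 0))
  expect_equal(range(s), c(0, pi / 2), tolerance = 1e-12)
  x <- seq(0, pi / 2, length.out = 500)
  expect_equal(transform_proportion(proportion_from_score(x)), x,
               tolerance = 1e-12)
})

test_that("novelty keying answers 'no' to every first presentation", {
  sch <- ocl_schedule("OCL80", seed = 4)
  keyed <- keyed_answers(sch)
  expect_equal(keyed[1], "no")
  expect_true(all(keyed[sch$trial_type != "target"] == "no"))
  expect_true(all(keyed[sch$trial_type == "target" &
                          sch$presentation_number == 1] == "no"))
  expect_true(all(keyed[sch$presentation_number >= 2] == "yes"))
  # literal alternative: every target trial keyed yes
  keyed2 <- keyed_answers(sch, target_keying = "always_yes")
  expect_true(all(keyed2[sch$trial_type == "target"] == "yes"))
})

test_that("forced correction records exactly one extra attempt when wrong", {
  sch <- ocl_schedule("OCL48", seed = 4)
  sess <- run_session(sch, responder_random(0.5), seed = 1)
  expect_equal(sess$attempts == 1L, sess$correct)
  expect_true(all(sess$attempts %in% 1:2))
})

test_that("reference responders reproduce the counting identities", {
  s80 <- ocl_schedule("OCL80", seed = 6)
  s48 <- ocl_schedule("OCL48", seed = 6)
  expect_equal(sum(run_session(s48, responder_keyed())$correct), 48)
  # an always-yes responder is correct only on the 28 target re-presentations
  yes <- run_session(s80, responder_fixed("yes"))
  expect_equal(sum(yes$correct), 28)
  expect_equal(mean(yes$correct), 0.35)
  short_responder <- function(schedule, keyed) keyed[-1]
  expect_error(run_session(s48, short_responder), "responses")
})

test_that("a fixed-accuracy responder recovers its accuracy over sessions", {
  sch <- ocl_schedule("OCL48", seed = 8)
  p_hat <- withr::with_seed(21, {
    vapply(1:1000, function(i) {
      mean(run_session(sch, responder_accuracy(0.7))$correct)
    }, numeric(1))
  })
  se <- sqrt(0.7 * 0.3 / (48 * 1000))
  expect_lt(abs(mean(p_hat) - 0.7), 3 * se)
})

test_that("session scores aggregate first responses by trial type", {
  sch <- ocl_schedule("OCL48", seed = 10)
  perfect <- score_session(run_session(sch, responder_keyed()))
  expect_equal(perfect$s_overall, pi / 2, tolerance = 1e-12)

  half <- session_with_counts(sch, list(target = 12, lure = 3, foil = 9))
  sc_half <- score_session(half)
  expect_equal(sc_half$p_overall, 0.5)
  expect_equal(sc_half$s_overall, pi / 4, tolerance = 1e-12)

  mixed <- session_with_counts(sch, list(target = 20, lure = 3, foil = 13))
  sc <- score_session(mixed)
  expect_equal(sc$p_overall, 36 / 48)
  expect_equal(sc$s_overall, transform_proportion(0.75), tolerance = 1e-12)
  expect_equal(format_score(sc$s_overall), "1.05")
  # per-type correct counts add up to the overall count
  expect_equal(sc$p_target * sc$n_target + sc$p_lure * sc$n_lure +
                 sc$p_foil * sc$n_foil,
               sc$p_overall * sc$n_trials)
  expect_error(score_session(mixed[0, ]), "non-empty")
})

test_that("floor/ceiling flags use a strict 10% rule", {
  none <- floor_ceiling_flags(rep(1.1, 23))
  expect_false(none$ceiling)
  expect_false(none$floor)

  three_max <- floor_ceiling_flags(c(rep(1.1, 20), rep(max_score(), 3)))
  expect_true(three_max$ceiling)
  expect_equal(three_max$prop_ceiling, 3 / 23)

  # exactly 10% does not trigger the flag
  ten_pct <- floor_ceiling_flags(c(rep(1.1, 9), chance_score()))
  expect_false(ten_pct$floor)
  expect_equal(ten_pct$prop_floor, 0.1)
  expect_error(floor_ceiling_flags(numeric(0)), "non-empty")
})
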