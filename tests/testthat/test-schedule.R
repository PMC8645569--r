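test_that("the deck holds 52 distinct cards, 13 per suit", {
  deck <- ocl_deck()
  expect_equal(nrow(deck), 52)
  expect_equal(unname(table(deck$suit)), rep(13L, 4), ignore_attr = TRUE)
  expect_false(any(duplicated(paste(deck$rank, deck$suit))))
  expect_equal(sum(deck$rank == 2 & deck$suit == "hearts"), 1)
})

test_that("target selection draws one card per suit, deterministically", {
  tg1 <- withr::with_seed(7, select_targets())
  tg2 <- withr::with_seed(7, select_targets())
  expect_identical(tg1, tg2)
  expect_setequal(as.character(tg1$suit), ocl_suits())
  expect_false(any(duplicated(tg1$rank)))
  expect_error(select_targets(ocl_deck()[1:10, ]), "52 distinct")
})

test_that("target ranks are marginally uniform within each suit", {
  draws <- withr::with_seed(11, {
    purrr::map(1:10000, ~ select_targets()$rank)
  })
  m <- do.call(rbind, draws)
  for (j in 1:4) {
    tab <- tabulate(m[, j], nbins = 13)
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 0.001)
  }
})

test_that("distractor pools follow the lure/foil rank rules", {
  withr::with_seed(3, {
    tg <- select_targets()
    d80 <- select_distractors(tg, ocl_config("OCL80"))
    # every same-rank non-target card is a lure; the rest are foils
    expect_equal(nrow(d80$lures), 12)
    expect_equal(nrow(d80$foils), 36)
    expect_setequal(unique(d80$lures$rank), tg$rank)
    expect_false(any(paste(d80$lures$rank, d80$lures$suit) %in%
                       paste(tg$rank, tg$suit)))
    expect_false(any(d80$foils$rank %in% tg$rank))

    d48 <- select_distractors(tg, ocl_config("OCL48"))
    expect_equal(nrow(d48$lures), 6)
    expect_equal(nrow(d48$foils), 18)
    expect_true(all(d48$lures$rank %in% tg$rank))
    expect_false(any(d48$foils$rank %in% tg$rank))
  })
})

test_that("configs demanding more cards than the deck offers are rejected", {
  expect_error(
    ocl_config(n_cycles = 8, distractors_per_cycle = 6, n_lures = 13,
               n_foils = 35),
    "lures")
  expect_error(
    ocl_config(n_cycles = 8, distractors_per_cycle = 6, n_lures = 12,
               n_foils = 35),
    "must equal")
})

test_that("canonical schedules have the exact published trial structure", {
  s80 <- ocl_schedule("OCL80", seed = 1)
  s48 <- ocl_schedule("OCL48", seed = 1)
  expect_equal(nrow(s80), 80)
  expect_equal(nrow(s48), 48)
  expect_equal(max(s80$cycle), 8)
  expect_equal(max(s48$cycle), 6)
  expect_equal(as.vector(table(s80$trial_type)), c(32, 12, 36))
  expect_equal(as.vector(table(s48$trial_type)), c(24, 6, 18))
})

test_that("schedule generation is a pure function of (config, seed)", {
  expect_identical(ocl_schedule("OCL48", seed = 99),
                   ocl_schedule("OCL48", seed = 99))
  expect_false(identical(ocl_schedule("OCL48", seed = 99)$rank,
                         ocl_schedule("OCL48", seed = 100)$rank))
})

test_that("generated schedules satisfy all design constraints over many seeds", {
  for (form in c("OCL80", "OCL48")) {
    expected <- if (form == "OCL80") c(32, 12, 36) else c(24, 6, 18)
    for (seed in 1:1000) {
      sch <- ocl_schedule(form, seed = seed)
      counts <- tabulate(sch$trial_type, 3)
      if (!all(counts == expected)) {
        fail(sprintf("wrong counts for %s seed %d", form, seed))
      }
      # consecutive presentations of a target lie in adjacent cycles with
      # at least one intervening trial
      key <- paste(sch$rank, sch$suit)
      if (any(key[-1] == key[-length(key)])) {
        fail(sprintf("immediate card repeat in %s seed %d", form, seed))
      }
      tg_rows <- sch[sch$trial_type == "target", ]
      gap_ok <- tg_rows |>
        dplyr::mutate(card = paste(rank, suit)) |>
        dplyr::summarise(ok = all(diff(cycle) == 1), .by = card)
      if (!all(gap_ok$ok)) {
        fail(sprintf("target skipped a cycle in %s seed %d", form, seed))
      }
      # boundary rule: first target of a cycle differs from the last target
      # of the previous cycle
      firsts <- tg_rows |>
        dplyr::slice_min(trial, by = cycle) |>
        dplyr::arrange(cycle)
      lasts <- tg_rows |>
        dplyr::slice_max(trial, by = cycle) |>
        dplyr::arrange(cycle)
      k <- nrow(firsts)
      if (any(paste(firsts$rank, firsts$suit)[-1] ==
                paste(lasts$rank, lasts$suit)[-k])) {
        fail(sprintf("boundary target repeat in %s seed %d", form, seed))
      }
      v <- validate_schedule(sch)
      if (!v$pass) {
        fail(sprintf("validation failed for %s seed %d: %s", form, seed,
                     paste(v$checks$check[!v$checks$pass], collapse = ", ")))
      }
    }
  }
  succeed()
})

test_that("validate_schedule reports constructed violations by name", {
  sch <- ocl_schedule("OCL48", seed = 2)
  # swap a target trial's card for a foil card: breaks once-per-cycle
  broken <- sch
  tg_idx <- which(broken$trial_type == "target")[1]
  foil_idx <- which(broken$trial_type == "foil")[1]
  broken$rank[tg_idx] <- broken$rank[foil_idx]
  broken$suit[tg_idx] <- broken$suit[foil_idx]
  v <- validate_schedule(broken)
  expect_false(v$pass)
  expect_true("target_once_per_cycle" %in% v$checks$check[!v$checks$pass])

  # drop the last trial: trial count violation
  short <- sch[-nrow(sch), ]
  attributes(short)[c("config", "targets", "lures", "foils")] <-
    attributes(sch)[c("config", "targets", "lures", "foils")]
  v2 <- validate_schedule(short)
  expect_false(v2$pass)
  expect_true("n_trials" %in% v2$checks$check[!v2$checks$pass])
})
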