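#' Select target cards from a deck
#'
#' Draws the target cards for one test administration: one card per suit,
#' rank uniform within suit, with the additional requirement that the four
#' target ranks are pairwise distinct so that every target owns its own
#' three same-rank lures. Draws with a repeated rank are rejected and
#' redrawn; because the acceptance region is invariant under any common
#' relabelling of ranks, the per-suit rank marginal stays uniform.
#'
#' @param deck A full 52-card deck from [ocl_deck()].
#' @param n_targets Number of targets (4).
#' @return A 4-row tibble of cards (`rank`, `suit`), one per suit.
#' @examples
#' withr::with_seed(1, select_targets(ocl_deck()))
#' @export
select_targets <- function(deck = ocl_deck(), n_targets = 4L) {
  check_deck(deck)
  if (n_targets != 4L) abort("`n_targets` must be 4, one per suit.")
  suits <- ocl_suits()
  repeat {
    ranks <- vapply(suits, function(s) {
      pool <- deck$rank[as.character(deck$suit) == s]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    if (!anyDuplicated(ranks)) break
  }
  tibble(rank = unname(ranks), suit = factor(suits, levels = suits))
}

#' Select lure and foil cards for a set of targets
#'
#' Lures are the non-target cards sharing a numerical rank with a target
#' (12 candidates when target ranks are distinct); foils are cards sharing
#' no rank with any target (36 candidates). The OCL80 uses every candidate;
#' the OCL48 samples 6 lures and 18 foils uniformly without replacement,
#' with no per-target balancing.
#'
#' @param targets 4-row tibble from [select_targets()].
#' @param config An [ocl_config()] (or form name).
#' @param deck The deck the targets came from.
#' @return A list with tibbles `lures` and `foils`.
#' @examples
#' withr::with_seed(1, {
#'   tg <- select_targets()
#'   select_distractors(tg, ocl_config("OCL48"))
#' })
#' @export
select_distractors <- function(targets, config, deck = ocl_deck()) {
  config <- as_ocl_config(config)
  check_deck(deck)
  if (nrow(targets) != config$n_targets ||
      anyDuplicated(as.character(targets$suit)) ||
      anyDuplicated(targets$rank)) {
    abort("`targets` must be 4 cards with distinct suits and distinct ranks.")
  }
  target_keys <- card_key(targets$rank, targets$suit)
  is_target <- card_key(deck$rank, deck$suit) %in% target_keys
  lure_pool <- deck[deck$rank %in% targets$rank & !is_target, ]
  foil_pool <- deck[!(deck$rank %in% targets$rank), ]
  if (config$n_lures > nrow(lure_pool)) {
    abort(sprintf("Config requests %d lures; only %d same-rank cards available.",
                  config$n_lures, nrow(lure_pool)))
  }
  lures <- lure_pool[sample.int(nrow(lure_pool), config$n_lures), ]
  foils <- foil_pool[sample.int(nrow(foil_pool), config$n_foils), ]
  list(lures = as_tibble(lures), foils = as_tibble(foils))
}

#' Assemble a trial schedule from card pools
#'
#' Interleaves targets and distractors into `n_cycles` consecutive blocks.
#' Each block presents all four targets once, in random order, together with
#' `distractors_per_cycle` distractors allocated at random to cycles (each
#' distractor card appears exactly once in the whole test). Within a block
#' the trial order is uniform; across the block boundary the first target of
#' a cycle is redrawn until it differs from the last target of the previous
#' cycle, so the same target is never presented twice without at least one
#' intervening trial.
#'
#' @param targets,lures,foils Card tibbles (from [select_targets()] and
#'   [select_distractors()]).
#' @param config An [ocl_config()] (or form name).
#' @return An `ocl_schedule` tibble with columns `trial`, `cycle`, `rank`,
#'   `suit`, `trial_type` and `presentation_number`, plus the card pools and
#'   config as attributes.
#' @examples
#' sch <- ocl_schedule("OCL48", seed = 1)
#' dplyr::count(sch, trial_type)
#' @export
assemble_schedule <- function(targets, lures, foils, config) {
  config <- as_ocl_config(config)
  if (nrow(lures) != config$n_lures || nrow(foils) != config$n_foils) {
    abort("Lure/foil pool sizes do not match the configuration.")
  }
  if (nrow(targets) != config$n_targets) {
    abort("Wrong number of targets for the configuration.")
  }
  dist <- bind_rows(
    mutate(as_tibble(lures), trial_type = "lure"),
    mutate(as_tibble(foils), trial_type = "foil")
  )
  # random distractor-to-cycle allocation, constrained to
  # distractors_per_cycle per cycle
  dist <- dist[sample.int(nrow(dist)), ]
  dist$cycle <- rep(seq_len(config$n_cycles),
                    each = config$distractors_per_cycle)

  block_size <- config$n_targets + config$distractors_per_cycle
  prev_last <- NA_character_
  blocks <- vector("list", config$n_cycles)
  for (cy in seq_len(config$n_cycles)) {
    repeat {
      t_order <- sample.int(config$n_targets)
      first_tg <- card_key(targets$rank[t_order[1]], targets$suit[t_order[1]])
      if (is.na(prev_last) || first_tg != prev_last) break
    }
    tg <- targets[t_order, ]
    tg$trial_type <- "target"
    tg$presentation_number <- cy
    dd <- dist[dist$cycle == cy, c("rank", "suit", "trial_type")]
    dd$presentation_number <- 1L
    block <- bind_rows(tg[, c("rank", "suit", "trial_type",
                              "presentation_number")], dd)
    # place targets (in t_order) at uniformly chosen positions
    pos_t <- sort(sample.int(block_size, config$n_targets))
    ord <- integer(block_size)
    ord[pos_t] <- seq_len(config$n_targets)
    ord[-pos_t] <- config$n_targets + seq_len(config$distractors_per_cycle)
    block <- block[ord, ]
    block$cycle <- cy
    prev_last <- card_key(tg$rank[config$n_targets],
                          tg$suit[config$n_targets])
    blocks[[cy]] <- block
  }
  trials <- bind_rows(blocks)
  trials$trial <- seq_len(nrow(trials))
  trials$trial_type <- factor(trials$trial_type,
                              levels = c("target", "lure", "foil"))
  out <- as_tibble(trials[, c("trial", "cycle", "rank", "suit", "trial_type",
                              "presentation_number")])
  new_ocl_schedule(out, config, as_tibble(targets[, c("rank", "suit")]),
                   as_tibble(lures[, c("rank", "suit")]),
                   as_tibble(foils[, c("rank", "suit")]))
}

new_ocl_schedule <- function(trials, config, targets, lures, foils) {
  structure(
    trials,
    config = config,
    targets = targets,
    lures = lures,
    foils = foils,
    class = c("ocl_schedule", class(tibble())))
}

#' Generate a complete test schedule
#'
#' One-call wrapper running the whole generation pipeline under a single
#' seeded random stream consumed in a fixed order (targets, then lures, then
#' foils, then per-cycle trial orders), so a schedule is a pure function of
#' (config, seed).
#'
#' @param form `"OCL80"` or `"OCL48"`, or an [ocl_config()].
#' @param seed Integer seed; falls back to the config's seed; `NULL` uses the
#'   current RNG state (not reproducible).
#' @return An `ocl_schedule` tibble; see [assemble_schedule()].
#' @examples
#' ocl_schedule("OCL80", seed = 42)
#' @export
ocl_schedule <- function(form = "OCL80", seed = NULL) {
  config <- as_ocl_config(form)
  seed <- seed %||% config$seed
  with_seed_if(seed, {
    deck <- ocl_deck()
    targets <- select_targets(deck, config$n_targets)
    pools <- select_distractors(targets, config, deck)
    assemble_schedule(targets, pools$lures, pools$foils, config)
  })
}

#' Accessors for schedule attributes
#'
#' @param schedule An `ocl_schedule`.
#' @return `schedule_config()` the `ocl_config`; the card accessors return
#'   tibbles of cards.
#' @export
schedule_config <- function(schedule) attr(schedule, "config")

#' @rdname schedule_config
#' @export
schedule_targets <- function(schedule) attr(schedule, "targets")

#' @rdname schedule_config
#' @export
schedule_lures <- function(schedule) attr(schedule, "lures")

#' @rdname schedule_config
#' @export
schedule_foils <- function(schedule) attr(schedule, "foils")

#' Validate a trial schedule
#'
#' Checks every structural constraint of the test design and returns a
#' report rather than failing: total trial count, per-type counts, one
#' presentation of each target per cycle, distinct target suits and ranks,
#' lure/foil rank rules, single presentation of each distractor, the
#' distractor-per-cycle quota, the cycle-boundary target rule, and
#' presentation-number bookkeeping.
#'
#' @param schedule An `ocl_schedule` (or a compatible tibble with a config
#'   attribute).
#' @return An `ocl_validation` list: `pass` (logical), `checks` (tibble with
#'   columns `check`, `pass`, `detail`) and `counts` (named trial-type
#'   counts).
#' @examples
#' validate_schedule(ocl_schedule("OCL48", seed = 1))
#' @export
validate_schedule <- function(schedule) {
  config <- schedule_config(schedule)
  if (is.null(config)) abort("Schedule carries no configuration attribute.")
  tg <- schedule_targets(schedule)
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(
      check = name, pass = pass, detail = detail)
  }

  counts <- table(factor(schedule$trial_type,
                         levels = c("target", "lure", "foil")))
  expected <- c(target = config$n_cycles * config$n_targets,
                lure = config$n_lures, foil = config$n_foils)
  add("n_trials", nrow(schedule) == config$n_trials,
      sprintf("%d of %d", nrow(schedule), config$n_trials))
  add("trial_type_counts", all(as.integer(counts) == expected),
      paste(names(counts), as.integer(counts), collapse = ", "))

  key <- card_key(schedule$rank, schedule$suit)
  tg_keys <- card_key(tg$rank, tg$suit)
  is_tg <- key %in% tg_keys

  is_tg_trial <- schedule$trial_type == "target"
  by_cycle <- split(key[is_tg_trial], schedule$cycle[is_tg_trial])
  tg_sorted <- sort(tg_keys)
  add("target_once_per_cycle",
      length(by_cycle) == config$n_cycles &&
        all(vapply(by_cycle, function(kk) identical(sort(kk), tg_sorted),
                   logical(1))),
      "every cycle presents each of the 4 targets exactly once")
  add("target_suits_distinct", !anyDuplicated(as.character(tg$suit)),
      "one target per suit")
  add("target_ranks_distinct", !anyDuplicated(tg$rank),
      "each target owns its same-rank lures")

  lure_rows <- schedule[schedule$trial_type == "lure", ]
  foil_rows <- schedule[schedule$trial_type == "foil", ]
  add("lures_share_target_rank",
      all(lure_rows$rank %in% tg$rank) &&
        !any(card_key(lure_rows$rank, lure_rows$suit) %in% tg_keys),
      "lures match a target rank, are not targets")
  add("foils_avoid_target_ranks", !any(foil_rows$rank %in% tg$rank),
      "foils share no rank with targets")

  dist_keys <- key[schedule$trial_type != "target"]
  add("distractors_once",
      !anyDuplicated(dist_keys) &&
        all(schedule$presentation_number[schedule$trial_type != "target"] == 1L),
      "each lure/foil presented exactly once")
  dpc <- schedule |>
    filter(.data$trial_type != "target") |>
    count(.data$cycle)
  add("distractors_per_cycle",
      nrow(dpc) == config$n_cycles &&
        all(dpc$n == config$distractors_per_cycle),
      sprintf("%d per cycle", config$distractors_per_cycle))

  # same card never on consecutive trials (the once-per-cycle structure plus
  # the boundary rule forbids back-to-back repeats of a target)
  add("no_immediate_repeat", all(key[-1] != key[-length(key)]),
      "no card on two consecutive trials")

  tg_pn <- schedule[is_tg, ]
  add("target_presentation_number",
      all(tg_pn$presentation_number == tg_pn$cycle),
      "presentation number tracks cycle for targets")

  checks <- bind_rows(checks)
  structure(
    list(pass = all(checks$pass), checks = checks,
         counts = setNames(as.integer(counts), names(counts))),
    class = "ocl_validation")
}

#' @export
print.ocl_validation <- function(x, ...) {
  cat(sprintf("<ocl_validation> %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  counts: %s\n",
              paste(names(x$counts), x$counts, collapse = ", ")))
  bad <- x$checks[!x$checks$pass, ]
  if (nrow(bad)) {
    cat("  violations:\n")
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("   - %s (%s)\n", bad$check[i], bad$detail[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.ocl_validation <- function(x, ...) x$checks
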