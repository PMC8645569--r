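#' Test form configuration
#'
#' Describes one OCL form: how many presentation cycles it has, how many
#' target cards, and how many distractors (lures and foils) accompany each
#' cycle. Two canonical presets are shipped:
#'
#' * `"OCL80"`: 8 cycles of 4 targets + 6 distractors (12 lures, 36 foils;
#'   80 trials).
#' * `"OCL48"`: 6 cycles of 4 targets + 4 distractors (6 lures, 18 foils;
#'   48 trials) — the reduced-difficulty form.
#'
#' Both presets keep the 3:1 foil-to-lure ratio. Custom configurations are
#' accepted as long as the distractor pools fit the deck: at most
#' `3 * n_targets` lures (the same-rank cards) and `52 - 4 * n_targets`
#' foils.
#'
#' @param form `"OCL80"`, `"OCL48"`, or `NULL` for a custom configuration.
#' @param n_cycles Number of presentation cycles (each shows every target
#'   once).
#' @param n_targets Number of target cards, one per suit (must be 4 for the
#'   canonical deck constraint "one from each suit").
#' @param distractors_per_cycle Distractors interleaved within each cycle.
#' @param n_lures,n_foils Total lure and foil counts; must sum to
#'   `n_cycles * distractors_per_cycle`.
#' @param seed Optional integer seed stored with the configuration and used
#'   by [ocl_schedule()] when no explicit seed is given.
#' @return An `ocl_config` list with fields `form`, `n_cycles`, `n_targets`,
#'   `distractors_per_cycle`, `n_lures`, `n_foils`, `n_trials`, `seed`.
#' @examples
#' ocl_config("OCL48")
#' ocl_config(n_cycles = 4, distractors_per_cycle = 3, n_lures = 3, n_foils = 9)
#' @export
ocl_config <- function(form = NULL, n_cycles = NULL, n_targets = 4L,
                       distractors_per_cycle = NULL, n_lures = NULL,
                       n_foils = NULL, seed = NULL) {
  presets <- list(
    OCL80 = list(n_cycles = 8L, distractors_per_cycle = 6L,
                 n_lures = 12L, n_foils = 36L),
    OCL48 = list(n_cycles = 6L, distractors_per_cycle = 4L,
                 n_lures = 6L, n_foils = 18L)
  )
  if (!is.null(form)) {
    form <- match.arg(form, names(presets))
    p <- presets[[form]]
    n_cycles <- n_cycles %||% p$n_cycles
    distractors_per_cycle <- distractors_per_cycle %||% p$distractors_per_cycle
    n_lures <- n_lures %||% p$n_lures
    n_foils <- n_foils %||% p$n_foils
  } else {
    form <- "custom"
  }
  if (is.null(n_cycles) || is.null(distractors_per_cycle) ||
      is.null(n_lures) || is.null(n_foils)) {
    abort("Custom configs need n_cycles, distractors_per_cycle, n_lures, n_foils.")
  }
  n_cycles <- as.integer(n_cycles)
  n_targets <- as.integer(n_targets)
  distractors_per_cycle <- as.integer(distractors_per_cycle)
  n_lures <- as.integer(n_lures)
  n_foils <- as.integer(n_foils)

  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(n_targets, "n_targets", lower = 1, upper = 4)
  check_number(distractors_per_cycle, "distractors_per_cycle", lower = 1)
  check_number(n_lures, "n_lures", lower = 0)
  check_number(n_foils, "n_foils", lower = 0)
  if (n_targets != 4L) {
    abort("`n_targets` must be 4: one target from each suit.")
  }
  if (n_lures + n_foils != n_cycles * distractors_per_cycle) {
    abort("n_lures + n_foils must equal n_cycles * distractors_per_cycle.")
  }
  if (n_lures > 3L * n_targets) {
    abort(sprintf(
      "Config requests %d lures but only %d same-rank cards exist.",
      n_lures, 3L * n_targets))
  }
  if (n_foils > 52L - 4L * n_targets) {
    abort(sprintf(
      "Config requests %d foils but only %d non-target-rank cards exist.",
      n_foils, 52L - 4L * n_targets))
  }

  structure(
    list(
      form = form,
      n_cycles = n_cycles,
      n_targets = n_targets,
      distractors_per_cycle = distractors_per_cycle,
      n_lures = n_lures,
      n_foils = n_foils,
      n_trials = n_cycles * (n_targets + distractors_per_cycle),
      seed = if (!is.null(seed)) as.integer(seed) else NULL
    ),
    class = "ocl_config"
  )
}

#' @export
print.ocl_config <- function(x, ...) {
  cat(sprintf(
    "<ocl_config %s> %d trials: %d cycles x (%d targets + %d distractors); %d lures, %d foils\n",
    x$form, x$n_trials, x$n_cycles, x$n_targets, x$distractors_per_cycle,
    x$n_lures, x$n_foils))
  invisible(x)
}

as_ocl_config <- function(x) {
  if (inherits(x, "ocl_config")) return(x)
  if (is.character(x) && length(x) == 1L) return(ocl_config(form = x))
  abort("Expected an `ocl_config` or a form name (\"OCL80\"/\"OCL48\").")
}
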