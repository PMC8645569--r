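# CSV interchange. All files are UTF-8, comma-separated, with a header row;
# trials and cycles are 1-based; suits use single letters C/D/H/S.

#' Read and write schedule CSV files
#'
#' Columns: `trial`, `cycle`, `rank`, `suit` (C/D/H/S), `trial_type`,
#' `presentation_number`. Reading reconstructs the `ocl_schedule` object
#' (config inferred from the cycle structure, card pools from the rows), so
#' write -> read -> write round-trips byte-identically.
#'
#' @param schedule An `ocl_schedule`.
#' @param path File path.
#' @return `read_schedule()` returns an `ocl_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_schedule(ocl_schedule("OCL48", seed = 1), p)
#' validate_schedule(read_schedule(p))$pass
#' @export
write_schedule <- function(schedule, path) {
  out <- tibble(
    trial = schedule$trial,
    cycle = schedule$cycle,
    rank = schedule$rank,
    suit = suit_to_letter(schedule$suit),
    trial_type = as.character(schedule$trial_type),
    presentation_number = schedule$presentation_number
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    trial = readr::col_integer(), cycle = readr::col_integer(),
    rank = readr::col_integer(), suit = readr::col_character(),
    trial_type = readr::col_character(),
    presentation_number = readr::col_integer()))
  required <- c("trial", "cycle", "rank", "suit", "trial_type",
                "presentation_number")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Schedule file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  trials <- tibble(
    trial = raw$trial, cycle = raw$cycle, rank = raw$rank,
    suit = letter_to_suit(raw$suit),
    trial_type = factor(raw$trial_type,
                        levels = c("target", "lure", "foil")),
    presentation_number = raw$presentation_number)
  n_cycles <- max(trials$cycle)
  counts <- table(trials$trial_type)
  n_targets <- as.integer(counts[["target"]]) / n_cycles
  dpc <- (as.integer(counts[["lure"]]) + as.integer(counts[["foil"]])) /
    n_cycles
  form <- if (nrow(trials) == 80L && n_cycles == 8L) "OCL80"
          else if (nrow(trials) == 48L && n_cycles == 6L) "OCL48" else NULL
  config <- ocl_config(form = form, n_cycles = n_cycles,
                       n_targets = as.integer(n_targets),
                       distractors_per_cycle = as.integer(dpc),
                       n_lures = as.integer(counts[["lure"]]),
                       n_foils = as.integer(counts[["foil"]]))
  pool <- function(type) {
    rows <- trials[trials$trial_type == type, c("rank", "suit")]
    distinct(rows)
  }
  tg <- trials |>
    filter(.data$trial_type == "target", .data$cycle == 1L) |>
    select("rank", "suit")
  new_ocl_schedule(trials, config, tg, pool("lure"), pool("foil"))
}

#' Read and write trial-log and score-table CSV files
#'
#' The trial log holds one row per administered trial (`subject_id`,
#' `form`, `trial`, `cycle`, `rank`, `suit`, `trial_type`,
#' `presentation_number`, `keyed_answer`, `first_response`, `correct`,
#' `attempts`, `latency_ms`); the score table one row per subject with
#' proportions and transformed scores overall and by trial type.
#'
#' @param session An `ocl_session` (or several row-bound together).
#' @param scores A score table, e.g. rows from [score_session()].
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_session_log <- function(session, path) {
  out <- as_tibble(session) |>
    mutate(suit = suit_to_letter(.data$suit),
           trial_type = as.character(.data$trial_type))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), form = readr::col_character(),
    trial = readr::col_integer(), cycle = readr::col_integer(),
    rank = readr::col_integer(), suit = readr::col_character(),
    trial_type = readr::col_character(),
    presentation_number = readr::col_integer(),
    keyed_answer = readr::col_character(),
    first_response = readr::col_character(),
    correct = readr::col_logical(), attempts = readr::col_integer(),
    latency_ms = readr::col_double()))
  raw |>
    mutate(suit = letter_to_suit(.data$suit),
           trial_type = factor(.data$trial_type,
                               levels = c("target", "lure", "foil")))
}

#' @rdname write_session_log
#' @export
write_score_table <- function(scores, path) {
  readr::write_csv(as_tibble(scores), path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_score_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_guess()))
}

#' Read a paired-scores CSV for equating
#'
#' Expects columns `subject_id`, `score_x`, `score_y` (one row per subject
#' who took both forms).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_paired_scores <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    score_x = readr::col_double(), score_y = readr::col_double()))
  missing_cols <- setdiff(c("subject_id", "score_x", "score_y"), names(out))
  if (length(missing_cols)) {
    abort(paste0("Paired score file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out
}

#' Write equating tables
#'
#' Writes the two directional tables of an [equate_forms()] fit
#' (`<stem>_x_to_y.csv`, `<stem>_y_to_x.csv`), annotated with the
#' attainable `n_correct` for the source form when its trial count is
#' given, plus a JSON run log (`<stem>_log.json`) recording n, B, degree
#' and the summary SEs.
#'
#' @param fit An `ocl_equating_fit`.
#' @param stem Output path stem.
#' @param n_trials_x,n_trials_y Optional trial counts of the two forms.
#' @return Character vector of written paths, invisibly.
#' @export
write_equating_tables <- function(fit, stem, n_trials_x = NULL,
                                  n_trials_y = NULL) {
  annotate <- function(tab, n_trials) {
    out <- as_tibble(tab)
    if (!is.null(n_trials)) {
      lookup <- score_to_n_correct(n_trials)
      out$n_correct <- lookup$n_correct[match(round(out$x_score * 100),
                                              round(lookup$score * 100))]
      out <- out[, c("n_correct", setdiff(names(out), "n_correct"))]
    }
    out
  }
  paths <- c(paste0(stem, "_x_to_y.csv"), paste0(stem, "_y_to_x.csv"),
             paste0(stem, "_log.json"))
  readr::write_csv(annotate(fit$x_to_y, n_trials_x), paths[1])
  readr::write_csv(annotate(fit$y_to_x, n_trials_y), paths[2])
  jsonlite::write_json(
    list(n = fit$n, B = fit$B, degree = fit$degree,
         n_skipped = fit$n_skipped,
         mean_se = as.list(fit$mean_se),
         weighted_mean_se = as.list(fit$weighted_mean_se)),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
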