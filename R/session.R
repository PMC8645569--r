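#' Administer a schedule to a responder
#'
#' Replays the forced-correction response flow: each trial records the
#' responder's first press; an incorrect first press requires exactly one
#' further press of the other (correct) alternative, so `attempts` is 1 when
#' the first response is correct and 2 otherwise. Only first responses feed
#' the accuracy score.
#'
#' @param schedule An `ocl_schedule`.
#' @param responder A responder function (see [responder_keyed()] and
#'   friends, or [simulate_responder()]): called as
#'   `responder(schedule, keyed)` and returning one `"yes"`/`"no"` per
#'   trial, optionally a tibble with columns `response` and `latency_ms`.
#' @param subject_id Identifier stored in the record.
#' @param target_keying Keying convention, see [keyed_answers()].
#' @param seed Optional seed for the responder's randomness.
#' @return An `ocl_session` tibble: `subject_id`, `form`, `trial`, `cycle`,
#'   `rank`, `suit`, `trial_type`, `presentation_number`, `keyed_answer`,
#'   `first_response`, `correct`, `attempts`, `latency_ms`.
#' @examples
#' sch <- ocl_schedule("OCL48", seed = 1)
#' sess <- run_session(sch, responder_accuracy(0.8), seed = 2)
#' mean(sess$correct)
#' @export
run_session <- function(schedule, responder, subject_id = "S1",
                        target_keying = c("novelty", "always_yes"),
                        seed = NULL) {
  target_keying <- match.arg(target_keying)
  keyed <- keyed_answers(schedule, target_keying)
  ans <- with_seed_if(seed, responder(schedule, keyed))
  latency <- rep(NA_real_, nrow(schedule))
  if (is.data.frame(ans)) {
    if (!is.null(ans$latency_ms)) latency <- as.numeric(ans$latency_ms)
    ans <- ans$response
  }
  ans <- as.character(ans)
  if (length(ans) < nrow(schedule)) {
    abort(sprintf("Responder supplied %d responses for %d trials.",
                  length(ans), nrow(schedule)))
  }
  if (!all(ans %in% c("yes", "no"))) {
    abort("Responses must be \"yes\" or \"no\".")
  }
  correct <- ans == keyed
  config <- schedule_config(schedule)
  out <- tibble(
    subject_id = subject_id,
    form = config$form,
    trial = schedule$trial,
    cycle = schedule$cycle,
    rank = schedule$rank,
    suit = schedule$suit,
    trial_type = schedule$trial_type,
    presentation_number = schedule$presentation_number,
    keyed_answer = keyed,
    first_response = ans,
    correct = correct,
    attempts = ifelse(correct, 1L, 2L),
    latency_ms = latency
  )
  class(out) <- c("ocl_session", class(tibble()))
  out
}

flip_answer <- function(x) ifelse(x == "yes", "no", "yes")

#' Reference responders
#'
#' Simple response sources for [run_session()]:
#'
#' * `responder_keyed()` always presses the keyed answer (a perfect
#'   respondent).
#' * `responder_fixed(answer)` always presses the same button.
#' * `responder_random(p_yes)` presses "yes" with probability `p_yes`
#'   independently per trial.
#' * `responder_accuracy(p_correct)` is correct with probability
#'   `p_correct` per trial regardless of trial type.
#'
#' For a respondent with per-trial-type accuracies, see
#' [simulate_responder()].
#'
#' @param answer `"yes"` or `"no"`.
#' @param p_yes,p_correct Probabilities in \[0, 1\].
#' @return A function `(schedule, keyed) -> character vector`.
#' @examples
#' sch <- ocl_schedule("OCL80", seed = 1)
#' sum(run_session(sch, responder_fixed("yes"))$correct)
#' @export
responder_keyed <- function() {
  function(schedule, keyed) keyed
}

#' @rdname responder_keyed
#' @export
responder_fixed <- function(answer = "yes") {
  if (!answer %in% c("yes", "no")) abort("`answer` must be \"yes\" or \"no\".")
  function(schedule, keyed) rep(answer, nrow(schedule))
}

#' @rdname responder_keyed
#' @export
responder_random <- function(p_yes = 0.5) {
  check_number(p_yes, "p_yes", 0, 1, len = 1)
  function(schedule, keyed) {
    ifelse(runif(nrow(schedule)) < p_yes, "yes", "no")
  }
}

#' @rdname responder_keyed
#' @export
responder_accuracy <- function(p_correct) {
  check_number(p_correct, "p_correct", 0, 1, len = 1)
  function(schedule, keyed) {
    ok <- runif(nrow(schedule)) < p_correct
    ifelse(ok, keyed, flip_answer(keyed))
  }
}
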