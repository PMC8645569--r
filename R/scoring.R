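#' Arcsine-square-root score transform
#'
#' The OCL reports accuracy as `asin(sqrt(p))` of the proportion of correct
#' first responses, a variance-stabilizing transform. Chance performance
#' (p = 0.5) maps to pi/4 (displayed 0.79) and perfect performance to pi/2
#' (displayed 1.57). `proportion_from_score()` is the exact inverse,
#' `sin(s)^2`.
#'
#' @param p Proportions in \[0, 1\].
#' @param s Transformed scores in \[0, pi/2\].
#' @return Numeric vector on the transformed (radians) or proportion scale.
#' @examples
#' transform_proportion(c(0.5, 0.75, 1))
#' proportion_from_score(pi / 4)
#' @export
transform_proportion <- function(p) {
  check_number(p, "p", lower = 0, upper = 1)
  asin(sqrt(p))
}

#' @rdname transform_proportion
#' @export
proportion_from_score <- function(s) {
  check_number(s, "s", lower = 0, upper = pi / 2)
  sin(s)^2
}

#' Scale bound constants
#'
#' Chance level pi/4 (displayed 0.79) and maximum pi/2 (displayed 1.57) of
#' the transformed accuracy scale.
#'
#' @return A length-1 numeric.
#' @examples
#' format_score(chance_score())
#' format_score(max_score())
#' @export
chance_score <- function() pi / 4

#' @rdname chance_score
#' @export
max_score <- function() pi / 2

#' Keyed (correct) answers for a schedule
#'
#' Under the default novelty keying the correct answer is "no" for the
#' first presentation of any card — every lure, every foil, and each
#' target's first showing (the answer to the very first trial is therefore
#' always "no") — and "yes" for every target re-presentation. The
#' alternative `always_yes` keying keys every target trial "yes",
#' including the first presentation, and makes a perfect score
#' unattainable for a truthful responder.
#'
#' @param schedule An `ocl_schedule`.
#' @param target_keying `"novelty"` (default) or `"always_yes"`.
#' @return Character vector of `"yes"`/`"no"`, one per trial.
#' @examples
#' keyed_answers(ocl_schedule("OCL48", seed = 1))[1:8]
#' @export
keyed_answers <- function(schedule, target_keying = c("novelty", "always_yes")) {
  target_keying <- match.arg(target_keying)
  if (target_keying == "novelty") {
    ifelse(schedule$presentation_number >= 2L, "yes", "no")
  } else {
    ifelse(schedule$trial_type == "target", "yes", "no")
  }
}

#' Score one administered session
#'
#' Computes the proportion of correct first responses overall and by trial
#' type, with their arcsine-square-root transforms. Only the first response
#' per trial is scored; the forced-correction follow-up press is recorded in
#' `attempts` but never contributes to accuracy.
#'
#' @param session An `ocl_session` tibble from [run_session()] (or any
#'   tibble with `trial_type` and `correct` columns).
#' @return A one-row tibble: `subject_id`, `form`, `n_trials`, overall and
#'   per-type counts (`n_*`), proportions (`p_*`) and transformed scores
#'   (`s_*`).
#' @examples
#' sch <- ocl_schedule("OCL48", seed = 1)
#' score_session(run_session(sch, responder_keyed()))
#' @export
score_session <- function(session) {
  if (!is.data.frame(session) || nrow(session) == 0L) {
    abort("`session` must be a non-empty session record.")
  }
  if (!all(c("trial_type", "correct") %in% names(session))) {
    abort("`session` needs `trial_type` and `correct` columns.")
  }
  prop <- function(ok) if (length(ok)) mean(ok) else NA_real_
  tt <- as.character(session$trial_type)
  p_overall <- mean(session$correct)
  p_target <- prop(session$correct[tt == "target"])
  p_lure <- prop(session$correct[tt == "lure"])
  p_foil <- prop(session$correct[tt == "foil"])
  tr <- function(p) if (is.na(p)) NA_real_ else transform_proportion(p)
  tibble(
    subject_id = as.character(session$subject_id[1] %||% NA_character_),
    form = as.character(session$form[1] %||% NA_character_),
    n_trials = nrow(session),
    n_target = sum(tt == "target"), n_lure = sum(tt == "lure"),
    n_foil = sum(tt == "foil"),
    p_overall = p_overall, s_overall = tr(p_overall),
    p_target = p_target, s_target = tr(p_target),
    p_lure = p_lure, s_lure = tr(p_lure),
    p_foil = p_foil, s_foil = tr(p_foil)
  )
}

#' Floor and ceiling effect detection
#'
#' A ceiling (floor) effect is flagged when strictly more than `threshold`
#' (default 10%) of the sample scores at or above the maximum (at or below
#' the chance level). Exactly 10% is not flagged.
#'
#' @param scores Numeric vector of transformed scores.
#' @param max_level,chance_level Scale bounds; default [max_score()] and
#'   [chance_score()].
#' @param threshold Proportion above which an effect is declared (0.10).
#' @param tol Numeric tolerance for the boundary comparison.
#' @return A one-row tibble: `n`, `prop_ceiling`, `prop_floor`,
#'   `ceiling`, `floor`.
#' @examples
#' floor_ceiling_flags(c(rep(1.1, 20), rep(max_score(), 3)))
#' @export
floor_ceiling_flags <- function(scores, max_level = max_score(),
                                chance_level = chance_score(),
                                threshold = 0.10, tol = 1e-8) {
  if (length(scores) == 0L || anyNA(scores)) {
    abort("`scores` must be non-empty and non-missing.")
  }
  prop_ceiling <- mean(scores >= max_level - tol)
  prop_floor <- mean(scores <= chance_level + tol)
  tibble(
    n = length(scores),
    prop_ceiling = prop_ceiling,
    prop_floor = prop_floor,
    ceiling = prop_ceiling > threshold,
    floor = prop_floor > threshold
  )
}
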