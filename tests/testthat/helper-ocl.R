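# shared fixtures, built in code

# a session record with an exact number of correct first responses per trial
# type (the first k trials of each type are marked correct)
session_with_counts <- function(schedule, n_correct_by_type) {
  keyed <- keyed_answers(schedule)
  correct <- logical(nrow(schedule))
  for (type in names(n_correct_by_type)) {
    idx <- which(as.character(schedule$trial_type) == type)
    k <- n_correct_by_type[[type]]
    stopifnot(k <= length(idx))
    correct[idx[seq_len(k)]] <- TRUE
  }
  tibble::tibble(
    subject_id = "S1",
    form = schedule_config(schedule)$form,
    trial = schedule$trial,
    trial_type = schedule$trial_type,
    keyed_answer = keyed,
    first_response = ifelse(correct, keyed,
                            ifelse(keyed == "yes", "no", "yes")),
    correct = correct,
    attempts = ifelse(correct, 1L, 2L)
  )
}

# frequency distribution from explicit counts on the 79-point grid
freqdist_from_counts <- function(counts) {
  d <- clamp_and_bin(numeric(0))
  d$count <- as.numeric(counts)
  attr(d, "n") <- sum(counts)
  d
}

# discretized normal-shaped fractional counts over the grid, strictly positive
smooth_counts <- function(mean, sd, total = 1e5) {
  g <- score_grid()
  w <- stats::dnorm(g, mean, sd)
  w <- pmax(w, 1e-8)
  w / sum(w) * total
}
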