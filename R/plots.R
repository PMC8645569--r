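#' Plot a trial schedule
#'
#' Shows the interleaving of targets, lures and foils across the test, one
#' tile per trial, with cycle boundaries marked.
#'
#' @param object An `ocl_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(ocl_schedule("OCL48", seed = 1))
#' @export
autoplot.ocl_schedule <- function(object, ...) {
  config <- schedule_config(object)
  df <- as_tibble(object)
  df$card <- paste(df$rank, suit_to_letter(df$suit))
  boundaries <- seq(0.5, config$n_trials + 0.5,
                    by = config$n_targets + config$distractors_per_cycle)
  ggplot(df, aes(x = .data$trial, y = .data$trial_type,
                 fill = .data$trial_type)) +
    geom_tile(height = 0.8, show.legend = FALSE) +
    geom_vline(xintercept = boundaries, linetype = "dotted",
               colour = "grey50") +
    labs(x = "Trial", y = NULL,
         title = sprintf("%s schedule: %d cycles of %d targets + %d distractors",
                         config$form, config$n_cycles, config$n_targets,
                         config$distractors_per_cycle)) +
    theme_minimal()
}

#' Plot an equating fit
#'
#' Equated score against source score with a bootstrap-SE ribbon and the
#' identity line; the widening ribbon at the extremes shows where the
#' equating is least certain.
#'
#' @param object An `ocl_equating_fit`.
#' @param direction `"x_to_y"` or `"y_to_x"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ocl_equating_fit <- function(object,
                                      direction = c("x_to_y", "y_to_x"),
                                      ...) {
  direction <- match.arg(direction)
  df <- as_tibble(object[[direction]])
  p <- ggplot(df, aes(x = .data$x_score, y = .data$equated_y)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    labs(x = "Score on source form", y = "Equated score",
         title = sprintf("Equipercentile equating (%s), degree-%d presmoothing",
                         gsub("_", " ", direction), object$degree)) +
    theme_minimal()
  if (!all(is.na(df$se_boot))) {
    p <- p + geom_ribbon(aes(ymin = .data$equated_y - 1.96 * .data$se_boot,
                             ymax = .data$equated_y + 1.96 * .data$se_boot),
                         alpha = 0.25, fill = "#2c7fb8")
  }
  p
}

#' Plot a simulated two-group study
#'
#' Overlaid score distributions of the control and patient cohorts with
#' their means; the separation in control-SD units is the Glass's delta.
#'
#' @param object An `ocl_two_group` from [simulate_two_group_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ocl_two_group <- function(object, ...) {
  df <- bind_rows(as_tibble(object$control), as_tibble(object$patient))
  means <- df |>
    summarise(m = mean(.data$s_overall), .by = "label")
  ggplot(df, aes(x = .data$s_overall, fill = .data$label)) +
    geom_histogram(alpha = 0.6, position = "identity", bins = 25) +
    geom_vline(data = means, aes(xintercept = .data$m,
                                 colour = .data$label),
               linetype = "dashed", show.legend = FALSE) +
    labs(x = "Transformed score", y = "Subjects", fill = NULL,
         title = sprintf("Glass's delta = %.2f", object$effect$estimate)) +
    theme_minimal()
}

#' Plot repeated sessions of a retest simulation
#'
#' One line per subject across sessions; flat, tightly bundled lines
#' indicate stable, reliable measurement.
#'
#' @param object An `ocl_retest` from [simulate_retest()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ocl_retest <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$session, y = .data$s_overall,
             group = .data$subject_id)) +
    geom_line(alpha = 0.3, colour = "#2c7fb8") +
    geom_hline(yintercept = c(chance_score(), max_score()),
               linetype = "dotted") +
    scale_x_continuous(breaks = unique(object$session)) +
    labs(x = "Session", y = "Transformed score") +
    theme_minimal()
}
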