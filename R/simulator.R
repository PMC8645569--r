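#' Respondent parameters
#'
#' Generative parameters for a simulated respondent: first-response accuracy
#' per trial type, an optional within-session learning increment on target
#' accuracy, between-subject dispersion applied on the logit scale, and a
#' test-retest correlation used by [simulate_retest()].
#'
#' The pattern-separation structure of the task predicts the ordering
#' `p_lure < p_foil < p_target`: lures share a rank with a studied target
#' and are hardest to reject.
#'
#' @param p_target,p_lure,p_foil Accuracy probabilities in \[0, 1\].
#' @param learning_rate Increment added to target accuracy per prior
#'   exposure of the same card, capped at 1. Default 0 (flat within-session
#'   performance; short-interval retesting shows no practice effect).
#' @param subject_sd Between-subject SD of a logit-scale ability offset.
#' @param retest_r Within-subject correlation of ability across repeated
#'   sessions, in \[0, 1\].
#' @return A `respondent_params` list.
#' @examples
#' respondent_params(p_target = 0.9, p_lure = 0.4, p_foil = 0.75)
#' @export
respondent_params <- function(p_target, p_lure, p_foil, learning_rate = 0,
                              subject_sd = 0, retest_r = NA_real_) {
  check_number(p_target, "p_target", 0, 1, len = 1)
  check_number(p_lure, "p_lure", 0, 1, len = 1)
  check_number(p_foil, "p_foil", 0, 1, len = 1)
  check_number(learning_rate, "learning_rate", 0, 1, len = 1)
  check_number(subject_sd, "subject_sd", 0, Inf, len = 1)
  if (!is.na(retest_r)) check_number(retest_r, "retest_r", 0, 1, len = 1)
  structure(
    list(p_target = p_target, p_lure = p_lure, p_foil = p_foil,
         learning_rate = learning_rate, subject_sd = subject_sd,
         retest_r = retest_r),
    class = "respondent_params")
}

#' Respondent parameters from transformed trial-type means
#'
#' Inverts the arcsine-square-root transform (`p = sin(mean)^2`) to turn
#' published per-trial-type group means into accuracy probabilities.
#'
#' @param target_mean,lure_mean,foil_mean Transformed-score means in
#'   \[0, pi/2\].
#' @inheritParams respondent_params
#' @return A `respondent_params` list.
#' @examples
#' # an older-adult profile: lures far harder than foils or targets
#' calibrate_trial_type_probs(target_mean = 1.12, lure_mean = 0.61,
#'                            foil_mean = 1.01)
#' @export
calibrate_trial_type_probs <- function(target_mean, lure_mean, foil_mean,
                                       learning_rate = 0, subject_sd = 0,
                                       retest_r = NA_real_) {
  respondent_params(
    p_target = proportion_from_score(target_mean),
    p_lure = proportion_from_score(lure_mean),
    p_foil = proportion_from_score(foil_mean),
    learning_rate = learning_rate, subject_sd = subject_sd,
    retest_r = retest_r)
}

#' Responder driven by per-trial-type accuracies
#'
#' Builds a responder function for [run_session()]. Each trial is answered
#' correctly with the trial-type accuracy; target accuracy is optionally
#' increased by `learning_rate` per prior exposure (capped at 1). When
#' `subject_sd > 0` one logit-scale ability offset is drawn per session and
#' applied to all three accuracies.
#'
#' @param params A [respondent_params()].
#' @return A function `(schedule, keyed) -> character vector`.
#' @examples
#' pars <- calibrate_trial_type_probs(1.24, 0.68, 1.02)
#' sch <- ocl_schedule("OCL48", seed = 1)
#' score_session(run_session(sch, simulate_responder(pars), seed = 2))
#' @export
simulate_responder <- function(params) {
  stopifnot(inherits(params, "respondent_params"))
  function(schedule, keyed) {
    p <- numeric(nrow(schedule))
    tt <- as.character(schedule$trial_type)
    p[tt == "lure"] <- params$p_lure
    p[tt == "foil"] <- params$p_foil
    is_tg <- tt == "target"
    p[is_tg] <- pmin(
      1, params$p_target +
        params$learning_rate * (schedule$presentation_number[is_tg] - 1L))
    if (params$subject_sd > 0) {
      z <- rnorm(1, 0, params$subject_sd)
      p <- plogis(qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + z)
    }
    ok <- runif(length(p)) < p
    ifelse(ok, keyed, flip_answer(keyed))
  }
}

#' Cohort specification
#'
#' Targets for a simulated cohort: the number of subjects and the mean and
#' SD its transformed overall scores should have on the given form.
#'
#' @param label Cohort label (e.g. `"CN_Abeta_neg"`).
#' @param n Number of subjects (>= 2).
#' @param target_mean Desired mean transformed score, in (pi/4, pi/2).
#' @param target_sd Desired SD of transformed scores (> 0).
#' @param seed Optional seed used by [simulate_cohort()] when no explicit
#'   seed is passed.
#' @return A `cohort_spec` list.
#' @examples
#' cohort_spec("CN_Abeta_neg", n = 22, target_mean = 1.09, target_sd = 0.09)
#' @export
cohort_spec <- function(label, n, target_mean, target_sd, seed = NULL) {
  check_number(n, "n", lower = 2, len = 1)
  check_number(target_sd, "target_sd", lower = 1e-12, len = 1)
  check_number(target_mean, "target_mean", len = 1)
  if (target_mean <= pi / 4 || target_mean >= pi / 2) {
    abort("`target_mean` must lie strictly between chance (pi/4) and maximum (pi/2).")
  }
  if (target_mean - 2 * target_sd < 0 || target_mean + 2 * target_sd > pi / 2) {
    warn(paste0(
      "cohort target mean +/- 2 SD extends beyond the [0, pi/2] score range; ",
      "latent abilities will be clamped."))
  }
  structure(
    list(label = as.character(label), n = as.integer(n),
         target_mean = target_mean, target_sd = target_sd,
         seed = if (!is.null(seed)) as.integer(seed) else NULL),
    class = "cohort_spec")
}

#' Published cohort moments shipped as presets
#'
#' Transformed-score group means and SDs reported for the cohorts used to
#' validate the two forms: the combined cognitively normal sample
#' (`CN_combined`), the amyloid-confirmed older cohorts
#' (`CN_Abeta_neg`, `AD_Abeta_pos`), the young retest sample
#' (`CN_young_retest`, baseline moments), and the large remote normative
#' sample (`MTurk`). `trial_type_presets()` gives the per-trial-type means
#' and SDs (averaged over forms) for the younger, older and combined
#' groups, which feed [calibrate_trial_type_probs()].
#'
#' @return A tibble of preset moments.
#' @examples
#' cohort_presets()
#' trial_type_presets()
#' @export
cohort_presets <- function() {
  tribble(
    ~label,            ~form,    ~n,   ~mean, ~sd,
    "CN_combined",     "OCL48",  56L,  1.09,  0.12,
    "CN_combined",     "OCL80",  56L,  1.00,  0.10,
    "CN_Abeta_neg",    "OCL48",  22L,  1.09,  0.09,
    "CN_Abeta_neg",    "OCL80",  22L,  1.00,  0.10,
    "AD_Abeta_pos",    "OCL48",  30L,  0.80,  0.11,
    "AD_Abeta_pos",    "OCL80",  30L,  0.80,  0.08,
    "CN_young_retest", "OCL48",  23L,  1.10,  0.10,
    "MTurk",           "OCL48",  401L, 1.07,  0.11,
    "MTurk",           "OCL80",  401L, 0.99,  0.10
  )
}

#' @rdname cohort_presets
#' @export
trial_type_presets <- function() {
  tribble(
    ~group,     ~trial_type, ~mean, ~sd,
    "younger",  "lure",      0.80,  0.13,
    "younger",  "foil",      1.05,  0.13,
    "younger",  "target",    1.31,  0.13,
    "older",    "lure",      0.61,  0.24,
    "older",    "foil",      1.01,  0.14,
    "older",    "target",    1.12,  0.10,
    "combined", "lure",      0.68,  0.22,
    "combined", "foil",      1.02,  0.13,
    "combined", "target",    1.24,  0.15
  )
}

#' @rdname cohort_presets
#' @param label,form Preset selector.
#' @param seed Optional seed stored in the returned spec.
#' @export
preset_cohort_spec <- function(label, form, seed = NULL) {
  row <- cohort_presets() |>
    filter(.data$label == !!label, .data$form == !!form)
  if (nrow(row) != 1L) {
    abort(sprintf("No preset cohort \"%s\" for form %s.", label, form))
  }
  cohort_spec(row$label, row$n, row$mean, row$sd, seed = seed)
}

# exact mean/variance of the transformed score of Binomial(n, sin^2(m))/n
binom_transform_moments <- function(ability, n_trials) {
  p <- sin(min(max(ability, 0), pi / 2))^2
  x <- 0:n_trials
  w <- dbinom(x, n_trials, p)
  s <- asin(sqrt(x / n_trials))
  mu <- sum(w * s)
  list(mean = mu, var = sum(w * (s - mu)^2))
}

# Calibrate the latent ability distribution so that observed session scores
# match the target moments. Latent abilities live on the transformed scale:
# a_i ~ N(mu, sigma) clamped to [0, pi/2]; a session draws
# Binomial(n_trials, sin^2(a_i)) correct responses. Because the transform is
# variance-stabilizing the observed SD is close to sqrt(sigma^2 + 1/(4 n)),
# and a short stochastic fixed-point iteration against Monte-Carlo moments
# (fixed internal seed, results memoised) removes the residual bias.
calibrate_cohort <- function(target_mean, target_sd, n_trials,
                             n_iter = 8L, n_mc = 20000L) {
  key <- sprintf("%.12g|%.12g|%d", target_mean, target_sd, n_trials)
  if (!is.null(the$calibrations[[key]])) return(the$calibrations[[key]])

  bt <- binom_transform_moments(target_mean, n_trials)
  v_bin <- bt$var
  infeasible_sd <- target_sd^2 <= v_bin
  mu <- target_mean
  sigma <- sqrt(max(target_sd^2 - v_bin, 1e-10))
  withr::with_seed(104729L, {
    for (i in seq_len(n_iter)) {
      a <- pmin(pmax(rnorm(n_mc, mu, sigma), 0), pi / 2)
      x <- rbinom(n_mc, n_trials, sin(a)^2)
      s <- asin(sqrt(x / n_trials))
      mu <- mu + (target_mean - mean(s))
      if (!infeasible_sd) {
        sigma <- max(sigma * target_sd / sd(s), 1e-6)
      }
      achieved_mean <- mean(s)
      achieved_sd <- sd(s)
    }
  })
  cal <- list(mu = mu, sigma = sigma, v_bin = v_bin,
              achieved_mean = achieved_mean, achieved_sd = achieved_sd,
              infeasible_sd = infeasible_sd,
              target_mean = target_mean, target_sd = target_sd,
              n_trials = n_trials)
  if (is.null(the$calibrations)) the$calibrations <- list()
  the$calibrations[[key]] <- cal
  cal
}

draw_cohort_scores <- function(n, cal) {
  a <- pmin(pmax(rnorm(n, cal$mu, cal$sigma), 0), pi / 2)
  x <- rbinom(n, cal$n_trials, sin(a)^2)
  tibble(ability = a, n_correct = x,
         p_overall = x / cal$n_trials,
         s_overall = asin(sqrt(x / cal$n_trials)))
}

#' Simulate a cohort of respondents
#'
#' Draws `spec$n` subjects from a two-level model: a latent ability per
#' subject on the transformed scale, then binomial trial-level noise for the
#' session. The latent distribution is calibrated by Monte-Carlo moment
#' matching so that the cohort's observed transformed scores have
#' approximately the requested mean and SD. Session noise puts a floor of
#' about `sqrt(1/(4 * n_trials))` (~0.072 for 48 trials) under the
#' achievable SD; a `target_sd` below that floor triggers a warning and the
#' latent dispersion collapses to zero.
#'
#' @param spec A [cohort_spec()].
#' @param config Form configuration (or form name); default OCL48.
#' @param seed Seed for the draw; defaults to `spec$seed`.
#' @return An `ocl_cohort` tibble with one row per subject: `subject_id`,
#'   `label`, `form`, `n_trials`, `n_correct`, `p_overall`, `s_overall`,
#'   plus the cohort specification and calibration as attributes.
#' @examples
#' cn <- simulate_cohort(preset_cohort_spec("CN_Abeta_neg", "OCL48"),
#'                       "OCL48", seed = 1)
#' c(mean(cn$s_overall), sd(cn$s_overall))
#' @export
simulate_cohort <- function(spec, config = ocl_config("OCL48"), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  config <- as_ocl_config(config)
  cal <- calibrate_cohort(spec$target_mean, spec$target_sd, config$n_trials)
  if (cal$infeasible_sd) {
    warn(sprintf(
      paste0("target_sd = %.3f is at or below the session noise floor ",
             "(%.3f for %d trials); observed SD will exceed the target."),
      spec$target_sd, sqrt(cal$v_bin), config$n_trials))
  }
  seed <- seed %||% spec$seed
  draws <- with_seed_if(seed, draw_cohort_scores(spec$n, cal))
  out <- tibble(
    subject_id = sprintf("%s_%03d", spec$label, seq_len(spec$n)),
    label = spec$label,
    form = config$form,
    n_trials = config$n_trials,
    n_correct = draws$n_correct,
    p_overall = draws$p_overall,
    s_overall = draws$s_overall
  )
  attr(out, "spec") <- spec
  attr(out, "calibration") <- cal
  attr(out, "ability") <- draws$ability
  class(out) <- c("ocl_cohort", class(tibble()))
  out
}

#' Simulate repeated sessions with test-retest dependence
#'
#' Each subject keeps a stable ability component across sessions and adds a
#' session-specific fluctuation; `retest_r` is the target intraclass
#' correlation of the observed transformed scores. Session (binomial)
#' measurement noise counts toward the within-subject variance, so the
#' achievable `retest_r` is capped at roughly
#' `1 - v_noise / target_sd^2`; a request beyond the cap is clamped with a
#' warning.
#'
#' @inheritParams simulate_cohort
#' @param n_sessions Number of repeated administrations (>= 2).
#' @param retest_r Target ICC of observed scores, in \[0, 1\].
#' @return A long tibble: `subject_id`, `session`, `n_correct`,
#'   `p_overall`, `s_overall` (class `ocl_retest`).
#' @examples
#' rt <- simulate_retest(cohort_spec("CN", 50, 1.09, 0.12), n_sessions = 3,
#'                       retest_r = 0.6, seed = 1)
#' icc(rt)
#' @export
simulate_retest <- function(spec, n_sessions = 3L, retest_r = 0.6,
                            config = ocl_config("OCL48"), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_number(retest_r, "retest_r", 0, 1, len = 1)
  if (n_sessions < 2L) abort("`n_sessions` must be at least 2.")
  config <- as_ocl_config(config)
  cal <- calibrate_cohort(spec$target_mean, spec$target_sd, config$n_trials)
  v_total <- spec$target_sd^2
  v_latent <- cal$sigma^2
  v_between <- retest_r * v_total
  if (v_between > v_latent) {
    warn(sprintf(
      paste0("retest_r = %.2f exceeds the achievable cap %.2f given the ",
             "session noise floor; clamping."),
      retest_r, v_latent / v_total))
    v_between <- v_latent
  }
  v_within_latent <- max(v_latent - v_between, 0)
  seed <- seed %||% spec$seed
  out <- with_seed_if(seed, {
    u <- rnorm(spec$n, cal$mu, sqrt(v_between))
    purrr::map(seq_len(n_sessions), function(ss) {
      a <- pmin(pmax(u + rnorm(spec$n, 0, sqrt(v_within_latent)), 0), pi / 2)
      x <- rbinom(spec$n, config$n_trials, sin(a)^2)
      tibble(
        subject_id = sprintf("%s_%03d", spec$label, seq_len(spec$n)),
        session = ss,
        n_correct = x,
        p_overall = x / config$n_trials,
        s_overall = asin(sqrt(x / config$n_trials)))
    }) |> list_rbind()
  })
  attr(out, "spec") <- spec
  attr(out, "retest_r") <- retest_r
  class(out) <- c("ocl_retest", class(tibble()))
  out
}

#' Simulate a case-control sensitivity study
#'
#' Draws a control and a patient cohort on the same form and reports the
#' Glass's delta for the group difference (control minus patient,
#' standardized by the control SD). `replicate_two_group_study()` repeats
#' the draw many times (without bootstrap CIs) and returns the per-replicate
#' effect sizes — the in-silico analogue of asking how large the
#' impairment effect is expected to be under the published group moments.
#'
#' @param control_spec,patient_spec [cohort_spec()]s.
#' @inheritParams simulate_cohort
#' @param n_boot Bootstrap resamples for the delta CI (0 to skip).
#' @return `simulate_two_group_study()`: an `ocl_two_group` list with
#'   `control`, `patient` (cohort tibbles) and `effect`
#'   (an `ocl_effect_size`). `replicate_two_group_study()`: a tibble with
#'   columns `replicate`, `glass_delta`.
#' @examples
#' st <- simulate_two_group_study(
#'   preset_cohort_spec("CN_Abeta_neg", "OCL48"),
#'   preset_cohort_spec("AD_Abeta_pos", "OCL48"),
#'   "OCL48", seed = 1, n_boot = 200)
#' st$effect
#' @export
simulate_two_group_study <- function(control_spec, patient_spec,
                                     config = ocl_config("OCL48"),
                                     seed = NULL, n_boot = 10000L) {
  config <- as_ocl_config(config)
  cal_c <- calibrate_cohort(control_spec$target_mean, control_spec$target_sd,
                            config$n_trials)
  cal_p <- calibrate_cohort(patient_spec$target_mean, patient_spec$target_sd,
                            config$n_trials)
  res <- with_seed_if(seed, {
    control <- simulate_cohort(control_spec, config, seed = NULL)
    patient <- simulate_cohort(patient_spec, config, seed = NULL)
    effect <- glass_delta(control$s_overall, patient$s_overall,
                          n_boot = n_boot, seed = NULL)
    list(control = control, patient = patient, effect = effect)
  })
  structure(res, class = "ocl_two_group")
}

#' @rdname simulate_two_group_study
#' @param n_replicates Number of replicate studies.
#' @export
replicate_two_group_study <- function(control_spec, patient_spec,
                                      config = ocl_config("OCL48"),
                                      n_replicates = 1000L, seed = NULL) {
  config <- as_ocl_config(config)
  cal_c <- calibrate_cohort(control_spec$target_mean, control_spec$target_sd,
                            config$n_trials)
  cal_p <- calibrate_cohort(patient_spec$target_mean, patient_spec$target_sd,
                            config$n_trials)
  deltas <- with_seed_if(seed, {
    vapply(seq_len(n_replicates), function(i) {
      ctl <- draw_cohort_scores(control_spec$n, cal_c)$s_overall
      pat <- draw_cohort_scores(patient_spec$n, cal_p)$s_overall
      (mean(ctl) - mean(pat)) / sd(ctl)
    }, numeric(1))
  })
  tibble(replicate = seq_len(n_replicates), glass_delta = deltas)
}

#' @export
print.ocl_two_group <- function(x, ...) {
  cat(sprintf("<ocl_two_group> control n=%d, patient n=%d, form %s\n",
              nrow(x$control), nrow(x$patient), x$control$form[1]))
  print(x$effect)
  invisible(x)
}
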