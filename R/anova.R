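#' Mixed (split-plot) ANOVA with sphericity diagnostics
#'
#' Type III F tests for a balanced design mixing between-subject grouping
#' factors and within-subject repeated factors, as used to analyse
#' trial-type x test-difficulty x age-group accuracy tables. For within
#' effects with three or more levels, Mauchly's sphericity test and the
#' Greenhouse-Geisser epsilon are computed; the corrected p-value is
#' reported and applied (as `p_reported`) when Mauchly's p falls below
#' `gg_alpha`. Two-level within effects have epsilon exactly 1.
#'
#' The engine is a multivariate linear model fit with repeated-measures
#' univariate tests (via `car::Anova`); this function owns the interface:
#' long table in, tidy effect table out.
#'
#' @param data Long-format data frame: one row per subject x within-cell.
#' @param dv Name of the score column.
#' @param subject Name of the subject-id column.
#' @param within Character vector of within-subject factor names (>= 1).
#' @param between Character vector of between-subject factor names (may be
#'   empty).
#' @param gg_alpha Mauchly significance level that triggers the
#'   Greenhouse-Geisser correction (default 0.05).
#' @param alpha Display threshold used by the print method (default 0.01).
#' @return An `ocl_anova` with a `table` tibble: `effect`, `ss`, `df1`,
#'   `error_ss`, `df2`, `f_stat`, `p_value`, `mauchly_stat`, `mauchly_p`,
#'   `gg_epsilon`, `p_gg`, `gg_applied`, `df1_adj`, `df2_adj`,
#'   `p_reported`.
#' @examples
#' d <- expand.grid(subject_id = paste0("S", 1:12),
#'                  form = c("OCL48", "OCL80"))
#' d$group <- rep(c("young", "old"), each = 6)[match(d$subject_id,
#'                                                   paste0("S", 1:12))]
#' d$score <- rnorm(nrow(d), 1, 0.1)
#' mixed_anova(d, dv = "score", subject = "subject_id",
#'             within = "form", between = "group")
#' @export
mixed_anova <- function(data, dv, subject, within, between = character(),
                        gg_alpha = 0.05, alpha = 0.01) {
  if (length(within) < 1) abort("Need at least one within-subject factor.")
  missing_cols <- setdiff(c(dv, subject, within, between), names(data))
  if (length(missing_cols)) {
    abort(paste0("Columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  data[[subject]] <- factor(data[[subject]])
  for (f in c(within, between)) data[[f]] <- factor(data[[f]])

  # balance: every subject holds every within-cell exactly once
  cell_counts <- data |> count(across(all_of(c(subject, within))))
  n_cells <- prod(vapply(within, function(f) nlevels(data[[f]]), integer(1)))
  per_subj <- data |> count(across(all_of(subject)))
  if (any(cell_counts$n != 1L) ||
      any(per_subj$n != n_cells)) {
    abort("Design is unbalanced: each subject needs every within-factor cell exactly once.")
  }
  if (length(between)) {
    # subjects nested in between groups
    grp <- data |> distinct(across(all_of(c(subject, between))))
    if (anyDuplicated(grp[[subject]])) {
      abort("A subject appears in more than one between-group cell.")
    }
  }

  wide <- data |>
    mutate(.cell = interaction(!!!rlang::syms(within), sep = ".",
                               lex.order = TRUE)) |>
    select(all_of(c(subject, between)), ".cell", all_of(dv)) |>
    pivot_wider(names_from = ".cell", values_from = all_of(dv))
  idata <- expand_grid(!!!lapply(setNames(within, within),
                                 function(f) levels(data[[f]]))) |>
    as.data.frame()
  for (f in within) idata[[f]] <- factor(idata[[f]], levels = levels(data[[f]]))
  # the response matrix columns follow the idata row order
  cell_names <- apply(idata, 1, paste, collapse = ".")
  resp <- as.matrix(wide[, cell_names, drop = FALSE])

  mod_df <- as.data.frame(wide[, between, drop = FALSE])
  for (f in between) {
    # sum-to-zero contrasts so Type III tests are orthogonal to the intercept
    stats::contrasts(mod_df[[f]]) <- stats::contr.sum(nlevels(mod_df[[f]]))
  }
  mod_df$.resp <- resp
  rhs <- if (length(between)) paste(between, collapse = " * ") else "1"
  mod <- lm(stats::as.formula(paste(".resp ~", rhs)), data = mod_df)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = " * ")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))

  uni <- s$univariate.tests
  tab <- tibble(
    effect = rownames(uni),
    ss = unname(uni[, "Sum Sq"]),
    df1 = unname(uni[, "num Df"]),
    error_ss = unname(uni[, "Error SS"]),
    df2 = unname(uni[, "den Df"]),
    f_stat = unname(uni[, "F value"]),
    p_value = unname(uni[, "Pr(>F)"])
  ) |>
    filter(.data$effect != "(Intercept)")

  involves_within <- unname(vapply(tab$effect, function(e) {
    any(vapply(within, function(f) f %in% strsplit(e, ":")[[1]], logical(1)))
  }, logical(1)))

  gg_eps <- rep(NA_real_, nrow(tab))
  p_gg <- rep(NA_real_, nrow(tab))
  mauchly_stat <- rep(NA_real_, nrow(tab))
  mauchly_p <- rep(NA_real_, nrow(tab))
  adj <- s$pval.adjustments
  if (!is.null(adj) && nrow(adj)) {
    i <- match(tab$effect, rownames(adj))
    gg_eps <- unname(ifelse(is.na(i), NA_real_, adj[i, "GG eps"]))
    p_gg <- unname(ifelse(is.na(i), NA_real_, adj[i, "Pr(>F[GG])"]))
  }
  sph <- s$sphericity.tests
  if (!is.null(sph) && nrow(sph)) {
    i <- match(tab$effect, rownames(sph))
    mauchly_stat <- unname(ifelse(is.na(i), NA_real_,
                                  sph[i, "Test statistic"]))
    mauchly_p <- unname(ifelse(is.na(i), NA_real_, sph[i, "p-value"]))
  }
  # within effects whose repeated df is 1 satisfy sphericity trivially
  gg_eps[involves_within & is.na(gg_eps)] <- 1
  p_gg[involves_within & is.na(p_gg)] <-
    tab$p_value[involves_within & is.na(p_gg)]

  gg_applied <- involves_within & !is.na(mauchly_p) & mauchly_p < gg_alpha
  tab <- tab |>
    mutate(
      within = involves_within,
      mauchly_stat = mauchly_stat,
      mauchly_p = mauchly_p,
      gg_epsilon = gg_eps,
      p_gg = p_gg,
      gg_applied = gg_applied,
      df1_adj = ifelse(gg_applied, .data$df1 * gg_eps, .data$df1),
      df2_adj = ifelse(gg_applied, .data$df2 * gg_eps, .data$df2),
      p_reported = ifelse(gg_applied, p_gg, .data$p_value)
    )
  structure(
    list(table = tab, within = within, between = between,
         gg_alpha = gg_alpha, alpha = alpha,
         n_subjects = nrow(wide)),
    class = "ocl_anova")
}

#' @export
print.ocl_anova <- function(x, ...) {
  cat(sprintf("<ocl_anova> %d subjects; within: %s%s\n", x$n_subjects,
              paste(x$within, collapse = ", "),
              if (length(x$between)) {
                paste0("; between: ", paste(x$between, collapse = ", "))
              } else ""))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    star <- if (t$p_reported[i] < x$alpha) " *" else ""
    gg <- if (t$gg_applied[i]) {
      sprintf(" [GG eps = %.3f]", t$gg_epsilon[i])
    } else ""
    cat(sprintf("  %-28s F(%.2f, %.2f) = %8.3f, p = %.4g%s%s\n",
                t$effect[i], t$df1_adj[i], t$df2_adj[i], t$f_stat[i],
                t$p_reported[i], gg, star))
  }
  cat(sprintf("  (* p < %.2g)\n", x$alpha))
  invisible(x)
}

#' @export
tidy.ocl_anova <- function(x, ...) x$table

#' @export
glance.ocl_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects,
         n_effects = nrow(x$table),
         gg_alpha = x$gg_alpha)
}
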