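sim_mixed_data <- function(n_per_group, group_effect = 0, form_effect = 0,
                           interaction = 0, sd = 0.1) {
  subjects <- sprintf("S%03d", seq_len(2 * n_per_group))
  grp <- rep(c("CN", "AD"), each = n_per_group)
  d <- tidyr::expand_grid(subject_id = subjects, form = c("OCL48", "OCL80"))
  d$group <- grp[match(d$subject_id, subjects)]
  mu <- 1 +
    ifelse(d$group == "CN", group_effect / 2, -group_effect / 2) +
    ifelse(d$form == "OCL48", form_effect / 2, -form_effect / 2) +
    ifelse(xor(d$group == "CN", d$form == "OCL48"), -interaction / 4,
           interaction / 4)
  subj_noise <- rnorm(2 * n_per_group, 0, sd)
  d$score <- mu + subj_noise[match(d$subject_id, subjects)] +
    rnorm(nrow(d), 0, sd)
  d
}

test_that("two-level within factors have epsilon exactly 1", {
  d <- withr::with_seed(41, sim_mixed_data(12))
  fit <- mixed_anova(d, dv = "score", subject = "subject_id",
                     within = "form", between = "group")
  tab <- tidy(fit)
  expect_equal(tab$gg_epsilon[tab$effect == "form"], 1)
  expect_false(any(tab$gg_applied))
  expect_setequal(tab$effect, c("group", "form", "group:form"))
})

test_that("mixed ANOVA F values agree with the aov error-stratum oracle", {
  d <- withr::with_seed(43, sim_mixed_data(10, group_effect = 0.1,
                                           form_effect = 0.05,
                                           interaction = 0.08))
  fit <- mixed_anova(d, dv = "score", subject = "subject_id",
                     within = "form", between = "group")
  tab <- tidy(fit)
  d$group <- factor(d$group)
  d$form <- factor(d$form)
  ao <- summary(stats::aov(score ~ group * form +
                             Error(subject_id / form), data = d))
  between_tab <- ao[["Error: subject_id"]][[1]]
  within_tab <- ao[["Error: subject_id:form"]][[1]]
  expect_equal(tab$f_stat[tab$effect == "group"],
               between_tab[trimws(rownames(between_tab)) == "group",
                           "F value"],
               tolerance = 1e-8)
  expect_equal(tab$f_stat[tab$effect == "form"],
               within_tab[trimws(rownames(within_tab)) == "form", "F value"],
               tolerance = 1e-8)
  expect_equal(tab$f_stat[tab$effect == "group:form"],
               within_tab[trimws(rownames(within_tab)) == "group:form",
                          "F value"],
               tolerance = 1e-8)
})

test_that("sums of squares are additive on balanced data", {
  d <- withr::with_seed(47, sim_mixed_data(15, group_effect = 0.1))
  fit <- mixed_anova(d, dv = "score", subject = "subject_id",
                     within = "form", between = "group")
  tab <- tidy(fit)
  strata <- unique(round(cbind(tab$error_ss, tab$df2), 10))
  total <- sum(tab$ss) + sum(strata[, 1])
  expect_equal(total, sum((d$score - mean(d$score))^2),
               tolerance = 1e-8)
})

test_that("additive truth yields significant mains and a null interaction", {
  d <- withr::with_seed(53, sim_mixed_data(60, group_effect = 0.15,
                                           form_effect = 0.1,
                                           interaction = 0))
  fit <- mixed_anova(d, dv = "score", subject = "subject_id",
                     within = "form", between = "group")
  tab <- tidy(fit)
  expect_lt(tab$p_reported[tab$effect == "group"], 0.01)
  expect_lt(tab$p_reported[tab$effect == "form"], 0.01)
  expect_gt(tab$p_reported[tab$effect == "group:form"], 0.01)
})

test_that("a three-level within factor gets Mauchly and GG diagnostics", {
  withr::with_seed(59, {
    n <- 24
    # heterogeneous correlations between conditions violate sphericity
    base <- rnorm(n, 1, 0.2)
    m <- cbind(base + rnorm(n, 0, 0.01),
               base + rnorm(n, 0, 0.01),
               rnorm(n, 1, 0.3))
    d <- tibble::tibble(
      subject_id = rep(sprintf("S%02d", 1:n), times = 3),
      tt = rep(c("lure", "foil", "target"), each = n),
      score = as.vector(m))
  })
  fit <- mixed_anova(d, dv = "score", subject = "subject_id", within = "tt")
  tab <- tidy(fit)
  row <- tab[tab$effect == "tt", ]
  expect_false(is.na(row$mauchly_p))
  expect_lt(row$mauchly_p, 0.05)
  expect_true(row$gg_applied)
  expect_gte(row$gg_epsilon, 1 / 2)
  expect_lt(row$gg_epsilon, 1)
  expect_equal(row$df1_adj, row$df1 * row$gg_epsilon)
})

test_that("unbalanced within cells are rejected", {
  d <- withr::with_seed(61, sim_mixed_data(8))
  expect_error(
    mixed_anova(d[-1, ], dv = "score", subject = "subject_id",
                within = "form", between = "group"),
    "unbalanced")
})

test_that("the mixed-design interaction holds its nominal type-I error", {
  rejections <- withr::with_seed(67, {
    vapply(1:2000, function(i) {
      d <- sim_mixed_data(8)
      fit <- mixed_anova(d, dv = "score", subject = "subject_id",
                         within = "form", between = "group")
      tab <- fit$table
      tab$p_value[tab$effect == "group:form"] < 0.05
    }, logical(1))
  })
  expect_gt(mean(rejections), 0.035)
  expect_lt(mean(rejections), 0.065)
})
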