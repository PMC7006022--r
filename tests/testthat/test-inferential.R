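test_that("split-plot ANOVA degenerates to zero F when all cells are equal", {
  s <- make_summaries(rep(c("negative_induction", "positive_induction"),
                          each = 3),
                      happy = rep(0.5, 6), angry = rep(0.5, 6))
  tab <- mixed_anova_2x2(s)
  expect_equal(tab$F[!is.na(tab$F)], c(0, 0, 0))
  expect_equal(tab$partial_eta_sq[!is.na(tab$partial_eta_sq)], c(0, 0, 0))
})

test_that("ANOVA F values match the least-squares oracle on toy designs", {
  # balanced 4-participant design
  s1 <- make_summaries(rep(c("negative_induction", "positive_induction"),
                           each = 2),
                       happy = c(0.2, 0.3, 0.6, 0.7),
                       angry = c(0.4, 0.55, 0.4, 0.45))
  # unbalanced 5- and 6-participant designs with irregular values
  s2 <- make_summaries(rep(c("negative_induction", "positive_induction"),
                           c(2, 3)),
                       happy = c(0.21, 0.35, 0.62, 0.55, 0.71),
                       angry = c(0.44, 0.52, 0.40, 0.61, 0.47))
  s3 <- make_summaries(rep(c("negative_induction", "positive_induction"),
                           c(4, 2)),
                       happy = c(0.9, 0.1, 0.4, 0.3, 0.8, 0.2),
                       angry = c(0.3, 0.6, 0.2, 0.9, 0.1, 0.5))
  for (s in list(s1, s2, s3)) {
    tab <- mixed_anova_2x2(s)
    oracle <- oracle_split_plot_F(s)
    expect_equal(tab$F[tab$source == "group"], oracle[["group"]],
                 tolerance = 1e-10)
    expect_equal(tab$F[tab$source == "valence"], oracle[["valence"]],
                 tolerance = 1e-10)
    expect_equal(tab$F[tab$source == "group:valence"],
                 oracle[["interaction"]], tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with the repeated-measures Type III reference", {
  s <- make_summaries(rep(c("negative_induction", "positive_induction"),
                          c(3, 5)),
                      happy = c(0.2, 0.25, 0.4, 0.6, 0.65, 0.7, 0.5, 0.55),
                      angry = c(0.5, 0.45, 0.6, 0.4, 0.35, 0.5, 0.45, 0.3))
  tab <- mixed_anova_2x2(s)
  # Type III requires sum-to-zero coding of the between factor
  mod <- lm(cbind(mean_happy, mean_angry) ~ group, data = s,
            contrasts = list(group = contr.sum))
  idata <- data.frame(valence = factor(c("happy", "angry")))
  av <- summary(car::Anova(mod, idata = idata, idesign = ~valence, type = 3),
                multivariate = FALSE)
  ref <- av$univariate.tests
  expect_equal(tab$F[tab$source == "group"], ref["group", "F value"],
               tolerance = 1e-10)
  expect_equal(tab$F[tab$source == "valence"], ref["valence", "F value"],
               tolerance = 1e-10)
  expect_equal(tab$F[tab$source == "group:valence"],
               ref["group:valence", "F value"], tolerance = 1e-10)
  expect_equal(tab$p[tab$source == "group:valence"],
               ref["group:valence", "Pr(>F)"], tolerance = 1e-10)
})

test_that("partial eta squared satisfies its F-df identity", {
  set.seed(42)
  for (rep in 1:5) {
    s <- make_summaries(rep(c("negative_induction", "positive_induction"),
                            c(5, 7)),
                        happy = runif(12), angry = runif(12))
    tab <- mixed_anova_2x2(s)
    df2 <- tab$df[tab$source == "within_error"]
    for (src in c("group", "valence", "group:valence")) {
      f <- tab$F[tab$source == src]
      eta <- tab$partial_eta_sq[tab$source == src]
      expect_equal(eta, f / (f + df2), tolerance = 1e-12)
      expect_true(eta >= 0 && eta <= 1)
    }
  }
})

test_that("ANOVA preconditions reject degenerate group structure", {
  s <- make_summaries(c("negative_induction", "positive_induction",
                        "positive_induction"),
                      happy = c(0.1, 0.2, 0.3), angry = c(0.2, 0.3, 0.4))
  expect_error(mixed_anova_2x2(s), "at least 2")
  s1 <- make_summaries(rep("negative_induction", 4), happy = runif(4),
                       angry = runif(4))
  expect_error(mixed_anova_2x2(s1), "2 induction groups")
})

test_that("paired t-tests match hand arithmetic and Bonferroni doubling", {
  # differences {0.1, 0.2, 0.3}: t = 0.2 / (0.1 / sqrt(3))
  s <- make_summaries(rep("negative_induction", 3),
                      happy = c(0.3, 0.3, 0.3), angry = c(0.4, 0.5, 0.6))
  s <- rbind(s, make_summaries(rep("positive_induction", 3),
                               happy = c(0.5, 0.6, 0.7),
                               angry = c(0.5, 0.6, 0.7)))
  res <- paired_t_bonferroni(s)
  t_hand <- 0.2 / (sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(res$negative_induction$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$negative_induction$df, 2)
  p_hand <- 2 * pt(t_hand, df = 2, lower.tail = FALSE)
  expect_equal(res$negative_induction$p_value, p_hand, tolerance = 1e-12)
  # m = 2 groups tested: p_adj = min(1, 2 p)
  expect_equal(res$negative_induction$p_adjusted,
               min(1, 2 * p_hand), tolerance = 1e-12)
  # identical pairs: degenerate, flagged with t = 0 and p = 1
  expect_equal(res$positive_induction$statistic, 0)
  expect_equal(res$positive_induction$p_value, 1)
  expect_match(res$positive_induction$note, "zero variance")
})

test_that("Bonferroni adjustment caps at 1", {
  s <- make_summaries(rep(c("negative_induction", "positive_induction"),
                          each = 3),
                      happy = c(0.50, 0.52, 0.48, 0.3, 0.5, 0.4),
                      angry = c(0.49, 0.53, 0.47, 0.31, 0.52, 0.38))
  res <- paired_t_bonferroni(s)
  for (g in names(res)) {
    expect_lte(res[[g]]$p_adjusted, 1)
    expect_gte(res[[g]]$p_adjusted, res[[g]]$p_value)
  }
})

test_that("Brown-Forsythe equals the hand-computed ANOVA on |x - median|", {
  # groups {0, 0, 4} and {1, 3}: absolute deviations {0, 0, 4} and {1, 1};
  # one-way F = (2/15) / ((32/3)/3) = 0.0375
  res <- brown_forsythe_test(c(0, 0, 4, 1, 3), rep(c("a", "b"), c(3, 2)))
  expect_equal(res$statistic, 0.0375, tolerance = 1e-12)
  expect_equal(res$df, c(1, 3))

  # identical multisets and location shifts give F = 0
  res0 <- brown_forsythe_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  res_shift <- brown_forsythe_test(c(1, 2, 3, 11, 12, 13),
                                   rep(c("a", "b"), each = 3))
  expect_equal(res_shift$statistic, 0, tolerance = 1e-12)

  expect_error(brown_forsythe_test(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("Shapiro-Wilk wrapper flags degenerate input and detects bimodality", {
  expect_error(shapiro_wilk_test(c(1, 2)), "3 <= n")
  res_const <- shapiro_wilk_test(rep(1, 10))
  expect_true(is.na(res_const$statistic))
  expect_match(res_const$note, "constant")
  # extreme two-point sample is decisively non-normal
  res_bi <- shapiro_wilk_test(rep(c(0, 1), each = 50))
  expect_lt(res_bi$p_value, 0.001)
  # reference-routine agreement
  set.seed(9)
  x <- rnorm(40)
  expect_equal(shapiro_wilk_test(x)$statistic, shapiro.test(x)$statistic[[1]],
               tolerance = 1e-12)
})

test_that("Pearson correlation matches hand arithmetic and rejects constants", {
  res <- pearson_correlation(0:3, c(0, 1, 0, 1))
  expect_equal(res$estimate, 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # perfect linear relation
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$estimate, 1,
               tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), ">= 3")
  # optional Bonferroni factor
  res_m <- pearson_correlation(0:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9, 10), m = 4)
  expect_equal(res_m$p_adjusted, min(1, 4 * res_m$p_value))
})

test_that("gender LRT is zero for constant gender and detects a large shift", {
  sim <- simulate_cohort(cohort_config(n_negative = 15, n_positive = 15,
                                       seed = 4))
  scores <- score_trials(sim$dataset)
  # constant gender: the augmented model adds nothing
  scores_const <- transform(scores, gender = "woman")
  res0 <- gender_effect_lrt(scores_const)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # inject a strong additive gender effect at the score level
  scores_shift <- scores
  women <- scores_shift$gender == "woman"
  scores_shift$score <- scores_shift$score - 0.2 * women
  scores_shift$score <- pmax(scores_shift$score, 0)
  res1 <- gender_effect_lrt(scores_shift)
  expect_equal(res1$df, 1)
  expect_lt(res1$p_value, 0.001)
})

test_that("gender LRT null distribution is approximately chi-squared(1)", {
  config <- cohort_config(n_negative = 12, n_positive = 12, seed = 0)
  stats <- vapply(1:60, function(i) {
    ds <- simulate_cohort(config, seed = 1000 + i)$dataset
    res <- gender_effect_lrt(score_trials(ds))
    res$statistic
  }, numeric(1))
  stats <- stats[!is.na(stats)]
  # mean of a chi-squared(1) is 1; rejection at 0.05 stays near nominal
  expect_gt(length(stats), 50)
  expect_equal(mean(stats), 1, tolerance = 0.45)
  rej <- mean(stats > qchisq(0.95, df = 1))
  expect_lt(rej, 0.15)
})

test_that("questionnaire correlation table mirrors the group-by-valence grid", {
  sim <- simulate_cohort(cohort_config(n_negative = 12, n_positive = 12,
                                       seed = 19))
  s <- summarize_participants(sim$dataset)
  q <- sim$dataset$participants[, c("participant_id", "ECS", "IRI", "BES",
                                    "QPC")]
  tab <- questionnaire_correlations(s, q)
  expect_equal(nrow(tab), 2 * 2 * 4)
  expect_true(all(abs(tab$r) <= 1))
  expect_true(all(tab$df == tab$n - 2))
  tab_adj <- questionnaire_correlations(s, q, adjust = TRUE)
  expect_equal(tab_adj$p_adjusted, pmin(1, tab_adj$p_value * nrow(tab_adj)))
})
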