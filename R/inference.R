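# Assumption checks, follow-up tests and individual-difference correlations.
# Standard tests are delegated to the stats/lme4 routines; every wrapper
# returns a uniform `contagion_test` record so the pipeline report can carry
# method, statistic, df, raw and adjusted p, and n for each row.

contagion_test <- function(method, statistic, df, p_value,
                           p_adjusted = NA_real_, n = NA_integer_,
                           estimate = NA_real_, note = NA_character_) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, p_adjusted = p_adjusted, n = n,
                 estimate = estimate, note = note),
            class = "contagion_test")
}

#' @export
print.contagion_test <- function(x, ...) {
  df_txt <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %s, df = %s, p = %s", x$method,
              format(x$statistic, digits = 4), df_txt,
              format.pval(x$p_value, digits = 3, eps = 1e-6)))
  if (!is.na(x$p_adjusted)) {
    cat(sprintf(", p_adj = %s",
                format.pval(x$p_adjusted, digits = 3, eps = 1e-6)))
  }
  if (!is.na(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Paired t-tests of angry vs happy contagion, Bonferroni-corrected
#'
#' Within each induction group, a two-sided paired-samples t-test compares
#' mean contagion to angry vs happy faces. Because one test is run per group,
#' each raw p-value is Bonferroni-adjusted by the number of groups tested:
#' `p_adj = min(1, m * p_raw)`.
#'
#' @param summaries data frame from [summarize_participants()].
#' @return named list (one `contagion_test` per group) with the paired t
#'   statistic, df, raw and adjusted p, and the mean angry-minus-happy
#'   difference as `estimate`. Zero variance of the differences yields a
#'   flagged result (`statistic = NA`) rather than an error.
#' @export
paired_t_bonferroni <- function(summaries) {
  groups <- sort(unique(summaries$group))
  m <- length(groups)
  out <- list()
  for (g in groups) {
    sub <- summaries[summaries$group == g, , drop = FALSE]
    if (nrow(sub) < 2L) {
      stop("group '", g, "' has fewer than 2 paired observations",
           call. = FALSE)
    }
    diff <- sub$mean_angry - sub$mean_happy
    if (stats::sd(diff) == 0) {
      out[[g]] <- contagion_test(
        "paired t-test (angry - happy)",
        statistic = if (all(diff == 0)) 0 else NA_real_,
        df = nrow(sub) - 1L,
        p_value = if (all(diff == 0)) 1 else NA_real_,
        p_adjusted = if (all(diff == 0)) 1 else NA_real_,
        n = nrow(sub), estimate = mean(diff),
        note = "zero variance of paired differences; statistic degenerate")
      next
    }
    tt <- stats::t.test(sub$mean_angry, sub$mean_happy, paired = TRUE)
    out[[g]] <- contagion_test(
      "paired t-test (angry - happy)",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, p_adjusted = min(1, m * tt$p.value),
      n = nrow(sub), estimate = mean(diff))
  }
  out
}

#' Brown-Forsythe test of homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group medians — the
#' median-centred variant of Levene's test.
#'
#' @param values numeric vector of observations.
#' @param group grouping vector, same length as `values`.
#' @return a `contagion_test` with the F statistic and `(df1, df2)`.
#' @export
brown_forsythe_test <- function(values, group) {
  stopifnot(length(values) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stop("Brown-Forsythe requires >= 2 groups with >= 2 values each",
         call. = FALSE)
  }
  med <- tapply(values, group, stats::median)
  z <- abs(values - med[group])
  fit <- stats::anova(stats::lm(z ~ group))
  contagion_test("Brown-Forsythe", statistic = fit[["F value"]][1],
                 df = c(fit$Df[1], fit$Df[2]),
                 p_value = fit[["Pr(>F)"]][1], n = length(values))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] returning the package's uniform
#' test record; a constant sample is returned flagged instead of erroring.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return a `contagion_test` with W as `statistic`.
#' @export
shapiro_wilk_test <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (n = ", n, ")", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return(contagion_test("Shapiro-Wilk", NA_real_, NA_integer_, NA_real_,
                          n = n, note = "constant sample; W undefined"))
  }
  sw <- stats::shapiro.test(values)
  contagion_test("Shapiro-Wilk", statistic = unname(sw$statistic),
                 df = NA_integer_, p_value = sw$p.value, n = n)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Pairwise deletion of missing values; by design no multiplicity adjustment
#' is applied unless `m` is given, in which case a Bonferroni factor `m` is
#' used.
#'
#' @param x,y numeric vectors of equal length (e.g. per-participant contagion
#'   scores and questionnaire totals).
#' @param m optional Bonferroni divisor (number of tests in the family);
#'   `NULL` leaves `p_adjusted` unset.
#' @return a `contagion_test` with r as `estimate`, t as `statistic`, df
#'   `n - 2`.
#' @export
pearson_correlation <- function(x, y, m = NULL) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("Pearson correlation requires >= 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  if (stats::sd(y) == 0) stop("y has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  contagion_test("Pearson correlation",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 p_adjusted = if (is.null(m)) NA_real_
                 else min(1, m * ct$p.value),
                 n = length(x), estimate = unname(ct$estimate))
}

#' Likelihood-ratio test for a gender effect on contagion
#'
#' Fits two nested linear mixed models to trial-level contagion scores by
#' maximum likelihood — reference: `score ~ group + valence +
#' (1 | participant_id)`; augmented: `+ gender` — and compares them with a
#' chi-squared likelihood-ratio test on 1 df. The random-effects structure is
#' deliberately a simple random intercept per participant (see the package
#' vignette for why richer structures are not identifiable here).
#'
#' @param trial_scores data frame from [score_trials()] (or equivalent) with
#'   columns `participant_id`, `group`, `valence`, `gender`, `score`.
#' @return a `contagion_test` with the LR statistic, df = 1 and p from the
#'   chi-squared reference distribution. Degenerate gender coding (fewer than
#'   two levels) or non-convergence yields a flagged result, not an error.
#' @export
gender_effect_lrt <- function(trial_scores) {
  needed <- c("participant_id", "group", "valence", "gender", "score")
  stopifnot(all(needed %in% names(trial_scores)))
  dat <- trial_scores[stats::complete.cases(trial_scores[, needed]), needed]
  n_sub <- length(unique(dat$participant_id))
  if (length(unique(dat$gender)) < 2L) {
    return(contagion_test("gender LRT (mixed models)", statistic = 0,
                          df = 1L, p_value = 1, n = n_sub,
                          note = "gender constant; models identical"))
  }
  notes <- character()
  fit <- tryCatch({
    withCallingHandlers({
      m0 <- lme4::lmer(score ~ group + valence + (1 | participant_id),
                       data = dat, REML = FALSE)
      m1 <- lme4::lmer(score ~ group + valence + gender +
                         (1 | participant_id), data = dat, REML = FALSE)
      stats::anova(m0, m1)
    }, warning = function(w) {
      # singular-fit / convergence notes are diagnostics, not failures
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      notes <<- c(notes, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(contagion_test("gender LRT (mixed models)", NA_real_, 1L,
                          NA_real_, n = n_sub,
                          note = paste("model fit failed:",
                                       conditionMessage(fit))))
  }
  contagion_test("gender LRT (mixed models)", statistic = fit$Chisq[2],
                 df = fit$Df[2],
                 p_value = fit[["Pr(>Chisq)"]][2], n = n_sub,
                 note = if (length(notes)) paste(unique(notes),
                                                 collapse = "; ")
                        else NA_character_)
}

#' Table of contagion-questionnaire correlations
#'
#' Mirrors the group-by-valence layout of the study design: for each
#' induction group, each face valence and each questionnaire instrument with
#' any data, the Pearson correlation between per-participant mean contagion
#' and the questionnaire total.
#'
#' @param summaries data frame from [summarize_participants()].
#' @param questionnaires data frame with `participant_id` and any of the
#'   instrument columns `ECS`, `IRI`, `BES`, `QPC`.
#' @param adjust if `TRUE`, Bonferroni-adjust within the family of all
#'   correlations computed (the analysis default is no adjustment).
#' @return data frame with columns `group`, `valence`, `instrument`, `r`,
#'   `df`, `p_value`, `p_adjusted`, `n`.
#' @export
questionnaire_correlations <- function(summaries, questionnaires,
                                       adjust = FALSE) {
  instruments <- intersect(INSTRUMENTS, names(questionnaires))
  instruments <- instruments[vapply(instruments, function(i) {
    any(!is.na(questionnaires[[i]]))
  }, logical(1))]
  rows <- list()
  for (g in sort(unique(summaries$group))) {
    sub <- summaries[summaries$group == g, , drop = FALSE]
    q <- questionnaires[match(sub$participant_id,
                              questionnaires$participant_id), , drop = FALSE]
    for (valence in VALENCES) {
      x <- sub[[paste0("mean_", valence)]]
      for (instr in instruments) {
        y <- q[[instr]]
        keep <- stats::complete.cases(x, y)
        if (sum(keep) < 3L || stats::sd(x[keep]) == 0 ||
            stats::sd(y[keep]) == 0) next
        ct <- pearson_correlation(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, valence = valence, instrument = instr,
          r = ct$estimate, df = ct$df, p_value = ct$p_value,
          p_adjusted = NA_real_, n = ct$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(group = character(), valence = character(),
                      instrument = character(), r = numeric(), df = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}
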