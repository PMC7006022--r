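# Main fitting surface: contagion_analysis() runs the fixed analysis chain
# validate -> score -> outlier-screen -> summarize -> ANOVA + follow-up
# t-tests + assumption checks -> questionnaire correlations -> gender LRT,
# and returns everything as one classed object.

#' Fit the full emotional-contagion analysis to a study dataset
#'
#' Runs the complete analysis chain on a `contagion_dataset`: hard validation,
#' per-trial contagion scoring, Tukey-fence outlier screening on the
#' per-participant cell means (flagged participants are excluded once, before
#' all inference, and logged), the 2 x 2 split-plot ANOVA with partial eta
#' squared, per-group Bonferroni-corrected paired t-tests (angry vs happy),
#' Shapiro-Wilk normality checks per design cell, Brown-Forsythe homogeneity
#' checks per valence, Pearson correlations with any questionnaire totals
#' present, and a likelihood-ratio test for a gender effect when gender is
#' recorded.
#'
#' @param dataset a `contagion_dataset` ([read_ratings_csv()],
#'   [simulate_cohort()], or [study_dataset()]).
#' @param fence_k Tukey fence multiplier for outlier screening (1.5 =
#'   conventional boxplot whiskers). `Inf` disables screening.
#' @param alpha two-sided significance level carried into the report.
#' @param adjust_correlations Bonferroni-adjust the questionnaire correlation
#'   family (the analysis default, like the original design, is no
#'   adjustment).
#' @return object of class `contagion_fit`; see [summary.contagion_fit()].
#'   Components include `summaries` (post-exclusion per-participant cell
#'   means), `excluded` (outlier log), `cells` (2 x 2 means and SDs),
#'   `anova`, `t_tests`, `assumptions`, `correlations`, `gender`.
#' @examples
#' sim <- simulate_cohort(default_calibrated_config(), seed = 42)
#' fit <- contagion_analysis(sim$dataset)
#' fit
#' coef(fit)
#' @export
contagion_analysis <- function(dataset, fence_k = 1.5, alpha = 0.05,
                               adjust_correlations = FALSE) {
  stopifnot(inherits(dataset, "contagion_dataset"))
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  assert_valid_dataset(dataset)
  trial_scores <- score_trials(dataset)
  summaries <- summarize_participants(trial_scores)

  if (is.finite(fence_k)) {
    flags <- detect_outliers(summaries, fence_multiplier = fence_k)
  } else {
    flags <- detect_outliers(summaries[0L, , drop = FALSE])  # screening off
  }
  excluded_ids <- unique(flags$participant_id)
  kept <- !(summaries$participant_id %in% excluded_ids)
  summaries_used <- summaries[kept, , drop = FALSE]
  trial_scores_used <-
    trial_scores[!(trial_scores$participant_id %in% excluded_ids), ,
                 drop = FALSE]

  cells <- cell_statistics(summaries_used)
  anova_tab <- mixed_anova_2x2(summaries_used)
  t_tests <- paired_t_bonferroni(summaries_used)

  assumptions <- list()
  for (g in GROUPS) {
    for (valence in VALENCES) {
      vals <- summaries_used[summaries_used$group == g,
                             paste0("mean_", valence)]
      if (length(vals) >= 3L) {
        assumptions[[paste("shapiro", g, valence, sep = ".")]] <-
          shapiro_wilk_test(vals)
      }
    }
  }
  for (valence in VALENCES) {
    assumptions[[paste0("brown_forsythe.", valence)]] <-
      brown_forsythe_test(summaries_used[[paste0("mean_", valence)]],
                          summaries_used$group)
  }

  questionnaires <- dataset$participants[, c("participant_id", INSTRUMENTS)]
  correlations <- questionnaire_correlations(summaries_used, questionnaires,
                                             adjust = adjust_correlations)

  gender <- NULL
  if (any(!is.na(trial_scores_used$gender)) &&
      length(unique(stats::na.omit(trial_scores_used$gender))) >= 1L) {
    gender <- gender_effect_lrt(trial_scores_used)
  }

  structure(list(
    n_input = nrow(dataset$participants),
    n_analyzed = nrow(summaries_used),
    n_by_group = table(factor(summaries_used$group, levels = GROUPS)),
    excluded = flags,
    trial_scores = trial_scores_used,
    summaries = summaries_used,
    cells = cells,
    anova = anova_tab,
    t_tests = t_tests,
    assumptions = assumptions,
    correlations = correlations,
    gender = gender,
    settings = list(fence_k = fence_k, alpha = alpha,
                    adjust_correlations = adjust_correlations),
    metadata = dataset$metadata
  ), class = "contagion_fit")
}

#' @export
print.contagion_fit <- function(x, ...) {
  cat("Emotional contagion analysis (3-D affective space)\n")
  cat(sprintf("  participants: %d analyzed of %d (%d excluded as outliers)\n",
              x$n_analyzed, x$n_input, x$n_input - x$n_analyzed))
  cat("  contagion cell means (rows: induction group):\n")
  print(round(x$cells$mean, 2))
  inter <- x$anova[x$anova$source == "group:valence", ]
  cat(sprintf("  interaction: F(%d, %d) = %.3f, p %s, partial eta^2 = %.3f\n",
              inter$df, x$anova$df[x$anova$source == "within_error"],
              inter$F,
              format.pval(inter$p, digits = 3, eps = 1e-3),
              inter$partial_eta_sq))
  invisible(x)
}

#' Summarize a fitted contagion analysis
#'
#' @param object a `contagion_fit`.
#' @param digits rounding for the printed tables.
#' @param ... unused.
#' @return `object`, invisibly; prints cell statistics, the ANOVA table,
#'   follow-up t-tests, assumption checks, questionnaire correlations and the
#'   gender likelihood-ratio test.
#' @export
summary.contagion_fit <- function(object, digits = 3, ...) {
  print(object)
  cat("\ncell SDs:\n")
  print(round(object$cells$sd, 2))
  cat("\n")
  print(object$anova, digits = digits)
  cat("\nfollow-up paired t-tests (Bonferroni m = 2):\n")
  for (g in names(object$t_tests)) {
    cat("  ", g, ": ", sep = "")
    print(object$t_tests[[g]])
  }
  cat("\nassumption checks:\n")
  for (nm in names(object$assumptions)) {
    cat("  ", nm, ": ", sep = "")
    print(object$assumptions[[nm]])
  }
  if (nrow(object$correlations)) {
    cat("\nquestionnaire correlations:\n")
    tab <- object$correlations
    tab$r <- round(tab$r, 2)
    tab$p_value <- round(tab$p_value, 3)
    print(tab, row.names = FALSE)
  }
  if (!is.null(object$gender)) {
    cat("\ngender effect: ")
    print(object$gender)
  }
  invisible(object)
}

#' Cell means of a fitted contagion analysis
#'
#' @param object a `contagion_fit`.
#' @param ... unused.
#' @return named numeric vector of the four contagion cell means,
#'   `<group>.<valence>`.
#' @export
coef.contagion_fit <- function(object, ...) {
  m <- object$cells$mean
  stats::setNames(as.vector(t(m)),
                  as.vector(t(outer(rownames(m), colnames(m), paste,
                                    sep = "."))))
}

#' Bar plot of contagion cell means with 95% confidence intervals
#'
#' @param x a `contagion_fit`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix of bar midpoints.
#' @export
plot.contagion_fit <- function(x, ...) {
  m <- x$cells$mean
  se <- x$cells$sd / sqrt(matrix(rep(as.vector(x$n_by_group), 2), 2))
  n_mat <- matrix(rep(as.vector(x$n_by_group), 2), 2)
  ci <- se * stats::qt(0.975, df = n_mat - 1)
  mid <- graphics::barplot(t(m), beside = TRUE, ylim = c(0, 1),
                           ylab = "mean emotional contagion (0-1)",
                           legend.text = colnames(m),
                           args.legend = list(x = "topright", bty = "n"),
                           ...)
  graphics::arrows(mid, t(m) - t(ci), mid, t(m) + t(ci),
                   angle = 90, code = 3, length = 0.05)
  invisible(mid)
}
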