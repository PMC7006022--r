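# 2 x 2 split-plot (mixed) ANOVA on participant-level contagion summaries:
# one between-subjects factor (induction group, possibly unbalanced) and one
# within-subjects factor (face valence, 2 levels, complete within participant).
#
# With a two-level within factor the decomposition reduces to two orthogonal
# univariate strata: participant means m_i = (happy_i + angry_i)/2 carry the
# between stratum, participant differences d_i = angry_i - happy_i carry the
# within stratum. Effects are tested with Type-III-style (unweighted-marginal)
# sums of squares so unbalanced group sizes do not leak the group effect into
# the valence main effect:
#   SS_group   = 2 * sum_j n_j (mbar_j - mbar)^2
#   SS_subj    = 2 * sum_i (m_i - mbar_{g(i)})^2           (between error)
#   SS_valence = 2 * dbar_u^2 / (1/n1 + 1/n2),  dbar_u = (dbar_1 + dbar_2)/2
#   SS_inter   = (dbar_1 - dbar_2)^2 / (2 (1/n1 + 1/n2))
#   SS_werr    = sum_i (d_i - dbar_{g(i)})^2 / 2           (within error)
# F_group = MS_group/MS_subj on (1, N-2); valence and interaction are tested
# against MS_werr on (1, N-2). Partial eta squared is
# SS_effect / (SS_effect + SS_error-of-that-stratum).

#' Split-plot 2 x 2 mixed ANOVA on contagion summaries
#'
#' @param summaries data frame from [summarize_participants()]: one row per
#'   participant with `group`, `mean_happy`, `mean_angry`. Both induction
#'   groups must have at least 2 participants.
#' @return object of class `contagion_anova`: a data frame with one row per
#'   source (`group`, `subjects_within_groups`, `valence`, `group:valence`,
#'   `within_error`) and columns `ss`, `df`, `ms`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "mean_happy", "mean_angry") %in% names(summaries)))
  groups <- sort(unique(summaries$group))
  if (length(groups) != 2L) {
    stop("exactly 2 induction groups required, got ", length(groups),
         call. = FALSE)
  }
  ns <- table(factor(summaries$group, levels = groups))
  if (any(ns < 2L)) {
    stop("each group needs at least 2 participants (sizes: ",
         paste(ns, collapse = ", "), ")", call. = FALSE)
  }
  if (any(!is.finite(summaries$mean_happy)) ||
      any(!is.finite(summaries$mean_angry))) {
    stop("summaries contain non-finite cell means", call. = FALSE)
  }
  n1 <- ns[[1]]; n2 <- ns[[2]]; n <- n1 + n2
  g <- summaries$group
  m <- (summaries$mean_happy + summaries$mean_angry) / 2
  d <- summaries$mean_angry - summaries$mean_happy

  mbar_g <- tapply(m, factor(g, levels = groups), mean)
  dbar_g <- tapply(d, factor(g, levels = groups), mean)

  ss_group <- 2 * sum(ns * (mbar_g - mean(m))^2)
  ss_subj <- 2 * sum((m - mbar_g[g])^2)
  harm <- 1 / n1 + 1 / n2
  dbar_u <- mean(dbar_g)
  ss_valence <- 2 * dbar_u^2 / harm
  ss_inter <- (dbar_g[[1]] - dbar_g[[2]])^2 / (2 * harm)
  ss_werr <- sum((d - dbar_g[g])^2) / 2

  df_err <- n - 2L
  ms_subj <- ss_subj / df_err
  ms_werr <- ss_werr / df_err
  f_group <- if (ms_subj > 0) ss_group / ms_subj else ifelse(ss_group > 0, Inf, 0)
  f_valence <- if (ms_werr > 0) ss_valence / ms_werr else ifelse(ss_valence > 0, Inf, 0)
  f_inter <- if (ms_werr > 0) ss_inter / ms_werr else ifelse(ss_inter > 0, Inf, 0)

  tab <- data.frame(
    source = c("group", "subjects_within_groups", "valence", "group:valence",
               "within_error"),
    ss = c(ss_group, ss_subj, ss_valence, ss_inter, ss_werr),
    df = c(1L, df_err, 1L, 1L, df_err),
    ms = c(ss_group, ms_subj, ss_valence, ss_inter, ms_werr),
    F = c(f_group, NA, f_valence, f_inter, NA),
    p = c(stats::pf(f_group, 1, df_err, lower.tail = FALSE), NA,
          stats::pf(f_valence, 1, df_err, lower.tail = FALSE),
          stats::pf(f_inter, 1, df_err, lower.tail = FALSE), NA),
    partial_eta_sq = c(ss_group / (ss_group + ss_subj), NA,
                       ss_valence / (ss_valence + ss_werr),
                       ss_inter / (ss_inter + ss_werr), NA),
    stringsAsFactors = FALSE
  )
  # all-zero degenerate strata: define F = 0, eta = 0
  tab$F[!is.na(tab$F) & !is.finite(tab$F) & tab$ss == 0] <- 0
  tab$partial_eta_sq[is.nan(tab$partial_eta_sq)] <- 0
  attr(tab, "groups") <- groups
  attr(tab, "n") <- c(ns[[1]], ns[[2]])
  class(tab) <- c("contagion_anova", "data.frame")
  tab
}

#' @export
`[.contagion_anova` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.contagion_anova <- function(x, digits = 3, ...) {
  cat(sprintf("2 x 2 split-plot ANOVA (groups: %s; n = %s)\n",
              paste(attr(x, "groups"), collapse = " vs "),
              paste(attr(x, "n"), collapse = " + ")))
  out <- as.data.frame(x)
  for (col in c("ss", "ms", "F", "partial_eta_sq")) {
    out[[col]] <- round(out[[col]], digits)
  }
  out$p <- format.pval(out$p, digits = digits, eps = 1e-3)
  print(out, row.names = FALSE)
  invisible(x)
}
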