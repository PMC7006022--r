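# Fixtures built in code: tiny hand-sized datasets plus an independent
# split-plot sums-of-squares oracle used to cross-check mixed_anova_2x2().

# A minimal complete participant: video coordinate plus 10 + 10 trials at
# fixed judgments.
make_participant_rows <- function(id, group, video = c(50, 50, 50),
                                  happy = c(20, 70, 40), angry = c(70, 20, 60),
                                  gender = "woman", age = 21) {
  trials <- data.frame(
    participant_id = id,
    face_id = c(sprintf("happy%02d", 1:10), sprintf("angry%02d", 1:10)),
    valence = rep(c("happy", "angry"), each = 10),
    presentation_order = 1:20,
    negativity = rep(c(happy[1], angry[1]), each = 10),
    positivity = rep(c(happy[2], angry[2]), each = 10),
    arousal = rep(c(happy[3], angry[3]), each = 10),
    stringsAsFactors = FALSE
  )
  participant <- data.frame(
    participant_id = id, group = group, gender = gender, age = age,
    video_negativity = video[1], video_positivity = video[2],
    video_arousal = video[3], stringsAsFactors = FALSE
  )
  list(participant = participant, trials = trials)
}

make_toy_dataset <- function(n_negative = 2, n_positive = 2) {
  parts <- list(); trials <- list()
  ids <- sprintf("S%02d", seq_len(n_negative + n_positive))
  groups <- rep(c("negative_induction", "positive_induction"),
                c(n_negative, n_positive))
  for (i in seq_along(ids)) {
    p <- make_participant_rows(ids[i], groups[i],
                               video = c(40 + i, 50 - i, 45 + i))
    parts[[i]] <- p$participant
    trials[[i]] <- p$trials
  }
  study_dataset(do.call(rbind, parts), do.call(rbind, trials))
}

# summaries table straight from cell values: one row per participant
make_summaries <- function(group, happy, angry) {
  data.frame(participant_id = sprintf("S%02d", seq_along(group)),
             group = group, mean_happy = happy, mean_angry = angry,
             n_happy = 10L, n_angry = 10L, stringsAsFactors = FALSE)
}

# Independent split-plot oracle: least-squares model comparison via lm() with
# sum-to-zero coding on the two orthogonal strata (participant means and
# within-participant differences). F for the valence main effect is the
# squared t of the intercept of the difference model (unweighted-marginal,
# i.e. Type III, convention); F for the interaction is the squared t of the
# group contrast in the same model.
oracle_split_plot_F <- function(summaries) {
  g <- factor(summaries$group)
  m <- (summaries$mean_happy + summaries$mean_angry) / 2
  d <- summaries$mean_angry - summaries$mean_happy
  fit_m <- lm(m ~ g)
  f_group <- anova(fit_m)[["F value"]][1]
  fit_d <- lm(d ~ g, contrasts = list(g = "contr.sum"))
  tt <- summary(fit_d)$coefficients
  c(group = f_group,
    valence = tt["(Intercept)", "t value"]^2,
    interaction = tt["g1", "t value"]^2)
}
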