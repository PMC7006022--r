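# Seeded synthetic-cohort generator. Participants are assigned to a negative
# or positive induction group; each reports a video (induced-state) coordinate
# drawn around the group's video anchor, then judges 10 happy and 10 angry
# faces. Judgments are pulled a fraction `assimilation` of the way from the
# face anchor toward the participant's own induced state — the generative
# formalization of the affect-as-information heuristic — with truncated
# Gaussian rating noise and a participant-level random shift.

#' Configuration for the synthetic-cohort generator
#'
#' @param n_negative,n_positive participants per induction group.
#' @param video_anchor_negative,video_anchor_positive length-3 mean video
#'   rating `(negativity, positivity, arousal)` under each induction.
#' @param face_anchor_happy,face_anchor_angry length-3 mean judgment of a
#'   happy/angry face absent any induction bias.
#' @param assimilation fraction in `[0, 1]` of the face-anchor-to-induced-state
#'   displacement applied to face judgments (0 = judgments ignore the induced
#'   state; 1 = judgments reproduce it exactly).
#' @param rating_sd pre-truncation SD of the per-rating Gaussian noise, in
#'   rating units, applied independently per dimension.
#' @param participant_sd SD of a per-participant random shift (one draw per
#'   dimension, shared across all of that participant's ratings).
#' @param questionnaire_corr target correlation between questionnaire totals
#'   and the participant's mean contagion score.
#' @param proportion_women fraction of participants generated as women.
#' @param seed integer seed; used by [simulate_cohort()] unless overridden.
#' @return object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_negative = 32L,
                          n_positive = 35L,
                          video_anchor_negative = c(95, 10, 80),
                          video_anchor_positive = c(20, 72, 82),
                          face_anchor_happy = c(5, 88, 35),
                          face_anchor_angry = c(88, 5, 50),
                          assimilation = 0.15,
                          rating_sd = 10,
                          participant_sd = 10,
                          questionnaire_corr = 0,
                          proportion_women = 0.507,
                          seed = 1L) {
  config <- list(n_negative = as.integer(n_negative),
                 n_positive = as.integer(n_positive),
                 video_anchor_negative = as.numeric(video_anchor_negative),
                 video_anchor_positive = as.numeric(video_anchor_positive),
                 face_anchor_happy = as.numeric(face_anchor_happy),
                 face_anchor_angry = as.numeric(face_anchor_angry),
                 assimilation = as.numeric(assimilation),
                 rating_sd = as.numeric(rating_sd),
                 participant_sd = as.numeric(participant_sd),
                 questionnaire_corr = as.numeric(questionnaire_corr),
                 proportion_women = as.numeric(proportion_women),
                 seed = as.integer(seed))
  class(config) <- "cohort_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  num <- unlist(config[setdiff(names(config), "seed")])
  if (any(!is.finite(num))) {
    stop("generator config contains non-finite values", call. = FALSE)
  }
  anchors <- c("video_anchor_negative", "video_anchor_positive",
               "face_anchor_happy", "face_anchor_angry")
  for (a in anchors) {
    x <- config[[a]]
    if (length(x) != 3L || any(x < 0 | x > RATING_MAX)) {
      stop(a, " must be 3 values in [0, 100]", call. = FALSE)
    }
  }
  if (config$n_negative < 1L || config$n_positive < 1L) {
    stop("group sizes must be positive", call. = FALSE)
  }
  if (config$assimilation < 0 || config$assimilation > 1) {
    stop("assimilation must lie in [0, 1]", call. = FALSE)
  }
  if (config$rating_sd < 0 || config$participant_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (abs(config$questionnaire_corr) > 1) {
    stop("questionnaire_corr must lie in [-1, 1]", call. = FALSE)
  }
  if (config$proportion_women < 0 || config$proportion_women > 1) {
    stop("proportion_women must lie in [0, 1]", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Truncated-normal draws on [0, 100]
#'
#' Samples `N(mean, sd)` truncated to the rating range by CDF inversion
#' (a uniform draw between the CDF values at the bounds, mapped back through
#' `qnorm`). `sd = 0` degenerates to the mean, clamped to the range.
#'
#' @keywords internal
rtrunc_rating <- function(n, mean, sd) {
  if (sd == 0) return(pmin(pmax(rep_len(mean, n), 0), RATING_MAX))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(RATING_MAX, mean, sd)
  u <- lo + stats::runif(n) * (hi - lo)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, 0), RATING_MAX)  # guards qnorm overflow at u ~ 0 or 1
}

# questionnaire total scales (mean, sd) typical of the published instruments;
# totals are rounded to integers as a summed Likert questionnaire would be
INSTRUMENT_SCALES <- list(ECS = c(45, 8), IRI = c(56, 12),
                          BES = c(70, 10), QPC = c(50, 9))

generate_core <- function(config, seed, video_anchors, face_anchors) {
  n <- config$n_negative + config$n_positive
  group <- rep(GROUPS, c(config$n_negative, config$n_positive))
  set.seed(seed)
  # draw order (fixed; determinism contract): gender, age, participant shift,
  # video ratings, then per participant trial order and judgments, then
  # questionnaire noise
  gender <- ifelse(stats::runif(n) < config$proportion_women, "woman", "man")
  age <- round(rtrunc_rating(n, 21.6, 3.7))  # truncation at 0 never binds
  shift <- matrix(stats::rnorm(n * 3L, 0, config$participant_sd), ncol = 3L)
  video <- matrix(NA_real_, n, 3L)
  for (d in 1:3) {
    mu <- ifelse(group == GROUPS[1], video_anchors[[1]][d],
                 video_anchors[[2]][d]) + shift[, d]
    video[, d] <- rtrunc_rating(n, mu, config$rating_sd)
  }
  face_ids <- c(paste0("happy", sprintf("%02d", 1:10)),
                paste0("angry", sprintf("%02d", 1:10)))
  valence <- rep(VALENCES, each = 10L)
  ids <- sprintf("P%03d", seq_len(n))
  # per-participant random presentation order, then all judgments in one
  # vectorized block per dimension (trial index varies fastest)
  ord <- vapply(seq_len(n), function(i) sample.int(20L), integer(20L))
  delta <- config$assimilation
  jm <- matrix(NA_real_, n * 20L, 3L)
  for (d in 1:3) {
    anchor <- ifelse(valence == VALENCES[1], face_anchors[[1]][d],
                     face_anchors[[2]][d])
    mu <- (1 - delta) * rep(anchor, n) +
      delta * rep(video[, d], each = 20L) + rep(shift[, d], each = 20L)
    jm[, d] <- rtrunc_rating(n * 20L, mu, config$rating_sd)
  }
  trials <- data.frame(
    participant_id = rep(ids, each = 20L),
    face_id = rep(face_ids, n),
    valence = rep(valence, n),
    presentation_order = as.vector(ord),
    negativity = jm[, 1], positivity = jm[, 2], arousal = jm[, 3],
    stringsAsFactors = FALSE
  )
  participants <- data.frame(
    participant_id = ids, group = group, gender = gender, age = age,
    video_negativity = video[, 1], video_positivity = video[, 2],
    video_arousal = video[, 3], stringsAsFactors = FALSE
  )
  # questionnaire totals: Gaussian-copula-style construction against each
  # participant's realized mean contagion
  dataset0 <- study_dataset(participants, trials)
  mean_ec <- summarize_participants(dataset0)
  m <- (mean_ec$mean_happy + mean_ec$mean_angry) / 2
  z_ec <- if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else rep(0, n)
  rho <- config$questionnaire_corr
  for (instr in INSTRUMENTS) {
    scale <- INSTRUMENT_SCALES[[instr]]
    z <- rho * z_ec + sqrt(1 - rho^2) * stats::rnorm(n)
    participants[[instr]] <- round(scale[1] + scale[2] * z)
  }
  study_dataset(participants, trials,
                metadata = list(generator = "contagion3d::simulate_cohort",
                                seed = seed,
                                config = unclass(config)))
}

#' Generate a synthetic study cohort
#'
#' Draws a full study dataset under the generative model described in the
#' package vignette: per-group video anchors, a per-participant Gaussian
#' shift shared across ratings, face judgments pulled toward the realized
#' induced state by the `assimilation` fraction, all ratings truncated to
#' `[0, 100]`, trial order randomized per participant. Identical
#' `(config, seed)` give byte-identical datasets.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with elements `dataset` (a `contagion_dataset`) and `report`
#'   (class `cohort_report`: realized group sizes and contagion cell means).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_config(config)
  dataset <- generate_core(config, seed,
                           list(config$video_anchor_negative,
                                config$video_anchor_positive),
                           list(config$face_anchor_happy,
                                config$face_anchor_angry))
  report <- cohort_report(dataset, config, seed)
  list(dataset = dataset, report = report)
}

#' Generate a null cohort (no group, valence, or interaction effect)
#'
#' Uses the machinery of [simulate_cohort()] but gives both groups the same
#' video anchor (`video_anchor_negative`) and both face categories the same
#' face anchor (`face_anchor_happy`), so the four design cells of the
#' contagion score are identically distributed by construction. Used to
#' calibrate the type-I error of the interaction test.
#'
#' @inheritParams simulate_cohort
#' @return a `contagion_dataset`.
#' @export
simulate_null_cohort <- function(config = cohort_config(),
                                 seed = config$seed) {
  validate_config(config)
  generate_core(config, seed,
                list(config$video_anchor_negative,
                     config$video_anchor_negative),
                list(config$face_anchor_happy, config$face_anchor_happy))
}

cohort_report <- function(dataset, config, seed) {
  summaries <- summarize_participants(dataset)
  cells <- cell_statistics(summaries)
  structure(list(config = config, seed = seed,
                 n_negative = sum(dataset$participants$group == GROUPS[1]),
                 n_positive = sum(dataset$participants$group == GROUPS[2]),
                 cell_means = cells$mean),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  seed: %d | n = %d + %d\n", x$seed, x$n_negative,
              x$n_positive))
  cat("  realized contagion cell means:\n")
  print(round(x$cell_means, 3))
  invisible(x)
}

#' Cell means and SDs of the 2 x 2 design
#'
#' @param summaries data frame from [summarize_participants()].
#' @return list of two 2 x 2 matrices (`mean`, `sd`) with rows
#'   `negative_induction`, `positive_induction` and columns `happy`, `angry`.
#' @export
cell_statistics <- function(summaries) {
  mk <- function(f) {
    m <- matrix(NA_real_, 2L, 2L, dimnames = list(GROUPS, VALENCES))
    for (g in GROUPS) {
      sub <- summaries[summaries$group == g, , drop = FALSE]
      m[g, "happy"] <- f(sub$mean_happy)
      m[g, "angry"] <- f(sub$mean_angry)
    }
    m
  }
  list(mean = mk(function(x) mean(x)), sd = mk(function(x) stats::sd(x)))
}
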