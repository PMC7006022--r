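# Contagion statistic: 1 - Euclidean distance between two affective
# coordinates, rescaled by the maximum possible distance 100 * sqrt(3).

#' Assert ratings lie in the affective-rating range
#'
#' @param x numeric vector or matrix of ratings.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
assert_ratings <- function(x, what = "rating") {
  if (!is.numeric(x)) {
    stop(what, " must be numeric", call. = FALSE)
  }
  bad <- !is.finite(x) | x < 0 | x > RATING_MAX
  if (any(bad)) {
    stop(what, " outside [0, 100] (or non-finite): ",
         paste(utils::head(format(x[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

as_coord_matrix <- function(x, what) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) {
      stop(what, " must have 3 columns (negativity, positivity, arousal)",
           call. = FALSE)
    }
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) {
      stop(what, " must have 3 columns (negativity, positivity, arousal)",
           call. = FALSE)
    }
  }
  assert_ratings(x, what)
  x
}

#' Emotional contagion score between two affective coordinates
#'
#' Computes `ec = 1 - sqrt(((n_v - n_f)^2 + (p_v - p_f)^2 + (a_v - a_f)^2) /
#' (100^2 * 3))`: one minus the Euclidean distance between the induced
#' affective state (`video`) and a face judgment (`face`), divided by the
#' maximum possible distance between two points of the `[0, 100]^3` space
#' (`100 * sqrt(3)`). The score is 1 when the coordinates coincide and 0 when
#' they are maximally distant (e.g. `(0,0,0)` vs `(100,100,100)`).
#'
#' @param video numeric length-3 vector `(negativity, positivity, arousal)` or
#'   an n x 3 matrix/data frame of such coordinates.
#' @param face same shape as `video`.
#' @return numeric vector of scores in `[0, 1]`, one per coordinate pair.
#'   Out-of-range or non-finite coordinates are an error, never clamped.
#' @examples
#' contagion_score(c(40, 60, 50), c(40, 60, 50))  # 1: identical states
#' contagion_score(c(0, 0, 0), c(100, 100, 100))  # 0: maximal distance
#' contagion_score(c(80, 10, 70), c(20, 60, 40))  # ~0.517
#' @export
contagion_score <- function(video, face) {
  v <- as_coord_matrix(video, "video coordinate")
  f <- as_coord_matrix(face, "face coordinate")
  if (nrow(v) != nrow(f)) {
    if (nrow(v) == 1L) v <- v[rep(1L, nrow(f)), , drop = FALSE]
    else if (nrow(f) == 1L) f <- f[rep(1L, nrow(v)), , drop = FALSE]
    else stop("video and face must have the same number of coordinates",
              call. = FALSE)
  }
  1 - sqrt(rowSums((v - f)^2) / (RATING_MAX^2 * 3))
}

#' Per-trial contagion scores for a dataset
#'
#' Scores every complete face trial of every participant against that
#' participant's video (induced-state) coordinate. Trials with any missing
#' rating are dropped with a warning; ratings are never imputed.
#'
#' @param dataset a `contagion_dataset` (see [study_dataset()]).
#' @return data frame with one row per scored trial: `participant_id`,
#'   `group`, `gender`, `face_id`, `valence`, `presentation_order`, `score`.
#' @export
score_trials <- function(dataset) {
  stopifnot(inherits(dataset, "contagion_dataset"))
  pp <- dataset$participants
  tr <- dataset$trials
  complete <- stats::complete.cases(tr[, DIMENSIONS])
  if (any(!complete)) {
    warning(sum(!complete), " trial(s) with missing ratings excluded from scoring")
    tr <- tr[complete, , drop = FALSE]
  }
  idx <- match(tr$participant_id, pp$participant_id)
  video <- as.matrix(pp[idx, paste0("video_", DIMENSIONS)])
  face <- as.matrix(tr[, DIMENSIONS])
  out <- data.frame(
    participant_id = tr$participant_id,
    group = pp$group[idx],
    gender = if ("gender" %in% names(pp)) pp$gender[idx] else NA_character_,
    face_id = tr$face_id,
    valence = tr$valence,
    presentation_order = tr$presentation_order,
    score = contagion_score(video, face),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-participant contagion summaries
#'
#' Averages per-trial contagion scores within each face-valence category,
#' giving the one-value-per-participant-per-cell dependent variable used by
#' the split-plot ANOVA.
#'
#' @param x a `contagion_dataset`, or a per-trial score table as returned by
#'   [score_trials()].
#' @return data frame with one row per participant: `participant_id`, `group`,
#'   `mean_happy`, `mean_angry`, `n_happy`, `n_angry`.
#' @export
summarize_participants <- function(x) {
  scores <- if (inherits(x, "contagion_dataset")) score_trials(x) else x
  stopifnot(is.data.frame(scores),
            all(c("participant_id", "group", "valence", "score") %in% names(scores)))
  ids <- unique(scores$participant_id)
  out <- data.frame(
    participant_id = ids,
    group = scores$group[match(ids, scores$participant_id)],
    mean_happy = NA_real_, mean_angry = NA_real_,
    n_happy = 0L, n_angry = 0L,
    stringsAsFactors = FALSE
  )
  for (valence in VALENCES) {
    sub <- scores[scores$valence == valence, , drop = FALSE]
    n <- tabulate(match(sub$participant_id, ids), length(ids))
    if (any(n == 0L)) {
      stop("participant(s) with zero usable '", valence, "' trials: ",
           paste(ids[n == 0L], collapse = ", "), call. = FALSE)
    }
    s <- vapply(split(sub$score, factor(sub$participant_id, levels = ids)),
                mean, numeric(1))
    out[[paste0("mean_", valence)]] <- unname(s)
    out[[paste0("n_", valence)]] <- n
  }
  rownames(out) <- NULL
  out
}

#' Boxplot-style (Tukey fence) outlier screening of contagion summaries
#'
#' Flags a participant when, within its own induction group, its mean happy or
#' mean angry contagion score falls outside `[Q1 - k*IQR, Q3 + k*IQR]` for
#' that cell — the numerical counterpart of flagging boxplot outliers.
#'
#' @param summaries data frame from [summarize_participants()].
#' @param fence_multiplier fence width `k`; 1.5 is the conventional boxplot
#'   default.
#' @return data frame of flagged participants (possibly 0 rows):
#'   `participant_id`, `group`, `cell`, `value`, `lower`, `upper`, `reason`.
#' @export
detect_outliers <- function(summaries, fence_multiplier = 1.5) {
  stopifnot(is.data.frame(summaries), fence_multiplier >= 0)
  flags <- list()
  for (g in unique(summaries$group)) {
    sub <- summaries[summaries$group == g, , drop = FALSE]
    if (nrow(sub) < 4L) {
      stop("group '", g, "' has fewer than 4 participants; ",
           "Tukey fences are undefined", call. = FALSE)
    }
    for (cell in c("mean_happy", "mean_angry")) {
      q <- stats::quantile(sub[[cell]], c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      lower <- q[1] - fence_multiplier * iqr
      upper <- q[2] + fence_multiplier * iqr
      out <- sub[[cell]] < lower | sub[[cell]] > upper
      if (any(out)) {
        flags[[length(flags) + 1L]] <- data.frame(
          participant_id = sub$participant_id[out],
          group = g,
          cell = cell,
          value = sub[[cell]][out],
          lower = lower,
          upper = upper,
          reason = sprintf("%s = %.4f outside [%.4f, %.4f] (k = %g)",
                           cell, sub[[cell]][out], lower, upper,
                           fence_multiplier),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(flags) == 0L) {
    return(data.frame(participant_id = character(), group = character(),
                      cell = character(), value = numeric(),
                      lower = numeric(), upper = numeric(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
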