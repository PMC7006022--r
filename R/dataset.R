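# Study dataset container: one participants table (induction group,
# demographics, video coordinate, questionnaire totals) plus one trials table
# (20 face judgments per complete participant).

PARTICIPANT_COLS <- c("participant_id", "group", "gender", "age",
                      paste0("video_", DIMENSIONS), INSTRUMENTS)
TRIAL_COLS <- c("participant_id", "face_id", "valence", "presentation_order",
                DIMENSIONS)

#' Construct a study dataset
#'
#' Bundles a participants table and a face-trials table into the container the
#' rest of the package operates on. Missing optional columns (gender, age,
#' questionnaire totals, presentation order) are filled with `NA`.
#'
#' @param participants data frame with columns `participant_id`, `group`
#'   (one of `"negative_induction"`, `"positive_induction"`),
#'   `video_negativity`, `video_positivity`, `video_arousal`, and optionally
#'   `gender`, `age`, `ECS`, `IRI`, `BES`, `QPC`.
#' @param trials data frame with columns `participant_id`, `face_id`,
#'   `valence` (`"happy"` or `"angry"`), `negativity`, `positivity`,
#'   `arousal`, and optionally `presentation_order`.
#' @param metadata named list of free-form provenance (seed, config hash, ...).
#' @return object of class `contagion_dataset`.
#' @seealso [validate_dataset()], [read_ratings_csv()], [simulate_cohort()]
#' @export
study_dataset <- function(participants, trials, metadata = list()) {
  stopifnot(is.data.frame(participants), is.data.frame(trials),
            is.list(metadata))
  for (col in setdiff(c("gender"), names(participants))) {
    participants[[col]] <- rep(NA_character_, nrow(participants))
  }
  for (col in setdiff(c("age", INSTRUMENTS), names(participants))) {
    participants[[col]] <- rep(NA_real_, nrow(participants))
  }
  if (!"presentation_order" %in% names(trials)) {
    trials$presentation_order <- rep(NA_integer_, nrow(trials))
  }
  missing_p <- setdiff(PARTICIPANT_COLS, names(participants))
  if (length(missing_p)) {
    stop("participants table lacks column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  missing_t <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_t)) {
    stop("trials table lacks column(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  participants <- participants[, PARTICIPANT_COLS]
  trials <- trials[, TRIAL_COLS]
  participants$participant_id <- as.character(participants$participant_id)
  trials$participant_id <- as.character(trials$participant_id)
  rownames(participants) <- rownames(trials) <- NULL
  structure(list(participants = participants, trials = trials,
                 metadata = metadata),
            class = "contagion_dataset")
}

#' @export
print.contagion_dataset <- function(x, ...) {
  n_group <- table(factor(x$participants$group, levels = GROUPS))
  cat("<contagion_dataset>\n")
  cat(sprintf("  participants: %d (%s: %d, %s: %d)\n",
              nrow(x$participants), GROUPS[1], n_group[1], GROUPS[2],
              n_group[2]))
  cat(sprintf("  face trials : %d\n", nrow(x$trials)))
  if (length(x$metadata)) {
    cat("  metadata    :", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

violation <- function(severity, participant_id, field, message) {
  data.frame(severity = severity, participant_id = participant_id,
             field = field, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(severity = character(), participant_id = character(),
             field = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a study dataset
#'
#' Checks every invariant of the study design and returns violations as data,
#' never as exceptions: ratings within `[0, 100]`, unique participant ids,
#' recognized group and valence labels, exactly 10 happy and 10 angry trials
#' per participant, no orphan trials. Missing optional fields (gender, age,
#' questionnaire totals) are warnings, not hard errors.
#'
#' @param dataset a `contagion_dataset`.
#' @return data frame of violations with columns `severity` (`"hard"` or
#'   `"warning"`), `participant_id`, `field`, `message`; zero rows when every
#'   invariant holds.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "contagion_dataset"))
  pp <- dataset$participants
  tr <- dataset$trials
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x

  dup <- unique(pp$participant_id[duplicated(pp$participant_id)])
  for (id in dup) {
    add(violation("hard", id, "participant_id", "duplicate participant_id"))
  }
  bad_group <- !pp$group %in% GROUPS
  for (i in which(bad_group)) {
    add(violation("hard", pp$participant_id[i], "group",
                  sprintf("unrecognized group label '%s'", pp$group[i])))
  }
  for (col in paste0("video_", DIMENSIONS)) {
    x <- pp[[col]]
    bad <- !is.na(x) & (!is.finite(x) | x < 0 | x > RATING_MAX)
    for (i in which(bad)) {
      add(violation("hard", pp$participant_id[i], col,
                    sprintf("%s = %s outside [0, 100]", col, format(x[i]))))
    }
    for (i in which(is.na(x))) {
      add(violation("hard", pp$participant_id[i], col,
                    paste(col, "is missing")))
    }
  }
  bad_valence <- !tr$valence %in% VALENCES
  for (i in which(bad_valence)) {
    add(violation("hard", tr$participant_id[i], "valence",
                  sprintf("trial %s has unrecognized valence '%s'",
                          tr$face_id[i], tr$valence[i])))
  }
  for (col in DIMENSIONS) {
    x <- tr[[col]]
    bad <- !is.na(x) & (!is.finite(x) | x < 0 | x > RATING_MAX)
    for (i in which(bad)) {
      add(violation("hard", tr$participant_id[i], col,
                    sprintf("trial %s: %s = %s outside [0, 100]",
                            tr$face_id[i], col, format(x[i]))))
    }
  }
  incomplete <- !stats::complete.cases(tr[, DIMENSIONS])
  for (i in which(incomplete)) {
    add(violation("warning", tr$participant_id[i], "trial",
                  sprintf("trial %s has missing rating(s); it is excluded from aggregation",
                          tr$face_id[i])))
  }
  orphan <- !tr$participant_id %in% pp$participant_id
  for (id in unique(tr$participant_id[orphan])) {
    add(violation("hard", id, "participant_id",
                  "trials reference a participant_id absent from the participants table"))
  }
  # trial counts per valence: the design is 10 happy + 10 angry
  for (i in seq_len(nrow(pp))) {
    id <- pp$participant_id[i]
    sub <- tr[tr$participant_id == id & !incomplete, , drop = FALSE]
    for (valence in VALENCES) {
      n <- sum(sub$valence == valence, na.rm = TRUE)
      if (n != 10L) {
        add(violation("hard", id, "trial count",
                      sprintf("%d complete %s trials (expected 10)", n, valence)))
      }
    }
    for (instr in INSTRUMENTS) {
      if (is.na(pp[[instr]][i])) {
        add(violation("warning", id, instr,
                      paste(instr, "total score is missing")))
      }
    }
  }
  if (length(v) == 0L) return(no_violations())
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Abort on hard validation failures
#' @keywords internal
assert_valid_dataset <- function(dataset) {
  v <- validate_dataset(dataset)
  hard <- v[v$severity == "hard", , drop = FALSE]
  if (nrow(hard)) {
    stop("dataset has ", nrow(hard), " hard validation failure(s); first: ",
         hard$message[1], " (participant ", hard$participant_id[1], ")",
         call. = FALSE)
  }
  invisible(dataset)
}
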