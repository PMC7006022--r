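# CSV I/O for rating data. Two dialects:
#   long — canonical; one row per rating event (1 video + 20 face rows per
#          participant), columns: participant_id, group, gender, age,
#          event_type {video, face}, face_id, valence, negativity, positivity,
#          arousal, presentation_order, ECS, IRI, BES, QPC (questionnaire
#          totals carried on the video row).
#   wide — one row per participant; video_* columns plus, per face slot
#          (happy01..happy10, angry01..angry10), <slot>_face_id,
#          <slot>_negativity, <slot>_positivity, <slot>_arousal,
#          <slot>_presentation_order. Eases hand-made fixtures; *_face_id and
#          *_presentation_order columns are optional on input.
# Files are RFC 4180 CSV (UTF-8, "." decimal) preceded by one "#" comment
# line carrying the schema version.

SCHEMA_VERSION <- "contagion3d ratings schema v1"

LONG_REQUIRED <- c("participant_id", "group", "event_type", DIMENSIONS)

wide_slots <- function() {
  as.vector(t(outer(VALENCES, sprintf("%02d", 1:10), paste0)))
}

parse_numeric <- function(x, col, rows_desc) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop("unparseable number in column '", col, "' (", rows_desc[bad[1]],
         "): '", x[bad[1]], "'", call. = FALSE)
  }
  out
}

check_range <- function(x, col, rows_desc) {
  bad <- which(!is.na(x) & (!is.finite(x) | x < 0 | x > RATING_MAX))
  if (length(bad)) {
    stop("rating outside [0, 100] in column '", col, "' (", rows_desc[bad[1]],
         "): ", format(x[bad[1]]), call. = FALSE)
  }
  x
}

#' Read a ratings CSV into a study dataset
#'
#' @param path CSV file path.
#' @param dialect `"long"` (canonical; one row per rating event) or `"wide"`
#'   (one row per participant). See the package vignette for both schemas.
#' @param col_map optional named character vector renaming input columns to
#'   schema columns, e.g. `c(subject = "participant_id")` — a mapping shim for
#'   externally deposited files whose headers differ from the schema.
#' @param group_map optional named character vector mapping input group labels
#'   to the canonical `"negative_induction"` / `"positive_induction"`.
#' @param valence_map optional named character vector mapping input valence
#'   labels to the canonical `"happy"` / `"angry"`.
#' @return a `contagion_dataset`. Unparseable cells, out-of-range ratings,
#'   missing required columns and duplicate participant ids are errors naming
#'   the offending column/participant, never silently repaired.
#' @export
read_ratings_csv <- function(path, dialect = c("long", "wide"),
                             col_map = NULL, group_map = NULL,
                             valence_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- col_map[names(raw)[hit]]
  }
  remap <- function(x, map) {
    if (is.null(map)) return(x)
    hit <- x %in% names(map)
    x[hit] <- map[x[hit]]
    x
  }
  if (dialect == "long") {
    missing <- setdiff(LONG_REQUIRED, names(raw))
    if (length(missing)) {
      stop("missing required column(s) for long dialect: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    raw$group <- remap(raw$group, group_map)
    if ("valence" %in% names(raw)) raw$valence <- remap(raw$valence, valence_map)
    rows_desc <- sprintf("participant %s, row %d", raw$participant_id,
                         seq_len(nrow(raw)) + 1L)
    for (col in DIMENSIONS) {
      raw[[col]] <- check_range(parse_numeric(raw[[col]], col, rows_desc),
                                col, rows_desc)
    }
    for (col in intersect(c("age", INSTRUMENTS), names(raw))) {
      raw[[col]] <- parse_numeric(raw[[col]], col, rows_desc)
    }
    if ("presentation_order" %in% names(raw)) {
      raw$presentation_order <-
        as.integer(parse_numeric(raw$presentation_order, "presentation_order",
                                 rows_desc))
    }
    is_video <- raw$event_type == "video"
    bad_type <- !raw$event_type %in% c("video", "face")
    if (any(bad_type)) {
      stop("unrecognized event_type '", raw$event_type[which(bad_type)[1]],
           "' (", rows_desc[which(bad_type)[1]], ")", call. = FALSE)
    }
    vid <- raw[is_video, , drop = FALSE]
    if (anyDuplicated(vid$participant_id)) {
      stop("duplicate participant_id: ",
           vid$participant_id[duplicated(vid$participant_id)][1],
           call. = FALSE)
    }
    missing_video <- setdiff(unique(raw$participant_id), vid$participant_id)
    if (length(missing_video)) {
      stop("participant(s) without a video row: ",
           paste(missing_video, collapse = ", "), call. = FALSE)
    }
    participants <- data.frame(
      participant_id = vid$participant_id,
      group = vid$group,
      gender = if ("gender" %in% names(vid)) vid$gender else NA_character_,
      age = if ("age" %in% names(vid)) vid$age else NA_real_,
      video_negativity = vid$negativity,
      video_positivity = vid$positivity,
      video_arousal = vid$arousal,
      stringsAsFactors = FALSE
    )
    for (instr in INSTRUMENTS) {
      participants[[instr]] <-
        if (instr %in% names(vid)) vid[[instr]] else NA_real_
    }
    fc <- raw[!is_video, , drop = FALSE]
    trials <- data.frame(
      participant_id = fc$participant_id,
      face_id = if ("face_id" %in% names(fc)) fc$face_id else NA_character_,
      valence = fc$valence,
      presentation_order = if ("presentation_order" %in% names(fc))
        fc$presentation_order else NA_integer_,
      negativity = fc$negativity,
      positivity = fc$positivity,
      arousal = fc$arousal,
      stringsAsFactors = FALSE
    )
    return(study_dataset(participants, trials,
                         metadata = list(source = path, dialect = "long")))
  }

  # wide dialect
  required <- c("participant_id", "group", paste0("video_", DIMENSIONS))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s) for wide dialect: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$participant_id)) {
    stop("duplicate participant_id: ",
         raw$participant_id[duplicated(raw$participant_id)][1], call. = FALSE)
  }
  raw$group <- remap(raw$group, group_map)
  rows_desc <- sprintf("participant %s", raw$participant_id)
  for (col in c(paste0("video_", DIMENSIONS))) {
    raw[[col]] <- check_range(parse_numeric(raw[[col]], col, rows_desc),
                              col, rows_desc)
  }
  for (col in intersect(c("age", INSTRUMENTS), names(raw))) {
    raw[[col]] <- parse_numeric(raw[[col]], col, rows_desc)
  }
  participants <- data.frame(
    participant_id = raw$participant_id,
    group = raw$group,
    gender = if ("gender" %in% names(raw)) raw$gender else NA_character_,
    age = if ("age" %in% names(raw)) raw$age else NA_real_,
    video_negativity = raw$video_negativity,
    video_positivity = raw$video_positivity,
    video_arousal = raw$video_arousal,
    stringsAsFactors = FALSE
  )
  for (instr in INSTRUMENTS) {
    participants[[instr]] <- if (instr %in% names(raw)) raw[[instr]] else NA_real_
  }
  trials <- list()
  for (slot in wide_slots()) {
    dim_cols <- paste0(slot, "_", DIMENSIONS)
    missing <- setdiff(dim_cols, names(raw))
    if (length(missing)) {
      stop("missing required column(s) for wide dialect: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    vals <- lapply(dim_cols, function(col) {
      check_range(parse_numeric(raw[[col]], col, rows_desc), col, rows_desc)
    })
    id_col <- paste0(slot, "_face_id")
    ord_col <- paste0(slot, "_presentation_order")
    trials[[slot]] <- data.frame(
      participant_id = raw$participant_id,
      face_id = if (id_col %in% names(raw)) raw[[id_col]] else slot,
      valence = remap(rep(sub("[0-9]+$", "", slot), nrow(raw)), valence_map),
      presentation_order = if (ord_col %in% names(raw))
        as.integer(parse_numeric(raw[[ord_col]], ord_col, rows_desc))
      else NA_integer_,
      negativity = vals[[1]], positivity = vals[[2]], arousal = vals[[3]],
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, trials)
  study_dataset(participants, trials,
                metadata = list(source = path, dialect = "wide"))
}

format_numeric_cols <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA,
                          sprintf("%.17g", df[[col]]))
    }
  }
  df
}

order_trials <- function(tr) {
  tr[order(tr$participant_id, tr$valence,
           ifelse(is.na(tr$presentation_order), .Machine$integer.max,
                  tr$presentation_order),
           tr$face_id), , drop = FALSE]
}

#' Write a study dataset to CSV
#'
#' Writes deterministically: participants sorted by `participant_id`, trials
#' by participant, valence, presentation order, face id. Numeric ratings are
#' written with 17 significant digits so that `read_ratings_csv()` recovers
#' them exactly (lossless round trip).
#'
#' @param dataset a `contagion_dataset`; must pass [validate_dataset()] with
#'   no hard violations.
#' @param path output file path.
#' @inheritParams read_ratings_csv
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(dataset, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  assert_valid_dataset(dataset)
  pp <- dataset$participants[order(dataset$participants$participant_id), ,
                             drop = FALSE]
  tr <- order_trials(dataset$trials)
  if (dialect == "long") {
    vid <- data.frame(
      participant_id = pp$participant_id, group = pp$group,
      gender = pp$gender, age = pp$age,
      event_type = rep("video", nrow(pp)),
      face_id = rep(NA_character_, nrow(pp)),
      valence = rep(NA_character_, nrow(pp)),
      presentation_order = rep(NA_integer_, nrow(pp)),
      negativity = pp$video_negativity, positivity = pp$video_positivity,
      arousal = pp$video_arousal,
      stringsAsFactors = FALSE
    )
    for (instr in INSTRUMENTS) vid[[instr]] <- pp[[instr]]
    idx <- match(tr$participant_id, pp$participant_id)
    fc <- data.frame(
      participant_id = tr$participant_id, group = pp$group[idx],
      gender = pp$gender[idx], age = pp$age[idx],
      event_type = rep("face", nrow(tr)),
      face_id = tr$face_id, valence = tr$valence,
      presentation_order = tr$presentation_order,
      negativity = tr$negativity, positivity = tr$positivity,
      arousal = tr$arousal,
      stringsAsFactors = FALSE
    )
    for (instr in INSTRUMENTS) fc[[instr]] <- rep(NA_real_, nrow(fc))
    long <- rbind(vid, fc)
    long <- long[order(long$participant_id, long$event_type != "video"), ,
                 drop = FALSE]
    # keep trial ordering within participant
    long <- long[order(long$participant_id,
                       long$event_type != "video",
                       match(paste(long$participant_id, long$face_id),
                             paste(tr$participant_id, tr$face_id))), ,
                 drop = FALSE]
    out <- format_numeric_cols(long)
  } else {
    out <- data.frame(participant_id = pp$participant_id, group = pp$group,
                      gender = pp$gender, age = pp$age,
                      video_negativity = pp$video_negativity,
                      video_positivity = pp$video_positivity,
                      video_arousal = pp$video_arousal,
                      stringsAsFactors = FALSE)
    for (slot in wide_slots()) {
      valence <- sub("[0-9]+$", "", slot)
      k <- as.integer(sub("^[a-z]+", "", slot))
      for (col in c("face_id", DIMENSIONS, "presentation_order")) {
        out[[paste0(slot, "_", col)]] <-
          vapply(pp$participant_id, function(id) {
            sub <- tr[tr$participant_id == id & tr$valence == valence, ,
                      drop = FALSE]
            if (k > nrow(sub)) return(NA_character_)
            as.character(sub[[col]][k])
          }, character(1))
      }
      for (dim in DIMENSIONS) {
        col <- paste0(slot, "_", dim)
        out[[col]] <- sprintf("%.17g", as.numeric(out[[col]]))
      }
    }
    for (instr in INSTRUMENTS) out[[instr]] <- pp[[instr]]
    out <- format_numeric_cols(out)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA_VERSION, " (", dialect, ")"), con)
  utils::write.csv(out, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
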