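test_that("valid datasets validate cleanly; design violations are reported", {
  ds <- make_toy_dataset()
  v <- validate_dataset(ds)
  expect_equal(sum(v$severity == "hard"), 0L)
  # missing questionnaire totals are warnings only
  expect_true(all(v$severity == "warning"))

  # 9 happy trials -> hard trial-count violation
  ds2 <- make_toy_dataset()
  ds2$trials <- ds2$trials[-which(ds2$trials$participant_id == "S01" &
                                    ds2$trials$valence == "happy")[1], ]
  v2 <- validate_dataset(ds2)
  hard <- v2[v2$severity == "hard", ]
  expect_equal(nrow(hard), 1L)
  expect_equal(hard$field, "trial count")
  expect_equal(hard$participant_id, "S01")

  # out-of-range rating -> hard violation naming the field
  ds3 <- make_toy_dataset()
  ds3$trials$arousal[5] <- 101
  v3 <- validate_dataset(ds3)
  expect_true(any(v3$severity == "hard" & v3$field == "arousal"))

  # duplicate participant id -> hard violation
  ds4 <- make_toy_dataset()
  ds4$participants$participant_id[2] <- "S01"
  v4 <- validate_dataset(ds4)
  expect_true(any(v4$field == "participant_id" &
                    grepl("duplicate", v4$message)))
})

test_that("synthetic cohorts pass validation with zero hard violations", {
  sim <- simulate_cohort(cohort_config(seed = 3))
  v <- validate_dataset(sim$dataset)
  expect_equal(sum(v$severity == "hard"), 0L)
})

test_that("CSV round trip is lossless in both dialects", {
  sim <- simulate_cohort(cohort_config(n_negative = 3, n_positive = 4,
                                       seed = 11))
  ds <- sim$dataset
  for (dialect in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_ratings_csv(ds, path, dialect = dialect)
    back <- read_ratings_csv(path, dialect = dialect)
    ord <- order(ds$participants$participant_id)
    expect_equal(back$participants[, names(back$participants)],
                 ds$participants[ord, ], ignore_attr = TRUE)
    # trials compare after canonical ordering
    key <- function(tr) tr[order(tr$participant_id, tr$face_id), ]
    got <- key(back$trials); want <- key(ds$trials)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
    # parsing never mutates values: rating sums identical
    expect_identical(sum(got[, c("negativity", "positivity", "arousal")]),
                     sum(want[, c("negativity", "positivity", "arousal")]))
  }
})

test_that("long reader builds one participant from video + trial rows", {
  p <- make_participant_rows("P1", "positive_induction")
  ds <- study_dataset(p$participant, p$trials)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ds, path, dialect = "long")
  lines <- readLines(path)
  expect_match(lines[1], "^# contagion3d ratings schema")
  expect_equal(length(lines), 1L + 1L + 21L)  # comment + header + rows
  back <- read_ratings_csv(path, "long")
  expect_equal(nrow(back$participants), 1L)
  expect_equal(nrow(back$trials), 20L)
})

test_that("reader errors name the offending column or participant", {
  p <- make_participant_rows("P1", "positive_induction")
  ds <- study_dataset(p$participant, p$trials)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ds, path, dialect = "long")

  # rating outside [0, 100]
  txt <- readLines(path)
  txt <- sub("^P1,positive_induction,woman,21,face,happy01,happy,1,20,70,40",
             "P1,positive_induction,woman,21,face,happy01,happy,1,101,70,40",
             txt)
  writeLines(txt, path)
  expect_error(read_ratings_csv(path, "long"), "negativity.*101|101.*negativity")

  # missing required column
  txt2 <- readLines(path)
  txt2[2] <- sub("negativity", "neg", txt2[2])
  writeLines(txt2, path)
  expect_error(read_ratings_csv(path, "long"), "negativity")

  expect_error(read_ratings_csv(file.path(tempdir(), "absent.csv"), "long"),
               "does not exist")
})

test_that("duplicate participants and unparseable cells are rejected", {
  p1 <- make_participant_rows("P1", "positive_induction")
  p2 <- make_participant_rows("P1", "negative_induction")
  ds <- study_dataset(rbind(p1$participant,
                            transform(p2$participant, participant_id = "P2")),
                      rbind(p1$trials,
                            transform(p2$trials, participant_id = "P2")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ds, path, "long")
  txt <- readLines(path)
  txt <- gsub("^P2,", "P1,", txt)
  writeLines(txt, path)
  expect_error(read_ratings_csv(path, "long"), "duplicate participant_id")

  writeLines(sub("(P1,positive_induction,woman,21,face,happy01,happy,1,)20",
                 "\\1twenty", readLines(path)), path)
  expect_error(read_ratings_csv(path, "long"), "unparseable")
})

test_that("empty dataset writes a header-only file", {
  ds <- study_dataset(
    data.frame(participant_id = character(), group = character(),
               video_negativity = numeric(), video_positivity = numeric(),
               video_arousal = numeric(), stringsAsFactors = FALSE),
    data.frame(participant_id = character(), face_id = character(),
               valence = character(), negativity = numeric(),
               positivity = numeric(), arousal = numeric(),
               stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ds, path, "long")
  lines <- readLines(path)
  expect_equal(length(lines), 2L)  # schema comment + header
})

test_that("group and column mapping shims translate external labels", {
  p <- make_participant_rows("P1", "positive_induction")
  ds <- study_dataset(p$participant, p$trials)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ds, path, "long")
  txt <- readLines(path)
  txt <- gsub("positive_induction", "pos", txt)
  txt[2] <- sub("participant_id", "subject", txt[2])
  writeLines(txt, path)
  back <- read_ratings_csv(path, "long",
                           col_map = c(subject = "participant_id"),
                           group_map = c(pos = "positive_induction"))
  expect_equal(back$participants$group, "positive_induction")
  expect_equal(back$participants$participant_id, "P1")
})
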