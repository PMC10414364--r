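write_notes_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- "ADMISSION_ID,AGE,CHARTTIME,CATEGORY,TEXT"
  writeLines(c(header, rows), path)
  path
}

test_that("load_notes reads well-formed files and reports malformed rows", {
  empty <- write_notes_csv(character())
  expect_equal(nrow(load_notes(empty)), 0)

  three <- write_notes_csv(c(
    'A1,70,2007-01-01 08:00:00,Nursing,first note',
    'A2,55,2007-01-02 09:00:00,Physician,second note',
    'A1,70,2007-01-03 10:00:00,Nursing,third note'))
  rec <- load_notes(three)
  expect_equal(nrow(rec), 3)
  expect_identical(rec$TEXT, c("first note", "second note", "third note"))

  bad_ts <- write_notes_csv(c(
    'A1,70,2007-01-01 08:00:00,Nursing,ok',
    'A2,55,not-a-date,Physician,bad'))
  expect_error(load_notes(bad_ts), "CHARTTIME at row\\(s\\) 2")

  no_col <- tempfile(fileext = ".csv")
  writeLines(c("ADMISSION_ID,AGE,CHARTTIME,CATEGORY", "A1,70,2007-01-01,N"), no_col)
  expect_error(load_notes(no_col), "missing column.*TEXT")
})

test_that("filter_cohort removes whole admissions below the age cut", {
  rec <- load_notes(write_notes_csv(c(
    'A1,70,2007-01-01 08:00:00,Nursing,a',
    'A1,70,2007-01-02 08:00:00,Nursing,b',
    'A2,10,2007-01-01 08:00:00,Nursing,c')))
  kept <- filter_cohort(rec, min_age = 16)
  expect_identical(unique(kept$ADMISSION_ID), "A1")
  expect_identical(filter_cohort(rec, min_age = 0), rec)
  expect_error(filter_cohort(rec, min_age = -1))
})

test_that("a cohort with 5 underage admissions of 100 retains 95", {
  co <- generate_cohort(synth_config(n_admissions_per_group = 50,
                                     n_underage = 5, seed = 13))
  dir <- tempfile(); write_cohort(co, dir)
  notes <- load_notes(file.path(dir, "notes.csv"))
  expect_equal(length(unique(notes$ADMISSION_ID)), 100)
  kept <- filter_cohort(notes, min_age = 16)
  expect_equal(length(unique(kept$ADMISSION_ID)), 95)
})

test_that("assemble_documents concatenates chronologically, stable on ties", {
  one <- load_notes(write_notes_csv('A1,70,2007-01-01 08:00:00,Nursing,only note'))
  d <- assemble_documents(one)
  expect_equal(d$text, "only note")
  expect_equal(d$note_count, 1L)

  shuffled <- load_notes(write_notes_csv(c(
    'A1,70,2007-01-02 08:00:00,Nursing,later',
    'A1,70,2007-01-01 08:00:00,Nursing,earlier')))
  expect_equal(assemble_documents(shuffled)$text, "earlier\nlater")

  tied <- load_notes(write_notes_csv(c(
    'A1,70,2007-01-01 08:00:00,Nursing,first in file',
    'A1,70,2007-01-01 08:00:00,Nursing,second in file')))
  expect_equal(assemble_documents(tied)$text, "first in file\nsecond in file")

  expect_error(assemble_documents(one[0, ]), "no note records")
})

test_that("assembly yields one document per admission and preserves every note", {
  co <- generate_cohort(synth_config(n_admissions_per_group = 10,
                                     notes_per_admission = c(3L, 3L), seed = 6))
  docs <- assemble_documents(co$notes)
  expect_equal(nrow(docs), length(unique(co$notes$ADMISSION_ID)))
  expect_true(all(docs$note_count == 3))
  # concatenation preserves each member note's characters exactly once
  for (id in docs$admission_id[1:3]) {
    member <- co$notes$TEXT[co$notes$ADMISSION_ID == id]
    text <- docs$text[docs$admission_id == id]
    expect_equal(nchar(text), sum(nchar(member)) + length(member) - 1L)
    for (m in member) expect_true(grepl(m, text, fixed = TRUE))
  }
  expected_first <- vapply(docs$admission_id, function(id)
    min(as.numeric(as.POSIXct(co$notes$CHARTTIME[co$notes$ADMISSION_ID == id],
                              tz = "UTC"))), numeric(1))
  expect_equal(as.numeric(docs$first_charttime), unname(expected_first))
})
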