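# Reading note/code tables, cohort filtering, and per-admission document
# assembly (all notes of an admission concatenated in chronological order).

.notes_schema <- c("ADMISSION_ID", "AGE", "CHARTTIME", "CATEGORY", "TEXT")

#' Load a notes table
#'
#' Expects a CSV with header ADMISSION_ID, AGE, CHARTTIME (ISO-8601),
#' CATEGORY, TEXT. Quoted fields may contain embedded newlines.
#'
#' @param path CSV file path
#' @return data frame of note records, one per row, in file order, with a
#'   parsed `charttime` POSIXct column.
#' @export
load_notes <- function(path) {
  if (!file.exists(path)) stopf("notes file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.notes_schema, names(df))
  if (length(missing)) {
    stopf("schema error: notes table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$charttime <- as.POSIXct(character(), tz = "UTC")
    return(df)
  }
  bad_id <- which(is.na(df$ADMISSION_ID) | df$ADMISSION_ID == "")
  if (length(bad_id)) {
    stopf("malformed notes: empty ADMISSION_ID at row(s) %s",
          paste(bad_id, collapse = ", "))
  }
  ct <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(ct)
    if (!any(todo)) break
    ct[todo] <- as.POSIXct(strptime(df$CHARTTIME[todo], fmt, tz = "UTC"))
  }
  bad_ct <- which(is.na(ct))
  if (length(bad_ct)) {
    stopf("malformed notes: unparseable CHARTTIME at row(s) %s",
          paste(bad_ct, collapse = ", "))
  }
  df$AGE <- as.numeric(df$AGE)
  df$charttime <- ct
  df
}

#' Load a codes table
#'
#' CSV with header ADMISSION_ID, CODE_TYPE, CODE.
#' @param path CSV file path
#' @return data frame of code records
#' @export
load_codes <- function(path) {
  if (!file.exists(path)) stopf("codes file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("ADMISSION_ID", "CODE_TYPE", "CODE"), names(df))
  if (length(missing)) {
    stopf("schema error: codes table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  df
}

#' Filter the cohort by age at admission
#'
#' Removes every note of any admission whose age is below `min_age`.
#' Admissions without notes never appear in a notes table, so they are
#' absent from the result by construction.
#'
#' @param records notes data frame from [load_notes()]
#' @param min_age minimum age in years (default 16, the adult-hospital cut)
#' @return the surviving note records
#' @export
filter_cohort <- function(records, min_age = 16) {
  if (min_age < 0) stopf("min_age must be >= 0")
  if (nrow(records) == 0) return(records)
  adm_age <- tapply(records$AGE, records$ADMISSION_ID, function(a) a[1])
  keep_adm <- names(adm_age)[adm_age >= min_age]
  records[records$ADMISSION_ID %in% keep_adm, , drop = FALSE]
}

#' Assemble one document per admission
#'
#' Concatenates each admission's notes sorted ascending by charttime
#' (stable on ties, preserving input order), joined with a newline.
#'
#' @param records notes data frame from [load_notes()] (non-empty)
#' @param groups optional named character vector mapping admission id to a
#'   group label, attached as the `group` column
#' @return data frame with one row per admission: `admission_id`, `text`,
#'   `note_count`, `first_charttime`, and optionally `group`
#' @export
assemble_documents <- function(records, groups = NULL) {
  if (nrow(records) == 0) stopf("assemble_documents: no note records")
  if (is.null(records$charttime)) {
    records$charttime <- as.POSIXct(records$CHARTTIME, tz = "UTC")
  }
  ord <- order(records$ADMISSION_ID, records$charttime)  # stable sort
  records <- records[ord, , drop = FALSE]
  ids <- unique(records$ADMISSION_ID)
  split_idx <- split(seq_len(nrow(records)), records$ADMISSION_ID)[ids]
  docs <- data.frame(
    admission_id = ids,
    text = vapply(split_idx, function(ix)
      paste(records$TEXT[ix], collapse = "\n"), character(1)),
    note_count = vapply(split_idx, length, integer(1)),
    first_charttime = as.POSIXct(
      vapply(split_idx, function(ix) as.numeric(records$charttime[ix][1]),
             numeric(1)),
      origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  rownames(docs) <- NULL
  if (!is.null(groups)) docs$group <- unname(groups[docs$admission_id])
  docs
}

#' Load an admission-to-group label mapping
#'
#' Two-column CSV (admission id, label), returned as a named character
#' vector suitable for [assemble_documents()].
#' @param path CSV file path
#' @return named character vector
#' @export
load_group_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stopf("group map needs two columns (admission id, label)")
  setNames(df[[2]], df[[1]])
}
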