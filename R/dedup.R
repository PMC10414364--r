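# Replicate-text removal within one admission document.
#
# Concatenated clinical notes repeat boilerplate paragraphs, sentences and
# list items verbatim; the replicates distort term statistics and slow
# manual review, so only the first occurrence of each unit is kept.
# Detection is exact-match on a normalized key, applied within a single
# admission document only — never across admissions.

# canonical form used for duplicate matching: lowercase, whitespace collapsed
.normalize_key <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

.abbreviations <- c("dr.", "mr.", "mrs.", "ms.", "st.", "vs.", "etc.",
                    "e.g.", "i.e.", "no.", "approx.")

#' Segment a document into duplicate-detection units
#'
#' Clinical notes break sentences with both regular punctuation and bare
#' newlines, and frequently use numbered/bulleted lists. Units are split on
#' sentence-final periods/question marks and on newline boundaries; list
#' markers ("1.", "a)"), decimal points ("1.23") and common abbreviations
#' ("dr.") do not split. Empty and whitespace-only units are dropped.
#'
#' @param text one document's text (may be empty)
#' @return data frame with columns `raw` (the trimmed unit text),
#'   `normalized_key` (lowercased, whitespace-collapsed form used for
#'   duplicate matching) and `position` (ordinal within the document)
#' @export
segment_units <- function(text) {
  stopifnot(length(text) == 1L)
  units <- character()
  for (line in strsplit(text, "\n", fixed = TRUE)[[1]]) {
    if (!nzchar(trimws(line))) next
    # candidate breaks: '.' or '?' followed by whitespace or line end
    cand <- gregexpr("[.?](?=\\s|$)", line, perl = TRUE)[[1]]
    if (cand[1] == -1L) {
      units <- c(units, trimws(line))
      next
    }
    start <- 1L
    for (pos in cand) {
      seg <- substr(line, start, pos)
      # word carrying the terminator (from last whitespace to the mark)
      word <- sub("^.*[[:space:]]", "", seg)
      if (substr(line, pos, pos) == "." &&
          (tolower(word) %in% .abbreviations ||
           grepl("^\\(?[0-9]+\\.$", trimws(seg)) ||   # numbered list marker
           grepl("^\\(?[a-z]\\.$", trimws(seg)))) {   # lettered list marker
        next
      }
      if (nzchar(trimws(seg))) units <- c(units, trimws(seg))
      start <- pos + 1L
    }
    if (start <= nchar(line) && nzchar(trimws(substr(line, start, nchar(line))))) {
      units <- c(units, trimws(substr(line, start, nchar(line))))
    }
  }
  data.frame(raw = units,
             normalized_key = .normalize_key(units),
             position = seq_along(units),
             stringsAsFactors = FALSE)
}

#' Remove or mark replicate units
#'
#' For each normalized key, the first-occurring unit is kept; later
#' occurrences are dropped (`mode = "remove"`, the pipeline default) or
#' wrapped in visible markers for audit output (`mode = "mark"`). Order is
#' preserved and units are rejoined with newlines.
#'
#' @param units data frame from [segment_units()]
#' @param mode `"remove"` or `"mark"`
#' @return the deduplicated (or marked) document text
#' @export
remove_duplicates <- function(units, mode = c("remove", "mark")) {
  mode <- match.arg(mode)
  if (nrow(units) == 0) return("")
  dup <- duplicated(units$normalized_key)
  if (mode == "remove") {
    return(paste(units$raw[!dup], collapse = "\n"))
  }
  out <- units$raw
  out[dup] <- paste0("[[DUPLICATE]] ", out[dup], " [[/DUPLICATE]]")
  paste(out, collapse = "\n")
}

#' Deduplicate one document
#'
#' Convenience wrapper: [segment_units()] then [remove_duplicates()].
#' @inheritParams segment_units
#' @inheritParams remove_duplicates
#' @return deduplicated document text
#' @export
dedup_document <- function(text, mode = "remove") {
  remove_duplicates(segment_units(text), mode = mode)
}

#' Deduplicate every document of an assembled corpus
#'
#' @param documents data frame from [assemble_documents()]
#' @param mode passed to [remove_duplicates()]
#' @return `documents` with the `text` column deduplicated per admission
#' @export
dedup_documents <- function(documents, mode = "remove") {
  documents$text <- vapply(documents$text, dedup_document, character(1),
                           mode = mode, USE.NAMES = FALSE)
  documents
}
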