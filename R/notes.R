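#' Read clinical notes from a JSON-lines file
#'
#' One note per line, UTF-8. Recognised fields: `note_id`, `patient_id`,
#' `text`, `note_type`, `encounter_type`, `department_name`, `specialty`,
#' `provider_type`, `icd10_codes` (array of code strings), `year`. Missing
#' metadata fields are filled with empty strings so downstream filters never
#' fail on absent keys.
#'
#' @param path Path to a JSONL file.
#' @return A data frame of notes, one row per note, with `icd10_codes` as a
#'   list column.
#' @seealso [write_notes()], [select_social_notes()], [filter_notes()]
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  as_notes(data.frame(
    note_id         = vapply(recs, function(r) as.character(r$note_id %||% NA_character_), ""),
    patient_id      = vapply(recs, function(r) as.character(r$patient_id %||% NA_character_), ""),
    text            = vapply(recs, function(r) as.character(r$text %||% ""), ""),
    note_type       = vapply(recs, function(r) as.character(r$note_type %||% ""), ""),
    encounter_type  = vapply(recs, function(r) as.character(r$encounter_type %||% ""), ""),
    department_name = vapply(recs, function(r) as.character(r$department_name %||% ""), ""),
    specialty       = vapply(recs, function(r) as.character(r$specialty %||% ""), ""),
    provider_type   = vapply(recs, function(r) as.character(r$provider_type %||% ""), ""),
    year            = vapply(recs, function(r) as.integer(r$year %||% NA_integer_), 1L),
    stringsAsFactors = FALSE
  ), icd10 = lapply(recs, function(r) as.character(unlist(r$icd10_codes))))
}

#' Write clinical notes to a JSON-lines file
#'
#' @param notes A notes data frame as returned by [read_notes()] or
#'   [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(
      note_id         = notes$note_id[i],
      patient_id      = notes$patient_id[i],
      text            = notes$text[i],
      note_type       = notes$note_type[i],
      encounter_type  = notes$encounter_type[i],
      department_name = notes$department_name[i],
      specialty       = notes$specialty[i],
      provider_type   = notes$provider_type[i],
      icd10_codes     = notes$icd10_codes[[i]],
      year            = notes$year[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Attach the icd10_codes list column and validate note_id uniqueness.
as_notes <- function(df, icd10 = NULL) {
  if (!is.null(icd10)) df$icd10_codes <- icd10
  if (is.null(df$icd10_codes)) df$icd10_codes <- replicate(nrow(df), character(0), simplify = FALSE)
  ids <- df$note_id[!is.na(df$note_id)]
  if (anyDuplicated(ids)) stop("note_id values must be unique within a corpus")
  df
}

#' Select notes whose metadata marks them as social work notes
#'
#' Keeps exactly the notes where the substring "social" occurs,
#' case-insensitively, in at least one of the encounter type, department
#' name, specialty, or provider type. Input order is preserved. Missing
#' (NA) metadata fields are treated as empty strings.
#'
#' @param notes A notes data frame.
#' @return The subset of `notes` flagged as social work notes.
#' @examples
#' notes <- generate_corpus(corpus_config(n_docs_per_category = 3, seed = 1))$notes
#' nrow(select_social_notes(notes)) <= nrow(notes)
#' @export
select_social_notes <- function(notes) {
  fields <- c("encounter_type", "department_name", "specialty", "provider_type")
  hit <- rep(FALSE, nrow(notes))
  for (f in fields) {
    v <- notes[[f]]
    if (is.null(v)) next
    v[is.na(v)] <- ""
    hit <- hit | grepl("social", v, ignore.case = TRUE)
  }
  notes[hit, , drop = FALSE]
}

#' Remove short and duplicate notes
#'
#' Drops every note whose raw text is under 30 characters, then removes
#' exact duplicate texts keeping the first occurrence. Line endings are
#' normalized (CRLF/CR to LF) before duplicate comparison so that byte-level
#' end-of-line differences do not defeat exact matching. Order is otherwise
#' preserved.
#'
#' @param notes A notes data frame.
#' @param min_chars Minimum raw text length in characters; notes strictly
#'   shorter are removed. Default 30.
#' @return The filtered notes data frame, with attribute `"drop_counts"`:
#'   a named integer vector with elements `short` and `duplicate`.
#' @export
filter_notes <- function(notes, min_chars = 30L) {
  if (nrow(notes) == 0L) {
    attr(notes, "drop_counts") <- c(short = 0L, duplicate = 0L)
    return(notes)
  }
  len <- nchar(notes$text, type = "chars")
  keep_len <- len >= min_chars
  n_short <- sum(!keep_len)
  out <- notes[keep_len, , drop = FALSE]
  norm <- gsub("\r\n?", "\n", out$text)
  dup <- duplicated(norm)
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  attr(out, "drop_counts") <- c(short = n_short, duplicate = n_dup)
  out
}

#' Tabulate patients by their number of notes
#'
#' Counts distinct patients holding exactly one note, between 2 and 5 notes
#' (inclusive), and more than 5 notes. The three strata always sum to the
#' distinct-patient total.
#'
#' @param notes A notes data frame carrying `patient_id`.
#' @return A data frame with columns `stratum` and `n_patients`, plus a
#'   final `total` row.
#' @export
summarize_cohort <- function(notes) {
  per_patient <- table(notes$patient_id)
  strata <- c(
    `1`     = sum(per_patient == 1L),
    `2-5`   = sum(per_patient >= 2L & per_patient <= 5L),
    `>5`    = sum(per_patient > 5L)
  )
  data.frame(
    stratum    = c(names(strata), "total"),
    n_patients = c(unname(strata), length(per_patient)),
    stringsAsFactors = FALSE
  )
}
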