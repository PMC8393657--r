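#' Define a diagnosis-code cohort
#'
#' A cohort is selected by ICD codes: a patient is retained when at least
#' one code matches an include prefix (wildcard-style, e.g. `"Q90"` for
#' `Q90*`) or an exact include code, and no code matches an exclude code.
#' Matching is on dot-stripped codes, so `"Q90"` covers `Q90.1`.
#'
#' @param include_prefixes Character vector of code prefixes.
#' @param include_exact Character vector of exact codes.
#' @param exclude_exact Character vector of exact codes forcing exclusion.
#' @return A list of class `cohort_definition`.
#' @export
cohort_definition <- function(include_prefixes = character(),
                              include_exact = character(),
                              exclude_exact = character()) {
  inc <- c(include_prefixes, include_exact)
  clash <- intersect(strip_dots(inc), strip_dots(exclude_exact))
  if (length(clash)) {
    abort(sprintf("include and exclude sets overlap: %s",
                  paste(clash, collapse = ", ")))
  }
  structure(list(include_prefixes = include_prefixes,
                 include_exact = include_exact,
                 exclude_exact = exclude_exact),
            class = "cohort_definition")
}

#' Cohort definition used for the trisomy 21 case cohort
#'
#' Includes ICD-10 `Q90*` and ICD-9 `758.0`; excludes the 22q11.2-deletion
#' codes (ICD-10 `Q93.81`, `D82.1`; ICD-9 `279.11`, `758.32`) that mark
#' similar yet distinct patients.
#'
#' @return A `cohort_definition`.
#' @export
down_syndrome_cohort <- function() {
  cohort_definition(
    include_prefixes = "Q90",
    include_exact = "758.0",
    exclude_exact = c("Q93.81", "D82.1", "279.11", "758.32")
  )
}

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

#' Select patients matching a cohort definition
#'
#' @param patients Data frame with columns `patient_id` and `icd_codes`
#'   (a list-column of character vectors, or a character column of
#'   `;`-separated codes).
#' @param definition A [cohort_definition()].
#' @return The retained rows as a tibble, input order preserved.
#' @export
select_cohort <- function(patients, definition) {
  stopifnot(inherits(definition, "cohort_definition"))
  patients <- as_tibble(patients)
  if (nrow(patients) == 0) return(patients)
  codes <- patients$icd_codes
  if (!is.list(codes)) codes <- strsplit(as.character(codes), ";", fixed = TRUE)
  codes <- lapply(codes, function(x) strip_dots(x[!is.na(x) & nzchar(x)]))
  inc_pref <- strip_dots(definition$include_prefixes)
  inc_exact <- strip_dots(definition$include_exact)
  exc <- strip_dots(definition$exclude_exact)
  keep <- vapply(codes, function(cs) {
    if (length(cs) == 0) return(FALSE)
    hit <- any(cs %in% inc_exact) ||
      (length(inc_pref) > 0 &&
         any(vapply(inc_pref, function(p) any(startsWith(cs, p)), logical(1))))
    hit && !any(cs %in% exc)
  }, logical(1))
  patients[keep, , drop = FALSE]
}

#' Note-quality assessment
#'
#' A note passes when its raw character count (whitespace included) is at
#' least `min_chars` and its text matches `header_pattern` — by default a
#' case-insensitive medical-record-number header (`MRN`, optional
#' separator, at least six digits), the hallmark of a properly formatted
#' note. A note below the length threshold is reported as `"too_short"`
#' even if it also lacks a header.
#'
#' @param notes Data frame with at least a `text` column.
#' @param min_chars Minimum character count; notes with fewer characters
#'   (strictly) are rejected.
#' @param header_pattern Regular expression that formatted notes match.
#' @return The input tibble with logical `passes`, `too_short` and
#'   `no_header` columns and a primary character `reason` (`NA`,
#'   `"too_short"` or `"no_header"`) appended, so a note failing both
#'   checks reports both.
#' @export
note_quality <- function(notes, min_chars = 3000,
                         header_pattern = default_header_pattern()) {
  notes <- as_tibble(notes)
  nc <- nchar(notes$text, type = "chars")
  has_header <- stringr::str_detect(notes$text, header_pattern)
  reason <- dplyr::case_when(
    nc < min_chars ~ "too_short",
    !has_header ~ "no_header",
    TRUE ~ NA_character_
  )
  notes$passes <- is.na(reason)
  notes$too_short <- nc < min_chars
  notes$no_header <- !has_header
  notes$reason <- reason
  notes
}

#' @rdname note_quality
#' @export
default_header_pattern <- function() "(?i)MRN[[:space:]:#-]*[0-9]{6,}"

#' Filter a note corpus on length and formatting quality
#'
#' Applies [note_quality()] per note and splits the corpus into retained
#' notes and a rejection tally. The filter is stateless across notes, and
#' retained plus rejected always equals the input count.
#'
#' @inheritParams note_quality
#' @return A list with `notes` (retained rows, quality columns dropped)
#'   and `rejections` (tibble of `reason`, `n`; zero rows when nothing was
#'   rejected).
#' @export
filter_corpus <- function(notes, min_chars = 3000,
                          header_pattern = default_header_pattern()) {
  qc <- note_quality(notes, min_chars = min_chars, header_pattern = header_pattern)
  tally <- qc |>
    filter(!.data$passes) |>
    count(.data$reason, name = "n")
  kept <- qc |>
    filter(.data$passes) |>
    select(-"passes", -"reason", -"too_short", -"no_header")
  list(notes = kept, rejections = tally)
}

#' Read and write clinical-note tables
#'
#' Notes travel as tab-separated tables with one row per note and columns
#' `note_id`, `patient_id`, `note_date` (ISO-8601), `birth_date`
#' (ISO-8601), `text`; extra columns (e.g. `cohort`) round-trip
#' unchanged. Note text must be single-line (the synthetic generator
#' guarantees this; EHR exports should be flattened upstream).
#'
#' @param path File path.
#' @param notes Notes tibble.
#' @return `read_notes()` returns a tibble with date columns parsed;
#'   `write_notes()` returns `path` invisibly.
#' @export
read_notes <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    note_id = readr::col_character(),
    patient_id = readr::col_character(),
    note_date = readr::col_date(),
    birth_date = readr::col_date(),
    text = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  bad <- !is.na(out$note_date) & !is.na(out$birth_date) & out$note_date < out$birth_date
  if (any(bad)) {
    abort(sprintf("%d note(s) dated before the patient's birth date", sum(bad)))
  }
  out
}

#' @rdname read_notes
#' @export
write_notes <- function(notes, path) {
  if (any(grepl("[\t\n]", notes$text))) {
    abort("note text must not contain tabs or newlines in the delimited format")
  }
  readr::write_tsv(notes, path, progress = FALSE)
  invisible(path)
}

#' Read and write patient tables
#'
#' Patients travel as tab-separated tables with columns `patient_id`,
#' `icd_codes` (`;`-separated), `birth_date` and any extra columns.
#'
#' @param path File path.
#' @param patients Patients tibble (`icd_codes` may be a list-column).
#' @return A tibble with `icd_codes` as a list-column, or `path`.
#' @export
read_patients <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    icd_codes = readr::col_character(),
    birth_date = readr::col_date(),
    .default = readr::col_character()
  ), progress = FALSE)
  out$icd_codes <- lapply(
    strsplit(dplyr::coalesce(out$icd_codes, ""), ";", fixed = TRUE),
    function(x) x[nzchar(x)]
  )
  out
}

#' @rdname read_patients
#' @export
write_patients <- function(patients, path) {
  patients <- as_tibble(patients)
  if (is.list(patients$icd_codes)) {
    patients$icd_codes <- vapply(patients$icd_codes, paste, character(1),
                                 collapse = ";")
  }
  readr::write_tsv(patients, path, progress = FALSE)
  invisible(path)
}
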