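#' Compute a phenotype frequency spectrum
#'
#' For every ontology term observed in an annotated corpus, computes the
#' four corpus measures:
#' * term frequency `tf` — total mention count, duplicates included;
#' * document frequency `df` — number of notes containing the term;
#' * inverse document frequency `idf = total_notes / df` (a plain ratio,
#'   no logarithm) and `tf_idf = tf * idf`;
#' * patient count and patient frequency — the fraction of the cohort's
#'   patients with at least one occurrence in any note, counted once per
#'   patient.
#'
#' With `propagate = TRUE`, each note's distinct term set is replaced by
#' its ancestor closure (root excluded) before document and patient
#' counting, so general terms accrue credit from specific ones. Term
#' frequency always counts literal mentions only: propagation adds
#' set-valued document/patient credit, never inflated mention counts, so
#' an ancestor never literally written in a note carries `tf = 0`.
#'
#' @param mentions Mentions tibble ([annotate_notes()] or
#'   [ingest_cui_annotations()]); mentions on notes absent from `notes`
#'   are ignored.
#' @param notes The corpus the denominators refer to (all retained notes,
#'   with `note_id` and `patient_id`). Patients appear in the denominator
#'   iff they have at least one retained note.
#' @param ontology A `phenotype_ontology`; required when
#'   `propagate = TRUE`, otherwise used only to attach term names.
#' @param propagate Propagate each note's term set to ancestors first?
#' @param cohort Label stored with the table (e.g. `"case"`,
#'   `"baseline"`).
#' @return A tibble of class `spectrum_tbl`, one row per term with
#'   columns `term_id`, `term_name`, `term_frequency`,
#'   `document_frequency`, `inverse_document_frequency`, `tf_idf`,
#'   `patient_count`, `patient_frequency`, sorted by descending patient
#'   frequency (ties by term id). Totals and the cohort label are carried
#'   as attributes and via [glance()].
#' @export
compute_spectrum <- function(mentions, notes, ontology = NULL,
                             propagate = FALSE, cohort = "case") {
  notes <- as_tibble(notes)
  if (nrow(notes) == 0) abort("empty corpus", class = "phenospectr_empty_corpus")
  if (propagate && is.null(ontology)) {
    abort("an ontology is required when propagate = TRUE")
  }
  total_notes <- nrow(notes)
  total_patients <- n_distinct(notes$patient_id)

  mentions <- as_tibble(mentions)
  mentions <- mentions[mentions$note_id %in% notes$note_id, , drop = FALSE]

  tf <- count(mentions, .data$term_id, name = "term_frequency")

  pairs <- distinct(mentions[, c("note_id", "term_id")])
  if (propagate) {
    prop <- propagation_table(ontology, unique(pairs$term_id))
    pairs <- pairs |>
      inner_join(prop, by = "term_id", relationship = "many-to-many") |>
      distinct(.data$note_id, term_id = .data$propagated_id)
  }
  df <- count(pairs, .data$term_id, name = "document_frequency")
  pat <- pairs |>
    left_join(notes[, c("note_id", "patient_id")], by = "note_id") |>
    distinct(.data$patient_id, .data$term_id) |>
    count(.data$term_id, name = "patient_count")

  out <- df |>
    left_join(pat, by = "term_id") |>
    left_join(tf, by = "term_id") |>
    mutate(
      term_frequency = dplyr::coalesce(.data$term_frequency, 0L),
      inverse_document_frequency = total_notes / .data$document_frequency,
      tf_idf = .data$term_frequency * .data$inverse_document_frequency,
      patient_frequency = .data$patient_count / total_patients
    )
  out$term_name <- if (!is.null(ontology)) {
    ontology$terms$name[match(out$term_id, ontology$terms$term_id)]
  } else {
    NA_character_
  }
  out <- out[, c("term_id", "term_name", "term_frequency",
                 "document_frequency", "inverse_document_frequency",
                 "tf_idf", "patient_count", "patient_frequency")]
  out <- arrange(out, desc(.data$patient_frequency), .data$term_id)
  new_spectrum_tbl(out, cohort = cohort, total_notes = total_notes,
                   total_patients = total_patients, propagated = propagate)
}

new_spectrum_tbl <- function(x, cohort, total_notes, total_patients,
                             propagated, n_baseline_filtered = 0L) {
  structure(
    x,
    cohort = cohort,
    total_notes = total_notes,
    total_patients = total_patients,
    propagated = propagated,
    n_baseline_filtered = n_baseline_filtered,
    class = c("spectrum_tbl", class(tibble()))
  )
}

spectrum_attrs <- function(x) {
  attributes(x)[c("cohort", "total_notes", "total_patients", "propagated",
                  "n_baseline_filtered")]
}

#' Remove baseline-noise terms from a case spectrum
#'
#' Drops every case term whose patient frequency in the baseline cohort is
#' strictly greater than `threshold` (default 5%): such terms mirror the
#' habitual annotation noise of clinical notes rather than the disease.
#' Terms absent from the baseline are retained. Both spectra should be
#' computed with identical propagation settings, or the comparison is
#' biased.
#'
#' @param case_spectrum,baseline_spectrum `spectrum_tbl` objects.
#' @param threshold Baseline patient-frequency cutoff (strict `>`
#'   removal; a term at exactly the threshold is retained).
#' @return The filtered case `spectrum_tbl`; the removed terms are
#'   recorded in attributes `removed_terms` and `n_baseline_filtered`.
#' @export
apply_baseline_filter <- function(case_spectrum, baseline_spectrum,
                                  threshold = 0.05) {
  noisy <- baseline_spectrum$term_id[baseline_spectrum$patient_frequency > threshold]
  removed <- intersect(case_spectrum$term_id, noisy)
  at <- spectrum_attrs(case_spectrum)
  out <- case_spectrum[!case_spectrum$term_id %in% noisy, , drop = FALSE]
  out <- new_spectrum_tbl(as_tibble(out), cohort = at$cohort,
                          total_notes = at$total_notes,
                          total_patients = at$total_patients,
                          propagated = at$propagated,
                          n_baseline_filtered = length(removed))
  attr(out, "removed_terms") <- removed
  out
}

#' Rank terms by a spectrum or enrichment measure
#'
#' Orders terms by a numeric column in descending order, breaking ties by
#' ascending term id so the ranking is deterministic, and keeps the top
#' `top_k` (or all, if fewer are available).
#'
#' @param x A data frame with a `term_id` column (e.g. a `spectrum_tbl`
#'   or enrichment table).
#' @param key Column to rank on, e.g. `"patient_frequency"` or
#'   `"odds_ratio"`.
#' @param top_k Number of terms to keep.
#' @return The top rows as a tibble in rank order.
#' @export
rank_terms <- function(x, key = "patient_frequency", top_k = 100L) {
  if (!key %in% names(x)) {
    abort(sprintf("unknown ranking key: %s", key))
  }
  as_tibble(x) |>
    arrange(desc(.data[[key]]), .data$term_id) |>
    slice_head(n = top_k)
}

#' Write a spectrum or enrichment table
#'
#' Fixed column order, tab-separated, ratios serialized at six
#' significant digits so outputs are diff-stable.
#'
#' @param x The table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  x <- as_tibble(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 6))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
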