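#' Age at a clinical note
#'
#' Fractional age in years at the note date, computed as the day count
#' from birth divided by 365.25 (leap-year-neutral convention).
#'
#' @param note_date,birth_date `Date` vectors (recycled as usual).
#' @return Numeric vector of ages in years.
#' @export
age_at_note <- function(note_date, birth_date) {
  age <- as.numeric(as.Date(note_date) - as.Date(birth_date)) / 365.25
  if (any(age < 0, na.rm = TRUE)) {
    abort("note_date precedes birth_date")
  }
  age
}

#' Define an age-bin grid
#'
#' Half-open bins `[lo, lo + width)`; the default is 3-month (0.25-year)
#' bins spanning ages 0 to 12.5 years. An age exactly on a boundary falls
#' in the upper bin; ages outside `[min_age, max_age)` are out of range.
#'
#' @param bin_width Bin width in years (default 0.25 = 3 months).
#' @param min_age,max_age Grid extent in years; the span must be a whole
#'   number of bins.
#' @return A list of class `age_bin_grid` with `bin_width`, `min_age`,
#'   `max_age`, `n_bins` and the lower `edges`.
#' @export
age_bin_grid <- function(bin_width = 0.25, min_age = 0, max_age = 12.5) {
  stopifnot(bin_width > 0, max_age > min_age)
  n_bins <- (max_age - min_age) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("(max_age - min_age) must be a whole number of bins")
  }
  n_bins <- as.integer(round(n_bins))
  structure(list(bin_width = bin_width, min_age = min_age, max_age = max_age,
                 n_bins = n_bins,
                 edges = min_age + bin_width * seq.int(0L, n_bins - 1L)),
            class = "age_bin_grid")
}

#' Bin ordinal of an age
#'
#' @param age Ages in years (vectorised).
#' @param grid An [age_bin_grid()].
#' @return Integer vector of 0-based bin ordinals; `NA` marks an
#'   out-of-range age (including `max_age` itself, the grid being
#'   half-open).
#' @export
bin_index <- function(age, grid) {
  stopifnot(inherits(grid, "age_bin_grid"))
  idx <- floor((age - grid$min_age) / grid$bin_width)
  idx <- as.integer(idx)
  idx[age < grid$min_age | age >= grid$max_age] <- NA_integer_
  idx
}

#' Term-by-age-bin visit count matrix
#'
#' For each requested term and age bin, counts the notes (patient visits)
#' whose age falls in the bin and whose — optionally propagated — term
#' set contains the term; a note counts once per term regardless of how
#' many times the term is mentioned in it. Notes aging outside the grid
#' are tallied per term in `out_of_range`, so for every term
#' `sum(counts) + out_of_range` equals the number of notes containing it.
#'
#' @param mentions Mentions tibble.
#' @param notes Notes tibble with `note_id`, `note_date`, `birth_date`.
#' @param terms Ordered character vector of term ids (row order of the
#'   result, e.g. from [rank_terms()]).
#' @param grid An [age_bin_grid()].
#' @param ontology,propagate As in [compute_spectrum()].
#' @return A tibble of class `term_age_matrix` in long format: `term_id`,
#'   `bin` (0-based ordinal), `bin_lo` (lower age edge), `n_notes`; one
#'   row per term and bin (zeros included). Attributes carry the grid,
#'   the term order and the per-term `out_of_range` tally.
#' @export
build_term_age_matrix <- function(mentions, notes, terms,
                                  grid = age_bin_grid(),
                                  ontology = NULL, propagate = FALSE) {
  stopifnot(length(terms) > 0)
  notes <- as_tibble(notes)
  pairs <- distinct(as_tibble(mentions)[, c("note_id", "term_id")])
  pairs <- pairs[pairs$note_id %in% notes$note_id, , drop = FALSE]
  if (propagate) {
    if (is.null(ontology)) abort("an ontology is required when propagate = TRUE")
    prop <- propagation_table(ontology, unique(pairs$term_id))
    pairs <- pairs |>
      inner_join(prop, by = "term_id", relationship = "many-to-many") |>
      distinct(.data$note_id, term_id = .data$propagated_id)
  }
  known <- unique(c(pairs$term_id,
                    if (!is.null(ontology)) ontology$terms$term_id))
  unknown <- setdiff(terms, known)
  if (length(unknown)) {
    abort(sprintf("unknown term(s) requested: %s",
                  paste(head(unknown, 10), collapse = ", ")))
  }
  pairs <- pairs[pairs$term_id %in% terms, , drop = FALSE]

  ages <- tibble(
    note_id = notes$note_id,
    bin = bin_index(age_at_note(notes$note_date, notes$birth_date), grid)
  )
  hits <- left_join(pairs, ages, by = "note_id")

  grid_tbl <- tidyr::expand_grid(term_id = terms, bin = seq.int(0L, grid$n_bins - 1L))
  counts <- hits |>
    filter(!is.na(.data$bin)) |>
    count(.data$term_id, .data$bin, name = "n_notes")
  out <- grid_tbl |>
    left_join(counts, by = c("term_id", "bin")) |>
    mutate(n_notes = dplyr::coalesce(.data$n_notes, 0L),
           bin_lo = grid$min_age + .data$bin * grid$bin_width) |>
    relocate("bin_lo", .after = "bin")

  oor <- hits |>
    filter(is.na(.data$bin)) |>
    count(.data$term_id, name = "n")
  out_of_range <- setNames(rep(0L, length(terms)), terms)
  out_of_range[oor$term_id] <- oor$n

  structure(out,
            grid = grid, terms = terms, out_of_range = out_of_range,
            class = c("term_age_matrix", class(tibble())))
}

#' Widen a term-age matrix
#'
#' @param x A `term_age_matrix`.
#' @return A wide tibble: one row per term in the stored order, one
#'   column per bin lower edge, plus `out_of_range`.
#' @export
term_age_wide <- function(x) {
  stopifnot(inherits(x, "term_age_matrix"))
  terms <- attr(x, "terms")
  wide <- as_tibble(x) |>
    select("term_id", "bin_lo", "n_notes") |>
    tidyr::pivot_wider(names_from = "bin_lo", values_from = "n_notes")
  wide <- wide[match(terms, wide$term_id), , drop = FALSE]
  wide$out_of_range <- unname(attr(x, "out_of_range")[terms])
  wide
}
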