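#' Build a surface-form lexicon from an ontology
#'
#' Collects every term's preferred name and synonyms (plus optional extra
#' labels) into a normalized dictionary used by the annotator. Labels are
#' normalized by lowercasing and collapsing runs of whitespace and
#' punctuation to single spaces between word tokens; a form shared by
#' several terms keeps all of their ids.
#'
#' @param ontology A `phenotype_ontology`.
#' @param mapping Optional `cui_mapping`; when given, its term ids are
#'   checked against the ontology.
#' @param extra_labels Optional data frame with columns `term_id`,
#'   `label` contributing additional surface forms.
#' @return An object of class `phenotype_lexicon`: a named list of
#'   term-id character vectors keyed by normalized form, with attribute
#'   `max_tokens`.
#' @export
build_lexicon <- function(ontology, mapping = NULL, extra_labels = NULL) {
  stopifnot(inherits(ontology, "phenotype_ontology"))
  ids <- ontology$terms$term_id
  if (!is.null(mapping)) {
    stray <- setdiff(mapping$term_id, ids)
    if (length(stray)) {
      abort(sprintf("mapping refers to term id(s) absent from the ontology: %s",
                    paste(head(stray, 5), collapse = ", ")))
    }
  }
  lab_tbl <- tibble(
    term_id = rep(ids, 1L + lengths(ontology$synonyms[ids])),
    label = unlist(purrr::map2(ontology$terms$name, ontology$synonyms[ids], c),
                   use.names = FALSE) %||% character(0)
  )
  if (!is.null(extra_labels)) {
    extra_labels <- as_tibble(extra_labels)
    stray <- setdiff(extra_labels$term_id, ids)
    if (length(stray)) {
      abort(sprintf("extra labels refer to unknown term id(s): %s",
                    paste(stray, collapse = ", ")))
    }
    lab_tbl <- bind_rows(lab_tbl, extra_labels[, c("term_id", "label")])
  }
  lab_tbl$form <- normalize_label(lab_tbl$label)
  lab_tbl <- lab_tbl[nzchar(lab_tbl$form), ]
  forms <- lapply(split(lab_tbl$term_id, lab_tbl$form), function(x) sort(unique(x)))
  structure(forms,
            max_tokens = if (length(forms)) {
              max(stringr::str_count(names(forms), stringr::fixed(" "))) + 1L
            } else 0L,
            class = "phenotype_lexicon")
}

normalize_label <- function(x) {
  toks <- stringr::str_extract_all(tolower(x), "[a-z0-9]+")
  vapply(toks, paste, character(1), collapse = " ")
}

#' @export
print.phenotype_lexicon <- function(x, ...) {
  cat(sprintf("<phenotype_lexicon> %d surface forms (longest %d token(s))\n",
              length(x), attr(x, "max_tokens")))
  invisible(x)
}

#' Annotate notes with dictionary term mentions
#'
#' A deterministic concept recogniser: note text is tokenised into word
#' tokens, token n-grams are looked up in the lexicon case-insensitively,
#' and overlapping candidate spans are resolved longest-match-first with
#' ties going to the leftmost span. Every surviving occurrence is
#' reported, duplicates included, so downstream term frequency reflects
#' the true mention count. Matches occur only at token boundaries
#' (`"cat"` never fires inside `"concatenated"`). Negated mentions are
#' not detected or removed.
#'
#' @param notes Data frame with columns `note_id` and `text` (extra
#'   columns such as `patient_id` are carried onto the mentions).
#' @param lexicon A [build_lexicon()] result.
#' @return A tibble of mentions: `note_id`, `term_id`, `start`, `end`
#'   (0-based, half-open character offsets), `matched_text`, plus
#'   `patient_id` when present in `notes`. Slicing the note text at
#'   `[start, end)` reproduces `matched_text` exactly.
#' @export
annotate_notes <- function(notes, lexicon) {
  stopifnot(inherits(lexicon, "phenotype_lexicon"))
  notes <- as_tibble(notes)
  if (length(lexicon) == 0 || nrow(notes) == 0) return(empty_mentions(notes))
  text <- notes$text
  locs <- stringr::str_locate_all(text, "[A-Za-z0-9]+")
  n_tok <- vapply(locs, nrow, integer(1))
  if (sum(n_tok) == 0) return(empty_mentions(notes))
  note_idx <- rep(seq_along(text), n_tok)
  loc <- do.call(rbind, locs)
  tok_start <- loc[, 1]
  tok_end <- loc[, 2]
  tok_str <- tolower(stringr::str_sub(text[note_idx], tok_start, tok_end))

  max_k <- attr(lexicon, "max_tokens")
  forms <- names(lexicon)
  cand <- list()
  ntot <- length(tok_str)
  gram <- tok_str
  for (k in seq_len(max_k)) {
    if (k > 1) {
      idx <- seq_len(ntot - k + 1L)
      gram <- paste(gram[idx], tok_str[idx + (k - 1L)])
    } else {
      idx <- seq_len(ntot)
    }
    same_note <- note_idx[idx] == note_idx[idx + (k - 1L)]
    hit <- same_note & gram %in% forms
    if (any(hit)) {
      i <- idx[hit]
      cand[[k]] <- tibble(
        note = note_idx[i],
        start = tok_start[i],
        end = tok_end[i + (k - 1L)],
        form = gram[hit]
      )
    }
    gram <- gram[seq_len(max(0L, ntot - k))]
    if (ntot - k < 1L) break
  }
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) return(empty_mentions(notes))

  cand <- cand[order(cand$note, -(cand$end - cand$start), cand$start), ]
  keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$note), function(rows) {
    acc_s <- integer(0)
    acc_e <- integer(0)
    ok <- logical(length(rows))
    for (j in seq_along(rows)) {
      s <- cand$start[rows[j]]
      e <- cand$end[rows[j]]
      if (!any(s <= acc_e & e >= acc_s)) {
        ok[j] <- TRUE
        acc_s <- c(acc_s, s)
        acc_e <- c(acc_e, e)
      }
    }
    rows[ok]
  }), use.names = FALSE)
  cand <- cand[sort(keep), ]

  ids_per_form <- lexicon[cand$form]
  out <- tibble(
    note_id = rep(notes$note_id[cand$note], lengths(ids_per_form)),
    term_id = unlist(ids_per_form, use.names = FALSE),
    start = rep(cand$start - 1L, lengths(ids_per_form)),
    end = rep(cand$end, lengths(ids_per_form)),
    matched_text = rep(stringr::str_sub(text[cand$note], cand$start, cand$end),
                       lengths(ids_per_form))
  )
  if ("patient_id" %in% names(notes)) {
    out <- left_join(out, notes[, c("note_id", "patient_id")], by = "note_id") |>
      relocate("patient_id", .after = "note_id")
  }
  out[order(match(out$note_id, notes$note_id), out$start, out$term_id), ]
}

empty_mentions <- function(notes) {
  out <- tibble(
    note_id = character(0), term_id = character(0),
    start = integer(0), end = integer(0), matched_text = character(0)
  )
  if ("patient_id" %in% names(notes)) {
    out$patient_id <- character(0)
    out <- relocate(out, "patient_id", .after = "note_id")
  }
  out
}

#' @rdname annotate_notes
#' @param text A single note text string.
#' @export
annotate_text <- function(text, lexicon) {
  stopifnot(length(text) == 1)
  annotate_notes(tibble(note_id = "note1", text = text), lexicon)
}

#' Ingest externally produced CUI annotations
#'
#' Converts a flat table of per-note UMLS concept hits (as an NLP engine
#' such as MetaMap would emit, one row per extracted concept instance)
#' into term mentions by translating each CUI through the concept
#' mapping. A CUI mapping to several term ids yields one mention per id;
#' CUIs absent from the mapping are skipped and counted. Character
#' offsets are not available on this path and are recorded as `NA`.
#'
#' @param rows Data frame with columns `note_id`, `cui`.
#' @param mapping A [parse_mrconso()] mapping.
#' @param notes Notes tibble the annotations refer to (used to resolve
#'   `note_id` and attach `patient_id`).
#' @return A mentions tibble as in [annotate_notes()] with `NA` offsets,
#'   plus attribute `n_unmapped` counting rows whose CUI had no mapping.
#' @export
ingest_cui_annotations <- function(rows, mapping, notes) {
  rows <- as_tibble(rows)
  unknown <- setdiff(rows$note_id, notes$note_id)
  if (length(unknown)) {
    abort(sprintf("annotation rows refer to unknown note id(s): %s",
                  paste(head(unknown, 10), collapse = ", ")))
  }
  hit <- inner_join(rows, mapping, by = "cui", relationship = "many-to-many")
  n_unmapped <- sum(!rows$cui %in% mapping$cui)
  out <- tibble(
    note_id = hit$note_id,
    term_id = hit$term_id,
    start = NA_integer_,
    end = NA_integer_,
    matched_text = NA_character_
  )
  if ("patient_id" %in% names(notes)) {
    out <- left_join(out, notes[, c("note_id", "patient_id")], by = "note_id") |>
      relocate("patient_id", .after = "note_id")
  }
  out <- out[order(match(out$note_id, notes$note_id), out$term_id), ]
  attr(out, "n_unmapped") <- n_unmapped
  out
}
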