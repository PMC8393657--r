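lens_lexicon <- function() build_lexicon(chain_ontology())

test_that("lexicon collects names and synonyms, normalized, with collisions kept", {
  lex <- lens_lexicon()
  expect_equal(lex[["cataract"]], "HP:0000518")
  expect_equal(lex[["cataracts"]], "HP:0000518")  # synonym, quotes stripped
  expect_equal(lex[["zonular cataract"]], "HP:0010920")

  shared <- parse_obo(obo_from_parents(
    list("R:1" = character(0), "A:1" = "R:1", "B:1" = "R:1"),
    synonyms = list("A:1" = "big ear", "B:1" = "big ear")
  ), root_id = "R:1")
  lex2 <- build_lexicon(shared)
  expect_setequal(lex2[["big ear"]], c("A:1", "B:1"))

  empty <- build_lexicon(parse_obo(character(0)))
  expect_length(empty, 0)

  expect_error(build_lexicon(chain_ontology(),
                             extra_labels = tibble::tibble(term_id = "HP:1",
                                                           label = "x")),
               regexp = "HP:1")
})

test_that("annotation prefers the longest match, leftmost on ties", {
  lex <- lens_lexicon()
  m <- annotate_text("Dense zonular cataract noted.", lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$term_id, "HP:0010920")
  expect_equal(m$matched_text, "zonular cataract")
  expect_equal(substr("Dense zonular cataract noted.", m$start + 1, m$end),
               "zonular cataract")
})

test_that("every occurrence is reported, duplicates preserved with offsets", {
  lex <- lens_lexicon()
  txt <- "cataract seen; later cataract again"
  m <- annotate_text(txt, lex)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(0L, 21L))
  expect_equal(unique(m$term_id), "HP:0000518")
})

test_that("matching respects token boundaries and case-insensitivity", {
  onto <- parse_obo(obo_from_parents(
    list("R:1" = character(0), "C:1" = "R:1"),
    synonyms = list("C:1" = "cat")
  ), root_id = "R:1")
  lex <- build_lexicon(onto)
  expect_equal(nrow(annotate_text("concatenated words", lex)), 0)
  expect_equal(nrow(annotate_text("a CAT appeared", lex)), 1)
  expect_equal(annotate_text("a CAT appeared", lex)$matched_text, "CAT")
})

test_that("identical text and lexicon give identical mention lists", {
  lex <- lens_lexicon()
  txt <- "cataract and zonular cataract and Cataracts"
  expect_identical(annotate_text(txt, lex), annotate_text(txt, lex))
})

test_that("mention offsets always re-slice to the matched text", {
  set.seed(5)
  gen <- generate_ontology(synth_config(seed = 3))
  cfg <- synth_config(seed = 3, n_case_patients = 15L, n_baseline_patients = 5L,
                      note_length = list(mean = 900, sd = 150, min = 300))
  corpus <- generate_corpus(cfg, gen$ontology, gen$mapping)
  lex <- build_lexicon(gen$ontology, gen$mapping)
  m <- annotate_notes(corpus$notes, lex)
  expect_gt(nrow(m), 0)
  txt <- setNames(corpus$notes$text, corpus$notes$note_id)
  expect_identical(substr(txt[m$note_id], m$start + 1, m$end),
                   setNames(m$matched_text, m$note_id))
})

test_that("adding a lexicon form never removes non-overlapping mentions", {
  base <- parse_obo(obo_from_parents(
    list("R:1" = character(0), "A:1" = "R:1", "B:1" = "R:1"),
    synonyms = list("A:1" = "blue sclera")
  ), root_id = "R:1")
  small <- build_lexicon(base)
  bigger <- build_lexicon(base, extra_labels = tibble::tibble(
    term_id = "B:1", label = "joint laxity"))
  txt <- "blue sclera with joint laxity"
  m1 <- annotate_text(txt, small)
  m2 <- annotate_text(txt, bigger)
  expect_true(all(m1$matched_text %in% m2$matched_text))
  expect_equal(nrow(m2), 2)
})

test_that("ingest translates CUI rows through the mapping", {
  onto <- chain_ontology()
  mapping <- tibble::tibble(cui = c("C0010951", "C0409998", "C0409998"),
                            term_id = c("HP:0000518", "HP:0000517", "HP:0012372"))
  class(mapping) <- c("cui_mapping", class(mapping))
  notes <- make_notes(c("n1", "n2"), c("p1", "p2"))

  m <- ingest_cui_annotations(tibble::tibble(note_id = "n1", cui = "C0010951"),
                              mapping, notes)
  expect_equal(m$term_id, "HP:0000518")
  expect_equal(m$patient_id, "p1")
  expect_true(is.na(m$start))

  m2 <- ingest_cui_annotations(tibble::tibble(note_id = "n1", cui = "C9999999"),
                               mapping, notes)
  expect_equal(nrow(m2), 0)
  expect_equal(attr(m2, "n_unmapped"), 1)

  m3 <- ingest_cui_annotations(tibble::tibble(note_id = "n2", cui = "C0409998"),
                               mapping, notes)
  expect_equal(nrow(m3), 2)

  expect_error(ingest_cui_annotations(tibble::tibble(note_id = "nope", cui = "C1"),
                                      mapping, notes),
               regexp = "nope")
})
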