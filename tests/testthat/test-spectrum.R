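mentions_tbl <- function(note_id, term_id) {
  tibble::tibble(note_id = note_id, term_id = term_id,
                 start = 0L, end = 1L, matched_text = "x")
}

test_that("frequency measures match hand arithmetic on a 3-note corpus", {
  notes <- make_notes(c("n1", "n2", "n3"), c("P1", "P1", "P2"))
  mentions <- mentions_tbl(c("n1", "n1", "n2"), rep("HP:0000518", 3))
  sp <- compute_spectrum(mentions, notes)
  row <- sp[sp$term_id == "HP:0000518", ]
  expect_equal(row$term_frequency, 3)
  expect_equal(row$document_frequency, 2)
  expect_equal(row$inverse_document_frequency, 3 / 2)
  expect_equal(row$tf_idf, 4.5)
  expect_equal(row$patient_count, 1)
  expect_equal(row$patient_frequency, 0.5)
  expect_equal(glance(sp)$total_notes, 3)
  expect_equal(glance(sp)$total_patients, 2)
})

test_that("a single-mention corpus sits at the identity scale", {
  notes <- make_notes("n1", "P1")
  sp <- compute_spectrum(mentions_tbl("n1", "HP:0000518"), notes)
  expect_equal(sp$term_frequency, 1)
  expect_equal(sp$document_frequency, 1)
  expect_equal(sp$inverse_document_frequency, 1)
  expect_equal(sp$tf_idf, 1)
  expect_equal(sp$patient_frequency, 1)
  expect_error(compute_spectrum(mentions_tbl("n1", "HP:0000518"), notes[0, ]),
               class = "phenospectr_empty_corpus")
})

test_that("propagation credits ancestors' document and patient counts, not tf", {
  onto <- chain_ontology()
  notes <- make_notes(c("n1", "n2"), c("P1", "P2"))
  mentions <- mentions_tbl("n1", "HP:0010920")
  sp <- compute_spectrum(mentions, notes, onto, propagate = TRUE)
  expect_setequal(sp$term_id, chain_ids())
  child <- sp[sp$term_id == "HP:0010920", ]
  parent <- sp[sp$term_id == "HP:0000518", ]
  expect_gte(parent$document_frequency, child$document_frequency)
  # ancestors were never literally mentioned
  expect_equal(parent$term_frequency, 0)
  expect_equal(child$term_frequency, 1)
  expect_false("HP:0000118" %in% sp$term_id)
})

test_that("parent counts dominate child counts after propagation (random corpora)", {
  set.seed(21)
  for (rep in 1:15) {
    parents <- random_parent_list(sample(5:25, 1))
    onto <- parse_obo(obo_from_parents(parents), root_id = names(parents)[1])
    ids <- setdiff(names(parents), names(parents)[1])
    n_notes <- sample(3:12, 1)
    notes <- make_notes(sprintf("n%02d", seq_len(n_notes)),
                        sprintf("P%d", sample(1:4, n_notes, replace = TRUE)))
    k <- sample(1:20, 1)
    mentions <- mentions_tbl(sample(notes$note_id, k, replace = TRUE),
                             sample(ids, k, replace = TRUE))
    sp <- compute_spectrum(mentions, notes, onto, propagate = TRUE)
    cnt <- setNames(sp$document_frequency, sp$term_id)
    pat <- setNames(sp$patient_count, sp$term_id)
    for (id in sp$term_id) {
      for (p in setdiff(parents[[id]], names(parents)[1])) {
        expect_gte(cnt[[p]], cnt[[id]])
        expect_gte(pat[[p]], pat[[id]])
      }
    }
  }
})

test_that("the baseline filter removes strictly-above-threshold terms only", {
  notes_c <- make_notes(c("c1", "c2"), c("P1", "P2"))
  case <- compute_spectrum(
    mentions_tbl(c("c1", "c1", "c2"), c("T:1", "T:2", "T:3")), notes_c)

  # baseline of 100 patients: T:1 in 6 patients (0.06), T:2 in 5 (0.05)
  notes_b <- make_notes(sprintf("b%03d", 1:100), sprintf("Q%03d", 1:100))
  base_m <- mentions_tbl(c(sprintf("b%03d", 1:6), sprintf("b%03d", 7:11)),
                         c(rep("T:1", 6), rep("T:2", 5)))
  base <- compute_spectrum(base_m, notes_b, cohort = "baseline")
  expect_equal(base$patient_frequency[base$term_id == "T:1"], 0.06)
  expect_equal(base$patient_frequency[base$term_id == "T:2"], 0.05)

  filt <- apply_baseline_filter(case, base, threshold = 0.05)
  expect_false("T:1" %in% filt$term_id)   # 0.06 > 0.05 -> removed
  expect_true("T:2" %in% filt$term_id)    # exactly 0.05 -> retained
  expect_true("T:3" %in% filt$term_id)    # absent from baseline -> retained
  expect_equal(attr(filt, "n_baseline_filtered"), 1)

  # removed set equals an independent recount
  indep <- intersect(case$term_id,
                     base$term_id[base$patient_count / 100 > 0.05])
  expect_setequal(attr(filt, "removed_terms"), indep)

  # vacuous threshold removes nothing
  expect_equal(nrow(apply_baseline_filter(case, base, threshold = 1)), nrow(case))
})

test_that("rank_terms is descending with deterministic term-id tie-breaks", {
  tbl <- tibble::tibble(term_id = c("T:3", "T:1", "T:2"),
                        patient_frequency = c(0.1, 0.9, 0.5))
  expect_equal(rank_terms(tbl, "patient_frequency", 2)$term_id, c("T:1", "T:2"))
  tied <- tibble::tibble(term_id = c("T:2", "T:1"), odds_ratio = c(3, 3))
  expect_equal(rank_terms(tied, "odds_ratio", 2)$term_id, c("T:1", "T:2"))
  expect_equal(nrow(rank_terms(tbl, "patient_frequency", 100)), 3)
  expect_error(rank_terms(tbl, "nope", 2), regexp = "unknown ranking key")
})
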