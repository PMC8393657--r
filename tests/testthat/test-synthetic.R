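small_cfg <- function(seed = 11, ...) {
  args <- list(seed = seed,
               n_case_patients = 40L, n_baseline_patients = 20L,
               case_notes = list(mean = 3, dispersion = 5),
               baseline_notes = list(mean = 1, dispersion = 5),
               note_length = list(mean = 1200, sd = 200, min = 400))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- small_cfg()
  g1 <- generate_ontology(cfg)
  g2 <- generate_ontology(cfg)
  expect_identical(write_obo(g1$ontology), write_obo(g2$ontology))
  expect_identical(g1$mapping, g2$mapping)
  c1 <- generate_corpus(cfg, g1$ontology, g1$mapping)
  c2 <- generate_corpus(cfg, g2$ontology, g2$mapping)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$ground_truth, c2$ground_truth)

  g3 <- generate_ontology(small_cfg(seed = 12))
  expect_false(identical(write_obo(g1$ontology), write_obo(g3$ontology)))
})

test_that("the synthetic ontology is a rooted DAG with multi-parent terms", {
  gen <- generate_ontology(synth_config(seed = 2, ontology = list(
    n_terms = 50L, multi_parent_fraction = 0.2)))
  onto <- gen$ontology
  expect_equal(nrow(onto$terms), 50)
  flags <- setNames(onto$terms$in_pheno_subtree, onto$terms$term_id)
  pheno <- grep("^HP:5", onto$terms$term_id, value = TRUE)
  expect_true(all(flags[pheno]))
  expect_gte(sum(lengths(onto$parents[pheno]) >= 2), 1)
  expect_equal(anyDuplicated(gen$mapping$cui), 0)
  # round-trips through the production OBO reader
  again <- parse_obo(write_obo(onto))
  expect_identical(again$parents, onto$parents)
})

test_that("degenerate config passes the quality filter completely", {
  cfg <- small_cfg(header_probability = 1,
                   note_length = list(mean = 4000, sd = 100, min = 3200))
  gen <- generate_ontology(cfg)
  corpus <- generate_corpus(cfg, gen$ontology, gen$mapping)
  fc <- filter_corpus(corpus$notes)
  expect_equal(nrow(fc$notes), nrow(corpus$notes))
  expect_equal(nrow(fc$rejections), 0)
})

test_that("dictionary annotation reproduces the planted ground truth exactly", {
  cfg <- small_cfg(seed = 4)
  gen <- generate_ontology(cfg)
  corpus <- generate_corpus(cfg, gen$ontology, gen$mapping)
  lex <- build_lexicon(gen$ontology, gen$mapping)
  found <- annotate_notes(corpus$notes, lex)
  gt <- corpus$ground_truth
  expect_identical(
    dplyr::arrange(found[, c("note_id", "term_id", "start", "end")],
                   note_id, term_id, start),
    dplyr::arrange(tibble::as_tibble(gt[, c("note_id", "term_id", "start", "end")]),
                   note_id, term_id, start))
})

test_that("empirical mention rates sit within 3 binomial SDs of the config", {
  cfg <- synth_config(seed = 6, n_case_patients = 120L,
                      n_baseline_patients = 5L,
                      case_notes = list(mean = 3, dispersion = 10),
                      note_length = list(mean = 900, sd = 100, min = 400))
  gen <- generate_ontology(cfg)
  corpus <- generate_corpus(cfg, gen$ontology, gen$mapping)
  gt <- corpus$ground_truth
  case_notes <- corpus$notes[corpus$notes$cohort == "case", ]
  n <- nrow(case_notes)
  expect_gte(n, 200)
  prof <- corpus$profiles
  for (role in c("enriched", "common", "noise")) {
    terms <- prof$term_id[prof$role == role & prof$age_dist == "uniform"]
    p <- prof$p_case[prof$role == role][1]
    hits <- gt[gt$cohort == "case" & gt$term_id %in% terms, ]
    rate <- nrow(dplyr::distinct(hits, note_id, term_id)) / (n * length(terms))
    se <- sqrt(p * (1 - p) / (n * length(terms)))
    expect_lt(abs(rate - p), 3 * se)
  }
})

test_that("planted case/baseline imbalance surfaces as a large odds ratio", {
  cfg <- synth_config(seed = 8, n_case_patients = 150L, n_baseline_patients = 150L,
                      case_notes = list(mean = 2, dispersion = 10),
                      baseline_notes = list(mean = 2, dispersion = 10),
                      note_length = list(mean = 900, sd = 100, min = 400),
                      profiles = list(p_baseline_enriched = 0.05))
  gen <- generate_ontology(cfg)
  corpus <- generate_corpus(cfg, gen$ontology, gen$mapping)
  lex <- build_lexicon(gen$ontology, gen$mapping)
  mentions <- annotate_notes(corpus$notes, lex)
  case_notes <- corpus$notes[corpus$notes$cohort == "case", ]
  base_notes <- corpus$notes[corpus$notes$cohort == "baseline", ]
  sp_c <- compute_spectrum(mentions, case_notes)
  sp_b <- compute_spectrum(mentions, base_notes, cohort = "baseline")
  en <- enrich_terms(sp_c, sp_b)
  planted <- corpus$profiles$term_id[corpus$profiles$role == "enriched"]
  expect_true(all(en$odds_ratio[en$term_id %in% planted] > 5))
})
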