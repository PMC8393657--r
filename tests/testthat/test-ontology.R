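test_that("parse_obo reads stanzas, drops obsolete terms, handles empty input", {
  onto <- parse_obo(c("[Term]", "id: HP:0000001", "name: All",
                      "[Term]", "id: HP:0000002", "name: Child",
                      "is_a: HP:0000001 ! All"),
                    root_id = "HP:0000001")
  expect_equal(nrow(onto$terms), 2)
  expect_equal(onto$parents[["HP:0000002"]], "HP:0000001")
  expect_equal(onto$parents[["HP:0000001"]], character(0))

  onto2 <- parse_obo(c("[Term]", "id: A:1", "name: a",
                       "[Term]", "id: A:2", "name: b", "is_obsolete: true",
                       "[Term]", "id: A:3", "name: c", "is_a: A:1"),
                     root_id = "A:1")
  expect_equal(nrow(onto2$terms), 2)
  expect_false("A:2" %in% onto2$terms$term_id)

  empty <- parse_obo(character(0))
  expect_equal(nrow(empty$terms), 0)
  expect_error(term_ancestors(empty, "HP:0000118"),
               class = "phenospectr_lookup_error")
})

test_that("parse_obo captures synonyms with quotes stripped", {
  onto <- chain_ontology()
  expect_equal(onto$synonyms[["HP:0000518"]], "Cataracts")
})

test_that("parse_obo reports malformed stanzas and is_a cycles", {
  expect_error(
    parse_obo(c("[Term]", "id: A:1", "name: ok",
                "[Term]", "name: no id here")),
    regexp = "stanza 2", class = "phenospectr_parse_error")
  expect_error(
    parse_obo(c("[Term]", "id: A:1", "is_a: A:2",
                "[Term]", "id: A:2", "is_a: A:1")),
    regexp = "cycle", class = "phenospectr_validation_error")
})

test_that("parse_mrconso keeps only the requested source vocabulary", {
  row18 <- function(cui, sdui, sab) {
    f <- rep("", 18)
    f[1] <- cui; f[11] <- sdui; f[12] <- sab
    paste0(paste(f, collapse = "|"), "|")
  }
  m <- parse_mrconso(c(row18("C0010951", "HP:0000518", "HPO"),
                       row18("C0010951", "12345", "SNOMEDCT_US")))
  expect_equal(m$cui, "C0010951")
  expect_equal(m$term_id, "HP:0000518")

  m2 <- parse_mrconso(c(row18("C0010951", "HP:0000518", "HPO"),
                        row18("C0010951", "HP:0010920", "HPO")))
  expect_setequal(m2$term_id[m2$cui == "C0010951"],
                  c("HP:0000518", "HP:0010920"))

  expect_warning(
    m3 <- parse_mrconso(c(row18("C1", "HP:0000001", "HPO"), "too|short")),
    regexp = "skipped 1")
  expect_equal(attr(m3, "n_skipped"), 1)
  expect_warning(parse_mrconso(row18("C1", "", "HPO")), regexp = "no MRCONSO rows")
})

test_that("ancestors stop at the root and cover the lens-abnormality chain", {
  onto <- chain_ontology()
  expect_equal(term_ancestors(onto, "HP:0000118"), character(0))
  anc <- term_ancestors(onto, "HP:0010920")
  expect_setequal(anc, c("HP:0000518", "HP:0000517", "HP:0012372",
                         "HP:0000478", "HP:0000118"))
  expect_false("HP:0000001" %in% anc)
})

test_that("ancestors follow every parent of a diamond DAG", {
  onto <- parse_obo(obo_from_parents(list(
    "R:1" = character(0),
    "P:1" = "R:1", "P:2" = "R:1",
    "X:1" = c("P:1", "P:2")
  )), root_id = "R:1")
  expect_setequal(term_ancestors(onto, "X:1"), c("P:1", "P:2", "R:1"))
})

test_that("propagate_terms adds the chain and excludes the root", {
  onto <- chain_ontology()
  expect_equal(propagate_terms(onto, character(0)), character(0))
  out <- propagate_terms(onto, "HP:0010920")
  expect_setequal(out, chain_ids())
  expect_false("HP:0000118" %in% out)
  expect_error(propagate_terms(onto, c("HP:0010920", "HP:9999999", "HP:8888888")),
               regexp = "HP:9999999.*HP:8888888",
               class = "phenospectr_lookup_error")
})

test_that("shared ancestors are reported once after propagation", {
  onto <- parse_obo(obo_from_parents(list(
    "R:1" = character(0), "G:1" = "R:1",
    "A:1" = "G:1", "B:1" = "G:1"
  )), root_id = "R:1")
  out <- propagate_terms(onto, c("A:1", "B:1"))
  expect_equal(sum(out == "G:1"), 1)
})

test_that("ancestors match the matrix transitive closure on random DAGs", {
  set.seed(42)
  for (rep in 1:25) {
    parents <- random_parent_list(sample(3:50, 1))
    onto <- parse_obo(obo_from_parents(parents), root_id = names(parents)[1])
    closure <- closure_by_matrix(parents)
    for (id in names(parents)) {
      expect_setequal(term_ancestors(onto, id),
                      names(which(closure[id, ])))
    }
  }
})

test_that("propagation is idempotent, monotone and never emits the root", {
  set.seed(7)
  for (rep in 1:20) {
    parents <- random_parent_list(sample(4:40, 1))
    root <- names(parents)[1]
    onto <- parse_obo(obo_from_parents(parents), root_id = root)
    ids <- setdiff(names(parents), root)
    s <- sample(ids, sample.int(length(ids), 1))
    t_sup <- union(s, sample(ids, sample.int(length(ids), 1)))
    ps <- propagate_terms(onto, s)
    expect_identical(propagate_terms(onto, ps), ps)
    expect_true(all(ps %in% propagate_terms(onto, t_sup)))
    expect_false(root %in% ps)
  }
})

test_that("terms outside the root subtree are flagged and still propagate", {
  onto <- parse_obo(obo_from_parents(list(
    "HP:0000001" = character(0),
    "HP:0000118" = "HP:0000001",
    "HP:0000005" = "HP:0000001",    # mode-of-inheritance analog
    "HP:0000006" = "HP:0000005",
    "HP:0001250" = "HP:0000118"
  )))
  flags <- setNames(onto$terms$in_pheno_subtree, onto$terms$term_id)
  expect_true(flags[["HP:0001250"]])
  expect_false(flags[["HP:0000006"]])
  # climbs to its own top-level ancestor, root never involved
  expect_setequal(propagate_terms(onto, "HP:0000006"),
                  c("HP:0000006", "HP:0000005", "HP:0000001"))
})

test_that("OBO serialisation round-trips through the parser", {
  onto <- chain_ontology()
  txt <- write_obo(onto)
  again <- parse_obo(txt)
  expect_equal(again$terms$term_id, onto$terms$term_id)
  expect_equal(again$parents, onto$parents)
  expect_equal(again$synonyms, onto$synonyms)
})
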