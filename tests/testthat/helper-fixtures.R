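# Shared fixtures and independent oracles used across the suite.

# OBO text for the lens-abnormality chain used throughout the HPO:
# Zonular cataract -> Cataract -> Abnormality of the lens ->
# Abnormal eye morphology -> Abnormality of the eye ->
# Phenotypic abnormality (root) -> All.
chain_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
    "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0000478", "name: Abnormality of the eye",
    "is_a: HP:0000118", "",
    "[Term]", "id: HP:0012372", "name: Abnormal eye morphology",
    "is_a: HP:0000478", "",
    "[Term]", "id: HP:0000517", "name: Abnormality of the lens",
    "is_a: HP:0012372", "",
    "[Term]", "id: HP:0000518", "name: Cataract",
    'synonym: "Cataracts" EXACT []',
    "is_a: HP:0000517", "",
    "[Term]", "id: HP:0010920", "name: Zonular cataract",
    "is_a: HP:0000518", "")
}

chain_ontology <- function() parse_obo(chain_obo())

chain_ids <- function() {
  c("HP:0000478", "HP:0012372", "HP:0000517", "HP:0000518", "HP:0010920")
}

# Build OBO text from an explicit parent list (names default to ids).
obo_from_parents <- function(parents, synonyms = NULL) {
  ids <- names(parents)
  unlist(lapply(ids, function(id) {
    c("[Term]", paste0("id: ", id), paste0("name: name ", id),
      if (!is.null(synonyms[[id]]))
        sprintf('synonym: "%s" EXACT []', synonyms[[id]]),
      paste0("is_a: ", parents[[id]]), "")
  }))
}

# Random DAG as a parent list over n nodes; node 1 is a parentless root
# and every other node gets >=1 parent among earlier nodes, so the DAG
# property holds by construction.
random_parent_list <- function(n, p_extra = 0.25) {
  ids <- sprintf("HP:%07d", seq_len(n) * 11L)
  parents <- setNames(vector("list", n), ids)
  parents[[1]] <- character(0)
  for (i in seq_len(n)[-1]) {
    k <- 1L + rbinom(1, min(i - 2L, 2L), p_extra)
    parents[[ids[i]]] <- ids[sample.int(i - 1L, min(k, i - 1L))]
  }
  parents
}

# Transitive-closure oracle by repeated boolean matrix multiplication.
closure_by_matrix <- function(parents) {
  ids <- names(parents)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) A[id, parents[[id]]] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Exhaustive two-sided Fisher oracle: enumerate every table with the
# observed margins, point probabilities from binomial coefficients.
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  x <- seq.int(max(0, k - r2), min(r1, k))
  probs <- choose(r1, x) * choose(r2, k - x) / choose(r1 + r2, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / choose(r1 + r2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Quick notes-table builder; text defaults to a passing note.
make_notes <- function(ids, patients, texts = NULL,
                       note_dates = NULL, birth_dates = NULL) {
  n <- length(ids)
  tibble::tibble(
    note_id = ids,
    patient_id = patients,
    note_date = note_dates %||% rep(as.Date("2020-06-01"), n),
    birth_date = birth_dates %||% rep(as.Date("2015-06-01"), n),
    text = texts %||% rep(passing_text(), n)
  )
}

passing_text <- function(n_chars = 3200) {
  paste0("MRN: 12345678 ", strrep("lorem ipsum dolor sit amet ", ceiling(n_chars / 27)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
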