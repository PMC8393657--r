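Package: phenospectr
Title: Phenotypic Spectrum Mining from Clinical Note Corpora with the
    Human Phenotype Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving ontology-based phenotype profiles from
    clinical note text. Parses OBO ontologies and UMLS MRCONSO-dialect
    concept mappings, applies cohort selection and note-quality filters,
    recognises Human Phenotype Ontology (HPO) concepts with a deterministic
    dictionary annotator (or ingests pre-computed CUI annotations),
    propagates terms to their ontology ancestors, computes term, document,
    inverse-document and patient frequencies, filters against a baseline
    cohort, tests case-versus-baseline enrichment with odds ratios and
    Fisher exact p-values under Bonferroni control, and builds age-binned
    term-by-visit matrices for longitudinal views. Includes a seedful
    synthetic EHR generator with recorded ground truth so every stage is
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
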