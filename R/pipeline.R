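#' Pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()]. With
#' `synthetic = TRUE` (the default) the pipeline generates its own
#' corpus via [generate_ontology()] / [generate_corpus()]; otherwise the
#' `inputs` paths must point at an OBO ontology, an MRCONSO-dialect
#' mapping, a notes table, a patients table and (when
#' `annotation_source = "ingest"`) a `note_id,cui` annotation table.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param synthetic Generate inputs with the synthetic module?
#' @param generator List of [synth_config()] overrides.
#' @param inputs Named list of input paths (`obo`, `mrconso`, `notes`,
#'   `patients`, `annotations`) for non-synthetic runs.
#' @param annotation_source `"dictionary"` (built-in annotator) or
#'   `"ingest"` (pre-computed CUI annotations).
#' @param min_chars,header_pattern Note-quality thresholds (case notes
#'   only; the baseline corpus is used unfiltered).
#' @param propagate Propagate term sets to ancestors before counting?
#' @param baseline_threshold Baseline patient-frequency cutoff for
#'   [apply_baseline_filter()].
#' @param alpha,multiplicity,enrichment_test,zero_correction Passed to
#'   [enrich_terms()].
#' @param top_k Number of top terms kept in rankings and the age matrix.
#' @param bin_width,min_age,max_age Age-grid parameters (years).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synthetic = TRUE,
                            generator = list(),
                            inputs = list(),
                            annotation_source = c("dictionary", "ingest"),
                            min_chars = 3000,
                            header_pattern = default_header_pattern(),
                            propagate = TRUE,
                            baseline_threshold = 0.05,
                            alpha = 0.05,
                            multiplicity = "bonferroni",
                            enrichment_test = "fisher",
                            zero_correction = 0.5,
                            top_k = 100L,
                            bin_width = 0.25, min_age = 0, max_age = 12.5) {
  annotation_source <- match.arg(annotation_source)
  structure(
    list(seed = as.integer(seed), synthetic = synthetic,
         generator = generator, inputs = inputs,
         annotation_source = annotation_source,
         min_chars = min_chars, header_pattern = header_pattern,
         propagate = propagate, baseline_threshold = baseline_threshold,
         alpha = alpha, multiplicity = multiplicity,
         enrichment_test = enrichment_test,
         zero_correction = zero_correction, top_k = top_k,
         bin_width = bin_width, min_age = min_age, max_age = max_age),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys abort, absent keys take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  stray <- setdiff(names(raw), known)
  if (length(stray)) {
    abort(sprintf("unknown config key(s): %s", paste(stray, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the phenotype-spectrum pipeline end to end
#'
#' Executes cohort selection, note-quality filtering (case notes only),
#' annotation (dictionary or ingest), ancestor propagation, case and
#' baseline frequency spectra, the baseline-noise filter,
#' case-versus-baseline enrichment with multiplicity control, term
#' ranking, and the term-by-age-bin matrix, persisting every
#' intermediate table plus a run manifest to `out_dir`. Re-running with
#' the same config and seed yields byte-identical outputs.
#'
#' @param config A [pipeline_config()], or a path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results:
#'   `spectrum_case`, `spectrum_baseline`, `spectrum_filtered`,
#'   `enrichment`, `top_patient_frequency`, `top_odds_ratio`,
#'   `age_matrix`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "phenospectr",
    version = as.character(utils::packageVersion("phenospectr")),
    seed = config$seed,
    config = config[setdiff(names(config), "inputs")],
    inputs = list(), counts = list()
  )
  fail <- function(stage_name, e) {
    manifest$failed_stage <- stage_name
    manifest$error <- conditionMessage(e)
    write_manifest(manifest, out_dir)
    abort(sprintf("pipeline stage '%s' failed: %s", stage_name,
                  conditionMessage(e)), parent = e)
  }
  stage <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) fail(stage_name, e))
  }

  # --- inputs -------------------------------------------------------------
  ingest_rows <- NULL
  if (isTRUE(config$synthetic)) {
    stage("generate", {
      sc <- do.call(synth_config, c(list(seed = config$seed), config$generator))
      gen <- generate_ontology(sc)
      corpus <- generate_corpus(sc, gen$ontology, gen$mapping)
      onto <- gen$ontology
      mapping <- gen$mapping
      notes_all <- corpus$notes
      patients <- corpus$patients
      write_obo(onto, file.path(out_dir, "ontology.obo"))
      write_mrconso(mapping, file.path(out_dir, "mapping.rrf"))
      write_notes(corpus$notes, file.path(out_dir, "notes.tsv"))
      write_patients(corpus$patients, file.path(out_dir, "patients.tsv"))
      readr::write_tsv(corpus$ground_truth,
                       file.path(out_dir, "ground_truth.tsv"), progress = FALSE)
      readr::write_tsv(corpus$profiles,
                       file.path(out_dir, "term_profiles.tsv"), progress = FALSE)
    })
  } else {
    stage("read_inputs", {
      ins <- config$inputs
      needed <- c("obo", "mrconso", "notes", "patients")
      missing_in <- setdiff(needed, names(ins))
      if (length(missing_in)) {
        abort(sprintf("missing input path(s): %s",
                      paste(missing_in, collapse = ", ")))
      }
      onto <- parse_obo(ins$obo)
      mapping <- parse_mrconso(ins$mrconso)
      notes_all <- read_notes(ins$notes)
      patients <- read_patients(ins$patients)
      manifest$inputs <- as.list(tools::md5sum(unlist(ins)))
      if (config$annotation_source == "ingest") {
        ingest_rows <- readr::read_tsv(ins$annotations,
                                        col_types = "cc", progress = FALSE)
      }
    })
  }
  if (isTRUE(config$synthetic) && config$annotation_source == "ingest") {
    # synthetic ingest path: flatten the recorded ground truth to CUI rows
    stage("synthesize_ingest", {
      gt <- readr::read_tsv(file.path(out_dir, "ground_truth.tsv"),
                            col_types = readr::cols(), progress = FALSE)
      ingest_rows <- gt |>
        left_join(as_tibble(mapping), by = "term_id") |>
        select("note_id", "cui")
    })
  }

  # --- cohort selection and note QC --------------------------------------
  stage("select_cohort", {
    if ("cohort" %in% names(patients)) {
      case_pat_all <- filter(patients, .data$cohort == "case")
      base_pat <- filter(patients, .data$cohort != "case")
    } else {
      case_pat_all <- patients
      base_pat <- patients[0, ]
    }
    case_pat <- select_cohort(case_pat_all, down_syndrome_cohort())
    base_pat <- base_pat
    manifest$counts$case_patients_queried <- nrow(case_pat_all)
    manifest$counts$case_patients_selected <- nrow(case_pat)
  })

  stage("filter_corpus", {
    case_notes_all <- filter(notes_all, .data$patient_id %in% case_pat$patient_id)
    fc <- filter_corpus(case_notes_all, min_chars = config$min_chars,
                        header_pattern = config$header_pattern)
    case_notes <- fc$notes
    base_notes <- filter(notes_all, .data$patient_id %in% base_pat$patient_id)
    manifest$counts$case_notes_total <- nrow(case_notes_all)
    manifest$counts$case_notes_retained <- nrow(case_notes)
    manifest$counts$case_notes_rejected <-
      setNames(as.list(fc$rejections$n), fc$rejections$reason)
    manifest$counts$baseline_notes <- nrow(base_notes)
    stopifnot(nrow(case_notes) + sum(fc$rejections$n) == nrow(case_notes_all))
  })

  # --- annotation ---------------------------------------------------------
  stage("annotate", {
    if (config$annotation_source == "dictionary") {
      lex <- build_lexicon(onto, mapping)
      mentions_case <- annotate_notes(case_notes, lex)
      mentions_base <- annotate_notes(base_notes, lex)
    } else {
      both <- bind_rows(case_notes, base_notes)
      rows <- filter(ingest_rows, .data$note_id %in% both$note_id)
      men <- ingest_cui_annotations(rows, mapping, both)
      mentions_case <- filter(men, .data$note_id %in% case_notes$note_id)
      mentions_base <- filter(men, .data$note_id %in% base_notes$note_id)
    }
    manifest$counts$case_mentions <- nrow(mentions_case)
    manifest$counts$baseline_mentions <- nrow(mentions_base)
  })

  # --- spectra, filter, enrichment ---------------------------------------
  stage("spectrum", {
    spectrum_case <- compute_spectrum(mentions_case, case_notes, onto,
                                       propagate = config$propagate,
                                       cohort = "case")
    spectrum_base <- compute_spectrum(mentions_base, base_notes, onto,
                                       propagate = config$propagate,
                                       cohort = "baseline")
    manifest$counts$case_terms <- nrow(spectrum_case)
    manifest$counts$baseline_terms <- nrow(spectrum_base)
    manifest$counts$case_patients_with_notes <-
      attr(spectrum_case, "total_patients")
  })

  stage("baseline_filter", {
    spectrum_filtered <- apply_baseline_filter(
      spectrum_case, spectrum_base, threshold = config$baseline_threshold)
    manifest$counts$terms_removed_by_baseline_filter <-
      attr(spectrum_filtered, "n_baseline_filtered")
    manifest$counts$case_terms_after_filter <- nrow(spectrum_filtered)
  })

  stage("enrichment", {
    enrichment <- enrich_terms(spectrum_filtered, spectrum_base,
                                alpha = config$alpha,
                                multiplicity = config$multiplicity,
                                test = config$enrichment_test,
                                zero_correction = config$zero_correction)
    manifest$counts$tests_performed <- attr(enrichment, "m")
    manifest$counts$significant_terms <- sum(enrichment$significant)
  })

  stage("rank_terms", {
    top_pf <- rank_terms(spectrum_filtered, "patient_frequency",
                          top_k = config$top_k)
    top_or <- rank_terms(enrichment, "odds_ratio", top_k = config$top_k)
  })

  stage("age_matrix", {
    grid <- age_bin_grid(config$bin_width, config$min_age, config$max_age)
    age_matrix <- build_term_age_matrix(
      mentions_case, case_notes, terms = top_pf$term_id, grid = grid,
      ontology = onto, propagate = config$propagate)
  })

  # --- outputs ------------------------------------------------------------
  stage("write_outputs", {
    write_result_table(spectrum_case, file.path(out_dir, "spectrum_case.tsv"))
    write_result_table(spectrum_base, file.path(out_dir, "spectrum_baseline.tsv"))
    write_result_table(spectrum_filtered,
                       file.path(out_dir, "spectrum_case_filtered.tsv"))
    write_result_table(enrichment, file.path(out_dir, "enrichment.tsv"))
    write_result_table(top_pf,
                       file.path(out_dir, "top_terms_patient_frequency.tsv"))
    write_result_table(top_or, file.path(out_dir, "top_terms_odds_ratio.tsv"))
    write_result_table(age_matrix, file.path(out_dir, "term_age_matrix.tsv"))
    write_result_table(term_age_wide(age_matrix),
                       file.path(out_dir, "term_age_matrix_wide.tsv"))
    write_manifest(manifest, out_dir)
  })

  invisible(list(
    ontology = onto,
    spectrum_case = spectrum_case, spectrum_baseline = spectrum_base,
    spectrum_filtered = spectrum_filtered, enrichment = enrichment,
    top_patient_frequency = top_pf, top_odds_ratio = top_or,
    age_matrix = age_matrix, manifest = manifest
  ))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(NULL)
}
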