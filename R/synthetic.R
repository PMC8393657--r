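#' Configuration for the synthetic EHR generator
#'
#' Bundles every knob of the synthetic ontology/corpus generator. The
#' defaults emulate the cohort structure of a paediatric case/baseline
#' text-mining study at one-tenth scale: 500 case and 500 baseline
#' patients, cases carrying about ten times as many notes per patient as
#' the baseline, note lengths straddling the 3000-character quality
#' threshold, an MRN-style header on most notes, ages spread over 0-12.5
#' years, ten case-enriched terms, a block of cohort-symmetric common
#' terms, and a handful of high-frequency noise terms that the baseline
#' filter is meant to remove. All randomness derives from `seed`.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_case_patients,n_baseline_patients Cohort sizes.
#' @param case_notes,baseline_notes Per-patient note-count distribution,
#'   a list `list(mean =, dispersion =)` (negative binomial; patients may
#'   draw zero notes).
#' @param note_length Note-length distribution `list(mean =, sd =,
#'   min =)` in characters.
#' @param header_probability Probability a note carries an MRN header.
#' @param age_range Visit ages are drawn uniformly from this range
#'   (years) before any per-term age weighting.
#' @param duplicate_mention_rate Poisson rate of extra copies of a
#'   planted mention within the same note.
#' @param exclude_code_fraction Fraction of case patients additionally
#'   given an excluded diagnosis code (to exercise cohort selection).
#' @param synonym_plant_probability Probability a planted mention uses
#'   the term's synonym rather than its preferred name.
#' @param ontology List of ontology-shape knobs: `n_terms`, `max_depth`,
#'   `synonyms_per_term` (0 or 1), `multi_parent_fraction`,
#'   `nonpheno_terms` (size of a branch outside the phenotypic root).
#' @param profiles List of term-profile knobs: `n_enriched`,
#'   `p_case_enriched`, `p_baseline_enriched`, `n_common`, `p_common`,
#'   `n_noise`, `p_noise`, and the point-mass age of the first enriched
#'   term (`age_point_mu`, `age_point_sigma`).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_case_patients = 500L,
                         n_baseline_patients = 500L,
                         case_notes = list(mean = 2.5, dispersion = 5),
                         baseline_notes = list(mean = 0.25, dispersion = 5),
                         note_length = list(mean = 3500, sd = 600, min = 400),
                         header_probability = 0.9,
                         age_range = c(0, 12.5),
                         duplicate_mention_rate = 0.2,
                         exclude_code_fraction = 0.02,
                         synonym_plant_probability = 0.3,
                         ontology = list(),
                         profiles = list()) {
  ontology <- modifyList(list(n_terms = 150L, max_depth = 5L,
                              synonyms_per_term = 1L,
                              multi_parent_fraction = 0.15,
                              nonpheno_terms = 3L), ontology)
  profiles <- modifyList(list(n_enriched = 10L, p_case_enriched = 0.4,
                              p_baseline_enriched = 0.02,
                              n_common = 110L, p_common = 0.05,
                              n_noise = 5L, p_noise = 0.6,
                              age_point_mu = 2.0, age_point_sigma = 0.1),
                         profiles)
  stopifnot(ontology$n_terms >= 2L,
            header_probability >= 0, header_probability <= 1,
            length(age_range) == 2, age_range[2] > age_range[1])
  structure(
    list(seed = as.integer(seed),
         n_case_patients = n_case_patients,
         n_baseline_patients = n_baseline_patients,
         case_notes = case_notes, baseline_notes = baseline_notes,
         note_length = note_length,
         header_probability = header_probability,
         age_range = age_range,
         duplicate_mention_rate = duplicate_mention_rate,
         exclude_code_fraction = exclude_code_fraction,
         synonym_plant_probability = synonym_plant_probability,
         ontology = ontology, profiles = profiles),
    class = "synth_config"
  )
}

# Coined-token machinery: surface forms are built from three-syllable
# tokens that can never collide with the closed filler vocabulary, so
# dictionary annotation on generated notes is exact by construction.
coined_token <- function(i) {
  syl <- c("ba", "de", "fi", "go", "hu", "ka", "lo", "mi", "nu", "po",
           "ra", "se", "ti", "vu", "za", "be", "do", "fu", "gi", "ho")
  paste0(syl[(i %/% 400L) %% 20L + 1L],
         syl[(i %/% 20L) %% 20L + 1L],
         syl[i %% 20L + 1L])
}

filler_vocabulary <- function() {
  c("the", "patient", "was", "seen", "in", "clinic", "today", "for",
    "routine", "follow", "up", "visit", "and", "remains", "stable", "on",
    "current", "plan", "of", "care", "with", "no", "new", "concerns",
    "reported", "by", "family", "vital", "signs", "were", "reviewed",
    "growth", "chart", "updated", "at", "this", "encounter", "diet",
    "sleep", "activity", "discussed", "length", "weight", "within",
    "expected", "range", "immunizations", "are", "to", "date", "exam",
    "performed", "findings", "documented", "below", "labs", "ordered",
    "as", "indicated", "results", "will", "be", "called", "parents",
    "questions", "answered", "return", "precautions", "given", "next",
    "appointment", "scheduled", "months", "from", "now", "continue",
    "home", "medications", "without", "change", "school", "attendance",
    "regular", "tolerating", "well", "overall", "doing", "nicely",
    "since", "last", "time", "here", "team", "agrees")
}

#' Generate a synthetic phenotype ontology and concept mapping
#'
#' Builds a rooted DAG with an analog of the phenotypic-abnormality root
#' (`HP:0000118` under a top node `HP:0000001`), a small branch outside
#' that root (exercising the subtree flag), a configurable fraction of
#' multi-parent terms (exercising DAG semantics), one synonym per term,
#' and a unique synthetic CUI per term. Deterministic under
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `ontology` (a `phenotype_ontology`) and `mapping`
#'   (a `cui_mapping` tibble).
#' @export
generate_ontology <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  oc <- config$ontology
  set.seed(config$seed)

  n_nonpheno <- oc$nonpheno_terms
  n_pheno <- oc$n_terms - 2L - n_nonpheno
  stopifnot(n_pheno >= 1L)

  ids <- c("HP:0000001", "HP:0000118",
           if (n_nonpheno > 0) sprintf("HP:%07d", 3000000L + seq_len(n_nonpheno)),
           sprintf("HP:%07d", 5000000L + seq_len(n_pheno)))
  n_all <- length(ids)
  nm <- character(n_all)
  nm[1] <- "All"
  nm[2] <- "Phenotypic abnormality"
  coin_name <- function(k) paste(coined_token(2L * k - 1L), coined_token(2L * k))
  if (n_nonpheno > 0) nm[2L + seq_len(n_nonpheno)] <- coin_name(3000L + seq_len(n_nonpheno))
  nm[2L + n_nonpheno + seq_len(n_pheno)] <- coin_name(seq_len(n_pheno))

  parents <- setNames(vector("list", n_all), ids)
  parents[["HP:0000001"]] <- character(0)
  parents[["HP:0000118"]] <- "HP:0000001"
  if (n_nonpheno > 0) {
    np_ids <- ids[2L + seq_len(n_nonpheno)]
    parents[[np_ids[1]]] <- "HP:0000001"
    for (j in seq_len(n_nonpheno)[-1]) parents[[np_ids[j]]] <- np_ids[1]
  }
  ph_ids <- ids[2L + n_nonpheno + seq_len(n_pheno)]
  level <- rep(seq_len(oc$max_depth), length.out = n_pheno)
  for (j in seq_len(n_pheno)) {
    if (level[j] == 1L) {
      parents[[ph_ids[j]]] <- "HP:0000118"
    } else {
      pool <- ph_ids[level == level[j] - 1L]
      parents[[ph_ids[j]]] <- pool[sample.int(length(pool), 1L)]
    }
  }
  multi <- which(level >= 2L &
                   runif(n_pheno) < oc$multi_parent_fraction)
  for (j in multi) {
    pool <- setdiff(c("HP:0000118", ph_ids[level < level[j]]),
                    parents[[ph_ids[j]]])
    if (length(pool)) {
      parents[[ph_ids[j]]] <- c(parents[[ph_ids[j]]],
                                pool[sample.int(length(pool), 1L)])
    }
  }

  synonyms <- setNames(rep(list(character(0)), n_all), ids)
  if (oc$synonyms_per_term > 0) {
    for (j in seq_len(n_pheno)) {
      synonyms[[ph_ids[j]]] <- paste(coined_token(1000L + 2L * j - 1L),
                                     coined_token(1000L + 2L * j))
    }
  }

  onto <- structure(
    list(terms = tibble(term_id = ids, name = nm, in_pheno_subtree = NA),
         parents = parents, synonyms = synonyms, root_id = "HP:0000118"),
    class = "phenotype_ontology"
  )
  onto$terms$in_pheno_subtree <- reaches_root(onto)

  mapping <- tibble(cui = sprintf("C%07d", 1000000L + seq_len(n_all)),
                    term_id = ids)
  class(mapping) <- c("cui_mapping", class(mapping))

  all_tokens <- unlist(strsplit(c(nm, unlist(synonyms)), " ", fixed = TRUE))
  stopifnot(!any(tolower(all_tokens) %in% filler_vocabulary()))

  list(ontology = onto, mapping = mapping)
}

# Per-term planting profiles: which terms are case-enriched, which are
# cohort-symmetric, which are high-frequency noise, and their age
# distributions. Chosen deterministically from the ontology's
# phenotypic terms in id order.
build_term_profiles <- function(config, ontology) {
  pc <- config$profiles
  eligible <- ontology$terms$term_id[
    ontology$terms$in_pheno_subtree %in% TRUE &
      ontology$terms$term_id != ontology$root_id
  ]
  eligible <- sort(eligible)
  need <- pc$n_enriched + pc$n_noise + pc$n_common
  if (length(eligible) < need) {
    abort(sprintf("ontology has %d usable terms but profiles need %d",
                  length(eligible), need))
  }
  enriched <- eligible[seq_len(pc$n_enriched)]
  noise <- eligible[pc$n_enriched + seq_len(pc$n_noise)]
  common <- eligible[pc$n_enriched + pc$n_noise + seq_len(pc$n_common)]
  aged <- eligible[pc$n_enriched + pc$n_noise + pc$n_common + 1:2]
  aged <- aged[!is.na(aged)]
  prof <- bind_rows(
    tibble(term_id = enriched, role = "enriched",
           p_case = pc$p_case_enriched, p_baseline = pc$p_baseline_enriched),
    tibble(term_id = noise, role = "noise",
           p_case = pc$p_noise, p_baseline = pc$p_noise),
    tibble(term_id = common, role = "common",
           p_case = pc$p_common, p_baseline = pc$p_common),
    # age-structured terms are cohort-symmetric so that age structure and
    # enrichment are probed independently of each other
    if (length(aged) >= 1) {
      tibble(term_id = aged[1], role = "age_point",
             p_case = 0.5, p_baseline = 0.5)
    },
    if (length(aged) >= 2) {
      tibble(term_id = aged[2], role = "age_window",
             p_case = 0.3, p_baseline = 0.3)
    }
  )
  prof$age_dist <- "uniform"
  prof$age_mu <- NA_real_
  prof$age_sigma <- NA_real_
  prof$age_lo <- NA_real_
  prof$age_hi <- NA_real_
  prof$age_dist[prof$role == "age_point"] <- "point"
  prof$age_mu[prof$role == "age_point"] <- pc$age_point_mu
  prof$age_sigma[prof$role == "age_point"] <- pc$age_point_sigma
  prof$age_dist[prof$role == "age_window"] <- "window"
  prof$age_lo[prof$role == "age_window"] <- 0
  prof$age_hi[prof$role == "age_window"] <- 1
  prof
}

#' Generate a synthetic clinical-note corpus with ground truth
#'
#' Assembles case and baseline cohorts of notes from a closed filler
#' vocabulary guaranteed free of lexicon surface forms, planting term
#' mentions verbatim at recorded character offsets. Per-note term
#' planting follows the configured per-term case/baseline probabilities,
#' modulated by the term's age distribution (uniform, Gaussian
#' point-mass, or age window) against the note's visit age. Note length
#' and MRN-header presence are drawn per config; every planted instance
#' is recorded in the ground-truth table.
#'
#' @param config A [synth_config()].
#' @param ontology,mapping From [generate_ontology()].
#' @return A list with
#'   * `notes`: tibble `note_id`, `patient_id`, `cohort`, `note_date`,
#'     `birth_date`, `text`;
#'   * `patients`: tibble `patient_id`, `cohort`, `birth_date`,
#'     `icd_codes` (list-column);
#'   * `ground_truth`: tibble `note_id`, `patient_id`, `cohort`,
#'     `term_id`, `surface`, `start`, `end` (0-based half-open), `age`;
#'   * `profiles`: the per-term planting profile table.
#' @export
generate_corpus <- function(config = synth_config(),
                            ontology, mapping = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(ontology, "phenotype_ontology"))
  set.seed(config$seed + 1L)
  prof <- build_term_profiles(config, ontology)
  filler <- filler_vocabulary()

  surface_of <- function(term_id, use_synonym) {
    nm <- ontology$terms$name[match(term_id, ontology$terms$term_id)]
    syn <- vapply(ontology$synonyms[term_id], function(s)
      if (length(s)) s[1] else NA_character_, character(1))
    if_else(use_synonym & !is.na(syn), syn, nm)
  }

  gen_cohort <- function(cohort, n_patients, notes_spec, p_col) {
    pid <- sprintf("%s%04d", if (cohort == "case") "DS" else "BL",
                   seq_len(n_patients))
    birth <- as.Date("2006-01-01") +
      sample.int(4000L, n_patients, replace = TRUE)
    n_notes <- rnbinom(n_patients, size = notes_spec$dispersion,
                       mu = notes_spec$mean)
    note_pid_idx <- rep(seq_len(n_patients), n_notes)
    n_total <- length(note_pid_idx)
    if (n_total == 0) {
      return(list(
        notes = tibble(note_id = character(0), patient_id = character(0),
                       cohort = character(0),
                       note_date = as.Date(character(0)),
                       birth_date = as.Date(character(0)),
                       text = character(0)),
        patients = tibble(patient_id = pid, cohort = cohort,
                          birth_date = birth),
        gt = NULL
      ))
    }
    age <- runif(n_total, config$age_range[1], config$age_range[2])
    note_date <- birth[note_pid_idx] + round(age * 365.25)
    note_id <- paste0(pid[note_pid_idx], "-N",
                      sprintf("%03d", sequence(n_notes)))

    # planting matrix: per term, per note
    plant_counts <- lapply(seq_len(nrow(prof)), function(i) {
      p <- prof[[p_col]][i]
      w <- switch(prof$age_dist[i],
        uniform = rep(1, n_total),
        point = exp(-(age - prof$age_mu[i])^2 / (2 * prof$age_sigma[i]^2)),
        window = as.numeric(age >= prof$age_lo[i] & age <= prof$age_hi[i])
      )
      hit <- rbinom(n_total, 1L, p * w)
      hit * (1L + rpois(n_total, config$duplicate_mention_rate) * hit)
    })
    plant <- do.call(cbind, plant_counts) # notes x terms

    target_len <- pmax(config$note_length$min,
                       round(rnorm(n_total, config$note_length$mean,
                                   config$note_length$sd)))
    has_header <- rbinom(n_total, 1L, config$header_probability) == 1L
    header_txt <- sprintf("MRN: %08d", sample.int(9.9e7, n_total, replace = TRUE))

    texts <- character(n_total)
    gt <- vector("list", n_total)
    for (ni in seq_len(n_total)) {
      counts <- plant[ni, ]
      inst_term <- rep(prof$term_id, counts)
      n_inst <- length(inst_term)
      use_syn <- runif(n_inst) < config$synonym_plant_probability
      inst_surface <- if (n_inst) surface_of(inst_term, use_syn) else character(0)
      planted_chars <- sum(nchar(inst_surface)) + n_inst
      nf <- max(5L, round((target_len[ni] - planted_chars -
                             if (has_header[ni]) 14L else 0L) / 6.3))
      elems <- sample(filler, nf, replace = TRUE)
      if (n_inst) {
        pos <- sort(sample.int(nf + n_inst, n_inst))
        full <- character(nf + n_inst)
        full[pos] <- inst_surface
        full[-pos] <- elems
        elems <- full
      } else {
        pos <- integer(0)
      }
      if (has_header[ni]) {
        elems <- c(header_txt[ni], elems)
        pos <- pos + 1L
      }
      el_len <- nchar(elems)
      start1 <- cumsum(c(1L, head(el_len, -1L) + 1L))
      texts[ni] <- paste(elems, collapse = " ")
      if (n_inst) {
        gt[[ni]] <- tibble(
          note_id = note_id[ni],
          patient_id = pid[note_pid_idx[ni]],
          cohort = cohort,
          term_id = inst_term,
          surface = inst_surface,
          start = start1[pos] - 1L,
          end = start1[pos] - 1L + el_len[pos],
          age = age[ni]
        )
      }
    }

    list(
      notes = tibble(note_id = note_id,
                     patient_id = pid[note_pid_idx],
                     cohort = cohort,
                     note_date = note_date,
                     birth_date = birth[note_pid_idx],
                     text = texts),
      patients = tibble(patient_id = pid, cohort = cohort, birth_date = birth),
      gt = bind_rows(gt)
    )
  }

  case <- gen_cohort("case", config$n_case_patients, config$case_notes, "p_case")
  base <- gen_cohort("baseline", config$n_baseline_patients,
                     config$baseline_notes, "p_baseline")

  include_codes <- c("Q90.0", "Q90.1", "Q90.2", "Q90.9", "758.0")
  baseline_codes <- c("J45.909", "L20.9", "K21.9", "M25.50", "R10.9")
  case_pat <- case$patients
  case_pat$icd_codes <- lapply(seq_len(nrow(case_pat)), function(i) {
    codes <- include_codes[sample.int(length(include_codes), 1L)]
    if (runif(1) < config$exclude_code_fraction) codes <- c(codes, "Q93.81")
    codes
  })
  base_pat <- base$patients
  base_pat$icd_codes <- lapply(seq_len(nrow(base_pat)), function(i) {
    baseline_codes[sample.int(length(baseline_codes), 1L)]
  })

  list(
    notes = bind_rows(case$notes, base$notes),
    patients = bind_rows(case_pat, base_pat)[, c("patient_id", "cohort",
                                                 "birth_date", "icd_codes")],
    ground_truth = bind_rows(case$gt, base$gt),
    profiles = prof
  )
}
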