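#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (id, name, `synonym:` and `is_a:` lines) into a
#' phenotype ontology object. Obsolete terms (`is_obsolete: true`) are
#' dropped; `is_a` edges pointing at terms absent from the file (e.g. at a
#' dropped obsolete term) are discarded with a warning. The designated root
#' (by default `HP:0000118`, "Phenotypic abnormality") is the stopping point
#' for ancestor traversal; terms that cannot reach it are retained but
#' flagged as lying outside the phenotypic-abnormality subtree.
#'
#' @param x Path to an OBO file, or a character vector of OBO text
#'   (a single string with embedded newlines is also accepted).
#' @param root_id Term id used as the propagation stop. Its presence is not
#'   required at parse time; operations that need it check lazily.
#' @return An object of class `phenotype_ontology`: a list with
#'   * `terms`: tibble with columns `term_id`, `name`, `in_pheno_subtree`;
#'   * `parents`, `synonyms`: named lists keyed by `term_id`;
#'   * `root_id`.
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All",
#'          "[Term]", "id: HP:0000002", "name: Child", "is_a: HP:0000001")
#' onto <- parse_obo(obo, root_id = "HP:0000001")
#' onto$parents[["HP:0000002"]]
#' @export
parse_obo <- function(x, root_id = "HP:0000118") {
  lines <- read_text_lines(x)
  lines <- sub("\\s+$", "", lines)

  stanza_starts <- which(lines == "[Term]")
  block_starts <- which(grepl("^\\[", lines))
  terms <- list()
  for (ord in seq_along(stanza_starts)) {
    beg <- stanza_starts[ord]
    nxt <- block_starts[block_starts > beg]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    body <- lines[seq.int(beg + 1L, length.out = max(0L, end - beg))]

    id <- field_values(body, "id")
    if (length(id) < 1L || !nzchar(id[1])) {
      abort(sprintf("OBO parse error: [Term] stanza %d has no id line", ord),
            class = "phenospectr_parse_error")
    }
    if (any(grepl("^is_obsolete:\\s*true", body))) next
    name <- field_values(body, "name")
    syn_raw <- field_values(body, "synonym")
    syns <- stringr::str_match(syn_raw, '^"([^"]*)"')[, 2]
    syns <- syns[!is.na(syns) & nzchar(syns)]
    isa <- field_values(body, "is_a")
    isa <- sub("\\s*!.*$", "", isa)
    isa <- trimws(isa)
    isa <- isa[nzchar(isa)]
    terms[[id[1]]] <- list(
      name = if (length(name)) name[1] else id[1],
      synonyms = unique(syns),
      parents = unique(isa)
    )
  }

  ids <- names(terms) %||% character(0)
  parents <- lapply(terms, function(t) t$parents)
  dangling <- unique(unlist(parents, use.names = FALSE))
  dangling <- setdiff(dangling, ids)
  if (length(dangling)) {
    warn(sprintf("dropping is_a references to %d term(s) absent from the file: %s",
                 length(dangling), paste(head(dangling, 5), collapse = ", ")))
    parents <- lapply(parents, function(p) setdiff(p, dangling))
  }
  names(parents) <- ids

  assert_acyclic(parents)

  onto <- structure(
    list(
      terms = tibble(
        term_id = ids,
        name = vapply(terms, function(t) t$name, character(1), USE.NAMES = FALSE),
        in_pheno_subtree = NA
      ),
      parents = parents,
      synonyms = setNames(lapply(terms, function(t) t$synonyms), ids),
      root_id = root_id
    ),
    class = "phenotype_ontology"
  )
  onto$terms$in_pheno_subtree <- reaches_root(onto)
  onto
}

read_text_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x)
  } else if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

field_values <- function(body, field) {
  pat <- paste0("^", field, ":\\s*")
  hits <- grep(pat, body, value = TRUE)
  sub(pat, "", hits)
}

# Kahn topological check on the parent relation; abort listing one cycle.
assert_acyclic <- function(parents) {
  if (length(parents) == 0) return(invisible(TRUE))
  ids <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  children <- split(
    rep(ids, lengths(parents)),
    factor(unlist(parents, use.names = FALSE), levels = ids)
  )
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    rem <- ids[indeg > 0L]
    cyc <- rem[1]
    cur <- cyc
    repeat {
      nxt <- intersect(parents[[cur]], rem)[1]
      if (nxt %in% cyc) {
        cyc <- c(cyc[which(cyc == nxt):length(cyc)], nxt)
        break
      }
      cyc <- c(cyc, nxt)
      cur <- nxt
    }
    abort(sprintf("cycle detected among is_a edges: %s",
                  paste(cyc, collapse = " -> ")),
          class = "phenospectr_validation_error")
  }
  invisible(TRUE)
}

reaches_root <- function(onto) {
  root <- onto$root_id
  ids <- onto$terms$term_id
  if (!root %in% ids) return(rep(NA, length(ids)))
  anc <- ancestor_closure(onto)
  ids == root | vapply(anc[ids], function(a) root %in% a, logical(1))
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat(sprintf("<phenotype_ontology> %d terms, root %s (%s)\n",
              nrow(x$terms), x$root_id,
              if (x$root_id %in% x$terms$term_id) "present" else "absent"))
  invisible(x)
}

#' Parse a concept mapping table in MRCONSO.RRF dialect
#'
#' Reads the pipe-delimited UMLS concept-names layout and keeps only rows
#' whose source vocabulary (`SAB`, 12th field) equals `source_vocabulary`
#' and whose source identifier (`SDUI`, 11th field) is non-empty; the SDUI
#' becomes the ontology term id. Rows too short to carry the CUI/SDUI/SAB
#' columns are skipped with a warning and counted.
#'
#' @param x Path to an RRF file or character vector of rows.
#' @param source_vocabulary Source vocabulary to retain (default `"HPO"`).
#' @return A tibble of class `cui_mapping` with columns `cui`, `term_id`
#'   (one row per distinct pair; one CUI may map to several term ids), and
#'   attribute `n_skipped` giving the malformed-row count.
#' @export
parse_mrconso <- function(x, source_vocabulary = "HPO") {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "|", fixed = TRUE)
  ok <- lengths(fields) >= 12L
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(sprintf("skipped %d malformed MRCONSO row(s) with fewer fields than the layout requires",
                 n_skipped))
  }
  fields <- fields[ok]
  cui <- vapply(fields, `[[`, character(1), 1L)
  sdui <- vapply(fields, `[[`, character(1), 11L)
  sab <- vapply(fields, `[[`, character(1), 12L)
  keep <- sab == source_vocabulary & nzchar(sdui)
  out <- distinct(tibble(cui = cui[keep], term_id = sdui[keep]))
  if (nrow(out) == 0) {
    warn(sprintf("no MRCONSO rows retained for source vocabulary '%s'",
                 source_vocabulary))
  }
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("cui_mapping", class(out))
  out
}

#' Ancestors of an ontology term
#'
#' All distinct terms reachable from `term_id` by following `is_a` parent
#' links. Traversal does not expand past the designated root: the root
#' itself appears in the result when reached, but nothing above it does.
#' For terms outside the root's subtree the climb runs to their own
#' top-level ancestor.
#'
#' @param ontology A `phenotype_ontology`.
#' @param term_id A single term id present in the ontology.
#' @return Character vector of ancestor term ids (excludes `term_id`).
#' @seealso [propagate_terms()]
#' @export
term_ancestors <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "phenotype_ontology"), length(term_id) == 1)
  if (!term_id %in% ontology$terms$term_id) {
    abort(sprintf("unknown term id: %s", term_id),
          class = "phenospectr_lookup_error")
  }
  root <- ontology$root_id
  parents <- ontology$parents
  seen <- character(0)
  frontier <- if (term_id == root) character(0) else parents[[term_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    expand <- setdiff(new, root)
    frontier <- unique(unlist(parents[expand], use.names = FALSE))
  }
  seen
}

# Ancestor sets for every term at once (topological sweep), honouring the
# stop-at-root rule. Returns a named list keyed by term_id.
ancestor_closure <- function(ontology) {
  parents <- ontology$parents
  root <- ontology$root_id
  ids <- names(parents)
  anc <- setNames(vector("list", length(ids)), ids)
  done <- setNames(rep(FALSE, length(ids)), ids)
  for (id in ids) {
    stack <- id
    while (length(stack)) {
      v <- stack[[length(stack)]]
      if (done[[v]]) {
        stack <- stack[-length(stack)]
        next
      }
      ps <- if (v == root) character(0) else parents[[v]]
      pending <- ps[!done[ps]]
      if (length(pending)) {
        stack <- c(stack, pending)
      } else {
        anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
        done[[v]] <- TRUE
        stack <- stack[-length(stack)]
      }
    }
  }
  anc
}

#' Propagate observed terms to their ontology ancestors
#'
#' Augments a set of observed terms with every ancestor up to — and
#' excluding — the designated root ("Phenotypic abnormality" in the HPO),
#' which is dropped as uninformative. Idempotent and monotone in the input
#' set.
#'
#' @param ontology A `phenotype_ontology`.
#' @param terms Character vector of observed term ids.
#' @return Character vector (sorted) of the propagated term set, never
#'   containing the root.
#' @examples
#' obo <- c("[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
#'          "[Term]", "id: HP:0000518", "name: Cataract", "is_a: HP:0000118",
#'          "[Term]", "id: HP:0010920", "name: Zonular cataract",
#'          "is_a: HP:0000518")
#' onto <- parse_obo(obo)
#' propagate_terms(onto, "HP:0010920")
#' @export
propagate_terms <- function(ontology, terms) {
  stopifnot(inherits(ontology, "phenotype_ontology"))
  terms <- unique(as.character(terms))
  if (length(terms) == 0) return(character(0))
  unknown <- setdiff(terms, ontology$terms$term_id)
  if (length(unknown)) {
    abort(sprintf("unknown term id(s): %s", paste(unknown, collapse = ", ")),
          class = "phenospectr_lookup_error")
  }
  anc <- ancestor_closure(ontology)
  out <- unique(c(terms, unlist(anc[terms], use.names = FALSE)))
  sort(setdiff(out, ontology$root_id))
}

# Long propagation table for a set of terms: each input term paired with
# itself plus each of its ancestors (root excluded). Used to propagate
# per-note term sets vectorised.
propagation_table <- function(ontology, terms) {
  terms <- unique(terms)
  unknown <- setdiff(terms, ontology$terms$term_id)
  if (length(unknown)) {
    abort(sprintf("unknown term id(s): %s", paste(unknown, collapse = ", ")),
          class = "phenospectr_lookup_error")
  }
  anc <- ancestor_closure(ontology)
  closures <- lapply(terms, function(t) setdiff(c(t, anc[[t]]), ontology$root_id))
  tibble(
    term_id = rep(terms, lengths(closures)),
    propagated_id = unlist(closures, use.names = FALSE)
  )
}

#' Serialise a phenotype ontology to OBO text
#'
#' @param ontology A `phenotype_ontology`.
#' @param path File to write; when `NULL` the OBO text is returned as a
#'   character vector of lines.
#' @return `path` invisibly, or the lines when `path` is `NULL`.
#' @export
write_obo <- function(ontology, path = NULL) {
  stopifnot(inherits(ontology, "phenotype_ontology"))
  blocks <- purrr::map2(
    ontology$terms$term_id, ontology$terms$name,
    function(id, nm) {
      syns <- ontology$synonyms[[id]]
      isa <- ontology$parents[[id]]
      c("[Term]",
        paste0("id: ", id),
        paste0("name: ", nm),
        if (length(syns)) sprintf('synonym: "%s" EXACT []', syns),
        if (length(isa)) paste0("is_a: ", isa),
        "")
    }
  )
  lines <- c("format-version: 1.2", "", unlist(blocks))
  if (is.null(path)) return(lines)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Serialise a CUI mapping to MRCONSO.RRF-dialect rows
#'
#' Emits 18-field pipe-delimited rows with the CUI in field 1, the term id
#' in the SDUI field (11) and `source_vocabulary` in the SAB field (12).
#'
#' @param mapping A `cui_mapping` tibble (columns `cui`, `term_id`).
#' @param path File to write; `NULL` returns the rows.
#' @param source_vocabulary Value for the SAB field.
#' @return `path` invisibly, or the rows when `path` is `NULL`.
#' @export
write_mrconso <- function(mapping, path = NULL, source_vocabulary = "HPO") {
  stopifnot(all(c("cui", "term_id") %in% names(mapping)))
  f <- matrix("", nrow = nrow(mapping), ncol = 18)
  f[, 1] <- mapping$cui
  f[, 2] <- "ENG"
  f[, 11] <- mapping$term_id
  f[, 12] <- source_vocabulary
  f[, 13] <- "PT"
  f[, 15] <- mapping$term_id
  rows <- paste0(apply(f, 1, paste, collapse = "|"), "|")
  if (is.null(path)) return(rows)
  readr::write_lines(rows, path)
  invisible(path)
}
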