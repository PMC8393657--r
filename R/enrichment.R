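#' Odds ratio of a 2x2 contingency table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` for case/baseline documents
#' with and without a term. When any cell is zero, the Haldane-Anscombe
#' correction adds `zero_correction` (default 0.5) to all four cells and
#' the result is flagged as corrected; a term absent from both cohorts
#' (`a == 0` and `c == 0`) has no meaningful odds and is returned as
#' undefined (`NA`).
#'
#' @param a,b,c,d Cell counts (vectorised): case documents with/without
#'   the term, baseline documents with/without. Row margins `a + b` and
#'   `c + d` must be positive.
#' @param zero_correction Amount added to every cell when any cell is 0.
#' @return A tibble with columns `odds_ratio`, `corrected` (logical) and
#'   `defined` (logical).
#' @export
odds_ratio <- function(a, b, c, d, zero_correction = 0.5) {
  if (any(a + b <= 0) || any(c + d <= 0)) {
    abort("both row margins of the contingency table must be positive")
  }
  undefined <- a == 0 & c == 0
  zero_cell <- (a == 0 | b == 0 | c == 0 | d == 0) & !undefined
  or <- (a * d) / (b * c)
  zc <- zero_correction
  or[zero_cell] <- ((a + zc) * (d + zc) / ((b + zc) * (c + zc)))[zero_cell]
  or[undefined] <- NA_real_
  tibble(odds_ratio = or, corrected = zero_cell, defined = !undefined)
}

#' Exact enrichment p-value for a 2x2 table
#'
#' Two-sided Fisher exact p-value, computed as the sum of hypergeometric
#' point probabilities no larger than that of the observed table (with
#' the customary `1 + 1e-7` relative guard against floating-point ties).
#' A chi-squared variant (with continuity correction) is available for
#' sensitivity analysis.
#'
#' @inheritParams odds_ratio
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
enrichment_p_value <- function(a, b, c, d, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  if (any(a + b <= 0) || any(c + d <= 0)) {
    abort("both row margins of the contingency table must be positive")
  }
  if (method == "chisq") {
    return(mapply(function(a, b, c, d) {
      suppressWarnings(chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value)
    }, a, b, c, d))
  }
  mapply(function(a, b, c, d) {
    r1 <- a + b
    r2 <- c + d
    k <- a + c
    x <- seq.int(max(0, k - r2), min(r1, k))
    probs <- dhyper(x, r1, r2, k)
    p_obs <- dhyper(a, r1, r2, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, a, b, c, d)
}

#' Flag significant results under multiple-testing control
#'
#' Bonferroni control flags a result significant iff its p-value is
#' strictly below `alpha / m`, where `m` is the number of tested terms;
#' Benjamini-Hochberg is available as an alternative. The family size
#' `m` and the cutoff are recorded as attributes.
#'
#' @param results Data frame with a `p_value` column.
#' @param alpha Family-wise (or FDR) level.
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @return `results` with a logical `significant` column and attributes
#'   `m`, `alpha`, `cutoff` (Bonferroni only) and `method`.
#' @export
bonferroni_mask <- function(results, alpha = 0.05,
                            method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (nrow(results) == 0) abort("no results to flag")
  m <- nrow(results)
  if (method == "bonferroni") {
    cutoff <- alpha / m
    results$significant <- results$p_value < cutoff
    attr(results, "cutoff") <- cutoff
  } else {
    results$significant <- p.adjust(results$p_value, method = "BH") < alpha
  }
  attr(results, "m") <- m
  attr(results, "alpha") <- alpha
  attr(results, "method") <- method
  results
}

#' Case-versus-baseline term enrichment
#'
#' Builds, for every term of the case spectrum, the 2x2 table of
#' case/baseline documents with and without the term (document
#' frequency is the enrichment basis; patient counts are carried along
#' for reference), then computes the odds ratio, the exact p-value and
#' the multiplicity verdict.
#'
#' @param case_spectrum,baseline_spectrum `spectrum_tbl` objects computed
#'   on the two cohorts with identical propagation settings (apply
#'   [apply_baseline_filter()] to the case table first if desired).
#' @param alpha Significance level for [bonferroni_mask()].
#' @param multiplicity `"bonferroni"` or `"BH"`.
#' @param test `"fisher"` or `"chisq"` (see [enrichment_p_value()]).
#' @param zero_correction Haldane-Anscombe increment for zero cells.
#' @return A tibble of class `enrichment_tbl` with columns `term_id`,
#'   `term_name`, `a`, `b`, `c`, `d`, `odds_ratio`, `corrected`,
#'   `p_value`, `significant`, sorted by descending odds ratio (ties by
#'   term id). Attributes record the family size `m`, `alpha` and the
#'   cohort totals.
#' @export
enrich_terms <- function(case_spectrum, baseline_spectrum, alpha = 0.05,
                         multiplicity = c("bonferroni", "BH"),
                         test = c("fisher", "chisq"), zero_correction = 0.5) {
  multiplicity <- match.arg(multiplicity)
  test <- match.arg(test)
  n_case <- attr(case_spectrum, "total_notes")
  n_base <- attr(baseline_spectrum, "total_notes")
  stopifnot(!is.null(n_case), !is.null(n_base))

  base_df <- setNames(baseline_spectrum$document_frequency,
                      baseline_spectrum$term_id)
  a <- case_spectrum$document_frequency
  c_ <- unname(base_df[case_spectrum$term_id])
  c_[is.na(c_)] <- 0L
  b <- n_case - a
  d <- n_base - c_

  or <- odds_ratio(a, b, c_, d, zero_correction = zero_correction)
  out <- tibble(
    term_id = case_spectrum$term_id,
    term_name = case_spectrum$term_name,
    a = a, b = b, c = c_, d = d,
    odds_ratio = or$odds_ratio,
    corrected = or$corrected,
    p_value = enrichment_p_value(a, b, c_, d, method = test)
  )
  out <- bonferroni_mask(out, alpha = alpha, method = multiplicity)
  at <- attributes(out)[c("m", "alpha", "cutoff", "method")]
  out <- arrange(as_tibble(out), desc(.data$odds_ratio), .data$term_id)
  structure(out,
            m = at$m, alpha = at$alpha, cutoff = at$cutoff,
            multiplicity = at$method, test = test,
            case_notes = n_case, baseline_notes = n_base,
            class = c("enrichment_tbl", class(tibble())))
}
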