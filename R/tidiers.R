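#' Tidy and summarise spectrum, enrichment and age-matrix objects
#'
#' `tidy()` returns the underlying table as a plain tibble; `glance()`
#' returns a one-row summary of the run-level quantities (cohort totals,
#' family size, significance counts).
#'
#' @param x A `spectrum_tbl`, `enrichment_tbl` or `term_age_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy spectrum_tbl
#' @export
tidy.spectrum_tbl <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidiers
#' @method glance spectrum_tbl
#' @export
glance.spectrum_tbl <- function(x, ...) {
  tibble(
    cohort = attr(x, "cohort"),
    total_notes = attr(x, "total_notes"),
    total_patients = attr(x, "total_patients"),
    n_terms = nrow(x),
    propagated = attr(x, "propagated"),
    n_baseline_filtered = attr(x, "n_baseline_filtered") %||% 0L
  )
}

#' @rdname tidiers
#' @method tidy enrichment_tbl
#' @export
tidy.enrichment_tbl <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidiers
#' @method glance enrichment_tbl
#' @export
glance.enrichment_tbl <- function(x, ...) {
  tibble(
    m = attr(x, "m"),
    alpha = attr(x, "alpha"),
    cutoff = attr(x, "cutoff") %||% NA_real_,
    multiplicity = attr(x, "multiplicity"),
    test = attr(x, "test"),
    case_notes = attr(x, "case_notes"),
    baseline_notes = attr(x, "baseline_notes"),
    n_significant = sum(x$significant)
  )
}

#' @rdname tidiers
#' @method tidy term_age_matrix
#' @export
tidy.term_age_matrix <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidiers
#' @method glance term_age_matrix
#' @export
glance.term_age_matrix <- function(x, ...) {
  grid <- attr(x, "grid")
  tibble(
    n_terms = length(attr(x, "terms")),
    n_bins = grid$n_bins,
    bin_width = grid$bin_width,
    min_age = grid$min_age,
    max_age = grid$max_age,
    out_of_range_notes = sum(attr(x, "out_of_range"))
  )
}

unclass_keep_tbl <- function(x) {
  tibble::new_tibble(as.list(x), nrow = nrow(x))
}

#' Plot the top of a phenotype spectrum
#'
#' Horizontal bar chart of the `top_k` terms by patient frequency.
#'
#' @param object A `spectrum_tbl`.
#' @param top_k Number of terms shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_tbl
#' @export
autoplot.spectrum_tbl <- function(object, top_k = 20L, ...) {
  top <- rank_terms(object, "patient_frequency", top_k = top_k)
  lab <- dplyr::coalesce(top$term_name, top$term_id)
  top$label <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$patient_frequency,
                                    y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "patient frequency", y = NULL,
                  title = sprintf("Top %d terms, %s cohort",
                                  nrow(top), attr(object, "cohort"))) +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Odds ratio (log scale) against p-value (-log10), with the
#' significance verdict mapped to colour.
#'
#' @param object An `enrichment_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_tbl
#' @export
autoplot.enrichment_tbl <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[is.finite(dat$odds_ratio) & dat$odds_ratio > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$odds_ratio,
                                    y = -log10(pmax(.data$p_value, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (document frequency)",
                  y = expression(-log[10](p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Heatmap of a term-by-age-bin matrix
#'
#' Terms on the y axis in their ranked order, age bins on the x axis,
#' visit counts as fill.
#'
#' @param object A `term_age_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot term_age_matrix
#' @export
autoplot.term_age_matrix <- function(object, ...) {
  terms <- attr(object, "terms")
  dat <- tidy(object)
  dat$term_id <- factor(dat$term_id, levels = rev(terms))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_lo, y = .data$term_id,
                                    fill = .data$n_notes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "age at visit (years)", y = NULL, fill = "visits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
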