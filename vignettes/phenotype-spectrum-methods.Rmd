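---
title: "Methods: ontology-propagated phenotype spectra from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-propagated phenotype spectra from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospectr)
```

## The problem and the model

Large genetic-disorder cohorts carry most of their phenotypic
information in free-text clinical notes. `phenospectr` turns a note
corpus into quantitative phenotype profiles in four steps: (i) cohort
and note-quality filtering, (ii) concept recognition against the Human
Phenotype Ontology (HPO), (iii) ontology-propagated frequency spectra
with a baseline-noise filter and case-versus-baseline enrichment, and
(iv) age-binned longitudinal term distributions.

The statistical objects are deliberately simple. For a corpus of $N$
notes over $P$ patients, each term $t$ gets

$$\mathrm{tf}(t) = \text{total mentions},\qquad
  \mathrm{df}(t) = \#\{\text{notes containing } t\},\qquad
  \mathrm{idf}(t) = N/\mathrm{df}(t),$$

$$\mathrm{pf}(t) = \#\{\text{patients with} \ge 1 \text{ mention}\}/P .$$

The inverse document frequency is the *plain ratio*, not its logarithm:
the quantity is defined that way here and downstream ranking only uses
its order, which the logarithm would not change. Patient frequency is
the primary spectrum measure because it is invariant to how many notes
a patient accumulates and to within-note repetition (copy-pasted text,
templated notes), which dominate raw tf–idf in real EHR corpora. The
patient denominator is the set of patients with at least one *retained*
note; patients whose notes are all filtered out drop from both
numerator and denominator (both counts appear in the run manifest).

## Ontology handling

The ontology is an `is_a` DAG. Although informal descriptions often say
"tree", HPO terms can have several parents, and propagation follows
*all* of them: the propagated set of an observed term set $S$ is
$S \cup \bigcup_{t\in S}\mathrm{anc}(t)$, truncated at the designated
root "Phenotypic abnormality" (`HP:0000118`), which is excluded from
every output as carrying no information. Terms outside that subtree
(e.g. the mode-of-inheritance branch) are retained and flagged; when
propagated they climb to their own top-level ancestor instead.
Propagation operates on each note's *distinct term set* before document
and patient counting, so ancestors gain document/patient credit, but it
never inflates `tf`, which stays a count of literal mentions. Obsolete
terms are dropped at parse time — they cannot carry annotations in
current HPO-based tooling. The propagation operator is idempotent and
monotone, and the test suite verifies both together with equivalence of
`term_ancestors()` to a boolean-matrix transitive closure on random
DAGs.

Concept mappings are read from the UMLS MRCONSO.RRF layout using only
the `SAB` (source vocabulary) and `SDUI` (source identifier) columns,
keeping `SAB == "HPO"` rows. A CUI mapping to several HPO ids
contributes every mapped id; dropping any of them would silently lose
terms.

## Annotation: a deterministic stand-in for an NLP engine

Production pipelines often use MetaMap or similar engines, which are
non-deterministic across versions and can hallucinate concepts. To make
the downstream statistics exactly testable, the built-in annotator is a
dictionary matcher: ontology names and synonyms are normalized
(lowercase, punctuation/whitespace collapsed between word tokens) and
matched at token boundaries, case-insensitively, with overlapping
candidates resolved longest-match-first and leftmost on ties. Every
occurrence is reported so `tf` reflects true mention counts. Negation
("no cataract") is *not* handled — a documented limitation biasing
toward the same over-counting a concept-spotting engine exhibits. For
real engine output, `ingest_cui_annotations()` accepts flat
`(note_id, cui)` rows and translates them through the mapping; both
paths produce identical downstream tables when fed equivalent
annotations, which the tests assert.

## Filters and their boundaries

- Notes with fewer than 3000 characters (strict `<`, raw length
  including whitespace) or without an MRN-style header
  (`MRN` + optional separator + ≥6 digits, case-insensitive,
  configurable) are rejected; a note failing both reports
  `too_short` as its primary reason. Retained + rejected always equals
  the input count.
- Cohort selection keeps a patient iff some ICD code matches an include
  prefix (`Q90` covers `Q90.x`; codes are compared dot-stripped) or
  exact code and no code matches an exclusion.
- The baseline filter removes case terms whose baseline patient
  frequency is strictly greater than 5% (a term at exactly the
  threshold survives). It is applied after propagating *both* cohorts
  identically; filtering only one side would bias the comparison.
  Duplicate notes are not deduplicated — patient frequency already
  absorbs them.

## Enrichment

Per term, the 2×2 table contrasts case and baseline *document*
frequencies (the spectrum itself is patient-based; both bases are
computed). The odds ratio is the cross product `ad/bc`; when a cell is
zero all four cells get +0.5 (Haldane–Anscombe) and the estimate is
flagged `corrected`; a term absent from both cohorts is undefined and
returned as `NA` rather than a number. The p-value is the two-sided
Fisher exact test, computed directly as the sum of hypergeometric point
probabilities not exceeding the observed table's (with the customary
`1 + 1e-7` floating-point guard); a chi-squared variant with continuity
correction is available as a sensitivity switch since small baseline
corpora make asymptotic tests unreliable. Multiplicity control is plain
Bonferroni at family-wise $\alpha = 0.05$ with a *strict* `p < α/m`
verdict; Benjamini–Hochberg is available as an option. The suite checks
the Fisher p against exhaustive enumeration over *all* 2×2 tables with
$n \le 30$ and against `stats::fisher.test()`.

## Longitudinal matrices

Visit age is `(note_date − birth_date)` in days divided by 365.25 — a
leap-year-neutral convention. Ages fall into half-open 3-month bins
`[lo, lo + 0.25)` spanning 0–12.5 years by default; an age exactly on a
boundary is promoted to the upper bin, and 12.5 itself is out of range.
Out-of-range visits are tallied per term rather than dropped, so each
row satisfies `sum(bins) + out_of_range = notes containing the term`.
Cells count *notes* (visits), once per term per note, regardless of
mention multiplicity. The grid is configurable; the defaults are the
natural choice for a paediatric cohort.

## The synthetic EHR generator

Because individual-level EHR data cannot be shared, every stage is
exercised on generated corpora with recorded ground truth. The
generator emulates, at one-tenth scale, the structure of a paediatric
case/baseline text-mining study:

- 500 case and 500 baseline patients; negative-binomial notes per
  patient with means 2.5 (case) and 0.25 (baseline), mirroring the
  roughly tenfold note-density imbalance such cohorts show;
- note lengths $\mathcal{N}(3500, 600)$ characters, deliberately
  straddling the 3000-character quality threshold; an MRN header with
  probability 0.9; visit ages uniform on 0–12.5 years;
- ten *enriched* terms planted at per-note document probability 0.4 in
  cases versus 0.02 in baseline, 110 cohort-symmetric *common* terms at
  0.05, five *noise* terms at 0.6 in both cohorts (these exceed the 5%
  baseline patient frequency and exercise the baseline filter), one
  term with a Gaussian point-mass age profile (2.0 ± 0.1 years) and one
  with a 0–1-year window, both cohort-symmetric so age structure and
  enrichment are probed independently;
- a 150-term synthetic ontology (depth 5, 15% multi-parent terms, a
  small branch outside the phenotypic root) with one synonym and one
  unique CUI per term.

Note text is assembled from a closed filler vocabulary guaranteed
disjoint from every lexicon token, and surface forms are inserted
verbatim at recorded offsets; consequently dictionary annotation
reproduces the ground-truth mention multiset *exactly*, and
precision/recall of the matcher are computable rather than estimated.
This is also what passing tests do and do not show: they validate the
counting, filtering, enrichment and binning machinery on text whose
annotation layer is perfect; they cannot certify any particular NLP
engine's behaviour on real prose, which is why the ingest path exists.
All randomness flows from one integer seed (stage sub-seeds are derived
by fixed offsets), and a fixed seed yields byte-identical corpora and
pipeline outputs.

## Test and acceptance scales

The property checks run at sizes chosen to finish in minutes on one
core while leaving comfortable statistical margins: 200 random DAGs
(≤50 nodes) for the closure oracle; 100 random corpora for hierarchical
monotonicity; all ~45k 2×2 tables with $n \le 30$ for the Fisher
oracle; 20 seeds of 500+500-patient corpora for planted-enrichment
recovery, where the planted 8× document-probability ratio implies
odds ratios near 12–13 against noise terms near 1, and the test demands
all ten planted terms in the odds-ratio top ten with Bonferroni
significance in at least 19 of 20 seeds; and 20 seeds for the age
point-mass recovery, where ages are drawn on a 1.5–2.5-year window so
the planted term accumulates ≥50 mentions and its argmax bin must land
within one bin of 2.0 years. For the enrichment recovery the two
cohorts use equal note densities — everything symmetric except the
planted ratio — so the measured property is the enrichment machinery
itself rather than cohort imbalance.

## Design choices made where the design was open

- **Enrichment test.** No specific test is canonical for
  document-frequency tables with tiny baseline counts; Fisher's exact
  test is the default and chi-squared a switch, and both are reported
  with the correction flag so a sensitivity analysis is one argument
  away.
- **"Bonferroni 5% FDR".** Family-wise Bonferroni at 0.05 is
  implemented as the primary control; BH is available. The two are
  distinct procedures and conflating them silently would make the
  verdict ambiguous.
- **Zero cells.** The +0.5 correction is applied to all four cells and
  flagged, keeping extreme-but-finite odds ratios comparable while
  making their provenance visible.
- **Boundary conventions.** Strict `<` for note length, strict `>` for
  the baseline filter, strict `<` for the Bonferroni verdict, half-open
  age bins with upward promotion: each boundary is pinned by a test.
- **Offsets from ingest.** Externally ingested annotations carry `NA`
  offsets rather than fabricated positions.

## Known limitations

No negation or family-history handling; no note-type/department
stratification; no word-sense disambiguation; no semantic-similarity
collapsing of related terms; no patient sub-clustering. The synthetic
corpus does not model misspellings, abbreviations, section structure,
or engine hallucinations — the ingest interface is the intended route
for real NLP output.
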