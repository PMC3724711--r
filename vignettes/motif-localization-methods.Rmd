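---
title: "Assigning subcellular localizations to sequence motifs: methods and design"
author: "motifCompartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning subcellular localizations to sequence motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifCompartments)
```

## The problem

PROSITE motifs come with curated hit lists: true positives (TP), proteins
that carry the motif and belong to the family, and false positives (FP),
proteins that match the motif sequence without the family's function.
Subcellular localization is a strong functional constraint, so comparing
where a motif's TP and FP sequences live is informative twice over: the
TP compartments characterize the family, and any non-random FP
concentration hints at sequence convergence or shared ancestry.
`motifCompartments` implements that comparison end to end, from flat-file
parsing to co-occurrence summaries.

## Localization model

A protein's compartments are read from its Swiss-Prot keywords through an
exact, whole-keyword, case-sensitive map onto a twelve-compartment
vocabulary (`compartmentVocabulary()`). Two modelling choices deserve
emphasis:

* **"Cell membrane" vs "Membrane".** Only the keyword *Cell membrane*
  assigns the plasma-membrane compartment (code `Mem`). The bare keyword
  *Membrane* marks any membrane association, including organelle
  membranes, and maps to nothing; matching whole keywords (never
  substrings) keeps the two apart.
* **The background universe.** The enrichment universe `N` is the set of
  proteins with **at least one** mapped compartment, not all database
  entries. A protein with no localization keyword carries no evidence
  either way; including it would dilute every background frequency by a
  factor unrelated to biology. Coverage (the fraction of a motif's
  sequences that have localization at all) is reported separately.

Two datasets are derived: the *multiple* dataset keeps every annotated
protein with all of its compartments, and the *single-only* dataset
(`restrictSingle()`) keeps exactly the proteins with one compartment.
The second removes the ambiguity that a multi-compartment protein
contributes to several backgrounds at once, at the price of a smaller
universe; the pipeline can run on either (`dataset = "multiple"` or
`"single"`), and both mapping files are faithful to their dataset.

A user-supplied two-column file (keyword TAB code,
`readCompartmentConfig()`) can replace or extend the mapping. The
seven-compartment mode exists for coarse analyses; since no canonical
seven-compartment subset is universally agreed, the default takes the
first seven vocabulary entries (cyt, chl, ext, Mem, Mit, Nuc, Per) and
`sevenCodes` makes the subset explicit.

## Enrichment test

With `N` annotated proteins of which `K` carry compartment `X`, and a
motif set contributing `n` annotated proteins of which `L` carry `X`, the
null model is sampling without replacement, so `L` is hypergeometric. The
reported p-value is the upper tail
`P(X >= L) = sum_{k=L}^{min(K,n)} C(K,k) C(N-K,n-k) / C(N,n)`
(`hypergeomPValue()`). A compartment is *assigned* only when the p-value
is at or below `alpha` (default 0.05) **and** the set frequency strictly
exceeds the background frequency (`L/n > K/N`); the second clause guards
against the degenerate case where a compartment so dominates the database
that a small tail probability does not indicate excess.

Three deliberate choices:

* **Raw p-values by default.** The per-motif, per-compartment tests are
  reported at the nominal 0.05 level without multiplicity correction;
  this keeps the significance semantics of per-motif annotation tables.
  `adjust` accepts any `p.adjust` method for users who want a corrected
  screen across the twelve compartments.
* **Assignment uses the TP side only.** FP enrichment is computed and
  reported (it drives the FP keyword analysis) but never contributes to a
  motif's compartment assignment: the assignment is meant to describe the
  family, which the FP sequences by definition do not represent.
* **Multi-compartment proteins count once per compartment.** `L` and the
  2xc table cells are compartment incidences, not protein partitions, so
  a protein in two compartments strengthens both columns.

Numerics: binomial coefficients are evaluated as `lchoose` sums in log
space, so `N` in the hundreds of thousands is safe; out-of-support terms
are exact zeros, the tail is clamped to `[0, 1]`, `L = 0` returns exactly
1 and `L > min(K, n)` exactly 0.

## Motif categories and the heterogeneity test

Motifs are first classified (`classifyMotif()`) into five mutually
exclusive categories: `empty_motif` (no localized sequence on either
side), `empty_tp`, `empty_fp`, `tp_eq_fp` (every localized TP and FP
sequence carries the same single compartment), and `testable`. Only
testable motifs proceed to the TP-vs-FP comparison; additionally, a set
with fewer than two localized sequences is skipped as insufficient data
("fewer than two" is interpreted on *localized* sequences, the only
reading that affects the statistics), as is a table that collapses to a
single shared column.

For a testable motif the 2xc table rows are the TP and FP compartment
incidence counts over the columns that are non-zero in at least one row.
The exact test follows the Freeman-Halton rule: conditioning on both
margins, the probability of a table is multivariate hypergeometric, and
the p-value is the total probability of all tables no more probable than
the observed one. Implementation details that matter for reproducibility:

* Probabilities are computed through log binomial coefficients; the
  enumerator runs depth-first over row-1 column counts with
  margin-feasibility pruning, vectorized across candidate prefixes.
* **Tie handling.** Tables whose probability is within a relative 1e-7 of
  the observed probability are included in the tail. This is the
  conservative convention (it can only increase the p-value) and matches
  the behaviour of `fisher.test()` for the 2x2 case, against which the
  engine is verified.
* **Budget and fallback.** Enumeration is capped at 5e6 candidate tables
  (a memory-conscious bound for the vectorized enumerator; configurable
  via `budget`). Beyond it, `fisher2xcMC()` samples fixed-margin tables
  with Patefield's algorithm (`r2dtable`), default 1e6 replicates, with a
  fixed documented seed (20120711) so pipeline output is deterministic;
  the estimator is the sampled fraction of tables at or below the
  observed probability, with its binomial standard error.
* The enumerator checks that the fixed-margin probabilities it visits sum
  to 1 (tolerance 1e-8) and warns otherwise; degenerate one-column tables
  return p = 1 since only one table exists.

## Co-occurrence and FP keyword summaries

Motif assignments are aggregated into a symmetric pair matrix (diagonal:
motifs assigned a single compartment; off-diagonal: motifs assigned
exactly that unordered pair) with the derived margins `2SL` (pair
involvement per compartment) and `1SL - 2SL`, whose sign shows whether a
compartment's motifs occur more often alone or in pairs. Combinations of
3-5 compartments are tabulated with repeat counts `R` and the margins `N`
(distinct combinations containing the compartment) and `NxR` (motifs
whose combination contains it). Rows sort by `R` descending then
lexicographically, so output is stable under input permutation.

For motifs whose FP set has at least one significant compartment, the
Swiss-Prot keywords of the FP proteins assigned to those compartments are
counted, keywords seen once are dropped, and four technical keywords
(3D-structure, Reference proteome, Complete proteome, Alternative
splicing) are excluded by default; the exclusion list is an explicit
keyword vector rather than a keyword-hierarchy lookup, so it works
without UniProt's hierarchy file and is user-extensible. Significant FP
compartments are pooled into one group by default — the examples that
motivate the analysis mix compartments in one group — with
`perCompartment = TRUE` available to split them.

## The synthetic generator

`generateSynthetic()` is first-class, tested code, not a test hack: it
emulates the joint structure the pipeline consumes and returns a truth
ledger against which every downstream count can be reconciled.

What it emulates, and the defaults:

* A protein pool (default 3000) whose primary compartment is drawn from a
  background over six abundant compartments (cyt 0.18, Nuc 0.15, Mem
  0.12, ext 0.10, Mit 0.08, chl 0.05), the remaining 32% unlocalized —
  roughly the 60% keyword-localization coverage of curated databases.
* A multi-compartment fraction of 0.068: localized proteins gain a second
  background-drawn compartment with that probability, the fraction
  observed among keyword-annotated Swiss-Prot proteins.
* Motifs (default 50, alternating pattern/matrix) whose TP sets (default
  20) are drawn without replacement with odds multiplier `tpRho`
  (default 10) for proteins in a designated target compartment; FP sets
  (default 10) default to background draws, or to their own target via
  `fpRho`. TP and FP sets of one motif are disjoint, but a protein may
  serve different motifs in different roles, as in real PROSITE.
* Decor keywords (Reference proteome 0.9, 3D-structure 0.2, Coiled coil
  0.1, Repeat 0.1) attached to all proteins, localized or not, so the
  technical-keyword exclusions and coverage denominators are exercised.

Identical seeds give byte-identical flat files. What it does **not**
emulate: sequence content (motifs carry dummy consensus strings),
secondary-accession aliasing, the long right tail of real TP set sizes
(PROSITE sets range from a handful to tens of thousands), correlated
compartment structure (ER/Golgi co-annotation), and curation noise in
TP/FP flags. Passing the synthetic validation therefore demonstrates the
statistics and plumbing are correct under a realistic-scale null and
planted-alternative model; it does not certify biological conclusions on
real releases, which require running the pipeline on actual Swiss-Prot
and PROSITE files.

## Validation problem sizes

The shipped validation works at deliberately desk-scale sizes: the
hypergeometric engine is checked against independent oracles exhaustively
for universes up to N = 60 (and against exact subset enumeration up to
N = 12); the exact 2xc engine against a brute-force fixed-margin
enumerator on every 2x2 and 2x3 table with total at most 12; the null
false-positive rates on a 500-motif cohort over 2000 proteins; and power
on 200 motifs with 50x odds and 10% background, where the planted
compartment is recovered essentially always. These sizes make the full
suite run in about a minute while keeping every check exact or
well-powered.

## Known limitations

* Keyword-based localization inherits curation gaps: absence of a
  localization keyword is treated as "unannotated", never as evidence of
  absence.
* The cytosol keyword (Cytoplasm) may cover cytoplasmic organelles in the
  multiple dataset; the single-only dataset exists precisely to firm that
  interpretation up.
* Raw 0.05 thresholds across thousands of motifs imply a predictable
  false-discovery load; the `adjust` option is the lever when a
  genome-scale screen rather than per-motif annotation is the goal.
* The exact engine's runtime grows with the product of column margins;
  very large, many-compartment motifs fall back to Monte Carlo, whose
  p-values carry sampling error of order `1/sqrt(reps)`.
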