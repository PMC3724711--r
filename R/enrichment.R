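## Upper-tail hypergeometric enrichment of compartments in a motif's TP or
## FP sequence set, and the motif category classification.
##
## The model: the database holds N localization-annotated proteins, K of
## which carry compartment X. A motif's set contributes n annotated
## proteins, L of which carry X. Under the null that the set is an
## unbiased draw, L follows the hypergeometric distribution; enrichment is
## the upper-tail probability P(X >= L), significant at p <= 0.05, and a
## compartment is only assigned when its frequency in the set strictly
## exceeds the database frequency.

#' Hypergeometric probability mass
#'
#' `P(X = k) = C(K,k) C(N-K, n-k) / C(N,n)` for a draw of `n` from a
#' universe of `N` containing `K` marked items. Computed in log space for
#' overflow safety; `k` outside the support returns 0. Vectorized over `k`.
#'
#' @param N Universe size.
#' @param K Number of marked items, `0 <= K <= N`.
#' @param n Draw size, `0 <= n <= N`.
#' @param k Number of marked items drawn (vectorized).
#' @return Probabilities, same length as `k`.
#' @examples
#' hypergeomPMF(50, 5, 10, 3)
#' @export
hypergeomPMF <- function(N, K, n, k) {
  if (N < 0 || K < 0 || K > N || n < 0 || n > N)
    stop("require 0 <= K <= N and 0 <= n <= N")
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  p <- numeric(length(k))
  ok <- k >= lo & k <= hi
  p[ok] <- exp(lchoose(K, k[ok]) + lchoose(N - K, n - k[ok]) - lchoose(N, n))
  p
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= L) = sum_{k=L}^{min(K,n)} P(X = k)`: the probability of observing
#' `L` or more marked items in the draw. Equals 1 whenever `L` is at or
#' below the lower support bound, and 0 when `L` exceeds `min(K, n)` (empty
#' sum). Clamped to `[0, 1]` against floating-point drift.
#'
#' @inheritParams hypergeomPMF
#' @param L Observed number of marked items, `0 <= L <= n`.
#' @return A single p-value in `[0, 1]`.
#' @examples
#' hypergeomPValue(50, 5, 10, 3)
#' @export
hypergeomPValue <- function(N, K, n, L) {
  if (L < 0 || L > n) stop("require 0 <= L <= n")
  hi <- min(K, n)
  if (L > hi) return(0)
  if (L <= max(0, n - (N - K))) return(1)
  min(1, max(0, sum(hypergeomPMF(N, K, n, L:hi))))
}

#' Localization counts for a protein accession set
#'
#' Counts, within a motif's TP or FP accession set, the proteins present in
#' the localization dataset (`n`), the per-compartment incidence `L[c]`
#' (a multi-compartment protein counts once per compartment it carries),
#' and the raw set size `nTotal` including proteins without localization.
#'
#' @param accessions Character vector of protein accessions (a set).
#' @param ds A [LocalizationDataset-class].
#' @return A list with `n`, `L` (named integer over the vocabulary codes),
#'   and `nTotal`.
#' @export
countSet <- function(accessions, ds) {
  accessions <- unique(accessions)
  codes <- vocabCodes(ds@vocabulary)
  hit <- ds@assignments[intersect(accessions, names(ds@assignments))]
  L <- integer(length(codes)); names(L) <- codes
  if (length(hit)) {
    tab <- table(factor(unlist(hit, use.names = FALSE), levels = codes))
    L[] <- as.integer(tab)
  }
  list(n = length(hit), L = L, nTotal = length(accessions))
}

#' Compartment enrichment of a sequence set
#'
#' Tests every compartment for over-representation in the set against the
#' database background. For compartments with `L[c] >= 1` the upper-tail
#' hypergeometric p-value is computed; compartments absent from the set get
#' `p = 1`. A compartment is flagged enriched iff `p <= alpha` and its set
#' frequency strictly exceeds the background frequency
#' (`L/n > K[c]/N`). Raw p-values are used by default, matching the
#' per-motif testing scheme; `adjust` applies a multiplicity correction
#' across the compartments for users who want one.
#'
#' @param counts Output of [countSet()]; `counts$n` must be at least 1.
#' @param ds A [LocalizationDataset-class] (the enrichment universe).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust A `p.adjust` method applied across compartments, or
#'   `"none"` (default).
#' @return A `data.frame` with columns `code`, `L`, `pValue`, `enriched`;
#'   attributes `n`, `N`.
#' @export
enrichSet <- function(counts, ds, alpha = 0.05, adjust = "none") {
  if (counts$n < 1L)
    stop("cannot test an empty set: no proteins with localization")
  codes <- vocabCodes(ds@vocabulary)
  n <- counts$n; N <- ds@N
  p <- vapply(codes, function(c) {
    if (counts$L[[c]] == 0L) 1
    else hypergeomPValue(N, ds@K[[c]], n, counts$L[[c]])
  }, 0)
  pAdj <- if (identical(adjust, "none")) p else stats::p.adjust(p, adjust)
  enriched <- pAdj <= alpha & counts$L[codes] / n > ds@K[codes] / N
  out <- data.frame(code = codes, L = as.integer(counts$L[codes]),
                    pValue = unname(pAdj), enriched = unname(enriched),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "N") <- N
  out
}

#' Classify a motif by the localization content of its hit sets
#'
#' The five mutually exclusive categories: `empty_motif` (neither TP nor FP
#' sequences have any localization), `empty_tp` / `empty_fp` (exactly one
#' side has none), `tp_eq_fp` (all localized TP and FP sequences carry the
#' same single compartment), and `testable` (both sides have localization
#' data and more than one compartment is involved).
#'
#' @param motif A [MotifRecord-class].
#' @param ds A [LocalizationDataset-class].
#' @return A single string, one of the five category names.
#' @export
classifyMotif <- function(motif, ds) {
  tp <- countSet(motif@tpAccessions, ds)
  fp <- countSet(motif@fpAccessions, ds)
  if (tp$n == 0L && fp$n == 0L) return("empty_motif")
  if (tp$n == 0L) return("empty_tp")
  if (fp$n == 0L) return("empty_fp")
  present <- names(tp$L)[tp$L + fp$L > 0L]
  if (length(present) == 1L) return("tp_eq_fp")
  "testable"
}

#' Assign compartments to a motif from its TP set
#'
#' A motif's localization assignment is the set of compartments enriched in
#' its true-positive sequences; false-positive enrichment is reported
#' separately but never contributes to the assignment.
#'
#' @param motif A [MotifRecord-class] with at least one localized TP
#'   protein.
#' @param ds A [LocalizationDataset-class].
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of assigned compartment codes (possibly empty).
#' @export
assignMotifLocalizations <- function(motif, ds, alpha = 0.05) {
  counts <- countSet(motif@tpAccessions, ds)
  enr <- enrichSet(counts, ds, alpha = alpha)
  enr$code[enr$enriched]
}
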