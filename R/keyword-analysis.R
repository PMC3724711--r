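## Keyword structure of false-positive sequence groups.

#' Default keyword exclusions
#'
#' The technical-term keywords (3D-structure, Reference proteome, Complete
#' proteome) and the coding-sequence-diversity keyword (Alternative
#' splicing) that carry no biological localization signal and are removed
#' before counting.
#'
#' @return Character vector of four keywords.
#' @export
defaultKeywordExclusions <- function() {
  c("3D-structure", "Reference proteome", "Complete proteome",
    "Alternative splicing")
}

#' Keyword frequencies in a motif's significant FP group
#'
#' For a motif whose FP set has at least one significantly enriched
#' compartment, collects the FP proteins assigned to those compartments
#' (pooled across compartments by default, or one group per compartment),
#' counts every Swiss-Prot keyword across the group, removes the exclusion
#' list, filters keywords seen only once, and sorts by count descending
#' (then alphabetically for determinism).
#'
#' @param motif A [MotifRecord-class].
#' @param records Named list of [ProteinRecord-class] objects indexed by
#'   primary accession (see [indexRecords()]).
#' @param ds A [LocalizationDataset-class].
#' @param fpEnrichment Output of [enrichSet()] on the motif's FP set.
#' @param exclusions Keywords removed before counting (default
#'   [defaultKeywordExclusions()]).
#' @param perCompartment If `TRUE`, return one group per significant
#'   compartment instead of pooling.
#' @return A `data.frame` with columns `group` (comma-joined significant
#'   codes, or one code per group), `keyword`, `count`, `groupSize`; empty
#'   with attribute `reason = "no significant FP compartment"` when the FP
#'   set has none.
#' @export
fpKeywordFrequencies <- function(motif, records, ds, fpEnrichment,
                                 exclusions = defaultKeywordExclusions(),
                                 perCompartment = FALSE) {
  sig <- fpEnrichment$code[fpEnrichment$enriched]
  empty <- data.frame(group = character(), keyword = character(),
                      count = integer(), groupSize = integer(),
                      stringsAsFactors = FALSE)
  if (!length(sig)) {
    attr(empty, "reason") <- "no significant FP compartment"
    return(empty)
  }
  countGroup <- function(codes, label) {
    members <- intersect(unique(motif@fpAccessions), names(ds@assignments))
    members <- members[vapply(ds@assignments[members],
                              function(a) any(a %in% codes), TRUE)]
    if (!length(members)) return(empty)
    kw <- unlist(lapply(records[members], function(r) unique(r@keywords)),
                 use.names = FALSE)
    kw <- kw[!kw %in% exclusions]
    if (!length(kw)) return(empty)
    tab <- sort(table(kw), decreasing = TRUE)
    tab <- tab[tab > 1L]
    if (!length(tab)) return(empty)
    ord <- order(-as.integer(tab), names(tab))
    data.frame(group = label, keyword = names(tab)[ord],
               count = as.integer(tab)[ord],
               groupSize = length(members), stringsAsFactors = FALSE)
  }
  if (perCompartment) {
    out <- do.call(rbind, lapply(sig, function(c) countGroup(c, c)))
  } else {
    out <- countGroup(sig, paste(sig, collapse = ","))
  }
  if (is.null(out)) empty else out
}

#' Index protein records by primary accession
#'
#' @param records List of [ProteinRecord-class] objects.
#' @return The same list, named by primary accession.
#' @export
indexRecords <- function(records) {
  names(records) <- vapply(records, function(r) r@accession, "")
  records
}
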