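#' @import methods
NULL

#' Compartment vocabulary: keyword to compartment mapping
#'
#' An ordered controlled vocabulary of subcellular compartments together with
#' the Swiss-Prot keyword that assigns each of them. Two modes exist:
#' `"twelve"` (the full set) and `"seven"` (a configurable subset used for
#' coarse analyses).
#'
#' @slot entries A `data.frame` with character columns `keyword` (the exact
#'   Swiss-Prot keyword), `compartment` (a human-readable compartment name)
#'   and `code` (a three-letter compartment code). Row order is meaningful
#'   and preserved in all outputs.
#' @slot mode Either `"twelve"` or `"seven"`.
#'
#' @seealso [compartmentVocabulary()], [keywordsToLocalizations()]
#' @export
setClass("CompartmentVocabulary",
  representation(entries = "data.frame", mode = "character"))

setValidity("CompartmentVocabulary", function(object) {
  e <- object@entries
  msgs <- character()
  if (!all(c("keyword", "compartment", "code") %in% names(e)))
    msgs <- c(msgs, "entries must have columns keyword, compartment, code")
  else {
    if (anyDuplicated(e$keyword)) msgs <- c(msgs, "keywords must be unique")
    if (anyDuplicated(e$code)) msgs <- c(msgs, "codes must be unique")
    if (identical(object@mode, "twelve")) {
      full <- c("cyt", "chl", "ext", "Mem", "Mit", "Nuc",
                "Per", "Ret", "Gol", "Prx", "Lys", "Vac")
      if (nrow(e) != 12L || !setequal(e$code, full))
        msgs <- c(msgs, "twelve mode requires exactly the 12 canonical codes")
    }
  }
  if (!length(object@mode) == 1L || !object@mode %in% c("twelve", "seven"))
    msgs <- c(msgs, "mode must be 'twelve' or 'seven'")
  if (length(msgs)) msgs else TRUE
})

#' A single Swiss-Prot protein record
#'
#' Minimal view of a UniProtKB/Swiss-Prot flat-file entry: the primary
#' accession, the entry name, the keyword set, and any secondary accessions
#' (aliases) that resolve to the primary one.
#'
#' @slot accession Primary (first) accession.
#' @slot entryName Entry name from the ID line.
#' @slot keywords Character vector of de-duplicated keywords (may be empty).
#' @slot aliases Secondary accessions, possibly empty.
#'
#' @seealso [readSwissProt()]
#' @export
setClass("ProteinRecord",
  representation(accession = "character", entryName = "character",
                 keywords = "character", aliases = "character"))

setValidity("ProteinRecord", function(object) {
  if (length(object@accession) != 1L || !nzchar(object@accession))
    "accession must be a single non-empty string" else TRUE
})

#' A PROSITE motif with its curated hit lists
#'
#' One motif from a PROSITE flat file: a pattern (regular-expression-like
#' consensus) or a matrix/profile (positional scores), plus the curated sets
#' of true-positive and false-positive Swiss-Prot accessions from its DR
#' lines.
#'
#' @slot accession PROSITE accession (`PS` + five digits).
#' @slot name Motif identifier from the ID line.
#' @slot description Concatenated DE text.
#' @slot kind `"pattern"` or `"matrix"`.
#' @slot consensus PA lines joined; empty for matrices.
#' @slot tpAccessions Protein accessions flagged `T` (true positives).
#' @slot fpAccessions Protein accessions flagged `F` (false positives).
#'
#' @seealso [readProsite()]
#' @export
setClass("MotifRecord",
  representation(accession = "character", name = "character",
                 description = "character", kind = "character",
                 consensus = "character",
                 tpAccessions = "character", fpAccessions = "character"))

setValidity("MotifRecord", function(object) {
  msgs <- character()
  if (!object@kind %in% c("pattern", "matrix"))
    msgs <- c(msgs, "kind must be 'pattern' or 'matrix'")
  if (length(intersect(object@tpAccessions, object@fpAccessions)))
    msgs <- c(msgs, "TP and FP accession sets must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Protein-to-compartment assignment table with background counts
#'
#' The accession-to-compartment map derived from Swiss-Prot keywords,
#' together with the database-wide background counts used as the enrichment
#' universe: `N` (number of proteins with at least one assigned compartment)
#' and `K[c]` (number of proteins assigned compartment `c`).
#'
#' @slot assignments Named list; each element is a non-empty character
#'   vector of compartment codes for one accession. In `single_only` mode
#'   every element has length 1.
#' @slot N Integer, `length(assignments)`.
#' @slot K Named integer vector over the vocabulary codes.
#' @slot mode `"multiple"` or `"single_only"`.
#' @slot vocabulary The [CompartmentVocabulary-class] the dataset was built
#'   with.
#'
#' @seealso [buildLocalizationDataset()], [restrictSingle()]
#' @export
setClass("LocalizationDataset",
  representation(assignments = "list", N = "integer", K = "integer",
                 mode = "character", vocabulary = "CompartmentVocabulary"))

setValidity("LocalizationDataset", function(object) {
  msgs <- character()
  if (object@N != length(object@assignments))
    msgs <- c(msgs, "N must equal the number of assigned accessions")
  lens <- lengths(object@assignments)
  if (any(lens < 1L)) msgs <- c(msgs, "every assignment must be non-empty")
  if (identical(object@mode, "single_only") && any(lens != 1L))
    msgs <- c(msgs, "single_only mode requires exactly one code per protein")
  if (any(object@K > object@N)) msgs <- c(msgs, "K[c] cannot exceed N")
  if (!object@mode %in% c("multiple", "single_only"))
    msgs <- c(msgs, "mode must be 'multiple' or 'single_only'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CompartmentVocabulary", function(object) {
  cat(sprintf("CompartmentVocabulary (%s mode): %d compartments\n",
              object@mode, nrow(object@entries)))
  cat("  ", paste(object@entries$code, collapse = " "), "\n", sep = "")
})

setMethod("show", "ProteinRecord", function(object) {
  cat(sprintf("ProteinRecord %s (%s): %d keyword(s)\n",
              object@accession, object@entryName, length(object@keywords)))
})

setMethod("show", "MotifRecord", function(object) {
  cat(sprintf("MotifRecord %s [%s] %s\n  TP: %d  FP: %d\n",
              object@accession, object@kind, object@name,
              length(object@tpAccessions), length(object@fpAccessions)))
})

setMethod("show", "LocalizationDataset", function(object) {
  cat(sprintf("LocalizationDataset (%s): N = %d proteins\n",
              object@mode, object@N))
  k <- object@K[object@K > 0L]
  if (length(k))
    cat("  K:", paste(sprintf("%s=%d", names(k), k), collapse = " "), "\n")
})
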