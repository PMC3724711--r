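## Keyword -> compartment vocabulary.
##
## The twelve-compartment map uses the exact Swiss-Prot keywords that mark a
## localization; the assignment keyword "Cell membrane" is deliberately
## distinct from the generic "Membrane" keyword, which marks any membrane
## association (including organelle membranes) and therefore maps to nothing.

.COMPARTMENT_TABLE <- data.frame(
  keyword = c("Cytoplasm", "Chloroplast", "Secreted", "Cell membrane",
              "Mitochondrion", "Nucleus", "Periplasm",
              "Endoplasmic reticulum", "Golgi apparatus", "Peroxisome",
              "Lysosome", "Vacuole"),
  compartment = c("Cytosol", "Chloroplast", "Extracellular", "C_Membrane",
                  "Mitochondrion", "Nucleus", "Periplasm", "E_Reticulum",
                  "Golgi", "Peroxisome", "Lysosome", "Vacuole"),
  code = c("cyt", "chl", "ext", "Mem", "Mit", "Nuc",
           "Per", "Ret", "Gol", "Prx", "Lys", "Vac"),
  stringsAsFactors = FALSE)

.SEVEN_DEFAULT <- c("cyt", "chl", "ext", "Mem", "Mit", "Nuc", "Per")

#' Construct the compartment vocabulary
#'
#' Builds the controlled vocabulary that maps Swiss-Prot localization
#' keywords to compartment codes. In `"twelve"` mode the full canonical set
#' is returned: Cytoplasm (cyt), Chloroplast (chl), Secreted (ext),
#' Cell membrane (Mem), Mitochondrion (Mit), Nucleus (Nuc), Periplasm (Per),
#' Endoplasmic reticulum (Ret), Golgi apparatus (Gol), Peroxisome (Prx),
#' Lysosome (Lys) and Vacuole (Vac). In `"seven"` mode a subset is used;
#' by default the first seven compartments above, overridable through
#' `sevenCodes`.
#'
#' Matching is against whole keywords only, so the bare Swiss-Prot keyword
#' "Membrane" never triggers the Cell membrane compartment.
#'
#' @param mode `"twelve"` (default) or `"seven"`.
#' @param sevenCodes Codes retained in seven mode; must be a subset of the
#'   twelve canonical codes.
#' @return A [CompartmentVocabulary-class] object.
#' @examples
#' vocab <- compartmentVocabulary()
#' keywordsToLocalizations(c("Cytoplasm", "Chloroplast"), vocab)
#' @export
compartmentVocabulary <- function(mode = c("twelve", "seven"),
                                  sevenCodes = NULL) {
  mode <- match.arg(mode)
  entries <- .COMPARTMENT_TABLE
  if (mode == "seven") {
    keep <- if (is.null(sevenCodes)) .SEVEN_DEFAULT else sevenCodes
    if (!all(keep %in% entries$code))
      stop("sevenCodes must be a subset of the twelve canonical codes")
    entries <- entries[entries$code %in% keep, , drop = FALSE]
    rownames(entries) <- NULL
  }
  new("CompartmentVocabulary", entries = entries, mode = mode)
}

#' Read a user-supplied keyword-to-compartment mapping
#'
#' Reads a plain-text two-column configuration (keyword TAB code, `#`
#' comments and blank lines ignored) and returns a vocabulary built from it,
#' allowing users to extend or replace the canonical mapping. Compartment
#' display names default to the code when the keyword is not one of the
#' canonical twelve.
#'
#' @param path Path to the tab-separated mapping file.
#' @return A [CompartmentVocabulary-class] object in `"seven"` mode
#'   semantics (a free-form vocabulary; no canonical-code constraint is
#'   imposed).
#' @export
readCompartmentConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("malformed vocabulary line(s): ", paste(lines[bad], collapse = "; "))
  keyword <- trimws(vapply(parts, `[[`, "", 1L))
  code <- trimws(vapply(parts, `[[`, "", 2L))
  canon <- .COMPARTMENT_TABLE$compartment[match(code, .COMPARTMENT_TABLE$code)]
  entries <- data.frame(keyword = keyword,
                        compartment = ifelse(is.na(canon), code, canon),
                        code = code, stringsAsFactors = FALSE)
  new("CompartmentVocabulary", entries = entries, mode = "seven")
}

#' Compartment codes of a vocabulary
#' @param vocab A [CompartmentVocabulary-class].
#' @return Character vector of compartment codes, in vocabulary order.
#' @export
vocabCodes <- function(vocab) vocab@entries$code

#' Localization keywords of a vocabulary
#' @param vocab A [CompartmentVocabulary-class].
#' @return Character vector of the exact Swiss-Prot keywords, in order.
#' @export
vocabKeywords <- function(vocab) vocab@entries$keyword

#' Map Swiss-Prot keywords to compartment codes
#'
#' Returns the set of compartment codes whose defining keyword appears in
#' the input. Matching is exact, whole-keyword and case-sensitive; keywords
#' outside the vocabulary contribute nothing.
#'
#' @param keywords Character vector of keyword strings (already tokenized,
#'   trailing punctuation stripped).
#' @param vocab A [CompartmentVocabulary-class].
#' @return Character vector of compartment codes (a set, in vocabulary
#'   order; possibly empty).
#' @examples
#' vocab <- compartmentVocabulary()
#' keywordsToLocalizations(c("Nucleus", "3D-structure"), vocab)
#' @export
keywordsToLocalizations <- function(keywords, vocab) {
  e <- vocab@entries
  e$code[e$keyword %in% keywords]
}
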