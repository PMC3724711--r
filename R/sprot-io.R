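## Swiss-Prot flat-file I/O and localization dataset construction.

.openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Parse a UniProtKB/Swiss-Prot flat file
#'
#' Reads the line types needed for localization analysis: `ID` (entry name),
#' `AC` (accessions; the first accession of the first AC line is the primary
#' one, the rest become aliases) and `KW` (keywords; wrapped lines are
#' concatenated before splitting on `;`, the terminal `.` is stripped, and
#' evidence tags in curly braces are discarded). Records end with `//`.
#'
#' @param path Path to a Swiss-Prot flat file (plain or gzip), or a
#'   character vector of lines via `text`.
#' @param text Optional character vector of flat-file lines (used instead of
#'   `path`).
#' @return A list of [ProteinRecord-class] objects.
#' @examples
#' txt <- c("ID   EX1_TEST   Reviewed;   10 AA.",
#'          "AC   P00001; Q00001;",
#'          "KW   Nucleus; 3D-structure.", "//")
#' readSwissProt(text = txt)
#' @export
readSwissProt <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    con <- .openText(path)
    on.exit(close(con))
    text <- readLines(con, warn = FALSE)
  }
  text <- unname(text)
  ends <- which(text == "//")
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    lines <- text[starts[i]:(ends[i] - 1L)]
    lines <- lines[nzchar(lines)]
    if (!length(lines)) next
    tag <- substr(lines, 1L, 2L)
    body <- trimws(substring(lines, 6L))
    acLines <- body[tag == "AC"]
    if (!length(acLines))
      stop(sprintf("malformed Swiss-Prot record ending at line %d: no AC line",
                   ends[i]))
    accs <- trimws(unlist(strsplit(paste(acLines, collapse = " "), ";")))
    accs <- accs[nzchar(accs)]
    idLine <- body[tag == "ID"]
    entryName <- if (length(idLine)) strsplit(idLine[1L], "\\s+")[[1L]][1L]
                 else ""
    kwLines <- body[tag == "KW"]
    keywords <- character()
    if (length(kwLines)) {
      kw <- paste(kwLines, collapse = " ")
      kw <- sub("\\.\\s*$", "", kw)
      kw <- gsub("\\{[^}]*\\}", "", kw)   # tolerate evidence tags
      keywords <- unique(trimws(strsplit(kw, ";")[[1L]]))
      keywords <- keywords[nzchar(keywords)]
    }
    records[[i]] <- new("ProteinRecord", accession = accs[1L],
                        entryName = entryName, keywords = keywords,
                        aliases = accs[-1L])
  }
  records[!vapply(records, is.null, logical(1L))]
}

#' Write protein records as a Swiss-Prot flat file
#'
#' Emits the minimal `ID`/`AC`/`KW` dialect consumed by [readSwissProt()],
#' wrapping long keyword lists across continuation KW lines. The writer and
#' parser round-trip exactly, which the synthetic-fixture tests rely on.
#'
#' @param records List of [ProteinRecord-class] objects.
#' @param path Output path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
writeSwissProt <- function(records, path = NULL) {
  out <- unlist(lapply(records, function(r) {
    lines <- c(sprintf("ID   %-24s Reviewed; %11d AA.",
                       if (nzchar(r@entryName)) r@entryName else
                         paste0(r@accession, "_X"), 100L),
               sprintf("AC   %s;",
                       paste(c(r@accession, r@aliases), collapse = "; ")))
    if (length(r@keywords)) {
      toks <- paste0(r@keywords, c(rep(";", length(r@keywords) - 1L), "."))
      kw <- character(); cur <- "KW  "
      for (t in toks) {
        if (nchar(cur) + 1L + nchar(t) > 75L && nchar(cur) > 4L) {
          kw <- c(kw, cur); cur <- "KW  "
        }
        cur <- paste(cur, t)
      }
      lines <- c(lines, c(kw, cur))
    }
    c(lines, "//")
  }))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Alias index for protein records
#'
#' Maps every accession (primary and secondary) to its primary accession, so
#' PROSITE DR lines citing merged (secondary) accessions resolve correctly.
#'
#' @param records List of [ProteinRecord-class] objects.
#' @return Named character vector: names are all known accessions, values
#'   the corresponding primary accession.
#' @export
aliasIndex <- function(records) {
  prim <- vapply(records, function(r) r@accession, "")
  ali <- lapply(records, function(r) r@aliases)
  idx <- c(prim, unlist(ali))
  names(idx) <- idx
  idx[unlist(ali)] <- rep(prim, lengths(ali))
  idx
}

#' Build the localization dataset from protein records
#'
#' Assigns one or more compartments to every protein whose keywords map to
#' at least one compartment code; proteins with no mapped keyword are
#' excluded, so the background universe `N` is the set of
#' localization-annotated proteins.
#'
#' @param records List of [ProteinRecord-class] objects.
#' @param vocab A [CompartmentVocabulary-class].
#' @return A [LocalizationDataset-class] in `"multiple"` mode.
#' @export
buildLocalizationDataset <- function(records, vocab) {
  codes <- lapply(records, function(r)
    keywordsToLocalizations(r@keywords, vocab))
  keep <- lengths(codes) > 0L
  assignments <- codes[keep]
  names(assignments) <- vapply(records[keep], function(r) r@accession, "")
  .newDataset(assignments, vocab, "multiple")
}

.newDataset <- function(assignments, vocab, mode) {
  allCodes <- vocabCodes(vocab)
  K <- integer(length(allCodes))
  names(K) <- allCodes
  if (length(assignments)) {
    tab <- table(factor(unlist(assignments, use.names = FALSE),
                        levels = allCodes))
    K[] <- as.integer(tab)
  }
  new("LocalizationDataset", assignments = assignments,
      N = length(assignments), K = K, mode = mode, vocabulary = vocab)
}

#' Restrict a dataset to single-localization proteins
#'
#' Keeps exactly the proteins assigned one compartment and recomputes the
#' background counts, yielding the dataset in which a cytosol annotation is
#' unequivocally cytosolic.
#'
#' @param ds A [LocalizationDataset-class] in `"multiple"` mode.
#' @return A [LocalizationDataset-class] in `"single_only"` mode.
#' @export
restrictSingle <- function(ds) {
  stopifnot(ds@mode == "multiple")
  keep <- lengths(ds@assignments) == 1L
  .newDataset(ds@assignments[keep], ds@vocabulary, "single_only")
}

#' Number of proteins in the enrichment universe
#' @param ds A [LocalizationDataset-class].
#' @return Integer `N`.
#' @export
datasetN <- function(ds) ds@N

#' Per-compartment background counts
#' @param ds A [LocalizationDataset-class].
#' @return Named integer vector `K` over the vocabulary codes.
#' @export
datasetK <- function(ds) ds@K

#' Protein-to-compartment assignments
#' @param ds A [LocalizationDataset-class].
#' @return Named list of compartment-code vectors.
#' @export
datasetAssignments <- function(ds) ds@assignments

#' Compartment frequency summary of a dataset
#'
#' Tabulates, per compartment, the number and percentage of proteins
#' assigned to it, plus the fraction of those proteins that carry more than
#' one compartment; the `Multiple` attribute gives the overall count and
#' percentage of multi-compartment proteins. Percentages are over `N`.
#'
#' @param ds A [LocalizationDataset-class] in `"multiple"` mode.
#' @return A `data.frame` with columns `code`, `count`, `percent`,
#'   `multiCount`, `multiFraction`; attributes `multipleCount` and
#'   `multiplePercent`.
#' @export
datasetFrequencies <- function(ds) {
  stopifnot(ds@mode == "multiple")
  codes <- vocabCodes(ds@vocabulary)
  lens <- lengths(ds@assignments)
  multi <- names(ds@assignments)[lens >= 2L]
  multiK <- integer(length(codes)); names(multiK) <- codes
  if (length(multi)) {
    tab <- table(factor(unlist(ds@assignments[multi], use.names = FALSE),
                        levels = codes))
    multiK[] <- as.integer(tab)
  }
  out <- data.frame(
    code = codes,
    count = as.integer(ds@K[codes]),
    percent = if (ds@N > 0L) 100 * ds@K[codes] / ds@N else rep(0, length(codes)),
    multiCount = as.integer(multiK),
    multiFraction = ifelse(ds@K[codes] > 0L, multiK / ds@K[codes], 0),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "multipleCount") <- length(multi)
  attr(out, "multiplePercent") <-
    if (ds@N > 0L) 100 * length(multi) / ds@N else 0
  out
}

#' Write the protein-localization mapping as TSV
#'
#' One line per assigned protein: accession, TAB, comma-separated
#' compartment codes (multiple codes only occur in `"multiple"` mode).
#'
#' @param ds A [LocalizationDataset-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeLocalizationMapping <- function(ds, path) {
  lines <- vapply(seq_along(ds@assignments), function(i)
    paste0(names(ds@assignments)[i], "\t",
           paste(ds@assignments[[i]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
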