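## PROSITE flat-file parsing (prosite.dat dialect).

#' Parse a PROSITE flat file
#'
#' Reads motif records following the `prosite.dat` conventions:
#' `ID   name; TYPE.` with TYPE in PATTERN/MATRIX, `AC   PSxxxxx;`,
#' `DE` description lines, `PA` consensus lines (patterns) or `MA` lines
#' (matrices), and `DR` cross-reference lines holding semicolon-separated
#' triplets `accession, entry_name, FLAG` with FLAG in T/N/P/F/?. Records
#' end with `//`; documentation-only blocks (no ID/AC) are skipped.
#'
#' True positives are the accessions flagged `T`, false positives those
#' flagged `F`; false negatives (`N`), potential hits (`P`) and unknowns
#' (`?`) are parsed but excluded from both sets. A DR triplet with an
#' unrecognized flag raises a warning and is skipped.
#'
#' @param path Path to a PROSITE flat file (plain or gzip).
#' @param text Optional character vector of lines, used instead of `path`.
#' @param aliases Optional alias index from [aliasIndex()]; DR accessions
#'   are resolved through it before set construction (unresolvable
#'   accessions are kept as-is).
#' @return A list of [MotifRecord-class] objects.
#' @export
readProsite <- function(path = NULL, text = NULL, aliases = NULL) {
  if (is.null(text)) {
    con <- .openText(path)
    on.exit(close(con))
    text <- readLines(con, warn = FALSE)
  }
  text <- unname(text)
  ends <- which(text == "//")
  starts <- c(1L, head(ends, -1L) + 1L)
  motifs <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    lines <- text[starts[i]:(ends[i] - 1L)]
    lines <- lines[nzchar(lines)]
    if (!length(lines)) next
    tag <- substr(lines, 1L, 2L)
    body <- trimws(substring(lines, 6L))
    idLine <- body[tag == "ID"]
    acLine <- body[tag == "AC"]
    if (!length(idLine) && !length(acLine)) next   # documentation block
    if (!length(acLine))
      stop(sprintf("PROSITE record ending at line %d has no AC line", ends[i]))
    m <- regmatches(idLine[1L],
                    regexec("^(\\S+);\\s*(PATTERN|MATRIX)", idLine[1L]))[[1L]]
    if (length(m) < 3L)
      stop(sprintf("cannot parse ID line of record ending at line %d: %s",
                   ends[i], idLine[1L]))
    kind <- if (m[3L] == "PATTERN") "pattern" else "matrix"
    accession <- sub(";.*$", "", acLine[1L])
    descr <- paste(body[tag == "DE"], collapse = " ")
    consensus <- if (kind == "pattern")
      paste(sub("\\s*$", "", body[tag == "PA"]), collapse = "") else ""
    tp <- character(); fp <- character()
    drBody <- body[tag == "DR"]
    if (length(drBody)) {
      trips <- unlist(strsplit(paste(drBody, collapse = " "), ";"))
      trips <- trimws(trips)
      trips <- trips[nzchar(trips)]
      for (t in trips) {
        fields <- trimws(strsplit(t, ",")[[1L]])
        if (length(fields) != 3L) {
          warning(sprintf("skipping malformed DR triplet in %s: '%s'",
                          accession, t))
          next
        }
        flag <- fields[3L]
        acc <- fields[1L]
        if (!is.null(aliases) && acc %in% names(aliases))
          acc <- unname(aliases[[acc]])
        if (flag == "T") tp <- c(tp, acc)
        else if (flag == "F") fp <- c(fp, acc)
        else if (!flag %in% c("N", "P", "?"))
          warning(sprintf("skipping DR triplet with unknown flag '%s' in %s",
                          flag, accession))
      }
    }
    motifs[[i]] <- new("MotifRecord", accession = accession,
                       name = sub(";$", "", m[2L]), description = descr,
                       kind = kind, consensus = consensus,
                       tpAccessions = unique(tp), fpAccessions = unique(fp))
  }
  motifs[!vapply(motifs, is.null, logical(1L))]
}

#' Write motif records as a PROSITE flat file
#'
#' Emits the `prosite.dat` dialect consumed by [readProsite()]; the
#' writer/parser pair round-trips exactly. True positives are written with
#' flag `T`, false positives with flag `F`, three triplets per DR line.
#'
#' @param motifs List of [MotifRecord-class] objects.
#' @param path Output path, or `NULL` to return lines invisibly.
#' @param entryNames Optional named character vector mapping protein
#'   accessions to entry names for the DR lines.
#' @return Invisibly, the character vector of lines written.
#' @export
writeProsite <- function(motifs, path = NULL, entryNames = NULL) {
  drLines <- function(accs, flag) {
    if (!length(accs)) return(character())
    nm <- if (is.null(entryNames)) paste0(accs, "_X")
          else ifelse(accs %in% names(entryNames),
                      entryNames[accs], paste0(accs, "_X"))
    trip <- sprintf("%s, %-10s, %s;", accs, nm, flag)
    grp <- split(trip, (seq_along(trip) - 1L) %/% 3L)
    vapply(grp, function(g) paste0("DR   ", paste(g, collapse = " ")), "")
  }
  out <- unlist(lapply(motifs, function(m) {
    lines <- c(sprintf("ID   %s; %s.", m@name,
                       if (m@kind == "pattern") "PATTERN" else "MATRIX"),
               sprintf("AC   %s;", m@accession),
               sprintf("DE   %s.", sub("\\.$", "", m@description)))
    if (m@kind == "pattern" && nzchar(m@consensus))
      lines <- c(lines, sprintf("PA   %s", m@consensus))
    if (m@kind == "matrix")
      lines <- c(lines, "MA   /GENERAL_SPEC: ALPHABET='ACDEFGHIKLMNPQRSTVWY';")
    c(lines, drLines(m@tpAccessions, "T"), drLines(m@fpAccessions, "F"), "//")
  }))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
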