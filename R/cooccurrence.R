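## Compartment co-occurrence summaries across motif assignments.

#' Pairwise co-occurrence matrix of motif assignments
#'
#' Summarizes motifs assigned exactly one compartment (`singles`, the
#' diagonal of the heat map) and exactly two compartments (`pairs`,
#' unordered). Per compartment, `twoSL[c]` is the number of motifs pairing
#' `c` with any other compartment and `oneMinusTwoSL[c] = singles[c] -
#' twoSL[c]`, a negative value indicating a compartment more often shared
#' than alone. Motifs with zero or three-plus compartments are ignored
#' here.
#'
#' @param assignments Named list: motif accession to character vector of
#'   assigned compartment codes.
#' @param codes Compartment codes defining matrix order (e.g.
#'   `vocabCodes(vocab)`).
#' @return A list with `singles` (named integer), `pairs` (symmetric
#'   integer matrix with singles on the diagonal), `twoSL` and
#'   `oneMinusTwoSL` (named integers).
#' @export
pairMatrix <- function(assignments, codes) {
  sizes <- lengths(assignments)
  singles <- integer(length(codes)); names(singles) <- codes
  one <- unlist(assignments[sizes == 1L], use.names = FALSE)
  if (length(one)) {
    tab <- table(factor(one, levels = codes))
    singles[] <- as.integer(tab)
  }
  mat <- matrix(0L, length(codes), length(codes),
                dimnames = list(codes, codes))
  for (a in assignments[sizes == 2L]) {
    i <- match(a[1L], codes); j <- match(a[2L], codes)
    mat[i, j] <- mat[i, j] + 1L
    mat[j, i] <- mat[j, i] + 1L
  }
  twoSL <- rowSums(mat)
  diag(mat) <- singles
  list(singles = singles, pairs = mat,
       twoSL = as.integer(twoSL) |> stats::setNames(codes),
       oneMinusTwoSL = singles - as.integer(twoSL))
}

#' Higher-order compartment combination table
#'
#' Tabulates the distinct compartment combinations of size `k` assigned to
#' motifs, with their repeat counts `R`, plus two per-compartment margins:
#' `N[c]`, the number of distinct combinations containing `c`, and
#' `NxR[c]`, the total number of motifs whose combination contains `c`.
#' Rows are sorted by `R` descending then lexicographically for
#' deterministic output.
#'
#' @param assignments Named list of assigned compartment-code vectors.
#' @param k Combination size (typically 3, 4 or 5).
#' @param codes Compartment codes defining margin order.
#' @return A list with `k`, `rows` (a `data.frame` with columns `combo`
#'   (comma-joined codes in vocabulary order) and `R`), `N` and `NxR`
#'   (named integers).
#' @export
comboTable <- function(assignments, k, codes) {
  sizes <- lengths(assignments)
  combos <- vapply(assignments[sizes == k],
                   function(a) paste(codes[sort(match(a, codes))],
                                     collapse = ","), "")
  Nc <- integer(length(codes)); names(Nc) <- codes
  NxR <- Nc
  if (length(combos)) {
    tab <- table(combos)
    rows <- data.frame(combo = names(tab), R = as.integer(tab),
                       stringsAsFactors = FALSE)
    rows <- rows[order(-rows$R, rows$combo), , drop = FALSE]
    rownames(rows) <- NULL
    for (i in seq_len(nrow(rows))) {
      members <- strsplit(rows$combo[i], ",")[[1L]]
      Nc[members] <- Nc[members] + 1L
      NxR[members] <- NxR[members] + rows$R[i]
    }
  } else {
    rows <- data.frame(combo = character(), R = integer(),
                       stringsAsFactors = FALSE)
  }
  list(k = k, rows = rows, N = Nc, NxR = NxR)
}

#' Assignment-size histogram across motifs
#'
#' Counts motifs by the number of compartments assigned to them (0 up to
#' `maxK`), the summary binned in the per-kind assignment tables.
#'
#' @param assignments Named list of assigned compartment-code vectors.
#' @param maxK Largest bin reported individually (default 6).
#' @return Named integer vector with names `"0"` .. `as.character(maxK)`.
#' @export
assignmentHistogram <- function(assignments, maxK = 6L) {
  sizes <- lengths(assignments)
  tab <- table(factor(pmin(sizes, maxK), levels = 0:maxK))
  stats::setNames(as.integer(tab), names(tab))
}
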