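# Shared fixture builders and independent oracles.

# Protein records from a named list: accession -> character vector of keywords.
makeRecords <- function(spec) {
  lapply(names(spec), function(a)
    new("ProteinRecord", accession = a, entryName = paste0(a, "_X"),
        keywords = spec[[a]], aliases = character()))
}

# Dataset straight from keyword spec.
makeDataset <- function(spec, vocab = compartmentVocabulary(),
                        single = FALSE) {
  ds <- buildLocalizationDataset(makeRecords(spec), vocab)
  if (single) restrictSingle(ds) else ds
}

makeMotif <- function(tp, fp, kind = "pattern", accession = "PS99999") {
  new("MotifRecord", accession = accession, name = "TEST_MOTIF",
      description = "test", kind = kind,
      consensus = if (kind == "pattern") "K-D-E-L." else "",
      tpAccessions = tp, fpAccessions = fp)
}

# A dataset with a known background: counts[c] proteins carry exactly
# compartment c (keywords looked up from the vocabulary).
backgroundDataset <- function(counts, vocab = compartmentVocabulary()) {
  kwOf <- setNames(vocabKeywords(vocab), vocabCodes(vocab))
  spec <- list()
  i <- 0L
  for (code in names(counts)) {
    for (j in seq_len(counts[[code]])) {
      i <- i + 1L
      spec[[sprintf("B%05d", i)]] <- unname(kwOf[[code]])
    }
  }
  makeDataset(spec, vocab)
}

# Exact upper-tail hypergeometric p-value by subset enumeration: fraction
# of the C(N, n) draws containing >= L of the K marked items. Exact
# integer arithmetic for small N.
bruteHyperPValue <- function(N, K, n, L) {
  if (n == 0L) return(if (L == 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  marked <- colSums(subsets <= K)   # items 1..K are the marked ones
  sum(marked >= L) / ncol(subsets)
}

# Independent Freeman-Halton enumerator: every non-negative 2xc table with
# the observed margins, probability via exact binomial-coefficient
# products; tail includes ties within relative 1e-7.
bruteFisher2xc <- function(tab, tieTol = 1e-7) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  cS <- colSums(tab); r1 <- sum(tab[1, ]); total <- sum(tab)
  grid <- expand.grid(lapply(cS, function(m) 0:m))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  probs <- Reduce(`*`, lapply(seq_along(cS), function(j)
    choose(cS[j], grid[[j]]))) / choose(total, r1)
  stopifnot(abs(sum(probs) - 1) < 1e-10)
  pObs <- prod(choose(cS, tab[1, ])) / choose(total, r1)
  sum(probs[probs <= pObs * (1 + tieTol)])
}

# All non-negative integer vectors of a given length with sum <= total.
compositionsUpTo <- function(cells, total) {
  if (cells == 1L) return(matrix(0:total, ncol = 1L))
  do.call(rbind, lapply(0:total, function(v)
    cbind(v, compositionsUpTo(cells - 1L, total - v))))
}

# All 2xc tables of non-negative integers with 1 <= total <= `total`.
allTables2xc <- function(ncol, total) {
  grid <- compositionsUpTo(2L * ncol, total)
  grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    matrix(as.integer(grid[i, ]), nrow = 2L, ncol = ncol))
}
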