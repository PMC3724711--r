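## Exact Fisher test for 2xc contingency tables (Freeman-Halton rule),
## comparing the compartment distribution of a motif's TP and FP sets.
##
## Conditional on both margins, the probability of a table is the
## multivariate hypergeometric mass; the two-sided exact p-value sums the
## probabilities of all fixed-margin tables no more probable than the
## observed one. Tables whose probability ties the observed one within a
## small relative tolerance are included in the tail (conservative).

#' Build the TP-vs-FP compartment contingency table for a motif
#'
#' Cell `(row, c)` holds the number of localized proteins of that set
#' carrying compartment `c`; a multi-compartment protein increments several
#' columns. All-zero columns are dropped. Motifs with fewer than two
#' localized sequences in either set, or whose sets collapse onto a single
#' shared compartment, are skipped as having insufficient data.
#'
#' @param motif A [MotifRecord-class].
#' @param ds A [LocalizationDataset-class].
#' @return A list with either `table` (a 2 x c integer matrix, rows
#'   `TP`/`FP`) and `skip = NULL`, or `table = NULL` and a `skip` reason
#'   string (`"single-sequence set"` or `"single shared compartment"`).
#' @export
buildContingencyTable <- function(motif, ds) {
  tp <- countSet(motif@tpAccessions, ds)
  fp <- countSet(motif@fpAccessions, ds)
  if (tp$n < 2L || fp$n < 2L)
    return(list(table = NULL, skip = "single-sequence set"))
  keep <- tp$L + fp$L > 0L
  if (sum(keep) <= 1L)
    return(list(table = NULL, skip = "single shared compartment"))
  tab <- rbind(TP = tp$L[keep], FP = fp$L[keep])
  storage.mode(tab) <- "integer"
  list(table = tab, skip = NULL)
}

.fisherPrep <- function(tab, tieTol) {
  stopifnot(is.matrix(tab), nrow(tab) == 2L, all(tab >= 0))
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (sum(tab) < 1L) stop("table must contain at least one observation")
  cS <- colSums(tab)
  r1 <- sum(tab[1L, ])
  total <- sum(tab)
  list(tab = tab, cS = cS, r1 = r1, total = total,
       logObs = sum(lchoose(cS, tab[1L, ])) - lchoose(total, r1),
       logCut = sum(lchoose(cS, tab[1L, ])) - lchoose(total, r1) +
         log1p(tieTol))
}

#' Exact Freeman-Halton p-value for a 2 x c table
#'
#' Enumerates every table with the observed row and column margins
#' (depth-first over row-1 column counts with margin-feasibility pruning,
#' vectorized across candidate prefixes) and sums the conditional
#' probabilities of tables whose probability is at most that of the
#' observed table, ties included within relative tolerance `tieTol`.
#' Probabilities are computed through log-binomial coefficients.
#'
#' For 2 x 2 tables this reproduces the classical two-sided Fisher exact
#' test. When the candidate-table count exceeds `budget` an error of class
#' `fisherBudgetError` is raised instructing the caller to use
#' [fisher2xcMC()].
#'
#' @param tab A 2 x c matrix of non-negative counts.
#' @param budget Maximum number of candidate tables to enumerate
#'   (default 5e6).
#' @param tieTol Relative tolerance for probability ties (default 1e-7).
#' @return The exact p-value, in `(0, 1]`.
#' @examples
#' fisher2xcExact(rbind(c(3, 0), c(0, 3)))   # 0.1
#' @export
fisher2xcExact <- function(tab, budget = 5e6, tieTol = 1e-7) {
  pr <- .fisherPrep(tab, tieTol)
  cS <- pr$cS; r1 <- pr$r1; cc <- length(cS)
  if (prod(pmin(cS, r1) + 1) > budget)
    stop(errorCondition(paste("candidate-table count exceeds enumeration",
                              "budget; use fisher2xcMC()"),
                        class = "fisherBudgetError"))
  if (cc == 1L) return(1)
  # vectorized DFS: states are partial row-1 prefixes
  rem <- r1
  lp <- 0
  for (j in seq_len(cc - 1L)) {
    capAfter <- sum(cS[(j + 1L):cc])
    lo <- pmax(0L, rem - capAfter)
    hi <- pmin(cS[j], rem)
    cnt <- hi - lo + 1L
    if (sum(cnt) > budget)
      stop(errorCondition("enumeration state count exceeds budget",
                          class = "fisherBudgetError"))
    idx <- rep(seq_along(rem), cnt)
    aj <- rep(lo, cnt) + sequence(cnt) - 1L
    lp <- lp[idx] + lchoose(cS[j], aj)
    rem <- rem[idx] - aj
  }
  lp <- lp + lchoose(cS[cc], rem) - lchoose(pr$total, r1)
  p <- exp(lp)
  totalMass <- sum(p)
  if (abs(totalMass - 1) > 1e-8)
    warning(sprintf("fixed-margin probabilities sum to %.12f", totalMass))
  min(1, sum(p[lp <= pr$logCut]))
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Monte Carlo Freeman-Halton p-value for a 2 x c table
#'
#' Estimates the exact p-value by sampling tables from the fixed-margin
#' null (Patefield's algorithm, via [stats::r2dtable()]) and computing the
#' fraction whose probability is at most the observed table's probability.
#' Deterministic for a fixed seed; the global RNG state is restored on
#' exit.
#'
#' @param tab A 2 x c matrix of non-negative counts.
#' @param reps Number of sampled tables (at least 1000; default 1e5).
#' @param seed Integer seed.
#' @param tieTol Relative tolerance for probability ties (default 1e-7).
#' @return A list with `p` (the estimate) and `se` (its binomial standard
#'   error).
#' @export
fisher2xcMC <- function(tab, reps = 1e5, seed = 1L, tieTol = 1e-7) {
  stopifnot(reps >= 1000)
  pr <- .fisherPrep(tab, tieTol)
  cS <- pr$cS; rS <- c(pr$r1, pr$total - pr$r1)
  hits <- 0
  .withSeed(seed, {
    done <- 0
    while (done < reps) {
      m <- min(50000L, reps - done)
      tabs <- stats::r2dtable(m, rS, cS)
      row1 <- matrix(vapply(tabs, function(x) x[1L, ], numeric(length(cS))),
                     ncol = length(cS), byrow = TRUE)
      lp <- rowSums(lchoose(matrix(cS, nrow = m, ncol = length(cS),
                                   byrow = TRUE), row1)) -
        lchoose(pr$total, pr$r1)
      hits <- hits + sum(lp <= pr$logCut)
      done <- done + m
    }
  })
  p <- hits / reps
  list(p = p, se = sqrt(p * (1 - p) / reps))
}

#' Test TP-vs-FP localization heterogeneity for one motif
#'
#' Builds the 2 x c compartment table and computes the exact
#' Freeman-Halton p-value, falling back to the Monte Carlo engine when the
#' enumeration budget is exceeded. The null hypothesis is that TP and FP
#' sequences share the same localization distribution; `p <= alpha` is
#' significant, meaning the two sets localize differently.
#'
#' @param motif A [MotifRecord-class]; should be `testable` per
#'   [classifyMotif()].
#' @param ds A [LocalizationDataset-class].
#' @param alpha Significance threshold (default 0.05).
#' @param budget Exact-enumeration budget (default 5e6 candidate tables).
#' @param mcReps Monte Carlo replicates for the fallback (default 1e6).
#' @param mcSeed Seed for the fallback (default 20120711).
#' @return A list with `p` (p-value or `NA` when skipped), `significant`,
#'   `method` (`"exact"`, `"mc"` or `NA`), and `skip` (reason or `NULL`).
#' @export
testMotifHeterogeneity <- function(motif, ds, alpha = 0.05, budget = 5e6,
                                   mcReps = 1e6, mcSeed = 20120711L) {
  bt <- buildContingencyTable(motif, ds)
  if (!is.null(bt$skip))
    return(list(p = NA_real_, significant = FALSE, method = NA_character_,
                skip = bt$skip))
  p <- tryCatch(
    list(value = fisher2xcExact(bt$table, budget = budget), method = "exact"),
    fisherBudgetError = function(e)
      list(value = fisher2xcMC(bt$table, reps = mcReps, seed = mcSeed)$p,
           method = "mc"))
  list(p = p$value, significant = p$value <= alpha, method = p$method,
       skip = NULL)
}
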