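## Deterministic synthetic-fixture generator: miniature Swiss-Prot and
## PROSITE flat files with planted localization and enrichment structure,
## plus a ground-truth ledger the tests reconcile against.

#' Configuration for the synthetic flat-file generator
#'
#' @slot nProteins Number of synthetic proteins.
#' @slot background Named numeric: per-compartment probability that a
#'   protein's primary localization is that compartment. Must sum to at
#'   most 1; the remainder is the fraction of unlocalized proteins.
#' @slot multiFraction Probability that a localized protein gains a second
#'   compartment drawn from the background (default 0.068, the
#'   multi-compartment fraction observed across keyword-annotated
#'   Swiss-Prot proteins).
#' @slot motifs A `data.frame` with one row per motif: `kind`
#'   (pattern/matrix), `tpSize`, `fpSize`, `tpTarget` (comma-joined target
#'   codes, or `""` for background sampling), `tpRho` (odds multiplier, at
#'   least 1, favouring target-compartment proteins when drawing the TP
#'   set), `fpTarget`, `fpRho` (same semantics for the FP set).
#' @slot decor A `data.frame` with columns `keyword`, `rate`: extra
#'   non-localization keywords attached independently per protein.
#' @slot seed Integer seed; identical seeds give byte-identical files.
#' @seealso [syntheticConfig()], [generateSynthetic()]
#' @export
setClass("SyntheticConfig",
  representation(nProteins = "integer", background = "numeric",
                 multiFraction = "numeric", motifs = "data.frame",
                 decor = "data.frame", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  b <- object@background
  if (is.null(names(b)) || any(!nzchar(names(b))))
    msgs <- c(msgs, "background must be a named numeric vector")
  if (any(b < 0) || any(b > 1) || sum(b) > 1 + 1e-12)
    msgs <- c(msgs, "background probabilities must lie in [0,1], sum <= 1")
  if (object@multiFraction < 0 || object@multiFraction > 1)
    msgs <- c(msgs, "multiFraction must be a probability")
  m <- object@motifs
  need <- c("kind", "tpSize", "fpSize", "tpTarget", "tpRho",
            "fpTarget", "fpRho")
  if (!all(need %in% names(m)))
    msgs <- c(msgs, paste("motifs needs columns:", paste(need, collapse = " ")))
  else {
    if (any(m$tpSize + m$fpSize > object@nProteins))
      msgs <- c(msgs, "tpSize + fpSize must not exceed nProteins")
    if (any(m$tpRho < 1) || any(m$fpRho < 1))
      msgs <- c(msgs, "enrichment odds multipliers must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Build a synthetic-generator configuration
#'
#' Defaults emulate a small keyword-annotated protein database: a
#' background over six abundant compartments totalling 0.68 of the pool
#' (the remainder unlocalized, giving roughly the 60% localization
#' coverage seen in curated data), a 6.8% multi-compartment fraction, and
#' a cohort of motifs alternating pattern/matrix whose TP sets favour a
#' designated compartment with odds multiplier `tpRho`.
#'
#' @param nProteins Number of proteins (default 3000).
#' @param background Named per-compartment primary-localization
#'   probabilities.
#' @param multiFraction Second-compartment probability (default 0.068).
#' @param nMotifs Number of motifs in the default cohort (default 50; the
#'   default spec cycles TP targets over the background compartments).
#' @param tpSize,fpSize Default set sizes (20 and 10).
#' @param tpRho Default TP enrichment odds multiplier (default 10).
#' @param fpRho Default FP multiplier (default 1: FP sets drawn from the
#'   background).
#' @param motifs Optional explicit motif `data.frame` overriding the
#'   default cohort.
#' @param decor Extra keyword decoration table.
#' @param seed Integer seed (default 1).
#' @return A [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nProteins = 3000L,
                            background = c(cyt = 0.18, Nuc = 0.15,
                                           Mem = 0.12, ext = 0.10,
                                           Mit = 0.08, chl = 0.05),
                            multiFraction = 0.068,
                            nMotifs = 50L, tpSize = 20L, fpSize = 10L,
                            tpRho = 10, fpRho = 1,
                            motifs = NULL,
                            decor = data.frame(
                              keyword = c("Reference proteome",
                                          "3D-structure", "Coiled coil",
                                          "Repeat"),
                              rate = c(0.9, 0.2, 0.1, 0.1),
                              stringsAsFactors = FALSE),
                            seed = 1L) {
  if (is.null(motifs)) {
    codes <- names(background)
    motifs <- data.frame(
      kind = rep(c("pattern", "matrix"), length.out = nMotifs),
      tpSize = as.integer(tpSize), fpSize = as.integer(fpSize),
      tpTarget = codes[(seq_len(nMotifs) - 1L) %% length(codes) + 1L],
      tpRho = tpRho, fpTarget = "", fpRho = fpRho,
      stringsAsFactors = FALSE)
  }
  new("SyntheticConfig", nProteins = as.integer(nProteins),
      background = background, multiFraction = multiFraction,
      motifs = motifs, decor = decor, seed = as.integer(seed))
}

.splitTargets <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, ",")[[1L]])
}

#' Generate synthetic Swiss-Prot and PROSITE flat files
#'
#' Samples a protein pool with the configured compartment background and
#' multi-compartment fraction, decorates it with non-localization
#' keywords, draws each motif's TP and FP accession sets without
#' replacement (target-compartment proteins weighted by the configured
#' odds multiplier; TP and FP of one motif are disjoint, but a protein may
#' serve different motifs in different roles), and renders both flat-file
#' dialects. Identical seeds give byte-identical output.
#'
#' @param config A [SyntheticConfig-class].
#' @param vocab Vocabulary used to translate compartment codes back into
#'   the keywords written to the KW lines (default the twelve-compartment
#'   vocabulary).
#' @return A list with `swissprot` and `prosite` (character vectors of
#'   flat-file lines) and `truth`, itself a list with `proteins` (a
#'   `data.frame`: `accession`, `codes` comma-joined, `keywords`
#'   comma-joined), `motifs` (the motif spec with accessions added), and
#'   `tpSets`/`fpSets` (named lists of accession vectors).
#' @export
generateSynthetic <- function(config, vocab = compartmentVocabulary()) {
  bg <- config@background
  codes <- names(bg)
  if (!all(codes %in% vocabCodes(vocab)))
    stop("background compartments must exist in the vocabulary")
  for (i in seq_len(nrow(config@motifs))) {
    for (tgt in c(.splitTargets(config@motifs$tpTarget[i]),
                  .splitTargets(config@motifs$fpTarget[i])))
      if (!tgt %in% codes || bg[[tgt]] == 0)
        stop(sprintf("motif %d targets compartment '%s' with zero background mass",
                     i, tgt))
  }
  kwOf <- stats::setNames(vocabKeywords(vocab), vocabCodes(vocab))
  .withSeed(config@seed, {
    n <- config@nProteins
    acc <- sprintf("P%05d", seq_len(n))
    entry <- sprintf("S%05d_SYNTH", seq_len(n))
    primary <- sample(c(codes, ".none"), n, replace = TRUE,
                      prob = c(bg, 1 - sum(bg)))
    protCodes <- lapply(seq_len(n), function(i) {
      if (primary[i] == ".none") return(character())
      cs <- primary[i]
      if (stats::runif(1) < config@multiFraction && length(codes) > 1L) {
        rest <- bg[codes != cs]
        cs <- c(cs, sample(names(rest), 1L, prob = rest))
      }
      cs
    })
    decorKw <- lapply(seq_len(n), function(i)
      config@decor$keyword[stats::runif(nrow(config@decor)) <
                             config@decor$rate])
    records <- lapply(seq_len(n), function(i)
      new("ProteinRecord", accession = acc[i], entryName = entry[i],
          keywords = c(unname(kwOf[protCodes[[i]]]), decorKw[[i]]),
          aliases = character()))
    hasTarget <- function(targets) {
      if (!length(targets)) return(rep(FALSE, n))
      vapply(protCodes, function(cs) any(cs %in% targets), TRUE)
    }
    nm <- nrow(config@motifs)
    motifAcc <- sprintf("PS%05d", seq_len(nm))
    tpSets <- vector("list", nm); fpSets <- vector("list", nm)
    motifs <- vector("list", nm)
    for (i in seq_len(nm)) {
      sp <- config@motifs[i, ]
      wTP <- ifelse(hasTarget(.splitTargets(sp$tpTarget)), sp$tpRho, 1)
      tp <- sample(acc, sp$tpSize, prob = wTP)
      rest <- setdiff(acc, tp)
      wFP <- ifelse(hasTarget(.splitTargets(sp$fpTarget)), sp$fpRho, 1)
      fp <- sample(rest, sp$fpSize, prob = wFP[match(rest, acc)])
      tpSets[[i]] <- sort(tp); fpSets[[i]] <- sort(fp)
      motifs[[i]] <- new("MotifRecord", accession = motifAcc[i],
                         name = sprintf("SYN_MOTIF_%d", i),
                         description = sprintf("Synthetic motif %d", i),
                         kind = sp$kind,
                         consensus = if (sp$kind == "pattern") "K-D-E-L." else "",
                         tpAccessions = tpSets[[i]],
                         fpAccessions = fpSets[[i]])
    }
    names(tpSets) <- motifAcc; names(fpSets) <- motifAcc
    truthMotifs <- cbind(accession = motifAcc, config@motifs,
                         stringsAsFactors = FALSE)
    list(
      swissprot = writeSwissProt(records),
      prosite = writeProsite(motifs,
                             entryNames = stats::setNames(entry, acc)),
      truth = list(
        proteins = data.frame(
          accession = acc,
          codes = vapply(protCodes, paste, "", collapse = ","),
          keywords = vapply(seq_len(n), function(i)
            paste(c(unname(kwOf[protCodes[[i]]]), decorKw[[i]]),
                  collapse = ","), ""),
          stringsAsFactors = FALSE),
        motifs = truthMotifs,
        tpSets = tpSets, fpSets = fpSets))
  })
}

#' Write a synthetic fixture to disk
#'
#' Renders a generated fixture as `swissprot.dat`, `prosite.dat`,
#' `truth_proteins.tsv` and `truth_motifs.tsv` under `dir`.
#'
#' @param synth Output of [generateSynthetic()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
writeSyntheticFiles <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("swissprot.dat", "prosite.dat",
                            "truth_proteins.tsv", "truth_motifs.tsv"))
  writeLines(synth$swissprot, paths[1L])
  writeLines(synth$prosite, paths[2L])
  utils::write.table(synth$truth$proteins, paths[3L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tm <- synth$truth$motifs
  tm$tp <- vapply(synth$truth$tpSets, paste, "", collapse = ",")
  tm$fp <- vapply(synth$truth$fpSets, paste, "", collapse = ",")
  utils::write.table(tm, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
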