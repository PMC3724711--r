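## Pipeline driver: parse inputs, run enrichment + heterogeneity for every
## motif, and emit the three output surfaces (protein mapping, per-motif
## tables, summary statistics) plus a machine-readable JSON mirror.

#' Round half away from zero
#'
#' Printed percentages use half-up rounding (0.5 always rounds away from
#' zero), matching conventional report formatting rather than banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Analyze a motif collection against a localization dataset
#'
#' For every motif: classify it, test TP and FP compartment enrichment,
#' derive the motif's compartment assignment from the enriched TP
#' compartments, and (for testable motifs) run the exact TP-vs-FP
#' heterogeneity test. This is the computational core shared by
#' [runPipeline()] and programmatic use.
#'
#' @param motifs List of [MotifRecord-class] objects.
#' @param ds A [LocalizationDataset-class].
#' @param alpha Significance threshold (default 0.05).
#' @param adjust Multiplicity correction across compartments (default
#'   `"none"`, matching raw per-test significance).
#' @param budget,mcReps,mcSeed Passed to [testMotifHeterogeneity()].
#' @return A list with `summary` (one row per motif: accession, name,
#'   kind, nTP/nFP totals and localized counts, category, `assigned`
#'   comma-joined codes, `fisherP`, `fisherSignificant`, `fisherMethod`,
#'   `fisherSkip`), `enrichment` (named list of per-motif `tp`/`fp`
#'   enrichment tables), and `assignments` (named list of assigned-code
#'   vectors, one per motif with at least one localized TP protein).
#' @export
analyzeMotifs <- function(motifs, ds, alpha = 0.05, adjust = "none",
                          budget = 5e6, mcReps = 1e6, mcSeed = 20120711L) {
  nMotif <- length(motifs)
  rows <- vector("list", nMotif)
  enrich <- vector("list", nMotif)
  assignments <- list()
  for (i in seq_len(nMotif)) {
    m <- motifs[[i]]
    tpC <- countSet(m@tpAccessions, ds)
    fpC <- countSet(m@fpAccessions, ds)
    category <- classifyMotif(m, ds)
    tpE <- if (tpC$n >= 1L) enrichSet(tpC, ds, alpha, adjust) else NULL
    fpE <- if (fpC$n >= 1L) enrichSet(fpC, ds, alpha, adjust) else NULL
    assigned <- if (!is.null(tpE)) tpE$code[tpE$enriched] else character()
    if (tpC$n >= 1L) assignments[[m@accession]] <- assigned
    het <- if (category == "testable")
      testMotifHeterogeneity(m, ds, alpha, budget, mcReps, mcSeed)
    else list(p = NA_real_, significant = FALSE, method = NA_character_,
              skip = paste("category:", category))
    rows[[i]] <- data.frame(
      accession = m@accession, name = m@name, kind = m@kind,
      nTP = tpC$nTotal, nTPLocalized = tpC$n,
      nFP = fpC$nTotal, nFPLocalized = fpC$n,
      category = category,
      assigned = paste(assigned, collapse = ","),
      fisherP = het$p, fisherSignificant = het$significant,
      fisherMethod = het$method,
      fisherSkip = if (is.null(het$skip)) NA_character_ else het$skip,
      stringsAsFactors = FALSE)
    enrich[[i]] <- list(tp = tpE, fp = fpE)
  }
  summary <- do.call(rbind, rows)
  names(enrich) <- summary$accession
  list(summary = summary, enrichment = enrich, assignments = assignments)
}

.coverageTable <- function(motifs, ds) {
  kinds <- vapply(motifs, function(m) m@kind, "")
  perKind <- function(keep) {
    tp <- unlist(lapply(motifs[keep], function(m) m@tpAccessions))
    fp <- unlist(lapply(motifs[keep], function(m) m@fpAccessions))
    locTP <- sum(tp %in% names(ds@assignments))
    locFP <- sum(fp %in% names(ds@assignments))
    c(motifs = sum(keep), tpTotal = length(tp), tpLocalized = locTP,
      fpTotal = length(fp), fpLocalized = locFP)
  }
  rows <- rbind(matrix = perKind(kinds == "matrix"),
                pattern = perKind(kinds == "pattern"),
                total = perKind(rep(TRUE, length(kinds))))
  out <- as.data.frame(rows)
  out$tpPercent <- ifelse(out$tpTotal > 0,
                          roundHalfUp(100 * out$tpLocalized / out$tpTotal), 0)
  out$fpPercent <- ifelse(out$fpTotal > 0,
                          roundHalfUp(100 * out$fpLocalized / out$fpTotal), 0)
  out
}

.formatMotifTable <- function(motif, enr, row, codes) {
  starify <- function(e) {
    if (is.null(e)) return(stats::setNames(rep("0", length(codes)), codes))
    v <- sprintf("%d%s", e$L, ifelse(e$enriched, "*", ""))
    stats::setNames(v, e$code)[codes]
  }
  fisherTxt <- if (!is.na(row$fisherP))
    sprintf("%.6g%s", row$fisherP, if (row$fisherSignificant) "\t*" else "")
  else sprintf("NA (%s)", row$fisherSkip)
  c(sprintf("AC   %s", motif@accession),
    sprintf("DE   %s", motif@description),
    sprintf("TYPE %s", motif@kind),
    if (nzchar(motif@consensus)) sprintf("CONS %s", motif@consensus),
    paste(c("SET", codes, "n_localized", "n_total"), collapse = "\t"),
    paste(c("TP", starify(enr$tp), row$nTPLocalized, row$nTP),
          collapse = "\t"),
    paste(c("FP", starify(enr$fp), row$nFPLocalized, row$nFP),
          collapse = "\t"),
    sprintf("CATEGORY\t%s", row$category),
    paste0("FISHER_P\t", fisherTxt),
    "//")
}

.statisticsReport <- function(motifs, ds, freqTable, res, pm, combos,
                              histogram, manifest, coverage) {
  cat0 <- table(factor(res$summary$category,
                       levels = c("empty_motif", "empty_tp", "empty_fp",
                                  "tp_eq_fp", "testable")))
  tested <- !is.na(res$summary$fisherP)
  sig <- sum(res$summary$fisherSignificant[tested])
  sizes <- lengths(res$assignments)
  lines <- c(
    "# Run manifest", manifest, "",
    "# Compartment frequencies (multiple-localization dataset)",
    sprintf("N_localized\t%d", ds@N),
    paste(c("code", "count", "percent"), collapse = "\t"),
    sprintf("%s\t%d\t%.2f", freqTable$code, freqTable$count,
            freqTable$percent),
    sprintf("Multiple\t%d\t%.2f", attr(freqTable, "multipleCount"),
            attr(freqTable, "multiplePercent")), "",
    "# Motif categories",
    sprintf("%s\t%d", names(cat0), as.integer(cat0)),
    sprintf("total\t%d", length(motifs)), "",
    "# Coverage by motif kind")
  cov <- coverage
  lines <- c(lines,
    paste(c("kind", colnames(cov)), collapse = "\t"),
    vapply(rownames(cov), function(r)
      paste(c(r, unlist(cov[r, ])), collapse = "\t"), ""), "",
    "# Assignment-size histogram (motifs with >= 1 localized TP protein)",
    paste(c("n_assigned", "count", "percent"), collapse = "\t"),
    sprintf("%s\t%d\t%.2f", names(histogram), histogram,
            if (sum(histogram) > 0) 100 * histogram / sum(histogram)
            else rep(0, length(histogram))), "",
    "# Fisher 2xc heterogeneity",
    sprintf("tested\t%d", sum(tested)),
    sprintf("significant\t%d", sig),
    sprintf("significant_percent\t%.2f",
            if (sum(tested) > 0) 100 * sig / sum(tested) else 0), "",
    "# Pair matrix (diagonal = single-compartment motifs)",
    paste(c("code", colnames(pm$pairs)), collapse = "\t"),
    vapply(rownames(pm$pairs), function(r)
      paste(c(r, pm$pairs[r, ]), collapse = "\t"), ""),
    paste(c("2SL", pm$twoSL), collapse = "\t"),
    paste(c("1SL-2SL", pm$oneMinusTwoSL), collapse = "\t"), "")
  for (co in combos) {
    lines <- c(lines,
      sprintf("# Combinations of %d compartments", co$k),
      paste(c("combo", "R"), collapse = "\t"),
      if (nrow(co$rows)) sprintf("%s\t%d", co$rows$combo, co$rows$R)
      else "(none)",
      paste(c("N", co$N), collapse = "\t"),
      paste(c("NxR", co$NxR), collapse = "\t"), "")
  }
  lines
}

#' Run the full motif-localization pipeline
#'
#' Parses a Swiss-Prot flat file and a PROSITE flat file, builds the
#' localization dataset (optionally restricted to single-localization
#' proteins), analyzes every motif of the requested kind, and writes three
#' output files: `<outPrefix>.mapping` (protein accession, TAB,
#' comma-separated compartment codes), `<outPrefix>.tables` (one blocked
#' report per motif with per-compartment TP/FP counts, enrichment
#' asterisks, category and Fisher p-value), and `<outPrefix>.statistics`
#' (compartment frequencies, category counts, coverage by kind,
#' assignment-size histogram, Fisher summary, pair matrix and combination
#' tables), plus `<outPrefix>.statistics.json`, a machine-readable mirror.
#'
#' @param swissprotPath Path to the Swiss-Prot flat file (plain or gzip).
#' @param prositePath Path to the PROSITE flat file (plain or gzip).
#' @param outPrefix Output path prefix.
#' @param kind Motif kind filter: `"all"`, `"pattern"` or `"matrix"`.
#' @param compartments `"twelve"` (default) or `"seven"`.
#' @param dataset `"multiple"` (default) or `"single"` (single-localization
#'   proteins only).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust Multiplicity correction across compartments (default
#'   `"none"`).
#' @param maxCombo Largest combination size tabulated (default 5).
#' @param budget,mcReps,mcSeed Heterogeneity-engine controls; see
#'   [testMotifHeterogeneity()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the [analyzeMotifs()] result augmented with
#'   `dataset`, `motifs` and the output paths.
#' @export
runPipeline <- function(swissprotPath, prositePath, outPrefix,
                        kind = c("all", "pattern", "matrix"),
                        compartments = c("twelve", "seven"),
                        dataset = c("multiple", "single"),
                        alpha = 0.05, adjust = "none", maxCombo = 5L,
                        budget = 5e6, mcReps = 1e6, mcSeed = 20120711L,
                        quiet = FALSE) {
  kind <- match.arg(kind)
  compartments <- match.arg(compartments)
  dataset <- match.arg(dataset)
  for (p in c(swissprotPath, prositePath))
    if (!file.exists(p)) stop("cannot read input file: ", p)
  say <- function(...) if (!quiet) message(sprintf(...))

  vocab <- compartmentVocabulary(compartments)
  say("parsing Swiss-Prot flat file: %s", swissprotPath)
  records <- readSwissProt(swissprotPath)
  say("parsed %d protein records", length(records))
  dsMulti <- buildLocalizationDataset(records, vocab)
  ds <- if (dataset == "single") restrictSingle(dsMulti) else dsMulti
  say("localization dataset (%s): N = %d", ds@mode, ds@N)

  say("parsing PROSITE flat file: %s", prositePath)
  motifs <- readProsite(prositePath, aliases = aliasIndex(records))
  if (kind != "all")
    motifs <- Filter(function(m) m@kind == kind, motifs)
  if (!length(motifs)) {
    message("no motifs remain after the kind filter; nothing to do")
    return(invisible(NULL))
  }
  say("analyzing %d motifs", length(motifs))
  res <- analyzeMotifs(motifs, ds, alpha, adjust, budget, mcReps, mcSeed)

  codes <- vocabCodes(vocab)
  pm <- pairMatrix(res$assignments, codes)
  combos <- lapply(3:maxCombo, function(k)
    comboTable(res$assignments, k, codes))
  histogram <- assignmentHistogram(res$assignments, maxK = length(codes))
  freqTable <- datasetFrequencies(dsMulti)
  coverage <- .coverageTable(motifs, ds)

  mappingPath <- paste0(outPrefix, ".mapping")
  tablesPath <- paste0(outPrefix, ".tables")
  statsPath <- paste0(outPrefix, ".statistics")
  jsonPath <- paste0(outPrefix, ".statistics.json")

  writeLocalizationMapping(ds, mappingPath)
  tableLines <- unlist(lapply(seq_along(motifs), function(i)
    .formatMotifTable(motifs[[i]], res$enrichment[[i]],
                      res$summary[i, ], codes)))
  writeLines(tableLines, tablesPath)

  manifest <- c(
    sprintf("package\tmotifCompartments %s",
            as.character(utils::packageVersion("motifCompartments"))),
    sprintf("swissprot\t%s\tmd5:%s", swissprotPath,
            unname(tools::md5sum(swissprotPath))),
    sprintf("prosite\t%s\tmd5:%s", prositePath,
            unname(tools::md5sum(prositePath))),
    sprintf("kind\t%s", kind),
    sprintf("compartments\t%s", compartments),
    sprintf("dataset\t%s", dataset),
    sprintf("alpha\t%g", alpha),
    sprintf("mc_seed\t%d", mcSeed))
  statLines <- .statisticsReport(motifs, ds, freqTable, res, pm, combos,
                                 histogram, manifest, coverage)
  writeLines(statLines, statsPath)

  cat0 <- table(factor(res$summary$category,
                       levels = c("empty_motif", "empty_tp", "empty_fp",
                                  "tp_eq_fp", "testable")))
  tested <- !is.na(res$summary$fisherP)
  jsonlite::write_json(list(
    nProteinsLocalized = ds@N,
    categories = as.list(stats::setNames(as.integer(cat0), names(cat0))),
    coverage = coverage,
    histogram = as.list(histogram),
    fisher = list(tested = sum(tested),
                  significant = sum(res$summary$fisherSignificant[tested])),
    multiplePercent = attr(freqTable, "multiplePercent"),
    pairSingles = as.list(pm$singles),
    pairTotal = sum(pm$pairs[upper.tri(pm$pairs)])),
    jsonPath, auto_unbox = TRUE, digits = NA)

  say("wrote %s, %s, %s", mappingPath, tablesPath, statsPath)
  invisible(c(res, list(dataset = ds, motifs = motifs,
                        paths = c(mapping = mappingPath, tables = tablesPath,
                                  statistics = statsPath, json = jsonPath))))
}
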