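test_that("Swiss-Prot records parse with keywords, aliases and wrapping", {
  txt <- c("ID   AAA_TEST                Reviewed;         100 AA.",
           "AC   P10000; Q00001; Q00002;",
           "KW   Nucleus; 3D-structure.",
           "//",
           "ID   BBB_TEST                Reviewed;         100 AA.",
           "AC   P20000;",
           "//",
           "ID   CCC_TEST                Reviewed;         100 AA.",
           "AC   P30000;",
           "KW   Cytoplasm; Nucleus; Reference proteome;",
           "KW   Alternative splicing {ECO:0000303}; Coiled coil.",
           "//")
  recs <- readSwissProt(text = txt)
  expect_length(recs, 3L)
  expect_identical(recs[[1]]@accession, "P10000")
  expect_identical(recs[[1]]@entryName, "AAA_TEST")
  expect_setequal(recs[[1]]@keywords, c("Nucleus", "3D-structure"))
  expect_setequal(recs[[1]]@aliases, c("Q00001", "Q00002"))
  expect_identical(recs[[2]]@keywords, character())
  # wrapped KW lines concatenate; evidence braces are dropped
  expect_setequal(recs[[3]]@keywords,
                  c("Cytoplasm", "Nucleus", "Reference proteome",
                    "Alternative splicing", "Coiled coil"))
  idx <- aliasIndex(recs)
  expect_identical(unname(idx[["Q00002"]]), "P10000")
  expect_identical(unname(idx[["P20000"]]), "P20000")
})

test_that("a record without an AC line is a parse error with its offset", {
  txt <- c("ID   XXX_TEST   Reviewed;   10 AA.", "KW   Nucleus.", "//")
  expect_error(readSwissProt(text = txt), "line 3.*no AC|no AC")
})

test_that("writer and parser round-trip protein records", {
  spec <- list(P00001 = c("Nucleus", "3D-structure"),
               P00002 = character(),
               P00003 = c("Cytoplasm", "Chloroplast", "Reference proteome",
                          "Alternative splicing", "Coiled coil", "Repeat",
                          "Transmembrane", "Membrane", "Cell membrane"))
  recs <- makeRecords(spec)
  back <- readSwissProt(text = writeSwissProt(recs))
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]@accession, recs[[i]]@accession)
    expect_setequal(back[[i]]@keywords, recs[[i]]@keywords)
  }
})

test_that("dataset construction counts the localization-annotated universe", {
  spec <- c(setNames(rep(list("Nucleus"), 4), paste0("N", 1:4)),
            setNames(rep(list(c("Cytoplasm", "Nucleus")), 2),
                     paste0("C", 1:2)),
            setNames(rep(list("3D-structure"), 4), paste0("X", 1:4)))
  ds <- makeDataset(spec)
  expect_identical(datasetN(ds), 6L)
  expect_identical(unname(datasetK(ds)[["Nuc"]]), 6L)
  expect_identical(unname(datasetK(ds)[["cyt"]]), 2L)
  # K is consistent with assignments
  for (code in vocabCodes(compartmentVocabulary())) {
    expect_identical(
      datasetK(ds)[[code]],
      sum(vapply(datasetAssignments(ds), function(a) code %in% a, TRUE)))
  }
  empty <- makeDataset(list())
  expect_identical(datasetN(empty), 0L)
})

test_that("single-localization restriction keeps a sub-map and recounts", {
  spec <- c(setNames(rep(list("Nucleus"), 4), paste0("N", 1:4)),
            setNames(rep(list(c("Cytoplasm", "Nucleus")), 2),
                     paste0("C", 1:2)))
  ds <- makeDataset(spec)
  single <- restrictSingle(ds)
  expect_identical(single@mode, "single_only")
  expect_identical(datasetN(single), 4L)
  expect_identical(unname(datasetK(single)[["Nuc"]]), 4L)
  expect_identical(unname(datasetK(single)[["cyt"]]), 0L)
  expect_true(all(names(datasetAssignments(single)) %in%
                    names(datasetAssignments(ds))))
  # all-single dataset is unchanged
  allSingle <- makeDataset(setNames(rep(list("Nucleus"), 3),
                                    paste0("S", 1:3)))
  expect_identical(datasetAssignments(restrictSingle(allSingle)),
                   datasetAssignments(allSingle))
})

test_that("frequency summary reports multi-compartment counts", {
  spec <- c(setNames(rep(list("Nucleus"), 4), paste0("N", 1:4)),
            setNames(rep(list(c("Cytoplasm", "Nucleus")), 2),
                     paste0("C", 1:2)))
  ds <- makeDataset(spec)
  freq <- datasetFrequencies(ds)
  expect_identical(attr(freq, "multipleCount"), 2L)
  expect_equal(attr(freq, "multiplePercent"), 100 * 2 / 6, tolerance = 1e-12)
  # sum over compartments of proteins whose ONLY compartment is c equals
  # N minus the multi-compartment count
  only <- vapply(vocabCodes(compartmentVocabulary()), function(code)
    sum(vapply(datasetAssignments(ds),
               function(a) identical(a, code), TRUE)), 0L)
  expect_identical(sum(only), datasetN(ds) - attr(freq, "multipleCount"))
})

test_that("mapping TSV lists accessions with comma-joined codes", {
  ds <- makeDataset(list(A1 = c("Cytoplasm", "Nucleus"), A2 = "Vacuole"))
  path <- tempfile()
  writeLocalizationMapping(ds, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  parts <- strsplit(lines, "\t")
  expect_setequal(vapply(parts, `[[`, "", 1L), c("A1", "A2"))
  codes <- setNames(vapply(parts, `[[`, "", 2L),
                    vapply(parts, `[[`, "", 1L))
  expect_setequal(strsplit(codes[["A1"]], ",")[[1]], c("cyt", "Nuc"))
  expect_identical(codes[["A2"]], "Vac")
})
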