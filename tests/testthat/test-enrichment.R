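test_that("hypergeometric pmf matches closed-form and boundary cases", {
  # C(5,3) C(45,7) / C(50,10), frozen from exact binomial products
  expect_equal(hypergeomPMF(50, 5, 10, 3), 0.04417678264645358,
               tolerance = 1e-14)
  expect_identical(hypergeomPMF(10, 10, 3, 3), 1)
  expect_identical(hypergeomPMF(10, 0, 3, 0), 1)
  expect_identical(hypergeomPMF(10, 2, 5, 4), 0)   # out of support
  expect_error(hypergeomPMF(10, 11, 3, 1), "K <= N")
  expect_error(hypergeomPMF(-1, 0, 0, 0), "K <= N")
  # normalization over the support, random parameter draws
  set.seed(7)
  for (i in 1:30) {
    N <- sample(1:80, 1L); K <- sample(0:N, 1L); n <- sample(0:N, 1L)
    expect_equal(sum(hypergeomPMF(N, K, n, 0:n)), 1, tolerance = 1e-12)
  }
})

test_that("upper-tail p-value sums the pmf and respects its bounds", {
  # sum over k = 3..5 of the pmf above, frozen from exact products
  expect_equal(hypergeomPValue(50, 5, 10, 3), 0.0482603031962091,
               tolerance = 1e-14)
  expect_identical(hypergeomPValue(50, 5, 10, 0), 1)
  expect_identical(hypergeomPValue(50, 5, 10, 6), 0)  # L > min(K, n)
  expect_identical(hypergeomPValue(10, 9, 5, 4), 1)   # L at support floor
  expect_error(hypergeomPValue(10, 5, 3, 4), "L <= n")
})

test_that("p-value is non-increasing in L and matches subset enumeration", {
  set.seed(13)
  for (i in 1:20) {
    N <- sample(4:12, 1L); K <- sample(0:N, 1L); n <- sample(1:N, 1L)
    pv <- vapply(0:n, function(L) hypergeomPValue(N, K, n, L), 0)
    expect_true(all(diff(pv) <= 1e-14))
    for (L in 0:min(K, n))
      expect_equal(pv[L + 1L], bruteHyperPValue(N, K, n, L),
                   tolerance = 1e-12)
  }
})

test_that("set counting handles multi-compartment and absent proteins", {
  ds <- makeDataset(list(A1 = "Nucleus", A2 = "Nucleus", A3 = "Nucleus",
                         A4 = c("Nucleus", "Cytoplasm"), A5 = "Vacuole"))
  counts <- countSet(c("A1", "A2", "A3", "A4", "ZZZ"), ds)
  expect_identical(counts$n, 4L)
  expect_identical(unname(counts$L[["Nuc"]]), 4L)
  expect_identical(unname(counts$L[["cyt"]]), 1L)
  expect_identical(counts$nTotal, 5L)
  empty <- countSet(character(), ds)
  expect_identical(empty$n, 0L)
  expect_true(all(empty$L == 0L))
  expect_error(enrichSet(empty, ds), "empty set")
})

test_that("enrichment requires both significance and excess frequency", {
  # background: 200 of 1000 proteins nuclear; a 10-protein set entirely
  # nuclear is overwhelmingly enriched
  ds <- backgroundDataset(c(Nuc = 200L, cyt = 800L))
  tp <- names(datasetAssignments(ds))[
    vapply(datasetAssignments(ds), function(a) "Nuc" %in% a, TRUE)][1:10]
  enr <- enrichSet(countSet(tp, ds), ds)
  nucRow <- enr[enr$code == "Nuc", ]
  expect_true(nucRow$enriched)
  expect_lt(nucRow$pValue, 1e-6)
  expect_false(any(enr$enriched[enr$code != "Nuc"]))
  expect_true(all(enr$pValue[enr$L == 0L] == 1))
  # frequency exactly at background: never enriched, whatever the p-value
  ds2 <- backgroundDataset(c(Nuc = 2L, cyt = 8L))
  mixed <- c(names(datasetAssignments(ds2))[
    vapply(datasetAssignments(ds2), function(a) "Nuc" %in% a, TRUE)][1],
    names(datasetAssignments(ds2))[
      vapply(datasetAssignments(ds2), function(a) "cyt" %in% a, TRUE)][1:4])
  enr2 <- enrichSet(countSet(mixed, ds2), ds2)
  row2 <- enr2[enr2$code == "Nuc", ]
  expect_identical(row2$L, 1L)         # L/n = 1/5 = K/N = 2/10
  expect_false(row2$enriched)
})

test_that("motif categories partition all TP/FP localization situations", {
  ds <- makeDataset(list(N1 = "Nucleus", N2 = "Nucleus", N3 = "Nucleus",
                         M1 = "Cell membrane", M2 = "Cell membrane"))
  expect_identical(classifyMotif(makeMotif("X1", "X2"), ds), "empty_motif")
  expect_identical(classifyMotif(makeMotif("X1", "M1"), ds), "empty_tp")
  expect_identical(classifyMotif(makeMotif("N1", "X1"), ds), "empty_fp")
  expect_identical(classifyMotif(makeMotif(c("N1", "N2"), "N3"), ds),
                   "tp_eq_fp")
  expect_identical(classifyMotif(makeMotif(c("N1", "N2"), c("M1", "M2")),
                                 ds), "testable")
  # exhaustive over generated motifs: exactly one category each
  cats <- c("empty_motif", "empty_tp", "empty_fp", "tp_eq_fp", "testable")
  set.seed(3)
  pool <- c("N1", "N2", "N3", "M1", "M2", "X1", "X2")
  for (i in 1:30) {
    tp <- sample(pool, sample(0:4, 1L))
    fp <- sample(setdiff(pool, tp), sample(0:3, 1L))
    expect_true(classifyMotif(makeMotif(tp, fp), ds) %in% cats)
  }
})

test_that("motif assignment recovers strongly enriched compartments", {
  ds <- backgroundDataset(c(Nuc = 30L, cyt = 100L, Mit = 30L, chl = 140L))
  byCode <- function(code) names(datasetAssignments(ds))[
    vapply(datasetAssignments(ds), function(a) code %in% a, TRUE)]
  m <- makeMotif(c(byCode("Nuc")[1:12], byCode("Mit")[1:12]),
                 byCode("chl")[1:5])
  assigned <- assignMotifLocalizations(m, ds)
  expect_setequal(assigned, c("Nuc", "Mit"))
})
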