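# Readers/writers: SMILES, FASTA, interactions, kernel matrices, hierarchy.

test_that("SMILES parsing recovers hand-checkable graphs", {
  g <- parseSmiles("C", "m1")
  expect_equal(g@atoms, "C")
  expect_equal(nrow(g@bonds), 0L)

  g <- parseSmiles("CC", "m2")
  expect_equal(g@atoms, c("C", "C"))
  expect_equal(g@bonds$order, "1")

  g <- parseSmiles("c1ccccc1", "m3")
  expect_equal(g@atoms, rep("c", 6))
  expect_equal(nrow(g@bonds), 6L)
  expect_true(all(g@bonds$order == "ar"))

  g <- parseSmiles("CC(=O)O", "m4")
  expect_equal(g@atoms, c("C", "C", "O", "O"))
  expect_setequal(g@bonds$order, c("1", "2"))

  # explicit single bond between aromatic atoms stays single (biphenyl bond)
  g <- parseSmiles("c1ccccc1-c1ccccc1", "m5")
  expect_equal(sum(g@bonds$order == "1"), 1L)
  expect_equal(sum(g@bonds$order == "ar"), 12L)
})

test_that("SMILES file reading reports per-line failures and duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("m1\tCC", "m2\tC(Q)"), f)
  expect_error(readSmilesFile(f), "line 2")
  writeLines(c("m1\tCC", "m1\tCCC"), f)
  expect_error(readSmilesFile(f), "duplicate")
  writeLines(c("m1\tCC", "m2\tc1ccccc1"), f)
  mols <- readSmilesFile(f)
  expect_named(mols, c("m1", "m2"))
})

test_that("SMILES round-trips preserve the labeled graph", {
  for (s in 1:25) {
    g <- randomMoleculeGraph(paste0("g", s), sample(2:9, 1), seed = s)
    g2 <- parseSmiles(writeSmiles(g), g@moleculeId)
    expect_equal(sort(g2@atoms), sort(g@atoms))
    expect_equal(nrow(g2@bonds), nrow(g@bonds))
    # isomorphism-invariant fingerprint: path-count profiles agree
    expect_equal(oraclePathCounts(g2, 4)[order(names(oraclePathCounts(g2, 4)))],
                 oraclePathCounts(g, 4)[order(names(oraclePathCounts(g, 4)))])
  }
})

test_that("FASTA reading takes ids up to whitespace and upper-cases", {
  f <- withr::local_tempfile()
  writeLines(c(">p1 some description", "ac", "de"), f)
  prots <- readFastaProteins(f)
  expect_equal(names(prots), "p1")
  expect_equal(as.character(prots[["p1"]]), "ACDE")

  writeLines(c(">p1", "", ">p2", "AA"), f)
  expect_error(readFastaProteins(f), "empty sequence.*p1")
  writeLines(c(">p1", "AC", ">p1", "DE"), f)
  expect_error(readFastaProteins(f), "duplicate")
  writeLines(c(">p1", "ACXZ"), f)
  expect_error(readFastaProteins(f), "non amino-acid")
})

test_that("interaction reading applies the unlabeled-as-negative convention", {
  ds0 <- workedExampleSet()
  f <- withr::local_tempfile()
  writeLines(c("pA\tm1\t1", "pB\tm2\t1", "pC\tm3"), f)
  ds <- readInteractions(f, datasetProteins(ds0), datasetMolecules(ds0))
  expect_equal(nrow(positivePairs(ds)), 3L)   # absent label defaults to 1
  expect_equal(nrow(explicitNegatives(ds)), 0L)

  writeLines(c("pA\tm1\t1", "pB\tm2\t-1", "pC\tm3\t0"), f)
  ds <- readInteractions(f, datasetProteins(ds0), datasetMolecules(ds0))
  expect_equal(nrow(positivePairs(ds)), 1L)
  expect_equal(nrow(explicitNegatives(ds)), 2L)

  writeLines("p99\tm1\t1", f)
  expect_error(readInteractions(f, datasetProteins(ds0),
                                datasetMolecules(ds0)), "unknown protein p99")
  writeLines(c("pA\tm1\t1", "pA\tm1\t-1"), f)
  expect_error(readInteractions(f, datasetProteins(ds0),
                                datasetMolecules(ds0)), "conflicting")
})

test_that("kernel matrix TSV round-trips exactly and validates symmetry", {
  ids <- c("a", "b")
  K <- KernelMatrix(diag(2), ids)
  f <- withr::local_tempfile()
  writeKernelMatrix(K, f)
  K2 <- readKernelMatrix(f)
  expect_identical(kernelIds(K2), ids)
  expect_lt(max(abs(kernelValues(K2) - kernelValues(K))), 1e-12)

  # randomized round trip including flags
  K3 <- centerNormalize(randomKernel(letters[1:6], 5, normalized = FALSE))
  writeKernelMatrix(K3, f)
  K4 <- readKernelMatrix(f)
  expect_lt(max(abs(kernelValues(K4) - kernelValues(K3))), 1e-12)
  expect_true(isCentered(K4))
  expect_true(isNormalized(K4))

  writeLines(c("id\ta\tb", "a\t1\t0.3", "b\t0.4\t1"), f)
  expect_error(readKernelMatrix(f), "asymmetric")
  writeLines(c("id\ta\tb", "b\t1\t0", "a\t0\t1"), f)
  expect_error(readKernelMatrix(f), "row ids")
})

test_that("hierarchy paths build a forest with path-prefix node identity", {
  f <- withr::local_tempfile()
  writeLines("p1\tGPCR/ClassA/Amine", f)
  h <- readHierarchy(f)
  expect_equal(length(hierarchyPath <- KronDTI:::hierarchyPath(h, "p1")), 3L)

  writeLines(c("p1\tA/B", "p2\tA/C"), f)
  h <- readHierarchy(f)
  expect_equal(intersect(KronDTI:::hierarchyPath(h, "p1"),
                         KronDTI:::hierarchyPath(h, "p2")), "A")

  writeLines(c("p1\tA/B", "p1\tA/C"), f)
  expect_error(readHierarchy(f), "conflicting")

  # round trip
  writeLines(c("p1\tA/B", "p2\tA/C", "p3\tD"), f)
  h <- readHierarchy(f)
  f2 <- withr::local_tempfile()
  writeHierarchy(h, f2)
  h2 <- readHierarchy(f2)
  expect_identical(h2@leafOf, h@leafOf)
  expect_setequal(h2@nodes, h@nodes)
})

test_that("InteractionDataset validity rejects corrupted inputs", {
  ds <- makeTinyDataset()
  expect_error(InteractionDataset(
    datasetProteins(ds), datasetMolecules(ds),
    positives = data.frame(protein_id = "P1", molecule_id = "NOPE")),
    "unknown molecule")
  expect_error(InteractionDataset(
    datasetProteins(ds), datasetMolecules(ds),
    positives = data.frame(protein_id = "P1", molecule_id = "M1"),
    explicitNegatives = data.frame(protein_id = "P1", molecule_id = "M1")),
    "overlap")
  bad <- Biostrings::AAStringSet(c(P1 = "ACDE"))
  names(bad) <- NULL
  expect_error(InteractionDataset(bad, datasetMolecules(ds)),
               "uniquely named")
})

test_that("interaction TSV round-trips positives and explicit negatives", {
  ds <- workedExampleSet()
  f <- withr::local_tempfile()
  writeInteractions(ds, f)
  ds2 <- readInteractions(f, datasetProteins(ds), datasetMolecules(ds))
  ord <- function(df) df[order(df$protein_id, df$molecule_id), ]
  expect_equal(ord(positivePairs(ds2)), ord(positivePairs(ds)),
               ignore_attr = TRUE)
  expect_equal(ord(explicitNegatives(ds2)), ord(explicitNegatives(ds)),
               ignore_attr = TRUE)
})
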