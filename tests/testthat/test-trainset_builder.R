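# Per-query training-set assembly: intra/extra-task selection, negative
# sampling, theta filters, WNN profiles.

tinyDs <- makeTinyDataset()
tinyK <- tinyKernels(tinyDs)

test_that("intra-task pairs are the union sharing either entity, sans query", {
  # P1 has ligands M1, M2; M1 has targets P1, P2
  got <- intraTaskPairs("P1", "M1", tinyDs)
  expect_equal(nrow(got), 2L)  # (P1,M2) and (P2,M1)
  expect_false(any(got$protein_id == "P1" & got$molecule_id == "M1"))
  # double-orphan query: empty
  expect_equal(nrow(intraTaskPairs("P6", "M6", tinyDs)), 0L)
  # the query pair itself is never returned even though it is positive
  got2 <- intraTaskPairs("P2", "M2", tinyDs)
  expect_false(any(got2$protein_id == "P2" & got2$molecule_id == "M2"))
})

test_that("intra-task negative sampling sizes, excludes and reproduces", {
  n1 <- suppressWarnings(
    sampleIntraNegatives("P1", "M1", tinyDs, nPlus = 3, ratio = 1, seed = 9))
  expect_equal(nrow(n1), 3L)
  expect_true(all(n1$molecule_id == "M1"))
  expect_false(any(.rowSums <- paste(n1$protein_id, n1$molecule_id) %in%
                     paste(positivePairs(tinyDs)$protein_id,
                           positivePairs(tinyDs)$molecule_id)))
  n2 <- suppressWarnings(
    sampleIntraNegatives("P1", "M1", tinyDs, nPlus = 3, ratio = 1, seed = 9))
  expect_identical(n1, n2)
  expect_warning(
    sampleIntraNegatives("P1", "M1", tinyDs, nPlus = 3, ratio = 10,
                         seed = 9), "smaller than requested")
  nb <- suppressWarnings(
    sampleIntraNegatives("P1", "M1", tinyDs, nPlus = 2, ratio = 2, seed = 9,
                         bothAxes = TRUE))
  expect_true(any(nb$protein_id == "P1") || all(nb$molecule_id == "M1"))
})

test_that("pair similarity is the kernel product and ranks like a full sort", {
  Kp <- tinyK$Kp; Km <- tinyK$Km
  v <- pairSimilarity("P2", "M2", "P1", "M1", Kp, Km)
  expect_equal(v, kernelValue(Kp, "P2", "P1") * kernelValue(Km, "M2", "M1"))
  cand <- expand.grid(protein_id = paste0("P", 2:6),
                      molecule_id = paste0("M", 2:6),
                      stringsAsFactors = FALSE)[1:10, ]
  sims <- pairSimilarity(cand$protein_id, cand$molecule_id, "P1", "M1",
                         Kp, Km)
  ranked <- KronDTI:::.rankBySimilarity(cand, sims)
  oracle <- cand[order(-sims, cand$protein_id, cand$molecule_id), ]
  expect_equal(ranked, oracle, ignore_attr = TRUE)
})

test_that("extra-task selection takes brute-force top-k, never shared ids", {
  Kp <- tinyK$Kp; Km <- tinyK$Km
  ex <- suppressWarnings(
    selectExtraTask("P1", "M1", tinyDs, Kp, Km, "nn_mt", nExtraPos = 2,
                    extraNegRatio = 1, seed = 4))
  expect_true(all(ex$positives$protein_id != "P1"))
  expect_true(all(ex$positives$molecule_id != "M1"))
  pos <- positivePairs(tinyDs)
  extra <- pos[pos$protein_id != "P1" & pos$molecule_id != "M1", ]
  sims <- pairSimilarity(extra$protein_id, extra$molecule_id, "P1", "M1",
                         Kp, Km)
  topOracle <- head(extra[order(-sims, extra$protein_id,
                                extra$molecule_id), ], 2)
  expect_equal(ex$positives, topOracle, ignore_attr = TRUE)
  expect_equal(nrow(ex$negatives), 2L)
  # rn mode is deterministic under a fixed seed
  r1 <- suppressWarnings(selectExtraTask("P1", "M1", tinyDs, Kp, Km, "rn_mt",
                                         2, 1, seed = 5))
  r2 <- suppressWarnings(selectExtraTask("P1", "M1", tinyDs, Kp, Km, "rn_mt",
                                         2, 1, seed = 5))
  expect_identical(r1, r2)
})

test_that("theta percentile filter keeps all at 100, none at 0", {
  Kp <- tinyK$Kp; Km <- tinyK$Km
  pairs <- positivePairs(tinyDs)
  expect_equal(applyThetaFilter(pairs, "P1", "M1", Kp, Km, 100), pairs)
  strangers <- pairs[pairs$protein_id != "P1" & pairs$molecule_id != "M1", ]
  expect_equal(nrow(applyThetaFilter(strangers, "P1", "M1", Kp, Km, 0)), 0L)
  # mixed fixture against an explicit percentile-and-filter oracle
  theta <- 50
  thr <- thetaThresholds(Kp, Km, theta)
  offp <- kernelValues(Kp)[row(kernelValues(Kp)) != col(kernelValues(Kp))]
  expect_equal(thr$protein, unname(quantile(offp, 0.5)))
  got <- applyThetaFilter(strangers, "P1", "M1", Kp, Km, theta)
  keep <- kernelValue(Kp, strangers$protein_id,
                      rep("P1", nrow(strangers))) < thr$protein &
    kernelValue(Km, strangers$molecule_id,
                rep("M1", nrow(strangers))) < thr$molecule
  expect_equal(got, strangers[keep, ], ignore_attr = TRUE)
})

test_that("WNN profiles follow the rank-decay rule and clip at 1", {
  prots <- Biostrings::AAStringSet(c(p1 = "ACDEFGHIKL", p2 = "ACDEFGHIKV"))
  mols <- list(a = parseSmiles("CC", "a"), b = parseSmiles("CCC", "b"),
               o = parseSmiles("CCO", "o"))
  ids <- c("a", "b", "o")
  vm <- matrix(c(1, 0.9, 0.5,
                 0.9, 1, 0.2,
                 0.5, 0.2, 1), 3, dimnames = list(ids, ids))
  Km <- KernelMatrix(vm, ids, normalized = TRUE)
  ds <- InteractionDataset(prots, mols, positives = data.frame(
    protein_id = c("p1", "p2"), molecule_id = c("b", "o")))
  # single relevant neighbor keeps its binary profile (T^0 = 1)
  dsOne <- InteractionDataset(prots, mols, positives = data.frame(
    protein_id = "p1", molecule_id = "b"))
  expect_equal(wnnProfile("a", "molecule", dsOne, Km, T = 0.5),
               c(p1 = 1, p2 = 0))
  # neighbors ranked 0.9 then 0.5: profile = 1 * [1,0] + 0.5 * [0,1]
  expect_equal(wnnProfile("a", "molecule", ds, Km, T = 0.5),
               c(p1 = 1, p2 = 0.5))
  # clipping: profiles never exceed 1
  ds2 <- InteractionDataset(prots, mols, positives = data.frame(
    protein_id = c("p1", "p1"), molecule_id = c("b", "o")))
  expect_true(all(wnnProfile("a", "molecule", ds2, Km, T = 0.9) <= 1))
  dsOrph <- InteractionDataset(prots, mols, positives = data.frame(
    protein_id = "p1", molecule_id = "a"))
  expect_error(wnnProfile("a", "molecule", dsOrph, Km, T = 0.5),
               "orphan")
})

test_that("buildTrainSet composes per mode with exact pair counts", {
  # fixture with n+ = 3 and a large negative pool so 3 + 30 is achievable
  synth <- generateSyntheticDataset(
    syntheticSpec(nProteinClusters = 5, nMoleculeClusters = 5,
                  entitiesPerCluster = 9, pIn = 0.35, pOut = 0.01,
                  seed = 23))
  ds <- synth$dataset
  ks <- list(Kp = proteinKernelMatrix(datasetProteins(ds), "sw",
                                      center = FALSE),
             Km = moleculeKernelMatrix(datasetMolecules(ds), "tanimoto",
                                       d = 4, center = FALSE))
  pos <- positivePairs(ds)
  nplus <- vapply(seq_len(nrow(pos)), function(i)
    nrow(intraTaskPairs(pos$protein_id[i], pos$molecule_id[i], ds)), 0L)
  q <- pos[which(nplus == 3)[1], ]
  cfgI <- trainConfig("mt_intra", negPosRatio = 10, seed = 2)
  tsI <- buildTrainSet(q$protein_id, q$molecule_id, ds, ks$Kp, ks$Km, cfgI)
  expect_equal(nrow(tsI), 33L)                    # 3 + 30
  expect_equal(sum(tsI$y == 1), 3L)
  cfgN <- trainConfig("nn_mt", negPosRatio = 10, nExtraPos = 5,
                      extraNegRatio = 1, seed = 2)
  tsN <- buildTrainSet(q$protein_id, q$molecule_id, ds, ks$Kp, ks$Km, cfgN)
  expect_equal(nrow(tsN), 43L)                    # 33 + 5 + 5
  expect_equal(table(tsN$origin)[["extra+"]], 5L)

  # NN-MT with ne+ = 0 reduces exactly to MT-intra
  cfg0 <- trainConfig("nn_mt", negPosRatio = 10, nExtraPos = 0, seed = 2)
  ts0 <- buildTrainSet(q$protein_id, q$molecule_id, ds, ks$Kp, ks$Km, cfg0)
  key <- function(df) sort(paste(df$protein_id, df$molecule_id, df$y))
  expect_identical(key(ts0), key(tsI))
})

test_that("double-orphan queries fail without WNN and train with it", {
  ds <- makeTinyDataset()
  ks <- tinyKernels(ds)
  # make P6/M6 truly double-orphan: drop their positives
  pos <- positivePairs(ds)
  ds@positives <- pos[pos$protein_id != "P6" & pos$molecule_id != "M6", ]
  cfg <- trainConfig("mt_intra", seed = 3)
  expect_error(buildTrainSet("P6", "M6", ds, ks$Kp, ks$Km, cfg),
               "untrainable")
  cfgW <- trainConfig("mt_intra", wnn = TRUE, wnnThreshold = 0.5,
                      wnnDecay = 0.8, seed = 3)
  tsW <- suppressWarnings(
    buildTrainSet("P6", "M6", ds, ks$Kp, ks$Km, cfgW))
  expect_gt(nrow(tsW), 0)
  expect_true("wnn+" %in% tsW$origin)
})

test_that("the query pair never leaks into its training set (fuzz)", {
  synth <- generateSyntheticDataset(
    syntheticSpec(nProteinClusters = 3, nMoleculeClusters = 3,
                  entitiesPerCluster = 5, pIn = 0.6, pOut = 0.05, seed = 31))
  ds <- synth$dataset
  Kp <- proteinKernelMatrix(datasetProteins(ds), "sw", center = FALSE)
  Km <- moleculeKernelMatrix(datasetMolecules(ds), "tanimoto", d = 4,
                             center = FALSE)
  pid <- proteinIds(ds); mid <- moleculeIds(ds)
  withr::with_seed(77, {
    for (rep in 1:200) {
      p <- sample(pid, 1); m <- sample(mid, 1)
      cfg <- trainConfig(sample(c("mt_intra", "nn_mt", "rn_mt"), 1),
                         nExtraPos = sample(0:5, 1),
                         theta = sample(c(NA, 50, 100), 1),
                         wnn = runif(1) < 0.3, seed = rep)
      ts <- tryCatch(
        suppressWarnings(buildTrainSet(p, m, ds, Kp, Km, cfg)),
        error = function(e) NULL)
      if (is.null(ts)) next
      expect_false(any(ts$protein_id == p & ts$molecule_id == m))
      expect_false(anyDuplicated(paste(ts$protein_id, ts$molecule_id)) > 0)
    }
  })
})

test_that("training sets are byte-identical under identical seeds", {
  ds <- makeTinyDataset()
  ks <- tinyKernels(ds)
  cfg <- trainConfig("rn_mt", nExtraPos = 2, seed = 11)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeTrainSet(suppressWarnings(
    buildTrainSet("P1", "M1", ds, ks$Kp, ks$Km, cfg)), f1)
  writeTrainSet(suppressWarnings(
    buildTrainSet("P1", "M1", ds, ks$Kp, ks$Km, cfg)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
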