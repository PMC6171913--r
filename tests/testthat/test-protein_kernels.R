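# Smith-Waterman kernel with PSD repair, LA kernel, neighborhood k-mer
# kernel, hierarchy kernel.

B62 <- KronDTI:::.substitutionMatrix("BLOSUM62")

test_that("Smith-Waterman score matches hand values and handles X/empty", {
  expect_equal(swScore("ACDE", "ACDE"), 24)   # 4 + 9 + 6 + 5
  expect_equal(swScore("AAAA", "CCCC"), 0)    # s(A,C) = 0
  expect_equal(swScore("AC", "CA"), swScore("CA", "AC"))
  expect_error(swScore("ACDE", ""), "empty")
  expect_error(swScore("ACDE", "ACZ"), "unknown residue")
  # X scores 0 against everything: aligning X against A adds nothing
  expect_equal(swScore("AXA", "AA", o = 100, e = 10), swScore("A", "A"))
})

test_that("Smith-Waterman equals exhaustive alignment enumeration", {
  withr::with_seed(11, {
    aa <- setdiff(rownames(B62), c("X", "*", "B", "Z", "J", "U", "O"))
    for (rep in 1:12) {
      s1 <- paste(sample(aa, sample(1:5, 1), replace = TRUE), collapse = "")
      s2 <- paste(sample(aa, sample(1:5, 1), replace = TRUE), collapse = "")
      o <- sample(c(1, 10, 50), 1); e <- sample(c(0.1, 0.5, 1), 1)
      expect_equal(swScore(s1, s2, o, e), oracleSwScore(s1, s2, o, e, B62),
                   label = paste(s1, s2, o, e))
    }
  })
})

test_that("PSD repair adds |lambda_min| to the diagonal when needed", {
  raw <- matrix(c(0, 1, 1, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  K <- psdRepair(raw)
  expect_equal(unname(kernelValues(K)), matrix(1, 2, 2))
  expect_gte(min(eigen(kernelValues(K), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)

  id3 <- diag(3); dimnames(id3) <- list(letters[1:3], letters[1:3])
  expect_equal(kernelValues(psdRepair(id3)), id3)

  withr::with_seed(5, {
    for (rep in 1:5) {
      m <- matrix(rnorm(36), 6); m <- m + t(m)
      dimnames(m) <- list(letters[1:6], letters[1:6])
      out <- psdRepair(m)
      expect_gte(min(eigen(kernelValues(out), symmetric = TRUE,
                           only.values = TRUE)$values), -1e-8)
      # off-diagonal untouched
      expect_equal(kernelValues(out)[row(m) != col(m)], m[row(m) != col(m)])
    }
  })
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(psdRepair(asym), "symmetric")
})

test_that("LA kernel is symmetric, matches the two-term closed form, and
           approaches SW as beta grows", {
  # single residues: only two local alignments exist (empty, A~A)
  expect_equal(laKernel("A", "A", beta = 1), 1 + exp(1 * B62["A", "A"]))
  expect_equal(laKernel("AC", "CADE", beta = 0.5),
               laKernel("CADE", "AC", beta = 0.5))

  pairs <- list(c("ACDE", "ACDE"), c("MKTAYIAK", "MKTAYIAK"),
                c("ACDEFG", "ACEFG"), c("WYWY", "WAWY"))
  for (pr in pairs) {
    sw <- swScore(pr[1], pr[2], o = 20, e = 1)
    approx <- vapply(c(0.5, 1, 5, 10), function(beta)
      laKernel(pr[1], pr[2], o = 20, e = 1, beta = beta, log = TRUE) / beta,
      0)
    # monotone approach from above and within 5% at beta = 10
    expect_true(all(diff(approx) < 1e-9), label = paste(pr, collapse = "/"))
    expect_true(all(approx >= sw - 1e-9))
    expect_lt((approx[4] - sw) / max(sw, 1), 0.05)
  }
})

test_that("neighborhood k-mer kernel matches explicit enumeration", {
  # exact-match neighborhoods at t = 0: shared-count inner product
  expect_equal(kmerProfileKernel("AAAA", "AAAC", k = 2, t = 0), 6)
  # identical sequences: squared norm of the occupancy vector, > 0
  v <- kmerProfileKernel("ACDEF", "ACDEF", k = 3, t = 7.5)
  expect_gt(v, 0)
  expect_warning(out <- kmerProfileKernel("AC", "AD", k = 5, t = 6),
                 "exceeds both")
  expect_equal(out, 0)

  # brute-force oracle over observed k-mers
  oracleKmer <- function(s1, s2, k, t) {
    km <- function(s) vapply(seq_len(nchar(s) - k + 1),
                             function(i) substr(s, i, i + k - 1), "")
    feats <- unique(c(km(s1), km(s2)))
    score <- function(x, y) {
      cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
      sum(B62[cbind(cx, cy)])
    }
    phi <- function(s) vapply(feats, function(y)
      sum(vapply(km(s), function(x) score(x, y) >= score(x, x) - t, TRUE)), 0)
    sum(phi(s1) * phi(s2))
  }
  withr::with_seed(23, {
    aa <- setdiff(rownames(B62), c("X", "*", "B", "Z", "J", "U", "O"))
    for (rep in 1:6) {
      s1 <- paste(sample(aa, 8, replace = TRUE), collapse = "")
      s2 <- paste(sample(aa, 9, replace = TRUE), collapse = "")
      k <- sample(2:3, 1); t <- sample(c(0, 6, 7.5, 9), 1)
      expect_equal(kmerProfileKernel(s1, s2, k, t),
                   oracleKmer(s1, s2, k, t), label = paste(s1, s2, k, t))
    }
  })
})

test_that("hierarchy kernel counts shared root-to-leaf nodes", {
  f <- withr::local_tempfile()
  writeLines(c("p1\tA/B/L1", "p2\tA/B/L1", "p3\tA/C", "p4\tD/E"), f)
  h <- readHierarchy(f)
  expect_equal(hierarchyKernel("p1", "p2", h), 3)   # same leaf at depth 3
  expect_equal(hierarchyKernel("p1", "p3", h), 1)   # siblings under A
  expect_equal(hierarchyKernel("p1", "p4", h), 0)   # disjoint roots
  expect_error(hierarchyKernel("p1", "p9", h), "not mapped")
})

test_that("protein kernel matrices are symmetric and PSD by construction", {
  ds <- makeTinyDataset()
  prots <- datasetProteins(ds)
  f <- withr::local_tempfile()
  writeLines(paste0(names(prots), "\tfam/c", rep(1:2, each = 3), "/",
                    names(prots)), f)
  h <- readHierarchy(f)
  for (kind in c("sw", "kmer_profile", "hierarchy")) {
    K <- proteinKernelMatrix(prots, kind, k = 3, hierarchy = h,
                             center = FALSE, normalize = FALSE)
    v <- kernelValues(K)
    expect_lt(max(abs(v - t(v))), 1e-10)
    expect_gte(min(eigen(v, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  Kla <- proteinKernelMatrix(prots[1:3], "la", beta = 0.1,
                             center = FALSE, normalize = FALSE)
  expect_gte(min(eigen(kernelValues(Kla), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-6)
})
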