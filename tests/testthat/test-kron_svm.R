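# Factorized Kronecker pair-kernel SVM and single-task baselines.

test_that("pair kernel value is the product and matches explicit Kronecker", {
  ids <- c("u", "v")
  Kp <- KernelMatrix(matrix(c(1, 0.5, 0.5, 1), 2,
                            dimnames = list(ids, ids)), ids)
  Km <- KernelMatrix(matrix(c(1, 0.4, 0.4, 1), 2,
                            dimnames = list(ids, ids)), ids)
  expect_equal(pairKernelValue("u", "u", "v", "v", Kp, Km), 0.2)
  expect_equal(pairKernelValue("u", "u", "u", "v", Kp, Km), 0.4)
  expect_error(pairKernelValue("u", "u", "w", "u", Kp, Km), "missing")

  for (dims in list(c(3, 3), c(4, 4), c(3, 4))) {
    pids <- paste0("p", seq_len(dims[1]))
    mids <- paste0("m", seq_len(dims[2]))
    Kp <- randomKernel(pids, 600 + dims[1])
    Km <- randomKernel(mids, 700 + dims[2])
    full <- kronecker(kernelValues(Kp), kernelValues(Km))  # oracle
    # Kronecker row/col order: (p index outer, m index inner)
    for (a in seq_len(dims[1] * dims[2])) for (b in seq_len(dims[1] * dims[2])) {
      p1 <- pids[(a - 1) %/% dims[2] + 1]; m1 <- mids[(a - 1) %% dims[2] + 1]
      p2 <- pids[(b - 1) %/% dims[2] + 1]; m2 <- mids[(b - 1) %% dims[2] + 1]
      expect_equal(pairKernelValue(p1, m1, p2, m2, Kp, Km), full[a, b],
                   tolerance = 1e-12)
    }
  }
})

test_that("the separable 4-pair fixture is fitted exactly and dual-feasibly", {
  fx <- separableFixture()
  m <- kronSvmFit(fx$train, fx$Kp, fx$Km, C = 10)
  d <- kronSvmDecision(m, fx$train, fx$Kp, fx$Km)
  expect_equal(sign(d$score), fx$train$y)            # training accuracy 1
  s <- supportPairs(m)
  expect_true(all(s$alpha >= 0 & s$alpha <= m@C + 1e-6))
  expect_lt(abs(sum(s$coef)), 1e-6)                  # sum alpha_i y_i = 0
  # doubling C leaves separable-case predictions unchanged
  m2 <- kronSvmFit(fx$train, fx$Kp, fx$Km, C = 20)
  d2 <- kronSvmDecision(m2, fx$train, fx$Kp, fx$Km)
  expect_equal(sign(d2$score), sign(d$score))
  # independent interior-point QP oracle agrees on the decision values
  G <- kernelValues(fx$Kp) * kernelValues(fx$Km)
  orc <- oracleSvmDual(G, fx$train$y, 10)
  expect_equal(unname(sign(orc$decision)), fx$train$y)

  expect_error(kronSvmFit(transform(fx$train, y = 1), fx$Kp, fx$Km),
               "single-class")
})

test_that("factorized decisions equal a dense Kronecker Gram computation", {
  pids <- paste0("p", 1:5); mids <- paste0("m", 1:6)
  Kp <- randomKernel(pids, 31)
  Km <- randomKernel(mids, 32)
  train <- withr::with_seed(33, data.frame(
    protein_id = sample(pids, 20, TRUE), molecule_id = sample(mids, 20, TRUE),
    y = rep(c(1, -1), 10)))
  train <- train[!duplicated(paste(train$protein_id, train$molecule_id)), ]
  m <- kronSvmFit(train, Kp, Km, C = 2)
  queries <- expand.grid(protein_id = pids, molecule_id = mids,
                         stringsAsFactors = FALSE)
  got <- kronSvmDecision(m, queries, Kp, Km)$score
  s <- supportPairs(m)
  dense <- vapply(seq_len(nrow(queries)), function(i)
    sum(s$coef * kernelValues(Km)[queries$molecule_id[i], s$molecule_id] *
          kernelValues(Kp)[queries$protein_id[i], s$protein_id]) + modelBias(m),
    0)
  expect_lt(max(abs(got - dense)), 1e-10)
  # zero similarity to every support pair leaves only the bias
  z <- c(kernelIds(Kp), "pz"); zm <- c(kernelIds(Km), "mz")
  vp <- rbind(cbind(kernelValues(Kp), 0), 0); vp[6, 6] <- 1
  vm <- rbind(cbind(kernelValues(Km), 0), 0); vm[7, 7] <- 1
  dimnames(vp) <- list(z, z); dimnames(vm) <- list(zm, zm)
  dz <- kronSvmDecision(m, data.frame(protein_id = "pz", molecule_id = "mz"),
                        KernelMatrix(vp, z), KernelMatrix(vm, zm))
  expect_equal(dz$score, modelBias(m))
})

test_that("single-task baselines fit and collapse equivalence holds", {
  ids <- paste0("p", 1:4)
  vp <- matrix(0, 4, 4, dimnames = list(ids, ids))
  vp[1:2, 1:2] <- 1; vp[3:4, 3:4] <- 1
  Kp <- KernelMatrix(vp, ids)
  train <- data.frame(protein_id = ids, molecule_id = "mol1",
                      y = c(1, 1, -1, -1))
  st <- singleTaskFit("mol1", "ligand_based", train, Kp, C = 5)
  d <- kronSvmDecision(st, data.frame(protein_id = ids,
                                      molecule_id = "mol1"), Kp = Kp)
  expect_equal(sign(d$score), train$y)

  expect_error(singleTaskFit("orphanMol", "ligand_based", train, Kp),
               "orphan")

  # constant unit molecule kernel: pair-space fit == ligand-based fit
  Km1 <- KernelMatrix(matrix(1, 1, 1, dimnames = list("mol1", "mol1")),
                      "mol1")
  kr <- kronSvmFit(train, Kp, Km1, C = 5)
  dk <- kronSvmDecision(kr, data.frame(protein_id = ids,
                                       molecule_id = "mol1"), Kp, Km1)
  expect_lt(max(abs(dk$score - d$score)), 1e-8)
})

test_that("dual feasibility holds across random fixture fits", {
  withr::with_seed(44, {
    for (rep in 1:6) {
      pids <- paste0("p", 1:6); mids <- paste0("m", 1:6)
      Kp <- randomKernel(pids, 800 + rep)
      Km <- randomKernel(mids, 900 + rep)
      tr <- data.frame(protein_id = sample(pids, 18, TRUE),
                       molecule_id = sample(mids, 18, TRUE),
                       y = sample(c(-1, 1), 18, TRUE, prob = c(0.5, 0.5)))
      tr <- tr[!duplicated(paste(tr$protein_id, tr$molecule_id)), ]
      if (length(unique(tr$y)) < 2) next
      C <- sample(c(0.5, 1, 10), 1)
      m <- kronSvmFit(tr, Kp, Km, C = C)
      s <- supportPairs(m)
      expect_true(all(s$alpha >= -1e-8 & s$alpha <= C + 1e-6))
      expect_lt(abs(sum(s$coef)), 1e-6)
    }
  })
})

test_that("models survive JSON round trips", {
  fx <- separableFixture()
  m <- kronSvmFit(fx$train, fx$Kp, fx$Km, C = 10)
  f <- withr::local_tempfile()
  writeModel(m, f)
  m2 <- readModel(f)
  expect_equal(supportPairs(m2), supportPairs(m))
  expect_equal(modelBias(m2), modelBias(m))
  d1 <- kronSvmDecision(m, fx$train, fx$Kp, fx$Km)
  d2 <- kronSvmDecision(m2, fx$train, fx$Kp, fx$Km)
  expect_equal(d2$score, d1$score)
})
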