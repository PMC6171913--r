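# Independent oracles and fixture builders shared across the test files.
# Every oracle re-derives its quantity by brute force (enumeration, explicit
# linear algebra, or an unrelated solver) so it never shares code with the
# implementation it checks.

bondGlyph <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")

# adjacency list (vertex -> data.frame(v, order)) built from scratch
oracleAdjacency <- function(g) {
  n <- length(g@atoms)
  adj <- replicate(n, data.frame(v = integer(), order = character()),
                   simplify = FALSE)
  b <- g@bonds
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- rbind(adj[[b$i[r]]],
                           data.frame(v = b$j[r], order = b$order[r]))
    adj[[b$j[r]]] <- rbind(adj[[b$j[r]]],
                           data.frame(v = b$i[r], order = b$order[r]))
  }
  adj
}

# brute-force labeled simple-path counts: enumerates every directed simple
# vertex sequence of 1..d atoms, dedupes undirected paths by their vertex
# sequence, then tallies canonical label strings
oraclePathCounts <- function(g, d) {
  n <- length(g@atoms)
  if (n == 0) return(setNames(numeric(0), character(0)))
  adj <- oracleAdjacency(g)
  seqs <- list()
  grow <- function(path) {
    seqs[[length(seqs) + 1L]] <<- path
    if (length(path) == d) return()
    nb <- adj[[path[length(path)]]]$v
    for (w in nb) if (!w %in% path) grow(c(path, w))
  }
  for (v in seq_len(n)) grow(v)
  seen <- character()
  counts <- list()
  for (path in seqs) {
    fwdKey <- paste(path, collapse = ",")
    revKey <- paste(rev(path), collapse = ",")
    vkey <- min(fwdKey, revKey)
    if (vkey %in% seen) next
    seen <- c(seen, vkey)
    lab <- function(p) {
      s <- g@atoms[p[1]]
      if (length(p) > 1) for (t in 2:length(p)) {
        nb <- adj[[p[t - 1]]]
        ord <- nb$order[nb$v == p[t]][1]
        s <- paste0(s, bondGlyph[[ord]], g@atoms[p[t]])
      }
      s
    }
    key <- min(lab(path), lab(rev(path)))
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  unlist(counts)
}

# truncated walk-pair enumeration for the marginalized kernel: explicit
# depth-limited recursion over pairs of positions, geometric tail beyond
# maxLen
oracleMarginalized <- function(g1, g2, q, maxLen = 12) {
  l1 <- g1@atoms; l2 <- g2@atoms
  a1 <- oracleAdjacency(g1); a2 <- oracleAdjacency(g2)
  d1 <- vapply(a1, nrow, 0L); d2 <- vapply(a2, nrow, 0L)
  rec <- function(u, v, depth) {
    stopU <- if (d1[u] == 0) 1 else q
    stopV <- if (d2[v] == 0) 1 else q
    total <- stopU * stopV
    if (depth == 0) return(total)
    nb1 <- a1[[u]]; nb2 <- a2[[v]]
    for (a in seq_len(nrow(nb1))) for (b in seq_len(nrow(nb2))) {
      if (nb1$order[a] != nb2$order[b]) next
      w1 <- nb1$v[a]; w2 <- nb2$v[b]
      if (l1[w1] != l2[w2]) next
      total <- total + (1 - q) / d1[u] * (1 - q) / d2[v] *
        rec(w1, w2, depth - 1)
    }
    total
  }
  acc <- 0
  for (u in seq_along(l1)) for (v in seq_along(l2))
    if (l1[u] == l2[v]) acc <- acc + rec(u, v, maxLen - 1)
  acc / (length(l1) * length(l2))
}

# exhaustive Smith-Waterman by enumerating every monotone matching of
# residue pairs; affine gap of length L between consecutive matched pairs
# costs o + L * e (for sequences of length <= 5)
oracleSwScore <- function(s1, s2, o, e, sm) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  n <- length(c1); m <- length(c2)
  best <- 0
  subsets <- function(k) {
    if (k == 0) return(list(integer(0)))
    unlist(lapply(0:(2^k - 1), function(mask)
      list(which(bitwAnd(mask, 2^(0:(k - 1))) > 0))), recursive = FALSE)
  }
  gapCost <- function(len) if (len > 0) o + len * e else 0
  for (I in subsets(n)) {
    k <- length(I)
    if (k == 0) next
    for (J in subsets(m)) {
      if (length(J) != k) next
      sc <- sum(sm[cbind(c1[I], c2[J])])
      if (k > 1) for (t in 2:k)
        sc <- sc - gapCost(I[t] - I[t - 1] - 1) - gapCost(J[t] - J[t - 1] - 1)
      if (sc > best) best <- sc
    }
  }
  best
}

# independent convex QP solver for the SVM dual (kernlab interior point
# rather than the implementation's SMO path)
oracleSvmDual <- function(G, y, C) {
  n <- length(y)
  H <- (G * outer(y, y))
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-10, n),
                       A = matrix(y, 1), b = 0, l = rep(0, n),
                       u = rep(C, n), r = 0)
  alpha <- kernlab::primal(sol)
  f <- drop(G %*% (alpha * y))
  onMargin <- which(alpha > 1e-5 & alpha < C - 1e-5)
  b <- if (length(onMargin)) mean(y[onMargin] - f[onMargin]) else 0
  list(alpha = alpha, b = b, decision = f + b)
}

# small random PSD kernel over the given ids (rank > dim, unit-ish diagonal)
randomKernel <- function(ids, seed, normalized = TRUE) {
  v <- withr::with_seed(seed, {
    X <- matrix(rnorm(length(ids) * (length(ids) + 3)), length(ids))
    tcrossprod(X)
  })
  if (normalized) v <- v / sqrt(outer(diag(v), diag(v)))
  dimnames(v) <- list(ids, ids)
  KernelMatrix(v, ids, normalized = normalized)
}

# random small molecule graph (connected, for parser/kernel property tests)
randomMoleculeGraph <- function(id, nAtoms, seed) {
  withr::with_seed(seed, {
    atoms <- sample(c("C", "N", "O", "S", "c", "n"), nAtoms, replace = TRUE)
    bonds <- data.frame(i = integer(), j = integer(), order = character())
    if (nAtoms > 1) {
      for (v in 2:nAtoms)
        bonds <- rbind(bonds, data.frame(
          i = sample.int(v - 1, 1), j = v,
          order = sample(c("1", "2", "ar"), 1, prob = c(0.7, 0.15, 0.15))))
      if (nAtoms > 3 && runif(1) < 0.5) {
        uv <- sort(sample.int(nAtoms, 2))
        if (!any(bonds$i == uv[1] & bonds$j == uv[2]))
          bonds <- rbind(bonds, data.frame(i = uv[1], j = uv[2], order = "1"))
      }
    }
    MoleculeGraph(id, atoms, bonds)
  })
}

# deterministic small interaction dataset for builder/CV tests:
# 6 proteins x 6 molecules with a planted 2-block structure
makeTinyDataset <- function() {
  prots <- Biostrings::AAStringSet(setNames(
    c("ACDEFGHIKL", "ACDEFGHIKV", "ACDEYGHIKL",
      "MNPQRSTVWY", "MNPQRSTVWC", "MNPQRSTVAY"),
    paste0("P", 1:6)))
  mols <- setNames(lapply(1:6, function(i)
    randomMoleculeGraph(paste0("M", i), 5 + (i %% 3), seed = 100 + i)),
    paste0("M", 1:6))
  # P6 and M6 are left orphan so double-orphan queries can be exercised
  positives <- data.frame(
    protein_id = c("P1", "P1", "P2", "P3", "P4", "P5", "P2"),
    molecule_id = c("M1", "M2", "M1", "M3", "M4", "M5", "M2"))
  InteractionDataset(prots, mols, positives = positives)
}

tinyKernels <- function(ds = makeTinyDataset()) {
  list(Kp = proteinKernelMatrix(datasetProteins(ds), "sw"),
       Km = moleculeKernelMatrix(datasetMolecules(ds), "tanimoto", d = 4))
}

# the separable 4-pair fixture: two similarity blocks, 2 positives vs 2
# negatives
separableFixture <- function() {
  ids <- paste0("e", 1:4)
  vp <- matrix(0, 4, 4, dimnames = list(ids, ids))
  vp[1:2, 1:2] <- 1; vp[3:4, 3:4] <- 1
  vm <- matrix(0, 4, 4, dimnames = list(ids, ids))
  vm[1:2, 1:2] <- 1; vm[3:4, 3:4] <- 1
  list(train = data.frame(protein_id = ids, molecule_id = ids,
                          y = c(1, 1, -1, -1)),
       Kp = KernelMatrix(vp, ids), Km = KernelMatrix(vm, ids))
}
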