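# Planted-cluster synthetic datasets: clustered molecule/protein similarity
# structure plus a planted bipartite interaction rule (within-cluster binding
# probability pIn >> cross-cluster pOut), so every pipeline stage is testable
# without external downloads.

.SYNTH_ELEMENTS <- c("C", "N", "O", "S")

# random connected molecular graph: spanning tree plus a few extra edges
.randomAncestorGraph <- function(nAtoms) {
  atoms <- sample(.SYNTH_ELEMENTS, nAtoms, replace = TRUE,
                  prob = c(0.6, 0.15, 0.15, 0.1))
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  for (v in 2:nAtoms) {
    u <- sample.int(v - 1, 1)
    ord <- sample(c("1", "2"), 1, prob = c(0.85, 0.15))
    bonds <- rbind(bonds, data.frame(i = u, j = v, order = ord))
  }
  nExtra <- sample(0:2, 1)
  for (k in seq_len(nExtra)) {
    uv <- sort(sample.int(nAtoms, 2))
    if (!any(bonds$i == uv[1] & bonds$j == uv[2]))
      bonds <- rbind(bonds, data.frame(i = uv[1], j = uv[2], order = "1"))
  }
  list(atoms = atoms, bonds = bonds)
}

.isConnected <- function(nAtoms, bonds) {
  if (nAtoms <= 1) return(TRUE)
  adj <- vector("list", nAtoms)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  seen <- rep(FALSE, nAtoms)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# one label-swap or connectivity-preserving edge edit
.mutateGraph <- function(atoms, bonds, maxRetries = 20) {
  for (try in seq_len(maxRetries)) {
    a2 <- atoms; b2 <- bonds
    move <- sample(c("label", "add", "remove"), 1, prob = c(0.5, 0.25, 0.25))
    if (move == "label") {
      v <- sample.int(length(a2), 1)
      a2[v] <- sample(setdiff(.SYNTH_ELEMENTS, a2[v]), 1)
    } else if (move == "add") {
      uv <- sort(sample.int(length(a2), 2))
      if (any(b2$i == uv[1] & b2$j == uv[2])) next
      b2 <- rbind(b2, data.frame(i = uv[1], j = uv[2], order = "1"))
    } else {
      if (nrow(b2) <= 1) next
      r <- sample.int(nrow(b2), 1)
      b2 <- b2[-r, , drop = FALSE]
      if (!.isConnected(length(a2), b2)) next
    }
    return(list(atoms = a2, bonds = b2))
  }
  stop("could not find a connectivity-preserving graph edit")
}

#' Generate a planted-cluster synthetic dataset
#'
#' Per molecule cluster, a random connected ancestor graph over C/N/O/S
#' (8-16 atoms) is mutated by \code{graphEditSteps} label/edge edits per
#' member; per protein cluster, a random ancestor sequence (length 120-200,
#' i.i.d. uniform over the 20 amino acids) is mutated by per-residue
#' substitutions at \code{mutationRate}. Positive interactions are drawn
#' Bernoulli(pIn) for matched cluster indices and Bernoulli(pOut) otherwise.
#' A family hierarchy with one node per protein cluster is attached.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list(dataset = \linkS4class{InteractionDataset},
#'   proteinClusters, moleculeClusters) where the cluster components are
#'   named integer vectors of ground-truth labels.
#' @export
generateSyntheticDataset <- function(spec = syntheticSpec()) {
  validObject(spec)
  withSeed(spec@seed, {
    aa20 <- setdiff(.AA_ALPHABET, "X")
    nP <- spec@nProteinClusters * spec@entitiesPerCluster
    nM <- spec@nMoleculeClusters * spec@entitiesPerCluster
    pid <- sprintf("P%02d", seq_len(nP))
    mid <- sprintf("M%02d", seq_len(nM))
    pCluster <- setNames(rep(seq_len(spec@nProteinClusters),
                             each = spec@entitiesPerCluster), pid)
    mCluster <- setNames(rep(seq_len(spec@nMoleculeClusters),
                             each = spec@entitiesPerCluster), mid)
    # proteins
    seqs <- character(nP)
    for (cl in seq_len(spec@nProteinClusters)) {
      len <- sample(120:200, 1)
      anc <- sample(aa20, len, replace = TRUE)
      for (m in which(pCluster == cl)) {
        s <- anc
        mut <- stats::runif(len) < spec@mutationRate
        if (any(mut))
          s[mut] <- sample(aa20, sum(mut), replace = TRUE)
        seqs[m] <- paste(s, collapse = "")
      }
    }
    proteins <- Biostrings::AAStringSet(setNames(seqs, pid))
    # molecules
    molecules <- vector("list", nM)
    for (cl in seq_len(spec@nMoleculeClusters)) {
      anc <- .randomAncestorGraph(sample(8:16, 1))
      for (m in which(mCluster == cl)) {
        g <- anc
        for (s in seq_len(spec@graphEditSteps))
          g <- .mutateGraph(g$atoms, g$bonds)
        molecules[[m]] <- MoleculeGraph(mid[m], g$atoms, g$bonds)
      }
    }
    names(molecules) <- mid
    # planted interactions
    pairs <- expand.grid(protein_id = pid, molecule_id = mid,
                         stringsAsFactors = FALSE)
    pr <- ifelse(pCluster[pairs$protein_id] == mCluster[pairs$molecule_id],
                 spec@pIn, spec@pOut)
    hit <- stats::runif(nrow(pairs)) < pr
    positives <- pairs[hit, , drop = FALSE]
    rownames(positives) <- NULL
    # family hierarchy: root / cluster / protein leaf
    hierLines <- sprintf("%s\tfamilies/cluster%d/%s", pid, pCluster[pid], pid)
    tf <- tempfile()
    writeLines(hierLines, tf)
    hier <- readHierarchy(tf)
    unlink(tf)
    list(dataset = InteractionDataset(proteins, molecules,
                                      positives = positives,
                                      hierarchy = hier),
         proteinClusters = pCluster, moleculeClusters = mCluster)
  })
}

#' Write a synthetic dataset to a directory
#'
#' Writes SMILES, FASTA, interactions TSV, hierarchy TSV and a truth JSON
#' (cluster labels) under \code{dir}.
#'
#' @param synth result of \code{\link{generateSyntheticDataset}}.
#' @param dir output directory (created if needed).
#' @export
writeSyntheticDataset <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- synth$dataset
  writeSmilesFile(ds@molecules, file.path(dir, "molecules.smi"))
  writeFastaProteins(ds@proteins, file.path(dir, "proteins.fasta"))
  writeInteractions(ds, file.path(dir, "interactions.tsv"))
  if (!is.null(ds@hierarchy))
    writeHierarchy(ds@hierarchy, file.path(dir, "hierarchy.tsv"))
  jsonlite::write_json(list(proteinClusters = as.list(synth$proteinClusters),
                            moleculeClusters = as.list(synth$moleculeClusters)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' The frozen worked-example dataset
#'
#' A small fixture (8 molecules, 8 proteins) shipped as plain-text files
#' under the package's \code{extdata/worked_example}. It contains the
#' hand-checkable molecules (methane, ethane, ethanol, benzene, ...) and
#' short sequences used by the documented kernel examples, and a separable
#' block of interactions for the SVM examples.
#'
#' @return an \linkS4class{InteractionDataset}.
#' @export
workedExampleSet <- function() {
  dir <- system.file("extdata", "worked_example", package = "KronDTI",
                     mustWork = TRUE)
  mols <- readSmilesFile(file.path(dir, "molecules.smi"))
  prots <- readFastaProteins(file.path(dir, "proteins.fasta"))
  hier <- readHierarchy(file.path(dir, "hierarchy.tsv"))
  readInteractions(file.path(dir, "interactions.tsv"), prots, mols,
                   hierarchy = hier)
}
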