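#' @import methods
#' @importFrom Biostrings AAStringSet
NULL

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","X")

.BOND_ORDERS <- c("1", "2", "3", "ar")

#' MoleculeGraph: labeled undirected graph of heavy atoms
#'
#' The substrate of the molecular graph kernels. Vertices carry element
#' labels (lower case for aromatic atoms, as in SMILES), edges carry bond
#' order labels \code{"1"}, \code{"2"}, \code{"3"} or \code{"ar"}.
#' Hydrogens are suppressed. Each bond is stored once with \code{i < j}.
#'
#' @slot moleculeId single identifier string.
#' @slot atoms character vector of atom labels (e.g. \code{"C"}, \code{"c"},
#'   \code{"N"}); lower case marks aromatic atoms.
#' @slot bonds data.frame with integer columns \code{i}, \code{j} and a
#'   character column \code{order}.
#' @exportClass MoleculeGraph
setClass("MoleculeGraph",
  representation(moleculeId = "character", atoms = "character",
                 bonds = "data.frame"),
  prototype(moleculeId = NA_character_, atoms = character(),
            bonds = data.frame(i = integer(), j = integer(),
                               order = character())))

setValidity("MoleculeGraph", function(object) {
  b <- object@bonds
  msg <- character()
  if (length(object@moleculeId) != 1L || is.na(object@moleculeId))
    msg <- c(msg, "moleculeId must be a single non-NA string")
  if (!all(c("i", "j", "order") %in% names(b)))
    msg <- c(msg, "bonds must have columns i, j, order")
  else if (nrow(b) > 0) {
    n <- length(object@atoms)
    if (any(b$i < 1L | b$j < 1L | b$i > n | b$j > n))
      msg <- c(msg, "bond endpoint out of range")
    if (any(b$i == b$j))
      msg <- c(msg, "self-bonds are not allowed")
    if (any(b$i >= b$j))
      msg <- c(msg, "bonds must be stored once with i < j")
    if (anyDuplicated(paste(b$i, b$j)))
      msg <- c(msg, "duplicate bonds")
    if (!all(b$order %in% .BOND_ORDERS))
      msg <- c(msg, "bond order labels must be one of 1, 2, 3, ar")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MoleculeGraph constructor
#' @param moleculeId,atoms,bonds see slots.
#' @export
MoleculeGraph <- function(moleculeId, atoms,
                          bonds = data.frame(i = integer(), j = integer(),
                                             order = character())) {
  if (nrow(bonds) > 0) {
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  new("MoleculeGraph", moleculeId = as.character(moleculeId),
      atoms = as.character(atoms),
      bonds = data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                         order = as.character(bonds$order)))
}

#' KernelMatrix: symmetric similarity matrix keyed by entity identifiers
#'
#' @slot ids character vector of entity identifiers (row/column order).
#' @slot values numeric symmetric matrix with dimnames equal to \code{ids}.
#' @slot centered logical flag: has feature-space centering been applied.
#' @slot normalized logical flag: has cosine normalization been applied.
#' @exportClass KernelMatrix
setClass("KernelMatrix",
  representation(ids = "character", values = "matrix",
                 centered = "logical", normalized = "logical"),
  prototype(centered = FALSE, normalized = FALSE))

setValidity("KernelMatrix", function(object) {
  v <- object@values
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate ids")
  if (nrow(v) != n || ncol(v) != n)
    msg <- c(msg, "values must be n x n with n = length(ids)")
  else {
    if (!is.numeric(v) || any(!is.finite(v)))
      msg <- c(msg, "values must be finite numeric")
    else if (n > 0 && max(abs(v - t(v))) > 1e-8)
      msg <- c(msg, "values not symmetric within 1e-8")
    if (!identical(rownames(v), object@ids) ||
        !identical(colnames(v), object@ids))
      msg <- c(msg, "dimnames must equal ids")
    if (isTRUE(object@normalized) && n > 0 &&
        max(abs(diag(v) - 1)) > 1e-10)
      msg <- c(msg, "normalized kernel must have unit diagonal within 1e-10")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn KernelMatrix constructor; symmetrizes tiny asymmetries and
#'   attaches dimnames.
#' @param values,ids,centered,normalized see slots.
#' @export
KernelMatrix <- function(values, ids = rownames(values),
                         centered = FALSE, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(ids)) stop("ids are required (or set rownames on values)")
  if (nrow(values) > 0 && max(abs(values - t(values))) <= 1e-8)
    values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  new("KernelMatrix", ids = as.character(ids), values = values,
      centered = centered, normalized = normalized)
}

#' Hierarchy: protein family hierarchy (a forest)
#'
#' @slot nodes all node identifiers.
#' @slot parent named character vector mapping child node -> parent node;
#'   roots are absent from the names.
#' @slot leafOf named character vector mapping protein_id -> leaf node.
#' @exportClass Hierarchy
setClass("Hierarchy",
  representation(nodes = "character", parent = "character",
                 leafOf = "character"),
  prototype(nodes = character(), parent = character(), leafOf = character()))

setValidity("Hierarchy", function(object) {
  msg <- character()
  if (length(object@parent) &&
      !(all(names(object@parent) %in% object@nodes) &&
        all(object@parent %in% object@nodes)))
    msg <- c(msg, "parent map references unknown nodes")
  if (length(object@leafOf) && !all(object@leafOf %in% object@nodes))
    msg <- c(msg, "leafOf references unknown nodes")
  # acyclicity: walking up from every node must terminate
  for (nd in object@nodes) {
    seen <- character(); cur <- nd
    while (cur %in% names(object@parent)) {
      if (cur %in% seen) return("cycle in hierarchy")
      seen <- c(seen, cur)
      cur <- object@parent[[cur]]
    }
  }
  if (length(msg)) msg else TRUE
})

#' InteractionDataset: bipartite labeled (protein, molecule) pair store
#'
#' Positives are explicit; every other pair is implicitly negative (the
#' unlabeled-as-negative convention). Explicit negatives can additionally be
#' stored so benchmark negative sets survive round-trips.
#'
#' @slot proteins \link[Biostrings]{AAStringSet} named by protein ids.
#' @slot molecules named list of \linkS4class{MoleculeGraph}.
#' @slot positives data.frame(protein_id, molecule_id).
#' @slot explicitNegatives data.frame(protein_id, molecule_id).
#' @slot hierarchy a \linkS4class{Hierarchy} or NULL.
#' @exportClass InteractionDataset
setClass("InteractionDataset",
  representation(proteins = "AAStringSet", molecules = "list",
                 positives = "data.frame", explicitNegatives = "data.frame",
                 hierarchy = "ANY"),
  prototype(positives = data.frame(protein_id = character(),
                                   molecule_id = character()),
            explicitNegatives = data.frame(protein_id = character(),
                                           molecule_id = character()),
            hierarchy = NULL))

.pairKeys <- function(df) paste(df$protein_id, df$molecule_id, sep = "\t")

setValidity("InteractionDataset", function(object) {
  msg <- character()
  pid <- names(object@proteins); mid <- names(object@molecules)
  if (is.null(pid) || anyDuplicated(pid))
    msg <- c(msg, "proteins must be uniquely named")
  if (length(object@molecules) &&
      (is.null(mid) || anyDuplicated(mid) ||
       !all(vapply(object@molecules, is, TRUE, "MoleculeGraph"))))
    msg <- c(msg, "molecules must be a uniquely named list of MoleculeGraph")
  seqs <- as.character(object@proteins)
  if (length(seqs)) {
    if (any(nchar(seqs) == 0)) msg <- c(msg, "empty protein sequence")
    bad <- vapply(strsplit(seqs, ""), function(ch)
      any(!ch %in% .AA_ALPHABET), TRUE)
    if (any(bad)) msg <- c(msg, "protein sequence outside amino-acid alphabet")
  }
  for (df in list(object@positives, object@explicitNegatives)) {
    if (!all(c("protein_id", "molecule_id") %in% names(df))) {
      msg <- c(msg, "pair tables need protein_id and molecule_id columns")
      next
    }
    if (nrow(df) && !all(df$protein_id %in% pid))
      msg <- c(msg, "pair references unknown protein")
    if (nrow(df) && !all(df$molecule_id %in% mid))
      msg <- c(msg, "pair references unknown molecule")
  }
  if (nrow(object@positives) && nrow(object@explicitNegatives) &&
      length(intersect(.pairKeys(object@positives),
                       .pairKeys(object@explicitNegatives))))
    msg <- c(msg, "positives and explicit negatives overlap")
  if (!is.null(object@hierarchy) && !is(object@hierarchy, "Hierarchy"))
    msg <- c(msg, "hierarchy must be NULL or a Hierarchy")
  if (length(msg)) msg else TRUE
})

#' @describeIn InteractionDataset constructor
#' @param proteins,molecules,positives,explicitNegatives,hierarchy see slots.
#' @export
InteractionDataset <- function(proteins, molecules,
    positives = data.frame(protein_id = character(),
                           molecule_id = character()),
    explicitNegatives = data.frame(protein_id = character(),
                                   molecule_id = character()),
    hierarchy = NULL) {
  if (!is(proteins, "AAStringSet")) proteins <- AAStringSet(proteins)
  norm <- function(df) {
    df <- data.frame(protein_id = as.character(df$protein_id),
                     molecule_id = as.character(df$molecule_id))
    rownames(df) <- NULL
    df
  }
  new("InteractionDataset", proteins = proteins, molecules = molecules,
      positives = norm(positives), explicitNegatives = norm(explicitNegatives),
      hierarchy = hierarchy)
}

#' KronSVMModel: a fitted (pair-space or single-task) SVM
#'
#' @slot kind one of \code{"pair"}, \code{"ligand_based"},
#'   \code{"target_based"}.
#' @slot support data.frame with columns protein_id, molecule_id, y, alpha,
#'   coef (coef = alpha * y); single-task models leave the non-task axis id
#'   fixed.
#' @slot b intercept; the decision score is
#'   \code{sum(coef_i * K(query, support_i)) - b}.
#' @slot C box constraint used at fit time.
#' @slot taskEntity for single-task models, the fixed entity id.
#' @exportClass KronSVMModel
setClass("KronSVMModel",
  representation(kind = "character", support = "data.frame", b = "numeric",
                 C = "numeric", taskEntity = "character"),
  prototype(kind = "pair", b = 0, C = Inf, taskEntity = NA_character_))

setValidity("KronSVMModel", function(object) {
  msg <- character()
  s <- object@support
  if (!all(c("protein_id", "molecule_id", "y", "alpha", "coef") %in% names(s)))
    msg <- c(msg, "support needs protein_id, molecule_id, y, alpha, coef")
  else {
    if (!all(s$y %in% c(-1, 1))) msg <- c(msg, "labels must be -1/+1")
    if (any(s$alpha < -1e-8 | s$alpha > object@C + 1e-6))
      msg <- c(msg, "alpha outside [0, C]")
  }
  if (length(msg)) msg else TRUE
})

#' FoldAssignment: a cross-validation fold system over pair samples
#'
#' Folds hold integer indices into the sample table they were built from.
#' For double-orphan schemes each test fold carries its own training pool
#' (\code{trainPools}); otherwise the pool is the complement of the fold.
#'
#' @slot scheme fold construction scheme name.
#' @slot folds list of integer index vectors (test folds).
#' @slot trainPools list of integer index vectors, or empty list.
#' @slot K requested entity-group count.
#' @slot seed RNG seed used.
#' @slot nSamples number of samples the indices refer to.
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  representation(scheme = "character", folds = "list", trainPools = "list",
                 K = "integer", seed = "integer", nSamples = "integer"),
  prototype(trainPools = list()))

setValidity("FoldAssignment", function(object) {
  idx <- unlist(object@folds)
  msg <- character()
  if (length(idx) && (any(idx < 1L) || any(idx > object@nSamples)))
    msg <- c(msg, "fold indices out of range")
  if (anyDuplicated(idx)) msg <- c(msg, "folds overlap")
  if (length(object@trainPools) &&
      length(object@trainPools) != length(object@folds))
    msg <- c(msg, "trainPools must match folds in length")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: per-query training-set construction parameters
#'
#' @slot mode \code{"mt_intra"}, \code{"nn_mt"} or \code{"rn_mt"}.
#' @slot negPosRatio intra-task negatives per positive (n-/n+), default 10.
#' @slot nExtraPos number of extra-task positives ne+ (ignored for mt_intra).
#' @slot extraNegRatio extra-task negatives per extra positive (ne-/ne+).
#' @slot theta percentile similarity threshold in [0, 100] or NA (no filter).
#' @slot thetaScope \code{"intra"} or \code{"intra_and_extra"}.
#' @slot thetaFilterNegatives also filter sampled negatives (default FALSE).
#' @slot negBothAxes sample intra-task negatives on both axes (default FALSE:
#'   ligand axis only, i.e. non-interacting proteins for the query molecule).
#' @slot wnn enable weighted-nearest-neighbor de-orphanization.
#' @slot wnnDecay rank decay T in (0,1), default 0.8.
#' @slot wnnThreshold profile threshold eta in (0,1), default 0.5.
#' @slot seed RNG seed for all sampling.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(mode = "character", negPosRatio = "numeric",
                 nExtraPos = "numeric", extraNegRatio = "numeric",
                 theta = "numeric", thetaScope = "character",
                 thetaFilterNegatives = "logical", negBothAxes = "logical",
                 wnn = "logical", wnnDecay = "numeric",
                 wnnThreshold = "numeric", seed = "integer"),
  prototype(mode = "nn_mt", negPosRatio = 10, nExtraPos = 10,
            extraNegRatio = 1, theta = NA_real_, thetaScope = "intra",
            thetaFilterNegatives = FALSE, negBothAxes = FALSE, wnn = FALSE,
            wnnDecay = 0.8, wnnThreshold = 0.5, seed = 1L))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("mt_intra", "nn_mt", "rn_mt"))
    msg <- c(msg, "mode must be mt_intra, nn_mt or rn_mt")
  if (object@negPosRatio <= 0) msg <- c(msg, "negPosRatio must be > 0")
  if (object@nExtraPos < 0) msg <- c(msg, "nExtraPos must be >= 0")
  if (object@extraNegRatio < 0) msg <- c(msg, "extraNegRatio must be >= 0")
  if (!is.na(object@theta) && (object@theta < 0 || object@theta > 100))
    msg <- c(msg, "theta must lie in [0, 100]")
  if (!object@thetaScope %in% c("intra", "intra_and_extra"))
    msg <- c(msg, "thetaScope must be intra or intra_and_extra")
  if (object@wnnDecay <= 0 || object@wnnDecay >= 1)
    msg <- c(msg, "wnnDecay must lie in (0,1)")
  if (object@wnnThreshold <= 0 || object@wnnThreshold >= 1)
    msg <- c(msg, "wnnThreshold must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig constructor with the recommended defaults
#'   (n-/n+ = 10, ne-/ne+ = 1).
#' @param mode,negPosRatio,nExtraPos,extraNegRatio,theta,thetaScope see slots.
#' @param thetaFilterNegatives,negBothAxes,wnn,wnnDecay,wnnThreshold,seed see
#'   slots.
#' @export
trainConfig <- function(mode = c("nn_mt", "mt_intra", "rn_mt"),
                        negPosRatio = 10, nExtraPos = 10, extraNegRatio = 1,
                        theta = NA_real_,
                        thetaScope = c("intra", "intra_and_extra"),
                        thetaFilterNegatives = FALSE, negBothAxes = FALSE,
                        wnn = FALSE, wnnDecay = 0.8, wnnThreshold = 0.5,
                        seed = 1L) {
  new("TrainConfig", mode = match.arg(mode), negPosRatio = negPosRatio,
      nExtraPos = nExtraPos, extraNegRatio = extraNegRatio,
      theta = as.numeric(theta), thetaScope = match.arg(thetaScope),
      thetaFilterNegatives = thetaFilterNegatives, negBothAxes = negBothAxes,
      wnn = wnn, wnnDecay = wnnDecay, wnnThreshold = wnnThreshold,
      seed = as.integer(seed))
}

#' SyntheticSpec: parameters of the planted-cluster synthetic generator
#'
#' Defaults are the study conditions used throughout the package's
#' end-to-end validation: 4 protein clusters x 4 molecule clusters with 8
#' entities each, within-cluster binding probability 0.9 against 0.02 across
#' clusters.
#'
#' @slot nProteinClusters,nMoleculeClusters cluster counts.
#' @slot entitiesPerCluster entities per cluster on each axis.
#' @slot pIn,pOut within/cross-cluster binding probabilities (pIn > pOut).
#' @slot mutationRate per-residue substitution probability for within-cluster
#'   sequence divergence.
#' @slot graphEditSteps label/edge edits applied to each cluster member's
#'   molecular graph.
#' @slot seed RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nProteinClusters = "integer", nMoleculeClusters = "integer",
                 entitiesPerCluster = "integer", pIn = "numeric",
                 pOut = "numeric", mutationRate = "numeric",
                 graphEditSteps = "integer", seed = "integer"),
  prototype(nProteinClusters = 4L, nMoleculeClusters = 4L,
            entitiesPerCluster = 8L, pIn = 0.9, pOut = 0.02,
            mutationRate = 0.1, graphEditSteps = 2L, seed = 1L))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (any(c(object@pIn, object@pOut) < 0 | c(object@pIn, object@pOut) > 1))
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@pIn <= object@pOut)
    msg <- c(msg, "planted-signal fixtures require pIn > pOut")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticSpec constructor
#' @param nProteinClusters,nMoleculeClusters,entitiesPerCluster see slots.
#' @param pIn,pOut,mutationRate,graphEditSteps,seed see slots.
#' @export
syntheticSpec <- function(nProteinClusters = 4L, nMoleculeClusters = 4L,
                          entitiesPerCluster = 8L, pIn = 0.9, pOut = 0.02,
                          mutationRate = 0.1, graphEditSteps = 2L, seed = 1L) {
  new("SyntheticSpec", nProteinClusters = as.integer(nProteinClusters),
      nMoleculeClusters = as.integer(nMoleculeClusters),
      entitiesPerCluster = as.integer(entitiesPerCluster),
      pIn = pIn, pOut = pOut, mutationRate = mutationRate,
      graphEditSteps = as.integer(graphEditSteps), seed = as.integer(seed))
}
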