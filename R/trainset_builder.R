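# Per-query reduced training sets: intra-task positives, sampled intra-task
# negatives, nearest-neighbor / random extra-task pairs, percentile
# similarity filters, and weighted-nearest-neighbor de-orphanization.

#' Intra-task positive pairs for a query
#'
#' All known positives sharing the query's protein or molecule, excluding
#' the query pair itself (leakage guard). May be empty (double-orphan
#' query).
#'
#' @param protein_id,molecule_id the query pair.
#' @param dataset an \linkS4class{InteractionDataset}.
#' @return data.frame(protein_id, molecule_id).
#' @export
intraTaskPairs <- function(protein_id, molecule_id, dataset) {
  pos <- dataset@positives
  keep <- (pos$protein_id == protein_id | pos$molecule_id == molecule_id) &
    !(pos$protein_id == protein_id & pos$molecule_id == molecule_id)
  out <- pos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample intra-task negative pairs
#'
#' Draws \code{round(ratio * nPlus)} pairs (p, m*) whose protein is not a
#' known target of the query molecule (and is not the query protein),
#' without replacement. With \code{bothAxes}, the symmetric ligand pool
#' (p*, m) is added before sampling. If the candidate pool is smaller than
#' requested, all candidates are taken with a warning.
#'
#' @param protein_id,molecule_id the query pair.
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param nPlus number of positive training pairs.
#' @param ratio negatives per positive (n-/n+).
#' @param seed RNG seed (fixed seed, identical sample).
#' @param bothAxes also sample (p*, m) pairs on the protein axis.
#' @return data.frame(protein_id, molecule_id).
#' @export
sampleIntraNegatives <- function(protein_id, molecule_id, dataset, nPlus,
                                 ratio = 10, seed = 1L, bothAxes = FALSE) {
  pos <- dataset@positives
  posKeys <- .pairKeys(pos)
  targetsOfM <- pos$protein_id[pos$molecule_id == molecule_id]
  cand <- data.frame(
    protein_id = setdiff(proteinIds(dataset), c(targetsOfM, protein_id)),
    molecule_id = molecule_id)
  if (bothAxes) {
    ligandsOfP <- pos$molecule_id[pos$protein_id == protein_id]
    cand <- rbind(cand, data.frame(
      protein_id = protein_id,
      molecule_id = setdiff(moleculeIds(dataset),
                            c(ligandsOfP, molecule_id))))
  }
  cand <- cand[!.pairKeys(cand) %in% posKeys, , drop = FALSE]
  nMinus <- roundHalfUp(ratio * nPlus)
  if (nrow(cand) < nMinus) {
    warning(sprintf(
      "negative candidate pool (%d) smaller than requested n- = %d; taking all",
      nrow(cand), nMinus))
    nMinus <- nrow(cand)
  }
  take <- withSeed(seed, sample.int(nrow(cand), nMinus))
  out <- cand[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kronecker-consistent pair similarity to the query
#'
#' \code{Kp(p, p*) * Km(m, m*)}: the pair kernel between candidate and
#' query, monotone in each factor.
#'
#' @param protein_id,molecule_id candidate pair (vectors allowed).
#' @param queryProtein,queryMolecule the query pair.
#' @param Kp,Km entity kernels.
#' @return numeric similarity value(s).
#' @export
pairSimilarity <- function(protein_id, molecule_id, queryProtein,
                           queryMolecule, Kp, Km) {
  kernelValue(Kp, protein_id, rep(queryProtein, length(protein_id))) *
    kernelValue(Km, molecule_id, rep(queryMolecule, length(molecule_id)))
}

# deterministic ordering: similarity desc, then lexicographic ids
.rankBySimilarity <- function(df, sim) {
  df[order(-sim, df$protein_id, df$molecule_id), , drop = FALSE]
}

#' Select extra-task training pairs
#'
#' Extra-task candidates share neither entity with the query. Positives:
#' the \code{nExtraPos} most similar positives by \code{pairSimilarity}
#' (mode \code{"nn_mt"}; ties broken lexicographically) or a seeded uniform
#' sample (mode \code{"rn_mt"}). Negatives: \code{round(extraNegRatio *
#' ne+)} extra-task non-positive pairs selected by the same rule (nearest
#' for nn, random for rn).
#'
#' @param protein_id,molecule_id the query pair.
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param Kp,Km entity kernels (required for nn_mt).
#' @param mode \code{"nn_mt"} or \code{"rn_mt"}.
#' @param nExtraPos requested number of extra-task positives (ne+).
#' @param extraNegRatio ne-/ne+ ratio.
#' @param seed RNG seed for the random variants.
#' @param positivePool optional replacement for the dataset positives
#'   (already theta-filtered, for \code{thetaScope = "intra_and_extra"}).
#' @return list(positives = data.frame, negatives = data.frame).
#' @export
selectExtraTask <- function(protein_id, molecule_id, dataset, Kp = NULL,
                            Km = NULL, mode = c("nn_mt", "rn_mt"),
                            nExtraPos = 10, extraNegRatio = 1, seed = 1L,
                            positivePool = NULL) {
  mode <- match.arg(mode)
  pos <- if (is.null(positivePool)) dataset@positives else positivePool
  extra <- pos[pos$protein_id != protein_id &
                 pos$molecule_id != molecule_id, , drop = FALSE]
  takeTop <- function(df, nWant, what) {
    if (nrow(df) < nWant) {
      warning(sprintf("only %d extra-task %s candidates for requested %d",
                      nrow(df), what, nWant))
      nWant <- nrow(df)
    }
    if (mode == "nn_mt") {
      sim <- pairSimilarity(df$protein_id, df$molecule_id, protein_id,
                            molecule_id, Kp, Km)
      utils::head(.rankBySimilarity(df, sim), nWant)
    } else {
      df[withSeed(seed + match(what, c("positive", "negative")),
                  sample.int(nrow(df), nWant)), , drop = FALSE]
    }
  }
  ep <- takeTop(extra, nExtraPos, "positive")
  nNeg <- roundHalfUp(extraNegRatio * nrow(ep))
  en <- ep[0, , drop = FALSE]
  if (nNeg > 0) {
    # non-positive extra-task pairs; enumerated lazily over the entity grid
    prot <- setdiff(proteinIds(dataset), protein_id)
    mol <- setdiff(moleculeIds(dataset), molecule_id)
    grid <- expand.grid(protein_id = prot, molecule_id = mol,
                        stringsAsFactors = FALSE)
    grid <- grid[!.pairKeys(grid) %in% .pairKeys(dataset@positives), ,
                 drop = FALSE]
    en <- takeTop(grid, nNeg, "negative")
  }
  rownames(ep) <- rownames(en) <- NULL
  list(positives = ep, negatives = en)
}

#' Dataset-wide percentile similarity thresholds
#'
#' The theta-th percentiles of the off-diagonal protein and molecule
#' similarity distributions (self-similarities excluded), computed once per
#' dataset.
#'
#' @param Kp,Km entity kernels.
#' @param theta percentile in [0, 100].
#' @return list(protein = threshold, molecule = threshold).
#' @export
thetaThresholds <- function(Kp, Km, theta) {
  stopifnot(theta >= 0, theta <= 100)
  off <- function(K) K@values[row(K@values) != col(K@values)]
  list(protein = stats::quantile(off(Kp), theta / 100, names = FALSE),
       molecule = stats::quantile(off(Km), theta / 100, names = FALSE))
}

#' Percentile similarity filter on training pairs
#'
#' Keeps pairs whose similarity to the query is strictly below the
#' theta-th percentile thresholds on both axes; theta = 100 disables the
#' filter (everything kept), theta = 0 keeps nothing. An axis on which the
#' candidate equals the query entity (intra-task pairs) is exempt, since its
#' self-similarity is maximal by construction.
#'
#' @param pairs data.frame(protein_id, molecule_id).
#' @param protein_id,molecule_id the query pair.
#' @param Kp,Km entity kernels.
#' @param theta percentile in [0, 100].
#' @return the filtered data.frame.
#' @export
applyThetaFilter <- function(pairs, protein_id, molecule_id, Kp, Km, theta) {
  if (theta >= 100 || nrow(pairs) == 0) return(pairs)
  thr <- thetaThresholds(Kp, Km, theta)
  kp <- kernelValue(Kp, pairs$protein_id,
                    rep(protein_id, nrow(pairs)))
  km <- kernelValue(Km, pairs$molecule_id,
                    rep(molecule_id, nrow(pairs)))
  okP <- pairs$protein_id == protein_id | kp < thr$protein
  okM <- pairs$molecule_id == molecule_id | km < thr$molecule
  out <- pairs[okP & okM, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted-nearest-neighbor interaction profile
#'
#' For an (orphan) entity, neighbors with at least one known interaction
#' are ranked by decreasing kernel similarity and their binary interaction
#' profiles summed with geometric rank decay \code{T^(rank-1)}; the result
#' is clipped to [0, 1].
#'
#' @param entity_id the entity to profile.
#' @param axis \code{"molecule"} or \code{"protein"}.
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param K the kernel on the entity's axis.
#' @param T rank decay in (0, 1).
#' @return named numeric vector over the opposite-axis entities.
#' @export
wnnProfile <- function(entity_id, axis = c("molecule", "protein"), dataset,
                       K, T = 0.8) {
  axis <- match.arg(axis)
  stopifnot(T > 0, T < 1)
  pos <- dataset@positives
  if (axis == "molecule") {
    own <- moleculeIds(dataset)
    opp <- proteinIds(dataset)
    ownCol <- "molecule_id"; oppCol <- "protein_id"
  } else {
    own <- proteinIds(dataset)
    opp <- moleculeIds(dataset)
    ownCol <- "protein_id"; oppCol <- "molecule_id"
  }
  nonOrphan <- setdiff(unique(pos[[ownCol]]), entity_id)
  if (!length(nonOrphan))
    stop("all neighbors of ", entity_id, " are orphan: WNN profile undefined")
  sim <- kernelValue(K, nonOrphan, rep(entity_id, length(nonOrphan)))
  ord <- order(-sim, nonOrphan)
  profile <- setNames(numeric(length(opp)), opp)
  for (r in seq_along(ord)) {
    nb <- nonOrphan[ord[r]]
    partners <- pos[[oppCol]][pos[[ownCol]] == nb]
    profile[partners] <- profile[partners] + T^(r - 1)
  }
  pmin(profile, 1)
}

#' Build the per-query reduced training set
#'
#' Assembles the MT-intra / NN-MT / RN-MT training set for one query pair:
#' intra-task positives (theta-filtered when configured), WNN
#' pseudo-positives when the query's protein or molecule is orphan and
#' \code{wnn} is on, sampled intra-task negatives, and (for nn/rn modes)
#' extra-task positives and negatives. The query pair is never included and
#' duplicates are removed. An empty result is an error ("untrainable
#' query").
#'
#' @param protein_id,molecule_id the query pair.
#' @param dataset an \linkS4class{InteractionDataset}; its positives are the
#'   training-visible interactions (exclude test information upstream).
#' @param Kp,Km entity kernels.
#' @param config a \linkS4class{TrainConfig}.
#' @return data.frame(protein_id, molecule_id, y, origin) with origin in
#'   intra+, intra-, extra+, extra-, wnn+.
#' @export
buildTrainSet <- function(protein_id, molecule_id, dataset, Kp, Km, config) {
  validObject(config)
  qseed <- deriveSeed(config@seed, protein_id, molecule_id)
  intraPos <- intraTaskPairs(protein_id, molecule_id, dataset)
  if (!is.na(config@theta))
    intraPos <- applyThetaFilter(intraPos, protein_id, molecule_id, Kp, Km,
                                 config@theta)
  wnnPos <- intraPos[0, , drop = FALSE]
  if (config@wnn) {
    pos <- dataset@positives
    orphanP <- !protein_id %in% pos$protein_id
    orphanM <- !molecule_id %in% pos$molecule_id
    if (orphanM) {
      prof <- wnnProfile(molecule_id, "molecule", dataset, Km,
                         config@wnnDecay)
      hits <- names(prof)[prof >= config@wnnThreshold]
      hits <- setdiff(hits, protein_id)
      if (length(hits))
        wnnPos <- rbind(wnnPos, data.frame(protein_id = hits,
                                           molecule_id = molecule_id))
    }
    if (orphanP) {
      prof <- wnnProfile(protein_id, "protein", dataset, Kp,
                         config@wnnDecay)
      hits <- names(prof)[prof >= config@wnnThreshold]
      hits <- setdiff(hits, molecule_id)
      if (length(hits))
        wnnPos <- rbind(wnnPos, data.frame(protein_id = protein_id,
                                           molecule_id = hits))
    }
  }
  nPlus <- nrow(intraPos) + nrow(wnnPos)
  intraNeg <- intraPos[0, , drop = FALSE]
  if (nPlus > 0) {
    # WNN pseudo-positives count as intra-task positives for n- sizing
    wnnAug <- dataset
    if (nrow(wnnPos))
      wnnAug@positives <- unique(rbind(dataset@positives, wnnPos))
    intraNeg <- sampleIntraNegatives(protein_id, molecule_id, wnnAug,
                                     nPlus, config@negPosRatio, qseed,
                                     config@negBothAxes)
    if (!is.na(config@theta) && config@thetaFilterNegatives)
      intraNeg <- applyThetaFilter(intraNeg, protein_id, molecule_id, Kp, Km,
                                   config@theta)
  }
  extraPos <- intraPos[0, , drop = FALSE]
  extraNeg <- intraPos[0, , drop = FALSE]
  if (config@mode %in% c("nn_mt", "rn_mt") && config@nExtraPos > 0) {
    pool <- NULL
    if (!is.na(config@theta) && config@thetaScope == "intra_and_extra")
      pool <- applyThetaFilter(dataset@positives, protein_id, molecule_id,
                               Kp, Km, config@theta)
    ex <- selectExtraTask(protein_id, molecule_id, dataset, Kp, Km,
                          mode = config@mode, nExtraPos = config@nExtraPos,
                          extraNegRatio = config@extraNegRatio, seed = qseed,
                          positivePool = pool)
    extraPos <- ex$positives
    extraNeg <- ex$negatives
  }
  tag <- function(df, y, origin) {
    if (!nrow(df))
      return(data.frame(protein_id = character(), molecule_id = character(),
                        y = numeric(), origin = character()))
    data.frame(protein_id = df$protein_id, molecule_id = df$molecule_id,
               y = y, origin = origin)
  }
  out <- rbind(tag(intraPos, 1, "intra+"), tag(wnnPos, 1, "wnn+"),
               tag(intraNeg, -1, "intra-"), tag(extraPos, 1, "extra+"),
               tag(extraNeg, -1, "extra-"))
  out <- out[!(out$protein_id == protein_id &
                 out$molecule_id == molecule_id), , drop = FALSE]
  out <- out[!duplicated(.pairKeys(out)), , drop = FALSE]
  if (nrow(out) == 0)
    stop("untrainable query (", protein_id, ", ", molecule_id,
         "): empty training set")
  rownames(out) <- NULL
  out
}

#' Serialize a training set to TSV
#'
#' @param trainSet data.frame from \code{\link{buildTrainSet}}.
#' @param path output file.
#' @export
writeTrainSet <- function(trainSet, path) {
  utils::write.table(trainSet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
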