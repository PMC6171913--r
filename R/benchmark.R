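# Pipeline orchestration: sample assembly, fold construction, per-query
# training-set building, SVM fitting, scoring and aggregation, with
# provenance and runtime leakage checks.

# cheap deterministic fingerprint for provenance records
.kernelDigest <- function(K) {
  v <- K@values
  sprintf("%dx%d:%.10e", nrow(v), ncol(v),
          sum(v * seq_along(v)) / length(v))
}

#' Assemble evaluation samples (positives + sampled negatives)
#'
#' All dataset positives plus \code{negPerPos} times as many implicit
#' negatives drawn uniformly without replacement (seeded), labeled -1.
#'
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param negPerPos negatives per positive in the evaluation set.
#' @param seed RNG seed.
#' @return data.frame(protein_id, molecule_id, y).
#' @export
makeEvaluationSamples <- function(dataset, negPerPos = 1, seed = 1L) {
  pos <- dataset@positives
  pos$y <- 1
  grid <- expand.grid(protein_id = proteinIds(dataset),
                      molecule_id = moleculeIds(dataset),
                      stringsAsFactors = FALSE)
  grid <- grid[!.pairKeys(grid) %in% .pairKeys(pos), , drop = FALSE]
  nNeg <- min(roundHalfUp(negPerPos * nrow(pos)), nrow(grid))
  neg <- grid[withSeed(seed, sample.int(nrow(grid), nNeg)), , drop = FALSE]
  neg$y <- -1
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

# score one query against the training-visible dataset; returns the decision
# score or NA when the query is untrainable
.scoreQuery <- function(protein_id, molecule_id, visible, Kp, Km, config, C,
                        orphanAxes = character(), KpSel = Kp, KmSel = Km) {
  ts <- tryCatch(buildTrainSet(protein_id, molecule_id, visible, KpSel,
                               KmSel, config),
                 error = function(e) NULL)
  if (is.null(ts) || length(unique(ts$y)) < 2) return(NA_real_)
  if (any(ts$protein_id == protein_id & ts$molecule_id == molecule_id))
    stop("leakage: query pair present in its own training set")
  # WNN pseudo-positives are imputed from training-visible data only, so
  # sharing the orphan query's entity is their purpose, not leakage
  posRows <- ts$y == 1 & ts$origin != "wnn+"
  if ("molecule" %in% orphanAxes &&
      any(posRows & ts$molecule_id == molecule_id))
    stop("leakage: positive training pair shares the orphan query molecule")
  if ("protein" %in% orphanAxes &&
      any(posRows & ts$protein_id == protein_id))
    stop("leakage: positive training pair shares the orphan query protein")
  model <- kronSvmFit(ts[, c("protein_id", "molecule_id", "y")], Kp, Km, C)
  kronSvmDecision(model, data.frame(protein_id = protein_id,
                                    molecule_id = molecule_id),
                  Kp, Km)$score
}

#' Run a cross-validated interaction-prediction benchmark
#'
#' For each CV split, a per-query training set is built from the
#' training-visible positives (the pool's positive samples), a Kronecker
#' pair-kernel SVM is fitted and the test pair scored; ROC-AUC and AUPR are
#' aggregated over folds (pooled over all left-out pairs for LOO schemes).
#' Under orphan schemes a runtime check fails the run if a positive training
#' pair shares an entity with its test pair.
#'
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param Kp,Km entity kernels.
#' @param samples evaluation samples (see
#'   \code{\link{makeEvaluationSamples}}); built with \code{negPerPos = 1}
#'   when NULL.
#' @param scheme a \code{\link{makeFolds}} scheme, or \code{"loo"} /
#'   \code{"loo_double_orphan"}.
#' @param K fold count for K-fold schemes.
#' @param config a \linkS4class{TrainConfig}.
#' @param C SVM box constraint.
#' @param seed master seed (folds, negative sampling, per-query draws).
#' @param evalIndices optional subset of sample indices to score (all
#'   samples still shape folds and training visibility).
#' @param KpSel,KmSel kernels used for nearest-neighbor selection and theta
#'   filtering in \code{\link{buildTrainSet}}. Default to \code{Kp}/\code{Km};
#'   pass normalized-but-uncentered kernels so that neighbor ranking uses
#'   nonnegative similarities (the product of two centered values is positive
#'   for pairs dissimilar on both axes, which corrupts "nearest").
#' @return list with per-fold metrics, pooled/aggregated auc and aupr
#'   (mean, sd), the scored predictions, failure count, and provenance.
#' @export
runBenchmark <- function(dataset, Kp, Km, samples = NULL, scheme = "random",
                         K = 5, config = trainConfig(), C = 1, seed = 1L,
                         evalIndices = NULL, KpSel = Kp, KmSel = Km) {
  if (is.null(samples))
    samples <- makeEvaluationSamples(dataset, 1, deriveSeed(seed, "samples"))
  config@seed <- as.integer(deriveSeed(seed, "train"))
  orphan <- c(if (grepl("orphan_ligand|double_orphan", scheme)) "molecule",
              if (grepl("orphan_protein|double_orphan", scheme)) "protein")
  visibleFor <- function(trainIdx) {
    posTrain <- samples[trainIdx, , drop = FALSE]
    posTrain <- posTrain[posTrain$y == 1, c("protein_id", "molecule_id"),
                         drop = FALSE]
    ds <- dataset
    ds@positives <- posTrain
    ds
  }
  preds <- data.frame()
  if (scheme %in% c("loo", "loo_double_orphan")) {
    splits <- looSplits(samples, orphanMode = scheme == "loo_double_orphan")
    if (!is.null(evalIndices))
      splits <- splits[vapply(splits, `[[`, 0L, "test") %in% evalIndices]
    for (sp in splits) {
      q <- samples[sp$test, ]
      sc <- .scoreQuery(q$protein_id, q$molecule_id, visibleFor(sp$train),
                        Kp, Km, config, C, orphan, KpSel, KmSel)
      preds <- rbind(preds, data.frame(protein_id = q$protein_id,
                                       molecule_id = q$molecule_id,
                                       y = q$y, score = sc, fold = 1L))
    }
  } else {
    folds <- makeFolds(samples, scheme, K, deriveSeed(seed, "folds"),
                       Kp, Km)
    for (f in seq_along(folds@folds)) {
      testIdx <- folds@folds[[f]]
      if (!is.null(evalIndices)) testIdx <- intersect(testIdx, evalIndices)
      if (!length(testIdx)) next
      visible <- visibleFor(trainPool(folds, f))
      for (i in testIdx) {
        q <- samples[i, ]
        sc <- .scoreQuery(q$protein_id, q$molecule_id, visible, Kp, Km,
                          config, C, orphan, KpSel, KmSel)
        preds <- rbind(preds, data.frame(protein_id = q$protein_id,
                                         molecule_id = q$molecule_id,
                                         y = q$y, score = sc, fold = f))
      }
    }
  }
  nFail <- sum(is.na(preds$score))
  # untrainable queries are scored at the midpoint rather than dropped
  preds$score[is.na(preds$score)] <- 0
  perFold <- do.call(rbind, lapply(split(preds, preds$fold), function(df) {
    data.frame(fold = df$fold[1],
               auc = if (length(unique(df$y)) == 2)
                 rocAuc(df$score, df$y) else NA_real_,
               aupr = if (any(df$y == 1))
                 aupr(df$score, df$y) else NA_real_,
               n = nrow(df))
  }))
  aggOf <- function(col) {
    v <- perFold[[col]][!is.na(perFold[[col]])]
    if (length(v)) aggregateScores(v) else c(mean = NA_real_, sd = NA_real_)
  }
  list(scheme = scheme, seed = seed, C = C,
       config = list(mode = config@mode, negPosRatio = config@negPosRatio,
                     nExtraPos = config@nExtraPos,
                     extraNegRatio = config@extraNegRatio,
                     theta = config@theta, wnn = config@wnn),
       perFold = perFold, auc = aggOf("auc"), aupr = aggOf("aupr"),
       predictions = preds, nUntrainable = nFail,
       provenance = list(kernelProtein = .kernelDigest(Kp),
                         kernelMolecule = .kernelDigest(Km),
                         nSamples = nrow(samples)))
}

#' Write a benchmark report to JSON
#'
#' @param report result of \code{\link{runBenchmark}}.
#' @param path output file.
#' @export
writeBenchmarkReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
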