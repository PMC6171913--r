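# Fold systems: random (stratified), orphan-ligand / orphan-protein /
# double-orphan, their clustered variants, leave-one-out, and nested CV for
# hyperparameter selection.

.SCHEMES <- c("random", "orphan_ligand", "orphan_protein", "double_orphan",
              "clustered_random", "clustered_orphan_ligand",
              "clustered_orphan_protein", "clustered_double_orphan", "loo")

# random K-group partition of entity ids
.randomGroups <- function(ids, K) {
  if (K > length(ids))
    stop("K = ", K, " exceeds entity count ", length(ids))
  g <- rep(seq_len(K), length.out = length(ids))
  split(ids, sample(g))
}

# similarity clusters from a normalized kernel: d = sqrt(2 - 2K), average
# linkage, cut at K clusters, ordered by size descending
.clusterGroups <- function(ids, K, kernel) {
  v <- kernel@values[ids, ids]
  d <- sqrt(pmax(2 - 2 * v, 0))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = K)
  groups <- split(ids, cl)
  if (any(vapply(groups, length, 0L) == 0))
    stop("empty cluster when cutting at K = ", K)
  groups[order(-vapply(groups, length, 0L))]
}

#' Construct cross-validation folds over pair samples
#'
#' Schemes: \code{random} shuffles pairs stratified by label so folds are
#' balanced in positives and negatives. \code{orphan_ligand}
#' (\code{orphan_protein}) partitions molecules (proteins) into K groups;
#' fold f holds every sample whose molecule (protein) is in group f, so test
#' entities are absent from all other folds. \code{double_orphan} crosses
#' the two partitions into K^2 test folds; fold (i, j)'s training pool is
#' every sample whose protein group differs from i AND molecule group
#' differs from j. Clustered variants replace random entity groups by
#' hierarchical-clustering groups (distance \code{sqrt(2 - 2K)}, average
#' linkage); clustered random/orphan folds pair protein cluster i with
#' molecule cluster i (clusters ordered by size descending) and cover only
#' samples whose entities fall in matched clusters.
#'
#' @param samples data.frame(protein_id, molecule_id, y).
#' @param scheme one of the scheme names above (\code{"loo"} excluded; see
#'   \code{\link{looSplits}}).
#' @param K entity-group count (default 5).
#' @param seed RNG seed.
#' @param Kp,Km normalized entity kernels; required for clustered schemes.
#' @return a \linkS4class{FoldAssignment}.
#' @export
makeFolds <- function(samples, scheme = .SCHEMES[1], K = 5, seed = 1L,
                      Kp = NULL, Km = NULL) {
  scheme <- match.arg(scheme, setdiff(.SCHEMES, "loo"))
  n <- nrow(samples)
  K <- as.integer(K)
  if (K < 2) stop("K must be >= 2")
  clustered <- startsWith(scheme, "clustered_")
  base <- sub("^clustered_", "", scheme)
  if (clustered && (is.null(Kp) || is.null(Km)))
    stop("clustered schemes require both kernels")
  prots <- unique(samples$protein_id)
  mols <- unique(samples$molecule_id)
  out <- withSeed(seed, {
    pGroups <- if (clustered) .clusterGroups(prots, K, Kp)
               else .randomGroups(prots, K)
    mGroups <- if (clustered) .clusterGroups(mols, K, Km)
               else .randomGroups(mols, K)
    pOf <- setNames(rep(seq_len(K), lengths(pGroups)), unlist(pGroups))
    mOf <- setNames(rep(seq_len(K), lengths(mGroups)), unlist(mGroups))
    pg <- pOf[samples$protein_id]
    mg <- mOf[samples$molecule_id]
    if (base == "random" && !clustered) {
      foldOf <- integer(n)
      for (lab in unique(samples$y)) {
        idx <- sample(which(samples$y == lab))
        foldOf[idx] <- rep(seq_len(K), length.out = length(idx))
      }
      list(folds = split(seq_len(n), factor(foldOf, levels = seq_len(K))),
           pools = list())
    } else if (base == "random") {
      folds <- lapply(seq_len(K), function(f)
        which(pg == f & mg == f))
      list(folds = folds, pools = list())
    } else if (base == "orphan_ligand") {
      list(folds = split(seq_len(n), factor(mg, levels = seq_len(K))),
           pools = list())
    } else if (base == "orphan_protein") {
      list(folds = split(seq_len(n), factor(pg, levels = seq_len(K))),
           pools = list())
    } else {  # double_orphan: K^2 folds, entity-disjoint training pools
      folds <- list(); pools <- list()
      for (i in seq_len(K)) for (j in seq_len(K)) {
        folds[[length(folds) + 1L]] <- which(pg == i & mg == j)
        pools[[length(pools) + 1L]] <- which(pg != i & mg != j)
      }
      list(folds = folds, pools = pools)
    }
  })
  new("FoldAssignment", scheme = scheme,
      folds = lapply(unname(out$folds), as.integer),
      trainPools = lapply(unname(out$pools), as.integer),
      K = K, seed = as.integer(seed), nSamples = as.integer(n))
}

#' Leave-one-out splits
#'
#' One split per sample. In \code{orphanMode}, every training sample sharing
#' the test pair's protein or molecule is removed from the pool
#' (double-orphan LOO).
#'
#' @param samples data.frame(protein_id, molecule_id, y) with >= 2 rows.
#' @param orphanMode drop train pairs sharing either test entity.
#' @return list of \code{list(test = index, train = indices)}.
#' @export
looSplits <- function(samples, orphanMode = FALSE) {
  n <- nrow(samples)
  if (n < 2) stop("leave-one-out needs at least 2 samples")
  lapply(seq_len(n), function(i) {
    train <- setdiff(seq_len(n), i)
    if (orphanMode)
      train <- train[samples$protein_id[train] != samples$protein_id[i] &
                       samples$molecule_id[train] != samples$molecule_id[i]]
    list(test = i, train = train)
  })
}

#' Nested cross-validation for hyperparameter selection
#'
#' K-fold outer CV; inside each outer training set, a (K-1)-fold inner CV
#' scores every grid point and the best (highest mean inner score) is refit
#' on the full outer-train and scored on the outer-test fold. Grid points on
#' which the trainer fails are excluded from selection with a message.
#'
#' @param samples data.frame(protein_id, molecule_id, y).
#' @param grid list of configuration objects (one per grid point).
#' @param trainer function(trainSamples, config) -> model object.
#' @param scorer function(model, testSamples) -> numeric score (higher is
#'   better, e.g. AUPR).
#' @param K outer fold count (inner CV uses K - 1 folds).
#' @param seed RNG seed.
#' @param scheme fold scheme for outer and inner folds.
#' @param Kp,Km kernels, forwarded to \code{\link{makeFolds}} for clustered
#'   schemes.
#' @return list(bestConfigs, outerScores, mean, sd).
#' @export
nestedCv <- function(samples, grid, trainer, scorer, K = 5, seed = 1L,
                     scheme = "random", Kp = NULL, Km = NULL) {
  if (!length(grid)) stop("empty hyperparameter grid")
  outer <- makeFolds(samples, scheme, K, seed, Kp, Km)
  outerScores <- numeric(0)
  bestConfigs <- list()
  for (f in seq_along(outer@folds)) {
    testIdx <- outer@folds[[f]]
    trainIdx <- trainPool(outer, f)
    if (!length(testIdx) || !length(trainIdx)) next
    trainSamples <- samples[trainIdx, , drop = FALSE]
    gridScores <- rep(NA_real_, length(grid))
    if (length(grid) == 1) {
      gridScores[1] <- 0
    } else {
      inner <- makeFolds(trainSamples, scheme, max(K - 1, 2),
                         deriveSeed(seed, "inner", f), Kp, Km)
      for (g in seq_along(grid)) {
        sc <- c()
        ok <- TRUE
        for (fi in seq_along(inner@folds)) {
          ti <- inner@folds[[fi]]
          tr <- trainPool(inner, fi)
          if (!length(ti) || !length(tr)) next
          res <- tryCatch({
            mod <- trainer(trainSamples[tr, , drop = FALSE], grid[[g]])
            scorer(mod, trainSamples[ti, , drop = FALSE])
          }, error = function(e) {
            message("grid point ", g, " failed on inner fold ", fi, ": ",
                    conditionMessage(e))
            NA_real_
          })
          if (is.na(res)) { ok <- FALSE; break }
          sc <- c(sc, res)
        }
        if (ok && length(sc)) gridScores[g] <- mean(sc)
      }
      if (all(is.na(gridScores)))
        stop("every grid point failed in inner CV of outer fold ", f)
    }
    best <- which.max(gridScores)
    mod <- trainer(trainSamples, grid[[best]])
    outerScores <- c(outerScores,
                     scorer(mod, samples[testIdx, , drop = FALSE]))
    bestConfigs[[length(bestConfigs) + 1L]] <- grid[[best]]
  }
  agg <- aggregateScores(outerScores)
  list(bestConfigs = bestConfigs, outerScores = outerScores,
       mean = agg["mean"], sd = agg["sd"])
}

#' Serialize a FoldAssignment to TSV
#'
#' @param folds a \linkS4class{FoldAssignment}.
#' @param samples the sample table the indices refer to.
#' @param path output file.
#' @export
writeFolds <- function(folds, samples, path) {
  rows <- do.call(rbind, lapply(seq_along(folds@folds), function(f) {
    idx <- folds@folds[[f]]
    if (!length(idx)) return(NULL)
    data.frame(protein_id = samples$protein_id[idx],
               molecule_id = samples$molecule_id[idx], fold = f)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
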