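# Ranking metrics (ROC-AUC, AUPR), degree-balanced negative test sets, and
# score aggregation.

.checkPredictions <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(!is.finite(scores))) stop("non-finite prediction score")
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1/+1")
}

#' ROC-AUC (Mann-Whitney formulation)
#'
#' Probability that a random positive outranks a random negative; ties are
#' credited 0.5, via midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels in -1/+1 (both classes required).
#' @return value in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  .checkPredictions(scores, labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == -1)
  if (nPos == 0 || nNeg == 0)
    stop("ROC-AUC undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (step integration)
#'
#' Scores are swept from high to low (tied scores grouped into one
#' threshold); the area accumulates precision at each recall step,
#' \eqn{\sum_k (R_k - R_{k-1}) P_k}, with no linear interpolation between PR
#' points.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels in -1/+1 (at least one positive required).
#' @return value in (0, 1].
#' @export
aupr <- function(scores, labels) {
  .checkPredictions(scores, labels)
  nPos <- sum(labels == 1)
  if (nPos == 0) stop("AUPR undefined with no positives")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == -1)
  # keep only the last index of each tied-score block
  lastOfBlock <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[lastOfBlock]; fp <- fp[lastOfBlock]
  recall <- tp / nPos
  precision <- tp / (tp + fp)
  dR <- diff(c(0, recall))
  sum(dR * precision)
}

#' Degree-balanced negative test sets
#'
#' Draws \code{nSets} sets of negative pairs, each with as many pairs as
#' there are positives, disjoint from the positives, and with every
#' protein's and molecule's negative degree equal to its positive degree.
#' Sets are constructed by shuffled stub pairing followed by 2-swap repair
#' of duplicate/positive collisions; if repair does not converge the
#' best-effort set is returned and the per-entity degree deviations are
#' attached as \code{attr(set, "deviations")}.
#'
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param nSets number of sets to draw (default 4).
#' @param seed RNG seed.
#' @param maxSwaps repair cap per set.
#' @return list of data.frame(protein_id, molecule_id), each possibly with a
#'   \code{"deviations"} attribute when infeasible.
#' @export
balancedNegativeSets <- function(dataset, nSets = 4, seed = 1L,
                                 maxSwaps = 1e5) {
  pos <- dataset@positives
  if (!nrow(pos)) stop("no positives to balance against")
  posKeys <- .pairKeys(pos)
  makeSet <- function(setSeed) withSeed(setSeed, {
    pStubs <- pos$protein_id
    mStubs <- sample(pos$molecule_id)
    bad <- function(p, m) {
      k <- pairKey(p, m)
      k %in% posKeys | duplicated(k) | k %in% k[duplicated(k)]
    }
    swaps <- 0
    repeat {
      badIdx <- which(bad(pStubs, mStubs))
      if (!length(badIdx) || swaps >= maxSwaps) break
      i <- badIdx[1]
      j <- sample.int(length(mStubs), 1)
      tmp <- mStubs[i]; mStubs[i] <- mStubs[j]; mStubs[j] <- tmp
      swaps <- swaps + 1
    }
    out <- data.frame(protein_id = pStubs, molecule_id = mStubs)
    badIdx <- which(bad(pStubs, mStubs))
    if (length(badIdx)) {
      # infeasible (or unrepaired): drop offending pairs, report deviations
      out <- out[-badIdx, , drop = FALSE]
      devP <- table(pos$protein_id)[unique(pos$protein_id)] -
        table(factor(out$protein_id, levels = unique(pos$protein_id)))
      devM <- table(pos$molecule_id)[unique(pos$molecule_id)] -
        table(factor(out$molecule_id, levels = unique(pos$molecule_id)))
      attr(out, "deviations") <- list(protein = devP[devP != 0],
                                      molecule = devM[devM != 0])
      warning("degree-balanced negative set infeasible or unrepaired; ",
              "returning best effort with deviation report")
    }
    rownames(out) <- NULL
    out
  })
  lapply(seq_len(nSets), function(s) makeSet(deriveSeed(seed, "negset", s)))
}

#' Aggregate per-fold scores
#'
#' @param scores numeric vector (>= 1 value).
#' @return c(mean =, sd =) with the population standard deviation
#'   (denominator n).
#' @export
aggregateScores <- function(scores) {
  stopifnot(length(scores) >= 1)
  m <- mean(scores)
  c(mean = m, sd = sqrt(mean((scores - m)^2)))
}

#' Write scored predictions to TSV
#'
#' @param predictions data.frame(protein_id, molecule_id, score, label).
#' @param path output file.
#' @export
writePredictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
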