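# Accessors and show methods for the core classes.

#' @rdname KernelMatrix-class
#' @param x a KernelMatrix
#' @export
kernelIds <- function(x) x@ids

#' @rdname KernelMatrix-class
#' @export
kernelValues <- function(x) x@values

#' @rdname KernelMatrix-class
#' @export
isCentered <- function(x) x@centered

#' @rdname KernelMatrix-class
#' @export
isNormalized <- function(x) x@normalized

#' Look up kernel values by entity id
#'
#' @param K a \linkS4class{KernelMatrix}
#' @param i,j entity identifiers (vectors recycle as in matrix indexing).
#' @return numeric vector/matrix of similarities.
#' @export
kernelValue <- function(K, i, j) {
  miss <- setdiff(unique(c(i, j)), K@ids)
  if (length(miss))
    stop("entity id(s) missing from kernel matrix: ",
         paste(miss, collapse = ", "))
  K@values[cbind(match(i, K@ids), match(j, K@ids))]
}

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d entities%s%s\n", length(object@ids),
              if (object@centered) ", centered" else "",
              if (object@normalized) ", normalized" else ""))
  if (length(object@ids))
    cat("  ids:", paste(utils::head(object@ids, 5), collapse = ", "),
        if (length(object@ids) > 5) "..." else "", "\n")
})

#' @rdname InteractionDataset-class
#' @param x an InteractionDataset
#' @export
datasetProteins <- function(x) x@proteins

#' @rdname InteractionDataset-class
#' @export
datasetMolecules <- function(x) x@molecules

#' @rdname InteractionDataset-class
#' @export
positivePairs <- function(x) x@positives

#' @rdname InteractionDataset-class
#' @export
explicitNegatives <- function(x) x@explicitNegatives

#' @rdname InteractionDataset-class
#' @export
datasetHierarchy <- function(x) x@hierarchy

#' @rdname InteractionDataset-class
#' @export
proteinIds <- function(x) names(x@proteins)

#' @rdname InteractionDataset-class
#' @export
moleculeIds <- function(x) names(x@molecules)

setMethod("show", "InteractionDataset", function(object) {
  cat(sprintf(paste0("InteractionDataset: %d proteins, %d molecules, ",
                     "%d positives, %d explicit negatives%s\n"),
              length(object@proteins), length(object@molecules),
              nrow(object@positives), nrow(object@explicitNegatives),
              if (!is.null(object@hierarchy)) ", with hierarchy" else ""))
})

setMethod("show", "MoleculeGraph", function(object) {
  cat(sprintf("MoleculeGraph %s: %d atoms, %d bonds [%s]\n",
              object@moleculeId, length(object@atoms), nrow(object@bonds),
              paste(object@atoms, collapse = "")))
})

setMethod("show", "KronSVMModel", function(object) {
  cat(sprintf("KronSVMModel (%s): %d support pairs, b = %.4g, C = %g\n",
              object@kind, nrow(object@support), object@b, object@C))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment (%s): %d folds over %d samples, seed %d\n",
              object@scheme, length(object@folds), object@nSamples,
              object@seed))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: mode=%s n-/n+=%g ne+=%g ne-/ne+=%g ",
                     "theta=%s (%s) wnn=%s seed=%d\n"),
              object@mode, object@negPosRatio, object@nExtraPos,
              object@extraNegRatio,
              if (is.na(object@theta)) "off" else object@theta,
              object@thetaScope, object@wnn, object@seed))
})

#' @rdname KronSVMModel-class
#' @param x a KronSVMModel
#' @export
supportPairs <- function(x) x@support

#' @rdname KronSVMModel-class
#' @export
modelBias <- function(x) x@b

#' @rdname FoldAssignment-class
#' @param x a FoldAssignment
#' @export
foldIndices <- function(x) x@folds

#' Training pool for a fold
#'
#' Returns the indices eligible for training against test fold \code{f}:
#' the fold's dedicated pool when the scheme defines one (double-orphan
#' schemes), otherwise the complement of the fold.
#'
#' @param x a \linkS4class{FoldAssignment}
#' @param f fold number
#' @export
trainPool <- function(x, f) {
  if (length(x@trainPools)) x@trainPools[[f]]
  else setdiff(seq_len(x@nSamples), x@folds[[f]])
}
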