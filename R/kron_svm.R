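# Multi-task SVM in (protein, molecule) pair space using the factorized
# Kronecker pair kernel, plus the ligand-based / target-based single-task
# baselines. The quadratic program is solved by kernlab's SMO (C-svc on a
# precomputed Gram matrix); dual feasibility is asserted after every fit.

#' Kronecker pair-kernel value
#'
#' Similarity between two (protein, molecule) pairs: the product
#' \code{Km(m, m') * Kp(p, p')}. Never materializes the np x np Kronecker
#' matrix.
#'
#' @param p,m,p2,m2 entity ids of the two pairs.
#' @param Kp,Km protein and molecule \linkS4class{KernelMatrix} objects.
#' @return scalar similarity.
#' @export
pairKernelValue <- function(p, m, p2, m2, Kp, Km) {
  kernelValue(Km, m, m2) * kernelValue(Kp, p, p2)
}

# factorized Gram matrix of a set of pairs against another set
.pairGram <- function(p1, m1, p2, m2, Kp, Km) {
  miss <- c(setdiff(unique(c(p1, p2)), Kp@ids),
            setdiff(unique(c(m1, m2)), Km@ids))
  if (length(miss))
    stop("entity id(s) missing from kernel matrices: ",
         paste(miss, collapse = ", "))
  Kp@values[p1, p2, drop = FALSE] * Km@values[m1, m2, drop = FALSE]
}

# builds a KronSVMModel; the cost slot is assigned after new() because a
# named argument "C" would partially match new()'s Class formal
.newModel <- function(kind, support, b, C, taskEntity = NA_character_) {
  obj <- new("KronSVMModel", kind = kind, support = support, b = b,
             taskEntity = taskEntity)
  obj@C <- C
  validObject(obj)
  obj
}

# shared SMO fit on a precomputed Gram matrix; returns coef/alpha/b and
# checks the dual constraints 0 <= alpha <= C, |sum alpha_i y_i| <= 1e-6
.svmFitGram <- function(G, y, C, tol = 1e-6) {
  if (length(unique(y)) < 2)
    stop("single-class input: SVM training needs both classes")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  lmin <- min(eigen((G + t(G)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  if (lmin < -1e-6)
    warning(sprintf("training Gram matrix not PSD (lambda_min = %.3g)", lmin))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(G), y, type = "C-svc",
                       C = C, scaled = FALSE)
  coefs <- unlist(kernlab::coef(fit))
  idx <- unlist(kernlab::alphaindex(fit))
  b <- -kernlab::b(fit)   # decision form sum(coef * K) + b
  alpha <- abs(coefs)
  if (any(alpha < -1e-8) || any(alpha > C + 1e-6))
    stop("solver returned alpha outside [0, C]")
  if (abs(sum(coefs)) > tol)
    stop(sprintf("dual equality constraint violated: |sum alpha y| = %.3g",
                 abs(sum(coefs))))
  list(index = idx, coef = coefs, alpha = alpha, b = b)
}

#' Fit the Kronecker pair-kernel SVM
#'
#' Soft-margin C-SVM over (protein, molecule) pair samples with the
#' factorized Kronecker kernel. The training Gram matrix is computed
#' entry-wise from the two entity kernels.
#'
#' @param train data.frame with columns \code{protein_id},
#'   \code{molecule_id}, \code{y} (labels in -1/+1).
#' @param Kp,Km protein and molecule \linkS4class{KernelMatrix} objects.
#' @param C box constraint (> 0).
#' @return a \linkS4class{KronSVMModel} of kind \code{"pair"}.
#' @export
kronSvmFit <- function(train, Kp, Km, C = 1) {
  stopifnot(C > 0, nrow(train) >= 2)
  G <- .pairGram(train$protein_id, train$molecule_id,
                 train$protein_id, train$molecule_id, Kp, Km)
  sol <- .svmFitGram(G, train$y, C)
  sup <- train[sol$index, c("protein_id", "molecule_id", "y"), drop = FALSE]
  sup$alpha <- sol$alpha
  sup$coef <- sol$coef
  rownames(sup) <- NULL
  .newModel("pair", sup, sol$b, C)
}

#' Decision scores of a fitted model on query pairs
#'
#' Scores are \code{sum_i coef_i K_pair(query, support_i) + b}; the
#' predicted class is the sign of the score. Scores with magnitude below
#' 1e-8 are flagged ambiguous rather than silently signed.
#'
#' @param model a \linkS4class{KronSVMModel}.
#' @param queries data.frame with columns \code{protein_id},
#'   \code{molecule_id} (single-task models use only their task axis).
#' @param Kp,Km entity kernels; single-task models need only the kernel of
#'   their task axis.
#' @return data.frame with columns \code{protein_id}, \code{molecule_id},
#'   \code{score}, \code{class} (sign; 0 = ambiguous).
#' @export
kronSvmDecision <- function(model, queries, Kp = NULL, Km = NULL) {
  s <- model@support
  scores <- switch(model@kind,
    pair = {
      stopifnot(!is.null(Kp), !is.null(Km))
      G <- .pairGram(queries$protein_id, queries$molecule_id,
                     s$protein_id, s$molecule_id, Kp, Km)
      drop(G %*% s$coef) + model@b
    },
    ligand_based = {
      stopifnot(!is.null(Kp))
      miss <- setdiff(unique(queries$protein_id), Kp@ids)
      if (length(miss)) stop("protein id(s) missing from kernel: ",
                             paste(miss, collapse = ", "))
      drop(Kp@values[queries$protein_id, s$protein_id, drop = FALSE] %*%
             s$coef) + model@b
    },
    target_based = {
      stopifnot(!is.null(Km))
      miss <- setdiff(unique(queries$molecule_id), Km@ids)
      if (length(miss)) stop("molecule id(s) missing from kernel: ",
                             paste(miss, collapse = ", "))
      drop(Km@values[queries$molecule_id, s$molecule_id, drop = FALSE] %*%
             s$coef) + model@b
    },
    stop("unknown model kind ", model@kind))
  cls <- ifelse(abs(scores) < 1e-8, 0, sign(scores))
  data.frame(protein_id = queries$protein_id,
             molecule_id = queries$molecule_id,
             score = scores, class = cls, row.names = NULL)
}

#' Fit a single-task SVM baseline
#'
#' \code{ligand_based}: the task is one molecule; samples are its target /
#' non-target proteins and the SVM runs on the protein kernel.
#' \code{target_based}: the task is one protein; the SVM runs on the
#' molecule kernel. An entity with no training pairs is an orphan and the
#' single-task model is undefined.
#'
#' @param taskEntity the fixed entity id (molecule for ligand_based, protein
#'   for target_based).
#' @param axis \code{"ligand_based"} or \code{"target_based"}.
#' @param train data.frame(protein_id, molecule_id, y) restricted to the
#'   task entity's pairs.
#' @param K the kernel of the varying axis.
#' @param C box constraint.
#' @return a \linkS4class{KronSVMModel} of the given kind.
#' @export
singleTaskFit <- function(taskEntity, axis = c("ligand_based",
                                               "target_based"),
                          train, K, C = 1) {
  axis <- match.arg(axis)
  fixedCol <- if (axis == "ligand_based") "molecule_id" else "protein_id"
  varyCol <- if (axis == "ligand_based") "protein_id" else "molecule_id"
  train <- train[train[[fixedCol]] == taskEntity, , drop = FALSE]
  if (nrow(train) == 0)
    stop("single-task undefined for orphan entity ", taskEntity)
  if (length(unique(train$y)) < 2)
    stop("single-task training for ", taskEntity,
         " needs at least one sample per class")
  ids <- train[[varyCol]]
  miss <- setdiff(unique(ids), K@ids)
  if (length(miss)) stop("entity id(s) missing from kernel: ",
                         paste(miss, collapse = ", "))
  G <- K@values[ids, ids, drop = FALSE]
  sol <- .svmFitGram(G, train$y, C)
  sup <- train[sol$index, c("protein_id", "molecule_id", "y"), drop = FALSE]
  sup$alpha <- sol$alpha
  sup$coef <- sol$coef
  rownames(sup) <- NULL
  .newModel(axis, sup, sol$b, C, taskEntity)
}

#' Serialize a fitted model to JSON
#'
#' @param model a \linkS4class{KronSVMModel}.
#' @param path output file.
#' @export
writeModel <- function(model, path) {
  jsonlite::write_json(list(kind = model@kind, support = model@support,
                            b = model@b, C = model@C,
                            taskEntity = model@taskEntity),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON file written by \code{\link{writeModel}}.
#' @return a \linkS4class{KronSVMModel}.
#' @export
readModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .newModel(x$kind, as.data.frame(x$support), x$b, x$C,
            if (is.null(x$taskEntity)) NA_character_ else x$taskEntity)
}
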