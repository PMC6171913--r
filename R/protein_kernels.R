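# Protein sequence kernels: Smith-Waterman score kernel (with PSD repair),
# local-alignment kernel, substitution-neighborhood k-mer kernel, and the
# family-hierarchy kernel.

# substitution matrix by name, with the X row/column zeroed so the unknown
# residue scores 0 against everything
.substitutionMatrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0
    m[, "X"] <- 0
  }
  m
}

.checkProteinSeq <- function(s, what = "sequence") {
  if (length(s) != 1 || is.na(s) || nchar(s) == 0)
    stop("empty ", what)
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), .AA_ALPHABET)
  if (length(bad))
    stop("unknown residue(s) in ", what, ": ", paste(bad, collapse = ", "))
  invisible(ch)
}

#' Smith-Waterman local alignment score
#'
#' Optimal affine-gap local alignment score; a gap of length L costs
#' \code{o + L * e}. The unknown residue X scores 0 against everything.
#'
#' @param s1,s2 amino-acid sequence strings (non-empty).
#' @param o gap opening penalty (> 0).
#' @param e gap extension penalty (> 0).
#' @param substitutionMatrix matrix name (default \code{"BLOSUM62"}) or a
#'   numeric substitution matrix.
#' @return alignment score >= 0; symmetric in its sequence arguments.
#' @export
swScore <- function(s1, s2, o = 10, e = 0.5,
                    substitutionMatrix = "BLOSUM62") {
  .checkProteinSeq(s1, "first sequence")
  .checkProteinSeq(s2, "second sequence")
  sm <- if (is.character(substitutionMatrix))
    .substitutionMatrix(substitutionMatrix) else substitutionMatrix
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2), type = "local",
    substitutionMatrix = sm, gapOpening = o, gapExtension = e,
    scoreOnly = TRUE))
}

#' Repair a symmetric similarity matrix to positive semidefiniteness
#'
#' If the smallest eigenvalue is negative, its magnitude is added to every
#' diagonal entry; an already-PSD matrix is returned unchanged.
#'
#' @param raw symmetric numeric matrix (with entity dimnames) or a
#'   \linkS4class{KernelMatrix}.
#' @return a \linkS4class{KernelMatrix} that is PSD within -1e-8.
#' @export
psdRepair <- function(raw) {
  if (is(raw, "KernelMatrix")) {
    v <- raw@values; ids <- raw@ids
  } else {
    v <- as.matrix(raw)
    ids <- rownames(v)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(v)))
  }
  if (max(abs(v - t(v))) > 1e-8)
    stop("psdRepair requires a symmetric matrix")
  v <- (v + t(v)) / 2
  lmin <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < 0) diag(v) <- diag(v) + abs(lmin)
  dimnames(v) <- list(ids, ids)
  KernelMatrix(v, ids)
}

# pairwise log-sum-exp, -Inf-safe
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Local alignment (LA) kernel
#'
#' Sums \code{exp(beta * score)} over all local alignments of the two
#' sequences (dynamic programming in the log domain). Gap convention matches
#' \code{\link{swScore}}: a gap of length L scores \code{-(o + L * e)}, so
#' \code{log(laKernel)/beta} converges to the Smith-Waterman score as beta
#' grows.
#'
#' @param s1,s2 amino-acid sequence strings.
#' @param o,e gap opening/extension penalties (> 0).
#' @param beta inverse temperature (> 0).
#' @param substitutionMatrix matrix name or numeric matrix.
#' @param log return the log kernel value (always finite) instead of the
#'   kernel value itself.
#' @return kernel value > 0 (or its log). Overflow of the linear-scale value
#'   despite log-domain computation is an error.
#' @export
laKernel <- function(s1, s2, o = 20, e = 1, beta = 0.5,
                     substitutionMatrix = "BLOSUM62", log = FALSE) {
  stopifnot(beta > 0)
  c1 <- .checkProteinSeq(s1, "first sequence")
  c2 <- .checkProteinSeq(s2, "second sequence")
  sm <- if (is.character(substitutionMatrix))
    .substitutionMatrix(substitutionMatrix) else substitutionMatrix
  n <- length(c1); m <- length(c2)
  gapO <- -beta * (o + e)   # log-weight of opening a gap (length-1 cost)
  gapE <- -beta * e         # log-weight of extending a gap by one
  NEG <- -Inf
  M  <- matrix(NEG, n + 1, m + 1)
  X  <- matrix(NEG, n + 1, m + 1)
  Y  <- matrix(NEG, n + 1, m + 1)
  X2 <- matrix(NEG, n + 1, m + 1)
  Y2 <- matrix(NEG, n + 1, m + 1)
  S <- beta * sm[c1, c2, drop = FALSE]
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- S[i - 1, j - 1] +
        .lse2(.lse2(0, M[i - 1, j - 1]),
              .lse2(X[i - 1, j - 1], Y[i - 1, j - 1]))
      X[i, j] <- .lse2(gapO + M[i - 1, j], gapE + X[i - 1, j])
      Y[i, j] <- .lse2(gapO + .lse2(M[i, j - 1], X[i, j - 1]),
                       gapE + Y[i, j - 1])
      X2[i, j] <- .lse2(M[i - 1, j], X2[i - 1, j])
      Y2[i, j] <- .lse2(.lse2(M[i, j - 1], X2[i, j - 1]), Y2[i, j - 1])
    }
  }
  logK <- .lse2(.lse2(0, M[n + 1, m + 1]),
                .lse2(X2[n + 1, m + 1], Y2[n + 1, m + 1]))
  if (log) return(logK)
  if (logK > base::log(.Machine$double.xmax))
    stop(sprintf("LA kernel overflows double precision (log value %.3g); ",
                 logK), "use log = TRUE")
  exp(logK)
}

.kmersOf <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1), function(i)
    paste(chars[i:(i + k - 1)], collapse = ""), "")
}

# score of k-mer x against k-mer y: sum of per-position substitution scores
.kmerScoreMatrix <- function(xs, ys, k, sm) {
  xm <- do.call(rbind, strsplit(xs, ""))
  ym <- do.call(rbind, strsplit(ys, ""))
  s <- matrix(0, length(xs), length(ys))
  for (j in seq_len(k))
    s <- s + sm[xm[, j], ym[, j], drop = FALSE]
  s
}

# neighborhood-occupancy feature vector of a sequence over `features`:
# phi[y] = #{k-mer occurrences x in s : score(x, y) >= score(x, x) - t}
.kmerProfileFeatures <- function(chars, k, t, sm, features) {
  phi <- setNames(numeric(length(features)), features)
  km <- .kmersOf(chars, k)
  if (!length(km) || !length(features)) return(phi)
  tab <- table(km)
  xs <- names(tab)
  sc <- .kmerScoreMatrix(xs, features, k, sm)
  self <- vapply(xs, function(x) {
    cx <- strsplit(x, "")[[1]]
    sum(sm[cbind(cx, cx)])
  }, 0)
  member <- sc >= (self - t)          # rows: observed x, cols: features y
  phi[] <- drop(as.numeric(tab) %*% member)   # weighted by occurrence counts
  phi
}

#' Substitution-neighborhood k-mer kernel
#'
#' A PSSM-free analogue of profile-style k-mer kernels: each k-mer x in a
#' sequence contributes to every feature k-mer y whose substitution score
#' against x is within \code{t} of x's self-score
#' (\eqn{\sum_j s(x_j, y_j) \ge \sum_j s(x_j, x_j) - t}); the kernel is the
#' inner product of the resulting occupancy-count vectors. The feature space
#' is restricted to observed k-mers: the union over the two sequences by
#' default, or a caller-supplied set (the matrix builder passes the
#' dataset-wide union so one fixed feature map underlies the whole matrix).
#'
#' @param s1,s2 amino-acid sequence strings.
#' @param k k-mer length (>= 1).
#' @param t allowed total score degradation (larger t, larger neighborhoods).
#' @param substitutionMatrix matrix name or numeric matrix.
#' @param features optional explicit feature k-mer set.
#' @return kernel value >= 0; 0 with a warning when k exceeds both sequence
#'   lengths.
#' @export
kmerProfileKernel <- function(s1, s2, k = 5, t = 7.5,
                              substitutionMatrix = "BLOSUM62",
                              features = NULL) {
  stopifnot(k >= 1)
  c1 <- .checkProteinSeq(s1, "first sequence")
  c2 <- .checkProteinSeq(s2, "second sequence")
  if (length(c1) < k && length(c2) < k) {
    warning("k exceeds both sequence lengths; kernel is 0")
    return(0)
  }
  sm <- if (is.character(substitutionMatrix))
    .substitutionMatrix(substitutionMatrix) else substitutionMatrix
  if (is.null(features))
    features <- sort(unique(c(.kmersOf(c1, k), .kmersOf(c2, k))))
  phi1 <- .kmerProfileFeatures(c1, k, t, sm, features)
  phi2 <- .kmerProfileFeatures(c2, k, t, sm, features)
  sum(phi1 * phi2)
}

#' Family-hierarchy kernel
#'
#' Number of nodes shared by the two proteins' root-to-leaf paths (leaf
#' included): the inner product of binary ancestor-indicator vectors.
#'
#' @param p1,p2 protein ids mapped in the hierarchy.
#' @param hierarchy a \linkS4class{Hierarchy}.
#' @return non-negative integer count.
#' @export
hierarchyKernel <- function(p1, p2, hierarchy) {
  length(intersect(hierarchyPath(hierarchy, p1),
                   hierarchyPath(hierarchy, p2)))
}

#' Compute a protein-protein kernel matrix
#'
#' For \code{kind = "sw"} the Smith-Waterman score matrix is made PSD by
#' \code{\link{psdRepair}} before post-processing; for \code{kind = "la"}
#' repair is applied defensively if the smallest eigenvalue falls below
#' -1e-6. The k-mer and hierarchy kernels are PSD by construction.
#'
#' @param proteins named \link[Biostrings]{AAStringSet}.
#' @param kind one of \code{"sw"}, \code{"la"}, \code{"kmer_profile"},
#'   \code{"hierarchy"}.
#' @param o,e,beta,k,t kernel hyperparameters (see the pairwise functions).
#' @param substitutionMatrix matrix name or numeric matrix.
#' @param hierarchy required for \code{kind = "hierarchy"}.
#' @param center,normalize post-processing (applied in that order, after any
#'   PSD repair).
#' @return a \linkS4class{KernelMatrix} over the protein ids.
#' @export
proteinKernelMatrix <- function(proteins,
                                kind = c("sw", "la", "kmer_profile",
                                         "hierarchy"),
                                o = 10, e = 0.5, beta = 0.5, k = 5, t = 7.5,
                                substitutionMatrix = "BLOSUM62",
                                hierarchy = NULL,
                                center = TRUE, normalize = TRUE) {
  kind <- match.arg(kind)
  ids <- names(proteins)
  n <- length(proteins)
  seqs <- as.character(proteins)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  sm <- if (is.character(substitutionMatrix))
    .substitutionMatrix(substitutionMatrix) else substitutionMatrix
  if (kind == "sw") {
    for (i in seq_len(n)) for (j in i:n)
      v[i, j] <- v[j, i] <- swScore(seqs[i], seqs[j], o = o, e = e,
                                    substitutionMatrix = sm)
    K <- psdRepair(v)
  } else if (kind == "la") {
    lg <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n)
      lg[i, j] <- lg[j, i] <- laKernel(seqs[i], seqs[j], o = o, e = e,
                                       beta = beta, substitutionMatrix = sm,
                                       log = TRUE)
    # work on a common scale to keep the matrix finite
    v <- exp(lg - max(lg))
    dimnames(v) <- list(ids, ids)
    lmin <- min(eigen((v + t(v)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
    K <- if (lmin < -1e-6) psdRepair(v) else KernelMatrix(v, ids)
  } else if (kind == "kmer_profile") {
    chars <- strsplit(seqs, "")
    features <- sort(unique(unlist(lapply(chars, .kmersOf, k = k))))
    phis <- do.call(rbind, lapply(chars, .kmerProfileFeatures, k = k, t = t,
                                  sm = sm, features = features))
    v <- tcrossprod(phis)
    dimnames(v) <- list(ids, ids)
    K <- KernelMatrix(v, ids)
  } else {
    if (is.null(hierarchy)) stop("hierarchy kernel requires a hierarchy")
    paths <- lapply(ids, hierarchyPath, hierarchy = hierarchy)
    for (i in seq_len(n)) for (j in i:n)
      v[i, j] <- v[j, i] <- length(intersect(paths[[i]], paths[[j]]))
    K <- KernelMatrix(v, ids)
  }
  if (center || normalize)
    K <- centerNormalize(K, center = center, normalize = normalize)
  K
}
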