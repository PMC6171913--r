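# Molecular graph kernels: Tanimoto path kernel and marginalized random-walk
# kernel, plus the shared centering/normalization post-processing.

.BOND_GLYPH <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":")

# adjacency as list of data.frames (neighbor index, bond order) per vertex
.adjacency <- function(g) {
  n <- length(g@atoms)
  adj <- replicate(n, data.frame(v = integer(), order = character()),
                   simplify = FALSE)
  for (r in seq_len(nrow(g@bonds))) {
    i <- g@bonds$i[r]; j <- g@bonds$j[r]; o <- g@bonds$order[r]
    adj[[i]] <- rbind(adj[[i]], data.frame(v = j, order = o))
    adj[[j]] <- rbind(adj[[j]], data.frame(v = i, order = o))
  }
  adj
}

#' Enumerate labeled simple paths of a molecular graph
#'
#' Counts all simple paths (no repeated vertex) containing 1..d atoms. A
#' path's key is the alternating atom/bond label string, canonicalized to
#' the lexicographically smaller of its two orientations so each undirected
#' path is counted once.
#'
#' @param g a \linkS4class{MoleculeGraph}.
#' @param d maximum number of atoms per path (>= 1).
#' @param labels optional replacement atom labels (used for Morgan-refined
#'   variants); defaults to the graph's atom labels.
#' @return named numeric vector mapping label strings to counts.
#' @export
enumerateLabeledPaths <- function(g, d, labels = g@atoms) {
  stopifnot(d >= 1)
  n <- length(g@atoms)
  counts <- new.env(hash = TRUE)
  bump <- function(key) {
    cur <- counts[[key]]
    counts[[key]] <- if (is.null(cur)) 1 else cur + 1
  }
  if (n == 0) return(setNames(numeric(0), character(0)))
  adj <- .adjacency(g)
  onPath <- rep(FALSE, n)
  # directed DFS; paths with >= 2 atoms are discovered twice (once per
  # orientation) and their counts halved afterwards
  extend <- function(v, fwd, rev, atomsLeft) {
    if (atomsLeft == 0) return()
    onPath[v] <<- TRUE
    nb <- adj[[v]]
    for (r in seq_len(nrow(nb))) {
      w <- nb$v[r]
      if (onPath[w]) next
      glyph <- .BOND_GLYPH[[nb$order[r]]]
      f2 <- paste0(fwd, glyph, labels[w])
      r2 <- paste0(labels[w], glyph, rev)
      bump(if (f2 <= r2) f2 else r2)
      extend(w, f2, r2, atomsLeft - 1L)
    }
    onPath[v] <<- FALSE
  }
  for (v in seq_len(n)) {
    bump(labels[v])
    if (d > 1) extend(v, labels[v], labels[v], d - 1L)
  }
  keys <- ls(counts)
  out <- vapply(keys, function(k) counts[[k]], 0)
  multi <- grepl("[-=#:]", keys)
  out[multi] <- out[multi] / 2
  out
}

#' Tanimoto path kernel between two molecules
#'
#' Jaccard similarity of the binary sets of labeled simple paths up to
#' \code{d} atoms (the default), or the count-based min/max Tanimoto when
#' \code{counts = TRUE}.
#'
#' @param g1,g2 \linkS4class{MoleculeGraph} objects (non-empty).
#' @param d maximum path length in atoms.
#' @param counts use min/max count similarity instead of binary presence.
#' @return similarity in [0, 1].
#' @export
tanimotoKernel <- function(g1, g2, d = 8, counts = FALSE) {
  f1 <- enumerateLabeledPaths(g1, d)
  f2 <- enumerateLabeledPaths(g2, d)
  if (!length(f1) && !length(f2))
    stop("both feature sets empty: cannot form Tanimoto ratio")
  if (counts) {
    keys <- union(names(f1), names(f2))
    a <- ifelse(keys %in% names(f1), f1[keys], 0)
    b <- ifelse(keys %in% names(f2), f2[keys], 0)
    sum(pmin(a, b)) / sum(pmax(a, b))
  } else {
    inter <- length(intersect(names(f1), names(f2)))
    inter / (length(f1) + length(f2) - inter)
  }
}

#' Morgan-style label refinement
#'
#' Performs \code{rounds} iterations in which each atom label is replaced by
#' the pair (old label, sorted multiset of (bond label, neighbor label)).
#' Labels are plain strings so refined labels remain comparable across
#' graphs. Zero rounds returns the raw element labels.
#'
#' @param g a \linkS4class{MoleculeGraph}.
#' @param rounds Morgan index (>= 0).
#' @return character vector of refined atom labels.
#' @export
morganRefine <- function(g, rounds) {
  stopifnot(rounds >= 0)
  labels <- g@atoms
  if (rounds == 0) return(labels)
  adj <- .adjacency(g)
  for (it in seq_len(rounds)) {
    labels <- vapply(seq_along(labels), function(v) {
      nb <- adj[[v]]
      if (!nrow(nb)) return(paste0(labels[v], "()"))
      parts <- sort(paste0(.BOND_GLYPH[nb$order], labels[nb$v]))
      paste0(labels[v], "(", paste(parts, collapse = ","), ")")
    }, "")
  }
  labels
}

#' Marginalized random-walk kernel between two molecules
#'
#' Kashima-style marginalized graph kernel: random walks start uniformly,
#' stop with probability \code{q} at each step (probability 1 at isolated
#' vertices, where no continuation exists) and move uniformly over
#' neighbors. A walk pair contributes the product of its joint probability
#' and of atom/bond label matches; labels may first be refined by
#' \code{morganIndex} Morgan rounds. The infinite sum is solved by
#' fixed-point iteration on the matched product graph.
#'
#' @param g1,g2 \linkS4class{MoleculeGraph} objects.
#' @param q stopping probability in (0, 1).
#' @param morganIndex Morgan label-refinement rounds (>= 0).
#' @param tol fixed-point convergence tolerance.
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return similarity >= 0.
#' @export
marginalizedKernel <- function(g1, g2, q = 0.1, morganIndex = 0,
                               tol = 1e-9, maxIter = 10000) {
  stopifnot(q > 0, q < 1)
  l1 <- morganRefine(g1, morganIndex)
  l2 <- morganRefine(g2, morganIndex)
  n1 <- length(l1); n2 <- length(l2)
  if (n1 == 0 || n2 == 0) return(0)
  adj1 <- .adjacency(g1); adj2 <- .adjacency(g2)
  deg1 <- vapply(adj1, nrow, 0L); deg2 <- vapply(adj2, nrow, 0L)
  # product-graph nodes: pairs with matching atom labels
  pn <- which(outer(l1, l2, "==") , arr.ind = TRUE)
  if (!nrow(pn)) return(0)
  np <- nrow(pn)
  idx <- matrix(0L, n1, n2)
  idx[pn] <- seq_len(np)
  stop1 <- ifelse(deg1[pn[, 1]] == 0, 1, q)
  stop2 <- ifelse(deg2[pn[, 2]] == 0, 1, q)
  base <- stop1 * stop2
  # transitions: for product node k, matched neighbor pairs with equal bond
  # labels, weight ((1-q)/deg1)((1-q)/deg2)
  trans <- vector("list", np)
  for (k in seq_len(np)) {
    u <- pn[k, 1]; v <- pn[k, 2]
    nb1 <- adj1[[u]]; nb2 <- adj2[[v]]
    if (!nrow(nb1) || !nrow(nb2)) next
    tlist <- list()
    for (a in seq_len(nrow(nb1))) for (b in seq_len(nrow(nb2))) {
      if (nb1$order[a] != nb2$order[b]) next
      k2 <- idx[nb1$v[a], nb2$v[b]]
      if (k2 == 0L) next
      w <- (1 - q) / deg1[u] * (1 - q) / deg2[v]
      tlist[[length(tlist) + 1L]] <- c(k2, w)
    }
    if (length(tlist)) trans[[k]] <- do.call(rbind, tlist)
  }
  R <- base
  for (it in seq_len(maxIter)) {
    Rnew <- base
    for (k in seq_len(np)) {
      tr <- trans[[k]]
      if (!is.null(tr)) Rnew[k] <- Rnew[k] + sum(tr[, 2] * R[tr[, 1]])
    }
    res <- max(abs(Rnew - R))
    R <- Rnew
    if (res < tol) break
    if (it == maxIter)
      stop(sprintf(
        "marginalized kernel did not converge in %d iterations (residual %g)",
        maxIter, res))
  }
  sum(R) / (n1 * n2)
}

#' Center and/or normalize a kernel matrix
#'
#' Centering is feature-space double centering
#' \eqn{K - \frac{1}{n} J K - \frac{1}{n} K J + \frac{1}{n^2} J K J};
#' cosine normalization \eqn{K_{ij}/\sqrt{K_{ii} K_{jj}}} is applied after
#' centering. A zero diagonal entry at normalization is an error naming the
#' entity.
#'
#' @param K a \linkS4class{KernelMatrix}.
#' @param center,normalize which steps to apply.
#' @return a \linkS4class{KernelMatrix} with updated flags.
#' @export
centerNormalize <- function(K, center = TRUE, normalize = TRUE) {
  v <- K@values
  n <- nrow(v)
  centered <- K@centered
  normalized <- K@normalized
  if (center && n > 0) {
    rm <- rowMeans(v)
    gm <- mean(v)
    v <- v - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
    centered <- TRUE
  }
  if (normalize && n > 0) {
    dg <- diag(v)
    bad <- abs(dg) < .Machine$double.eps * 100
    if (any(bad))
      stop("zero self-similarity at normalization for entity: ",
           paste(K@ids[bad], collapse = ", "))
    if (any(dg < 0))
      stop("negative self-similarity at normalization for entity: ",
           paste(K@ids[dg < 0], collapse = ", "))
    v <- v / sqrt(outer(dg, dg))
    diag(v) <- 1
    normalized <- TRUE
  }
  dimnames(v) <- list(K@ids, K@ids)
  KernelMatrix(v, K@ids, centered = centered, normalized = normalized)
}

#' Compute a molecule-molecule kernel matrix
#'
#' @param molecules named list of \linkS4class{MoleculeGraph}.
#' @param kind \code{"tanimoto"} (path kernel, default d = 8) or
#'   \code{"marginalized"}.
#' @param d Tanimoto path length.
#' @param q marginalized stopping probability.
#' @param morganIndex Morgan refinement rounds for the marginalized kernel.
#' @param counts count-based Tanimoto variant.
#' @param center,normalize post-processing (applied in that order).
#' @return a \linkS4class{KernelMatrix} over the molecule ids.
#' @export
moleculeKernelMatrix <- function(molecules,
                                 kind = c("tanimoto", "marginalized"),
                                 d = 8, q = 0.1, morganIndex = 0,
                                 counts = FALSE,
                                 center = TRUE, normalize = TRUE) {
  kind <- match.arg(kind)
  ids <- names(molecules)
  n <- length(molecules)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  if (kind == "tanimoto") {
    feats <- lapply(molecules, enumerateLabeledPaths, d = d)
    for (i in seq_len(n)) for (j in i:n) {
      f1 <- feats[[i]]; f2 <- feats[[j]]
      if (!length(f1) && !length(f2))
        stop("both feature sets empty for molecules ", ids[i], ", ", ids[j])
      val <- if (counts) {
        keys <- union(names(f1), names(f2))
        a <- ifelse(keys %in% names(f1), f1[keys], 0)
        b <- ifelse(keys %in% names(f2), f2[keys], 0)
        sum(pmin(a, b)) / sum(pmax(a, b))
      } else {
        inter <- length(intersect(names(f1), names(f2)))
        inter / (length(f1) + length(f2) - inter)
      }
      v[i, j] <- v[j, i] <- val
    }
  } else {
    for (i in seq_len(n)) for (j in i:n)
      v[i, j] <- v[j, i] <- marginalizedKernel(molecules[[i]],
                                               molecules[[j]], q = q,
                                               morganIndex = morganIndex)
  }
  K <- KernelMatrix(v, ids)
  if (center || normalize)
    K <- centerNormalize(K, center = center, normalize = normalize)
  K
}
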