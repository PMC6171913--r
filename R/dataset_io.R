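# Readers/writers for the external formats: SMILES lists, FASTA, interaction
# TSVs, dense kernel-matrix TSVs and hierarchy-path TSVs. All files are
# UTF-8/LF plain text.

.ORGANIC_ATOMS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ATOMS <- c("b", "c", "n", "o", "p", "s")
.BOND_SYMBOLS <- c("-" = "1", "=" = "2", "#" = "3", ":" = "ar")

.isAromaticLabel <- function(label) label %in% .AROMATIC_ATOMS

#' Parse a SMILES string into a MoleculeGraph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I), aromatic
#' lower-case atoms, explicit bonds \code{- = # :}, branches, ring closures
#' (digits and \code{\%nn}) and the dot disconnector. Hydrogens are
#' suppressed; aromatic atoms keep their lower-case labels and bonds between
#' two aromatic atoms default to the aromatic bond label. Charges, isotopes,
#' stereo marks and bracket atoms are not supported.
#'
#' @param smiles single SMILES string.
#' @param moleculeId identifier stored in the graph.
#' @return a \linkS4class{MoleculeGraph}.
#' @export
parseSmiles <- function(smiles, moleculeId = "mol") {
  chars <- strsplit(smiles, "")[[1]]
  atoms <- character()
  bonds <- list()
  stack <- integer()      # branch return points
  prev <- NA_integer_     # last atom written
  pendingBond <- NA_character_
  rings <- list()         # closure label -> list(atom, bond)
  i <- 1L
  addBond <- function(a, b, sym) {
    ord <- if (!is.na(sym)) .BOND_SYMBOLS[[sym]]
      else if (.isAromaticLabel(atoms[a]) && .isAromaticLabel(atoms[b])) "ar"
      else "1"
    bonds[[length(bonds) + 1L]] <<- list(i = min(a, b), j = max(a, b),
                                         order = ord)
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    two <- if (i < length(chars)) paste0(ch, chars[i + 1L]) else ""
    if (two %in% .ORGANIC_ATOMS || ch %in% c(.ORGANIC_ATOMS,
                                             .AROMATIC_ATOMS)) {
      label <- if (two %in% .ORGANIC_ATOMS) two else ch
      atoms <- c(atoms, label)
      cur <- length(atoms)
      if (!is.na(prev)) addBond(prev, cur, pendingBond)
      else if (!is.na(pendingBond))
        stop("bond symbol with no preceding atom in SMILES '", smiles, "'")
      pendingBond <- NA_character_
      prev <- cur
      i <- i + nchar(label)
    } else if (ch %in% names(.BOND_SYMBOLS)) {
      pendingBond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES '", smiles, "'")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > length(chars))
          stop("truncated %nn ring closure in SMILES '", smiles, "'")
        lab <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      if (is.na(prev))
        stop("ring closure before any atom in SMILES '", smiles, "'")
      if (!is.null(rings[[lab]])) {
        open <- rings[[lab]]
        sym <- if (!is.na(pendingBond)) pendingBond else open$bond
        addBond(open$atom, prev, sym)
        rings[[lab]] <- NULL
      } else {
        rings[[lab]] <- list(atom = prev, bond = pendingBond)
      }
      pendingBond <- NA_character_
    } else if (ch == ".") {
      prev <- NA_integer_
      pendingBond <- NA_character_
      i <- i + 1L
    } else {
      stop("unsupported SMILES token '", ch, "' in '", smiles, "'")
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES '", smiles, "'")
  if (length(rings)) stop("unclosed ring bond in SMILES '", smiles, "'")
  bdf <- if (length(bonds))
    data.frame(i = vapply(bonds, `[[`, 1L, "i"),
               j = vapply(bonds, `[[`, 1L, "j"),
               order = vapply(bonds, `[[`, "", "order"))
  else data.frame(i = integer(), j = integer(), order = character())
  if (anyDuplicated(paste(bdf$i, bdf$j)))
    stop("duplicate bond in SMILES '", smiles, "'")
  MoleculeGraph(moleculeId, atoms, bdf)
}

#' Write a MoleculeGraph as a SMILES string
#'
#' Depth-first traversal with ring-closure digits for cycle back-edges.
#' Inverse of \code{\link{parseSmiles}} up to atom reordering: parsing the
#' output yields an isomorphic labeled graph.
#'
#' @param g a \linkS4class{MoleculeGraph}.
#' @return a SMILES string.
#' @export
writeSmiles <- function(g) {
  n <- length(g@atoms)
  if (n == 0) return("")
  adj <- vector("list", n)
  bondOf <- new.env()
  for (r in seq_len(nrow(g@bonds))) {
    i <- g@bonds$i[r]; j <- g@bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    assign(pairKey(min(i, j), max(i, j)), g@bonds$order[r], envir = bondOf)
  }
  bondSym <- function(a, b) {
    ord <- get(pairKey(min(a, b), max(a, b)), envir = bondOf)
    aro <- .isAromaticLabel(g@atoms[a]) && .isAromaticLabel(g@atoms[b])
    switch(ord,
           "1" = if (aro) "-" else "",
           "2" = "=", "3" = "#",
           "ar" = if (aro) "" else ":")
  }
  visited <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  ringAt <- vector("list", n)   # tokens to append right after each atom
  nextDigit <- 0L
  ringOpen <- list()
  # iterative DFS to mark tree/back edges and assign ring digits
  order <- integer()
  dfs <- function(start) {
    stack <- list(c(start, NA_integer_))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1]; p <- top[2]
      if (visited[v]) next
      visited[v] <<- TRUE; parent[v] <<- p
      order <<- c(order, v)
      nb <- sort(adj[[v]])
      for (w in rev(nb)) {
        if (!visited[w]) stack[[length(stack) + 1L]] <- c(w, v)
        else if (!identical(w, p)) {
          key <- pairKey(min(v, w), max(v, w))
          if (is.null(ringOpen[[key]])) {
            nextDigit <<- nextDigit + 1L
            tok <- if (nextDigit <= 9) as.character(nextDigit)
                   else sprintf("%%%02d", nextDigit)
            ringOpen[[key]] <<- tok
            ringAt[[w]] <<- c(ringAt[[w]], paste0(bondSym(v, w), tok))
            ringAt[[v]] <<- c(ringAt[[v]], tok)
          }
        }
      }
    }
  }
  # recursive emit along the DFS tree (molecule graphs are small)
  children <- function(v) {
    kids <- adj[[v]][parent[adj[[v]]] == v & !is.na(parent[adj[[v]]])]
    sort(unique(kids))
  }
  emit <- function(v) {
    s <- paste0(g@atoms[v], paste(ringAt[[v]], collapse = ""))
    kids <- children(v)
    if (length(kids)) {
      for (k in seq_along(kids)) {
        sub <- paste0(bondSym(v, kids[k]), emit(kids[k]))
        s <- if (k < length(kids)) paste0(s, "(", sub, ")")
             else paste0(s, sub)
      }
    }
    s
  }
  parts <- character()
  for (start in seq_len(n)) {
    if (!visited[start]) {
      dfs(start)
      parts <- c(parts, emit(start))
    }
  }
  paste(parts, collapse = ".")
}

#' Read a tab-separated id/SMILES file
#'
#' Each line is \code{molecule_id<TAB>SMILES}. Parse failures are reported
#' per line; duplicate ids are an error.
#'
#' @param path file path.
#' @return named list of \linkS4class{MoleculeGraph}.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  errs <- character()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) {
      errs <- c(errs, sprintf("line %d: expected id<TAB>SMILES", k))
      next
    }
    g <- tryCatch(parseSmiles(f[2], f[1]), error = function(e)
      conditionMessage(e))
    if (is.character(g))
      errs <- c(errs, sprintf("line %d (%s): %s", k, f[1], g))
    else {
      if (f[1] %in% names(out))
        errs <- c(errs, sprintf("line %d: duplicate molecule id '%s'", k,
                                f[1]))
      else out[[f[1]]] <- g
    }
  }
  if (length(errs))
    stop("SMILES file errors:\n", paste(errs, collapse = "\n"))
  out
}

#' Write molecules to a tab-separated id/SMILES file
#'
#' @param molecules named list of \linkS4class{MoleculeGraph}.
#' @param path output file.
#' @export
writeSmilesFile <- function(molecules, path) {
  writeLines(vapply(molecules, function(g)
    paste(g@moleculeId, writeSmiles(g), sep = "\t"), ""), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Identifiers are taken from the header up to the first whitespace;
#' sequences are upper-cased. 'X' is allowed; other non-standard residues,
#' empty sequences and duplicate ids are errors.
#'
#' @param path FASTA file.
#' @return an \link[Biostrings]{AAStringSet} named by protein id.
#' @export
readFastaProteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  txt <- toupper(as.character(seqs))
  empty <- nchar(txt) == 0
  if (any(empty))
    stop("empty sequence for protein(s): ",
         paste(ids[empty], collapse = ", "))
  bad <- vapply(strsplit(txt, ""), function(ch)
    any(!ch %in% .AA_ALPHABET), TRUE)
  if (any(bad))
    stop("non amino-acid characters in protein(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::AAStringSet(txt)
  names(out) <- ids
  out
}

#' Write proteins to FASTA
#'
#' @param proteins named \link[Biostrings]{AAStringSet}.
#' @param path output file.
#' @export
writeFastaProteins <- function(proteins, path) {
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

#' Read an interaction edge list into an InteractionDataset
#'
#' Rows are \code{protein_id<TAB>molecule_id[<TAB>label]} with label 1
#' (positive; the default when absent) or 0/-1 (explicit negative). All
#' remaining pairs are implicitly negative. Unknown entity ids and
#' conflicting duplicate rows are errors.
#'
#' @param path TSV file.
#' @param proteins named \link[Biostrings]{AAStringSet}.
#' @param molecules named list of \linkS4class{MoleculeGraph}.
#' @param hierarchy optional \linkS4class{Hierarchy}.
#' @return an \linkS4class{InteractionDataset}.
#' @export
readInteractions <- function(path, proteins, molecules, hierarchy = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pos <- list(); neg <- list(); lab <- new.env()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop(sprintf("line %d: expected at least 2 fields", k))
    p <- f[1]; m <- f[2]
    l <- if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1
    if (is.na(l) || !l %in% c(1, 0, -1))
      stop(sprintf("line %d: label must be 1, 0 or -1", k))
    if (!p %in% names(proteins)) stop("unknown protein ", p)
    if (!m %in% names(molecules)) stop("unknown molecule ", m)
    l <- if (l == 1) 1 else -1
    key <- pairKey(p, m)
    if (!is.null(lab[[key]]) && lab[[key]] != l)
      stop("conflicting labels for pair (", p, ", ", m, ")")
    lab[[key]] <- l
    if (l == 1) pos[[key]] <- c(p, m) else neg[[key]] <- c(p, m)
  }
  toDf <- function(lst) {
    if (!length(lst))
      return(data.frame(protein_id = character(), molecule_id = character()))
    m <- do.call(rbind, lst)
    data.frame(protein_id = m[, 1], molecule_id = m[, 2],
               row.names = NULL)
  }
  InteractionDataset(proteins, molecules, positives = toDf(pos),
                     explicitNegatives = toDf(neg), hierarchy = hierarchy)
}

#' Write an InteractionDataset's labeled pairs to TSV
#'
#' @param dataset an \linkS4class{InteractionDataset}.
#' @param path output file.
#' @export
writeInteractions <- function(dataset, path) {
  pos <- dataset@positives; neg <- dataset@explicitNegatives
  lines <- c(
    if (nrow(pos)) paste(pos$protein_id, pos$molecule_id, "1", sep = "\t"),
    if (nrow(neg)) paste(neg$protein_id, neg$molecule_id, "-1", sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense kernel matrix from TSV
#'
#' First row and first column hold entity identifiers; an optional leading
#' comment line \code{# centered=... normalized=...} restores the
#' post-processing flags. Asymmetry beyond 1e-8 and row/column id mismatches
#' are errors.
#'
#' @param path TSV file.
#' @return a \linkS4class{KernelMatrix}.
#' @export
readKernelMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  centered <- FALSE; normalized <- FALSE
  if (length(lines) && startsWith(lines[1], "#")) {
    centered <- grepl("centered=TRUE", lines[1], fixed = TRUE)
    normalized <- grepl("normalized=TRUE", lines[1], fixed = TRUE)
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  colIds <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rowIds <- vapply(rows, `[`, "", 1)
  if (!identical(rowIds, colIds))
    stop("kernel matrix row ids do not match column ids")
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(colIds))))
  if (any(!is.finite(vals))) stop("non-numeric cell in kernel matrix")
  dimnames(vals) <- list(rowIds, colIds)
  if (max(abs(vals - t(vals))) > 1e-8)
    stop("kernel matrix asymmetric beyond tolerance 1e-8")
  KernelMatrix(vals, rowIds, centered = centered, normalized = normalized)
}

#' Write a KernelMatrix to dense TSV (full double precision)
#'
#' @param K a \linkS4class{KernelMatrix}.
#' @param path output file.
#' @export
writeKernelMatrix <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# centered=%s normalized=%s", K@centered,
                     K@normalized), con)
  writeLines(paste(c("id", K@ids), collapse = "\t"), con)
  for (r in seq_along(K@ids))
    writeLines(paste(c(K@ids[r],
                       format(K@values[r, ], digits = 17, trim = TRUE,
                              scientific = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a protein family hierarchy from ancestor-path TSV
#'
#' Rows are \code{protein_id<TAB>root/child/.../leaf}. Node identity is the
#' full path prefix, so equal-named nodes under different parents stay
#' distinct and the structure is a forest by construction. Two rows giving
#' one protein different paths is an error.
#'
#' @param path TSV file.
#' @return a \linkS4class{Hierarchy}.
#' @export
readHierarchy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- character(); parent <- character(); leafOf <- character()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2) stop(sprintf("line %d: expected id<TAB>path", k))
    pid <- f[1]
    labels <- strsplit(f[2], "/", fixed = TRUE)[[1]]
    if (!length(labels) || any(!nzchar(labels)))
      stop(sprintf("line %d: malformed path '%s'", k, f[2]))
    ids <- vapply(seq_along(labels), function(d)
      paste(labels[seq_len(d)], collapse = "/"), "")
    if (pid %in% names(leafOf)) {
      if (!identical(leafOf[[pid]], ids[length(ids)]))
        stop("conflicting hierarchy paths for protein ", pid)
      next
    }
    nodes <- union(nodes, ids)
    if (length(ids) > 1)
      for (d in 2:length(ids)) parent[ids[d]] <- ids[d - 1]
    leafOf[pid] <- ids[length(ids)]
  }
  new("Hierarchy", nodes = nodes, parent = parent, leafOf = leafOf)
}

#' Write a Hierarchy to ancestor-path TSV
#'
#' @param hierarchy a \linkS4class{Hierarchy}.
#' @param path output file.
#' @export
writeHierarchy <- function(hierarchy, path) {
  lines <- vapply(names(hierarchy@leafOf), function(pid)
    paste(pid, hierarchy@leafOf[[pid]], sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# Root-to-leaf node path of a protein (node ids, root first).
hierarchyPath <- function(hierarchy, protein_id) {
  if (!protein_id %in% names(hierarchy@leafOf))
    stop("protein ", protein_id, " is not mapped in the hierarchy")
  cur <- hierarchy@leafOf[[protein_id]]
  path <- cur
  while (cur %in% names(hierarchy@parent)) {
    cur <- hierarchy@parent[[cur]]
    path <- c(cur, path)
  }
  path
}
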